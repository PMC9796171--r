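#' Specification of a synthetic cell-length profile
#'
#' Synthetic profiles emulate cortical cell-length measurements along the
#' root: a piecewise-linear mean (one row of `segments` per growth regime)
#' plus additive Gaussian measurement noise, truncated so no cell is
#' shorter than `min_length`. Presets:
#' * `"wt_like"` — three regimes: a near-flat proliferation domain (25
#'   cells from 4.5 µm, slope 0.05 µm/cell), a moderate transition domain
#'   (10 cells from 6 µm, slope 1.5) and a steep elongation zone (12 cells
#'   from 24 µm, slope 12);
#' * `"mto2_like"` — two regimes: a TD-like domain (12 cells from 6 µm,
#'   slope 1.5) then the elongation zone (10 cells from 25 µm, slope 12);
#' * `"exhausted"` — a single monotone regime (18 cells from 7 µm, slope
#'   3.5), the profile of a root whose meristem is spent.
#'
#' @param preset One of `"wt_like"`, `"mto2_like"`, `"exhausted"`,
#'   `"custom"`.
#' @param segments For `"custom"`: a data frame with columns `n_cells`,
#'   `start_length` (µm) and `slope` (µm per cell), one row per regime.
#' @param noise_sd Additive Gaussian noise SD (µm); default 0.4, small
#'   relative to the ~4-5 µm proliferation-domain cells.
#' @param between_root_cv Coefficient of variation of the multiplicative
#'   jitter applied to segment start lengths and slopes across a cohort;
#'   default 0.1.
#' @param min_length Truncation floor for generated lengths (µm);
#'   default 0.5.
#' @return A list of class `profile_spec`.
#' @export
#' @examples
#' profile_spec("mto2_like", noise_sd = 0)
profile_spec <- function(preset = c("wt_like", "mto2_like", "exhausted", "custom"),
                         segments = NULL,
                         noise_sd = 0.4,
                         between_root_cv = 0.1,
                         min_length = 0.5) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(segments)) {
      stop("`segments` is required for a custom spec", call. = FALSE)
    }
  } else {
    segments <- switch(preset,
      wt_like = data.frame(
        n_cells = c(25L, 10L, 12L),
        start_length = c(4.5, 6, 24),
        slope = c(0.05, 1.5, 12)
      ),
      mto2_like = data.frame(
        n_cells = c(12L, 10L),
        start_length = c(6, 25),
        slope = c(1.5, 12)
      ),
      exhausted = data.frame(
        n_cells = 18L, start_length = 7, slope = 3.5
      )
    )
  }
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("n_cells", "start_length", "slope") %in% names(segments)))
  if (any(segments$n_cells < 3)) {
    stop("each segment must contain at least 3 cells", call. = FALSE)
  }
  if (any(segments$start_length <= 0)) {
    stop("segment start lengths must be positive", call. = FALSE)
  }
  if (noise_sd < 0 || between_root_cv < 0 || min_length <= 0) {
    stop("noise_sd and between_root_cv must be >= 0 and min_length > 0",
      call. = FALSE
    )
  }
  structure(
    list(
      preset = preset, segments = segments, noise_sd = noise_sd,
      between_root_cv = between_root_cv, min_length = min_length
    ),
    class = "profile_spec"
  )
}

# Piecewise-linear mean lengths of a segments table.
segments_mean <- function(segments) {
  unlist(lapply(seq_len(nrow(segments)), function(k) {
    segments$start_length[k] +
      segments$slope[k] * (seq_len(segments$n_cells[k]) - 1)
  }), use.names = FALSE)
}

#' Generate one synthetic cell-length profile
#'
#' @param spec A [profile_spec()].
#' @param seed Integer seed; identical spec and seed reproduce the profile
#'   exactly. The global RNG state is left untouched.
#' @param root_id Identifier stored in the output.
#' @return A tibble with columns `root_id`, `cell_index` (1-based from the
#'   QC-adjacent cell) and `length_um`; all lengths strictly positive.
#' @export
#' @examples
#' generate_profile(profile_spec("wt_like", noise_sd = 0), seed = 1)
generate_profile <- function(spec, seed = 1L, root_id = "root1") {
  stopifnot(inherits(spec, "profile_spec"))
  mu <- segments_mean(spec$segments)
  lengths <- withr::with_seed(as.integer(seed), {
    pmax(mu + stats::rnorm(length(mu), 0, spec$noise_sd), spec$min_length)
  })
  tibble::tibble(
    root_id = root_id,
    cell_index = seq_along(lengths),
    length_um = lengths
  )
}

#' Generate a cohort of synthetic profiles
#'
#' Draws `k` profiles whose segment start lengths and slopes are jittered
#' across roots by a multiplicative factor `1 + between_root_cv * z`
#' (`z ~ N(0, 1)`, factor floored at 0.2), emulating between-root
#' variability; within-root noise follows the spec.
#'
#' @inheritParams generate_profile
#' @param k Number of roots (>= 1).
#' @param id_prefix Prefix of the generated `root_id`s.
#' @return A tibble in the same format as [generate_profile()], with `k`
#'   distinct `root_id`s.
#' @export
#' @examples
#' generate_cohort(profile_spec("wt_like"), k = 3, seed = 7)
generate_cohort <- function(spec, k, seed = 1L, id_prefix = spec$preset) {
  stopifnot(inherits(spec, "profile_spec"))
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    dplyr::bind_rows(lapply(seq_len(k), function(i) {
      seg <- spec$segments
      if (spec$between_root_cv > 0) {
        jit <- function(v) {
          v * pmax(1 + stats::rnorm(length(v), 0, spec$between_root_cv), 0.2)
        }
        seg$start_length <- jit(seg$start_length)
        seg$slope <- sign(seg$slope) * jit(abs(seg$slope) + 1e-12)
      }
      mu <- segments_mean(seg)
      lengths <- pmax(
        mu + stats::rnorm(length(mu), 0, spec$noise_sd),
        spec$min_length
      )
      tibble::tibble(
        root_id = sprintf("%s_%03d", id_prefix, i),
        cell_index = seq_along(lengths),
        length_um = lengths
      )
    }))
  })
}
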