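# Multiple-structural-change (MSC) zonation of cortical cell-length
# profiles: exact dynamic-programming placement of breakpoints between
# per-segment ordinary-least-squares lines, BIC selection of the breakpoint
# count, and annotation of the root growth domains.

#' Minimal-segment fraction f for a sample of profiles
#'
#' `f` is the smallest two-decimal fraction such that `f * n_s >= 3`, where
#' `n_s` is the number of cells in the smallest cell-length profile of the
#' sample, i.e. `ceiling(300 / n_s) / 100`. It sets, per root, the minimal
#' number of cells `h = f * n` that may constitute a longitudinal domain.
#'
#' @param data A profiles data frame (`root_id`, `cell_index`, `length_um`),
#'   a list/vector of per-root cell counts, or a single profile's lengths.
#' @return The fraction `f` (two decimals).
#' @seealso [compute_h()]
#' @export
#' @examples
#' compute_f(c(rep(1, 25))) # single root of 25 cells -> 0.12
compute_f <- function(data) {
  ns <- profile_sizes(data)
  n_s <- min(ns)
  if (n_s < 7) {
    stop(sprintf(
      "smallest profile has %d cells; at least 7 are required for a feasible minimal segment (3 <= h < n/2)",
      n_s
    ), call. = FALSE)
  }
  ceiling(300 / n_s) / 100
}

# Per-root sizes from any accepted input shape.
profile_sizes <- function(data) {
  if (is.data.frame(data)) {
    stopifnot(all(c("root_id", "length_um") %in% names(data)))
    as.integer(table(data$root_id))
  } else if (is.list(data)) {
    vapply(data, length, 1L)
  } else {
    length(data)
  }
}

#' Minimal segment size h for one profile
#'
#' `h = floor(f * n)`, constrained to `3 <= h < n/2` (a linear segment has
#' two regressors, so fewer than 3 cells cannot constitute a domain); an
#' infeasible profile — `f * n < 3`, which cannot happen when `f` comes
#' from [compute_f()] on the same sample, or `h >= n/2` — raises an error
#' rather than silently clamping.
#'
#' @param f Fraction from [compute_f()].
#' @param n Number of cells in the profile.
#' @param root_id Optional identifier used in error messages.
#' @return Integer minimal segment size.
#' @export
#' @examples
#' compute_h(0.12, 25) # 3
compute_h <- function(f, n, root_id = NULL) {
  if (n < 7) {
    stop(sprintf(
      "profile%s has %d cells; at least 7 are required",
      if (is.null(root_id)) "" else paste0(" '", root_id, "'"), n
    ), call. = FALSE)
  }
  if (f * n < 3 - 1e-9) {
    stop(sprintf(
      "minimal segment f * n = %.2f is below 3 for profile%s",
      f * n, if (is.null(root_id)) "" else paste0(" '", root_id, "'")
    ), call. = FALSE)
  }
  h <- as.integer(floor(f * n + 1e-9))
  if (h >= n / 2) {
    stop(sprintf(
      "minimal segment h = %d is not smaller than n/2 = %g for profile%s",
      h, n / 2, if (is.null(root_id)) "" else paste0(" '", root_id, "'")
    ), call. = FALSE)
  }
  h
}

# Segment RSS in O(1) from cumulative sums over x = 1..n (cell index) and
# y = lengths. Returns the residual sum of squares of the OLS line fitted
# to points i..j.
make_rss_fn <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x))
  cxy <- c(0, cumsum(x * y))
  cyy <- c(0, cumsum(y * y))
  function(i, j) {
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]
    sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]
    sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    vxx <- sxx - sx * sx / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy * sy / m
    rss <- if (vxx <= 0) vyy else vyy - vxy * vxy / vxx
    max(rss, 0)
  }
}

# OLS coefficients of the line fitted to y[i..j] over x = i..j.
segment_fit <- function(y, i, j) {
  x <- i:j
  yy <- y[i:j]
  vxx <- sum((x - mean(x))^2)
  slope <- if (vxx == 0) 0 else sum((x - mean(x)) * (yy - mean(yy))) / vxx
  intercept <- mean(yy) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

#' Optimal placement of m breakpoints in a cell-length profile
#'
#' Fits `m + 1` ordinary-least-squares lines (intercept and slope over cell
#' index) to contiguous segments of at least `h` cells each, choosing the
#' segment ends that minimise the total residual sum of squares by dynamic
#' programming over admissible segment ends. The optimum is exact and
#' deterministic; RSS ties are broken toward the lexicographically smallest
#' breakpoint indices.
#'
#' @param lengths Numeric vector of ordered cell lengths (µm), index 1 at
#'   the initial (QC-adjacent) cell; all values must be positive.
#' @param m Number of breakpoints (>= 0).
#' @param h Minimal segment size (from [compute_h()]).
#' @return An object of class `msc_model`: a list with `m`, `breakpoints`
#'   (last cell index of each of the first `m` segments), `segments`
#'   (tibble: `segment`, `start`, `end`, `n`, `intercept`, `slope`), `rss`,
#'   `bic`, `n`, `h`.
#' @export
#' @examples
#' y <- c(rep(5, 10), seq(6, 24, by = 2))
#' fit_breakpoints(y, m = 1, h = 3)
fit_breakpoints <- function(lengths, m, h) {
  y <- as.numeric(lengths)
  n <- length(y)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("all cell lengths must be positive and finite", call. = FALSE)
  }
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  if (h < 3) stop("`h` must be >= 3", call. = FALSE)
  if ((m + 1) * h > n) {
    stop(sprintf(
      "infeasible segmentation: (m + 1) * h = %d exceeds n = %d",
      (m + 1) * h, n
    ), call. = FALSE)
  }
  rss_fn <- make_rss_fn(y)

  # D[k, j]: minimal RSS of splitting cells 1..j into k segments (each >= h)
  # back[k, j]: end of segment k - 1 in the optimum
  K <- m + 1
  D <- matrix(Inf, nrow = K, ncol = n)
  back <- matrix(NA_integer_, nrow = K, ncol = n)
  for (j in h:n) D[1, j] <- rss_fn(1, j)
  if (K > 1) {
    for (k in 2:K) {
      for (j in (k * h):n) {
        best <- Inf
        best_i <- NA_integer_
        for (i in ((k - 1) * h):(j - h)) {
          cand <- D[k - 1, i] + rss_fn(i + 1, j)
          # strict improvement keeps the earliest (lexicographically
          # smallest) breakpoints on ties
          if (cand < best - 1e-12) {
            best <- cand
            best_i <- i
          }
        }
        D[k, j] <- best
        back[k, j] <- best_i
      }
    }
  }

  ends <- integer(K)
  ends[K] <- n
  if (K > 1) {
    for (k in K:2) ends[k - 1] <- back[k, ends[k]]
  }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  fits <- t(vapply(
    seq_len(K),
    function(k) segment_fit(y, starts[k], ends[k]),
    numeric(2)
  ))
  rss <- D[K, n]
  structure(
    list(
      m = as.integer(m),
      breakpoints = if (m > 0) ends[seq_len(m)] else integer(0),
      segments = tibble::tibble(
        segment = seq_len(K), start = starts, end = ends,
        n = ends - starts + 1L,
        intercept = fits[, "intercept"], slope = fits[, "slope"]
      ),
      rss = rss, bic = msc_bic(rss, n, m), n = n, h = as.integer(h),
      lengths = y
    ),
    class = "msc_model"
  )
}

# BIC of a segmented Gaussian regression: log-likelihood
# LL = -(n/2) (log(2 pi) + log(RSS/n) + 1); parameters are the 2 (m + 1)
# segment coefficients, the m breakpoints and the error variance.
msc_bic <- function(rss, n, m) {
  ll <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  npar <- 2 * (m + 1) + m + 1
  -2 * ll + npar * log(n)
}

#' @export
print.msc_model <- function(x, ...) {
  cat(sprintf(
    "<msc_model> n = %d cells, m = %d breakpoint(s)%s, RSS = %.4g, BIC = %.4g\n",
    x$n, x$m,
    if (x$m > 0) paste0(" at ", paste(x$breakpoints, collapse = ", ")) else "",
    x$rss, x$bic
  ))
  invisible(x)
}

#' Select the most parsimonious breakpoint count by BIC
#'
#' Fits models with `m = 0 .. m_max` breakpoints (skipping infeasible `m`)
#' and returns the minimum-BIC model; BIC ties resolve to the smaller `m`.
#'
#' @inheritParams fit_breakpoints
#' @param m_max Largest breakpoint count considered (default 2).
#' @return The selected `msc_model`, with a `bic_table` element listing
#'   `m`, `rss` and `bic` for every feasible fit.
#' @export
#' @examples
#' y <- c(rep(5, 10), seq(6, 24, by = 2))
#' select_breakpoints(y, h = 3)$m
select_breakpoints <- function(lengths, h, m_max = 2) {
  if (m_max < 0) stop("`m_max` must be >= 0", call. = FALSE)
  n <- length(lengths)
  feasible <- Filter(function(m) (m + 1) * h <= n, 0:m_max)
  if (length(feasible) == 0) {
    stop("no feasible breakpoint count for this profile", call. = FALSE)
  }
  fits <- lapply(feasible, function(m) fit_breakpoints(lengths, m, h))
  bics <- vapply(fits, function(f) f$bic, 0)
  best <- fits[[which.min(bics)]] # which.min returns the first (smallest m)
  best$bic_table <- tibble::tibble(
    m = as.integer(feasible),
    rss = vapply(fits, function(f) f$rss, 0),
    bic = bics
  )
  best
}

#' Annotate root growth domains from a fitted breakpoint model
#'
#' Maps the selected breakpoint count onto domain labels: with two
#' breakpoints the segments are PD, TD and EZ; with one breakpoint the RAM
#' is represented by the TD alone (TD then EZ); with none all cells are
#' `undetermined` (no RAM/EZ boundary detected). Per-domain cell counts,
#' summed lengths and mean lengths are reported.
#'
#' @param model An `msc_model` fitted on the profile.
#' @param force_m Optionally refit with a fixed breakpoint count before
#'   annotating (`force_m = 2` is the wild-type convention).
#' @return A list of class `msc_domains`: `labels` (per cell), `domains`
#'   (tibble: `domain`, `n_cells`, `total_length_um`, `mean_length_um`) and
#'   the (possibly refitted) `model`.
#' @export
annotate_domains <- function(model, force_m = NULL) {
  stopifnot(inherits(model, "msc_model"))
  if (!is.null(force_m) && force_m != model$m) {
    model <- fit_breakpoints(model$lengths, m = force_m, h = model$h)
  }
  n <- model$n
  labels <- switch(as.character(model$m),
    "2" = rep(c("PD", "TD", "EZ"), times = model$segments$n),
    "1" = rep(c("TD", "EZ"), times = model$segments$n),
    "0" = rep("undetermined", n),
    rep(as.character(seq_len(model$m + 1)), times = model$segments$n)
  )
  if (model$m %in% 1:2) {
    doms <- unique(labels)
    stats_tbl <- tibble::tibble(
      domain = doms,
      n_cells = vapply(doms, function(d) sum(labels == d), 0L,
        USE.NAMES = FALSE
      ),
      total_length_um = vapply(
        doms, function(d) sum(model$lengths[labels == d]), 0,
        USE.NAMES = FALSE
      ),
      mean_length_um = vapply(
        doms, function(d) mean(model$lengths[labels == d]), 0,
        USE.NAMES = FALSE
      )
    )
  } else {
    stats_tbl <- tibble::tibble(
      domain = character(0), n_cells = integer(0),
      total_length_um = numeric(0), mean_length_um = numeric(0)
    )
  }
  structure(
    list(labels = labels, domains = stats_tbl, model = model),
    class = "msc_domains"
  )
}

#' @export
print.msc_domains <- function(x, ...) {
  cat("<msc_domains> m =", x$model$m, "\n")
  print(x$domains)
  invisible(x)
}

#' MSC analysis of a cohort of cell-length profiles
#'
#' Computes the shared minimal-segment fraction `f` from the smallest
#' profile of the sample, then per root the minimal segment size `h`,
#' selects the breakpoint count by BIC (or applies the fixed two-breakpoint
#' wild-type convention) and annotates domains.
#'
#' @param data Profiles data frame with columns `root_id`, `cell_index`
#'   (contiguous from 1 within each root) and `length_um`; see
#'   [read_profiles()].
#' @param genotype_mode `"auto"` (BIC selection per root, the mutant-style
#'   analysis), `"wt"` (always two breakpoints) or `"mutant"` (alias of
#'   `"auto"`).
#' @param m_max Largest breakpoint count considered (default 2).
#' @return A list of class `msc_sample`: `per_root` (tibble: `root_id`,
#'   `n`, `h`, `m`, `bp1`, `bp2`, per-domain summary columns), `cohort`
#'   (tibble of percentages of the `m` classes), `f`, and `fits` (named
#'   list of `msc_domains`).
#' @export
#' @examples
#' cohort <- generate_cohort(profile_spec("wt_like"), k = 3, seed = 1)
#' classify_sample(cohort)$cohort
classify_sample <- function(data, genotype_mode = c("auto", "wt", "mutant"),
                            m_max = 2) {
  genotype_mode <- match.arg(genotype_mode)
  data <- validate_profiles(data)
  f <- compute_f(data)
  roots <- split(data, factor(data$root_id, levels = unique(data$root_id)))
  fits <- lapply(names(roots), function(id) {
    y <- roots[[id]]$length_um[order(roots[[id]]$cell_index)]
    h <- compute_h(f, length(y), root_id = id)
    model <- if (genotype_mode == "wt") {
      fit_breakpoints(y, m = 2, h = h)
    } else {
      select_breakpoints(y, h = h, m_max = m_max)
    }
    annotate_domains(model)
  })
  names(fits) <- names(roots)

  per_root <- dplyr::bind_rows(lapply(names(fits), function(id) {
    dm <- fits[[id]]
    md <- dm$model
    bp <- md$breakpoints
    dom_stat <- function(d, col) {
      v <- dm$domains[[col]][dm$domains$domain == d]
      if (length(v) == 0) NA_real_ else v
    }
    tibble::tibble(
      root_id = id, n = md$n, h = md$h, m = md$m,
      bp1 = if (length(bp) >= 1) bp[1] else NA_integer_,
      bp2 = if (length(bp) >= 2) bp[2] else NA_integer_,
      rss = md$rss, bic = md$bic,
      pd_cells = dom_stat("PD", "n_cells"),
      td_cells = dom_stat("TD", "n_cells"),
      ez_cells = dom_stat("EZ", "n_cells"),
      pd_mean_um = dom_stat("PD", "mean_length_um"),
      td_mean_um = dom_stat("TD", "mean_length_um"),
      ez_mean_um = dom_stat("EZ", "mean_length_um")
    )
  }))
  cohort <- per_root |>
    dplyr::count(.data$m, name = "n_roots") |>
    dplyr::mutate(pct = 100 * .data$n_roots / sum(.data$n_roots))
  structure(
    list(per_root = per_root, cohort = cohort, f = f, fits = fits,
         genotype_mode = genotype_mode),
    class = "msc_sample"
  )
}

#' @export
print.msc_sample <- function(x, ...) {
  cat(sprintf(
    "<msc_sample> %d roots, f = %.2f (mode %s)\n",
    nrow(x$per_root), x$f, x$genotype_mode
  ))
  print(x$cohort)
  invisible(x)
}
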