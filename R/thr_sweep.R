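#' Default sweep ranges for the steady-state Thr model
#'
#' Km constants for the synthases are explored over 1-1000 and the usage
#' rate `delta` over 1-10; the catabolic constants `Km3`, `Km4`, `Km5`
#' (extended variant) over 1-100.
#'
#' @param variant `"synthesis_only"` or `"extended"`.
#' @return Named list of `c(min, max)` ranges.
#' @export
default_sweep_ranges <- function(variant = c("synthesis_only", "extended")) {
  variant <- match.arg(variant)
  ranges <- list(
    Km1 = c(1, 1000), Km2 = c(1, 1000), delta = c(1, 10)
  )
  if (variant == "extended") {
    ranges <- c(ranges, list(Km3 = c(1, 100), Km4 = c(1, 100), Km5 = c(1, 100)))
  }
  ranges
}

#' Parameter sweep of the steady-state Thr model
#'
#' Samples `n_sets` parameter sets by Latin-hypercube over the given ranges,
#' evaluates the wild-type and `mto2-2` profiles for each set, and applies
#' the paper-selection criterion: a set is `accepted` when the whole-root
#' (position-summed) mutant/Wt Thr ratio is at least 1.5, the experimentally
#' established fold-difference. Wild-type sets violating the
#' two-orders-of-magnitude activity constraint `Km2 >= 100 * Km1` are
#' resampled uniformly over the admissible region.
#'
#' @param n_sets Number of parameter sets (>= 1).
#' @param ranges Named list of `c(min, max)` ranges per parameter; see
#'   [default_sweep_ranges()].
#' @param seed Integer seed; the sweep is fully reproducible.
#' @param variant Model variant.
#' @param gradients Expression gradients; default [default_gradients()].
#' @param positions Positions at which profiles are evaluated.
#' @param tsy2_compensation Mutant compensation factor; see [thr_params()].
#' @param min_ratio Acceptance threshold on the whole-root ratio
#'   (default 1.5).
#'
#' @return A tibble of class `thr_sweep`, one row per parameter set, with
#'   the sampled parameters, `whole_root_thr_ratio` (mutant/Wt summed Thr),
#'   `scn_thr_ratio` (mutant/Wt Thr at position 0), the pattern flags
#'   `wt_max_at_scn`, `mutant_ez_elevated`, `mutant_scn_deficient`,
#'   `gly_ile_max_at_scn`, and `accepted`.
#' @export
#' @examples
#' sweep_thr_parameters(n_sets = 5, seed = 1)
sweep_thr_parameters <- function(n_sets,
                                 ranges = default_sweep_ranges(variant),
                                 seed = 1L,
                                 variant = c("synthesis_only", "extended"),
                                 gradients = default_gradients(),
                                 positions = seq(0, 1, length.out = 101),
                                 tsy2_compensation = 250,
                                 min_ratio = 1.5) {
  variant <- match.arg(variant)
  if (!is.numeric(n_sets) || n_sets < 1) {
    stop("`n_sets` must be >= 1", call. = FALSE)
  }
  if (length(ranges) == 0 || any(!vapply(ranges, length, 1L) == 2L)) {
    stop("`ranges` must be a non-empty list of c(min, max) pairs",
      call. = FALSE
    )
  }
  n_sets <- as.integer(n_sets)
  pars <- names(ranges)

  samples <- withr::with_seed(as.integer(seed), {
    u <- lhs::randomLHS(n_sets, length(pars))
    colnames(u) <- pars
    for (p in pars) {
      u[, p] <- ranges[[p]][1] + u[, p] * (ranges[[p]][2] - ranges[[p]][1])
    }
    # enforce Km2 >= 100 * Km1 for the wild type by uniform rejection
    # resampling over the joint (Km1, Km2) range
    bad <- which(u[, "Km2"] < 100 * u[, "Km1"])
    while (length(bad) > 0) {
      u[bad, "Km1"] <- stats::runif(
        length(bad), ranges[["Km1"]][1], ranges[["Km1"]][2]
      )
      u[bad, "Km2"] <- stats::runif(
        length(bad), ranges[["Km2"]][1], ranges[["Km2"]][2]
      )
      bad <- which(u[, "Km2"] < 100 * u[, "Km1"])
    }
    u
  })

  genes <- if (variant == "extended") {
    c("MTO2", "TSY2", "THA12", "OMR1")
  } else {
    c("MTO2", "TSY2")
  }
  e <- eval_gradients(gradients, positions, genes)

  eval_set <- function(i) {
    row <- samples[i, ]
    make_params <- function(genotype) {
      thr_params(
        S = 1,
        Km1 = row[["Km1"]], Km2 = row[["Km2"]],
        Km3 = if ("Km3" %in% pars) row[["Km3"]] else 10,
        Km4 = if ("Km4" %in% pars) row[["Km4"]] else 10,
        Km5 = if ("Km5" %in% pars) row[["Km5"]] else 10,
        delta = row[["delta"]], genotype = genotype,
        tsy2_compensation = tsy2_compensation
      )
    }
    wt <- make_params("Wt")
    mut <- make_params("mto2-2")
    if (variant == "synthesis_only") {
      thr_wt <- steady_state_synthesis(wt, e$MTO2, e$TSY2)
      thr_mut <- steady_state_synthesis(mut, e$MTO2, e$TSY2)
      gly_ile_flag <- NA
      prof_wt <- tibble::tibble(
        position = positions, thr = thr_wt, gly = NA_real_, ile = NA_real_
      )
      prof_mut <- tibble::tibble(
        position = positions, thr = thr_mut, gly = NA_real_, ile = NA_real_
      )
    } else {
      ss_wt <- steady_state_extended(wt, e$MTO2, e$TSY2, e$THA12, e$OMR1)
      ss_mut <- steady_state_extended(mut, e$MTO2, e$TSY2, e$THA12, e$OMR1)
      thr_wt <- ss_wt$thr
      thr_mut <- ss_mut$thr
      prof_wt <- tibble::tibble(position = positions, !!!ss_wt)
      prof_mut <- tibble::tibble(position = positions, !!!ss_mut)
      gly_ile_flag <- classify_pattern(prof_wt)$gly_ile_max_at_scn
    }
    pat_wt <- classify_pattern(prof_wt)
    pat_mut <- classify_pattern(prof_mut)
    ratio <- sum(thr_mut) / sum(thr_wt)
    tibble::tibble(
      set = i,
      !!!as.list(row),
      whole_root_thr_ratio = ratio,
      scn_thr_ratio = thr_mut[1] / thr_wt[1],
      wt_max_at_scn = pat_wt$max_at_scn,
      mutant_ez_elevated = pat_mut$ez_elevated,
      mutant_scn_deficient = thr_mut[1] < thr_wt[1],
      gly_ile_max_at_scn = gly_ile_flag,
      accepted = ratio >= min_ratio
    )
  }

  out <- dplyr::bind_rows(lapply(seq_len(n_sets), eval_set))
  attr(out, "variant") <- variant
  attr(out, "seed") <- as.integer(seed)
  attr(out, "min_ratio") <- min_ratio
  class(out) <- c("thr_sweep", class(out))
  out
}
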