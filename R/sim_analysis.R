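#' Compare two cell-length distributions
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie and
#' continuity correction, appropriate for heavily tied grid-valued lengths)
#' and an unpaired two-tailed Student's t-test.
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @return A one-row tibble: `mwu_p`, `t_p`, `n_a`, `n_b`.
#' @export
#' @examples
#' compare_distributions(c(4, 5, 6, 7), c(10, 11, 12, 13))
compare_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample must contain at least 3 observations", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    # fully degenerate: no location shift detectable
    mwu_p <- 1
    t_p <- 1
  } else {
    mwu_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    t_p <- tryCatch(
      stats::t.test(a, b, var.equal = TRUE)$p.value,
      error = function(e) {
        # constant samples with different means: complete separation
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      }
    )
  }
  tibble::tibble(mwu_p = mwu_p, t_p = t_p, n_a = length(a), n_b = length(b))
}

#' Time window where mutant RAM cells match wild-type TD cells
#'
#' For every recorded time shared by the two trajectories, compares the
#' mutant RAM cell-length distribution with the wild-type TD (and PD)
#' distributions by Mann-Whitney U test, and returns the maximal contiguous
#' interval `[t1, t2]` in which mutant RAM and Wt TD are statistically
#' indistinguishable (`p > alpha`). Inside the window the comparison with
#' the Wt PD is also reported (`pd_separated`: `p <= alpha` throughout),
#' capturing the result that the mutant RAM behaves as the wild-type
#' transition domain, not as the proliferation domain.
#'
#' @param traj_mut,traj_wt `root_trajectory` objects on the same time grid.
#' @param alpha Significance level; default 0.05.
#' @param file_index Analysis cell file; default 1.
#' @param min_n Minimum per-sample size for a comparison (default 3); times
#'   with smaller samples are skipped.
#' @return A list of class `indist_window`: `window` (one-row tibble with
#'   `t1`, `t2`, `n_times`, `pd_separated`, `empty`) and `by_time` (per-time
#'   p-values and sample sizes).
#' @export
find_indistinguishable_window <- function(traj_mut, traj_wt, alpha = 0.05,
                                          file_index = 1, min_n = 3) {
  times <- intersect(
    round(traj_mut$growth$time, 9), round(traj_wt$growth$time, 9)
  )
  times <- sort(times[times > 0])
  if (length(times) == 0) {
    stop("trajectories share no recording times", call. = FALSE)
  }
  rows <- lapply(times, function(t) {
    ram <- cell_lengths(traj_mut, "RAM", file_index = file_index, time = t)
    td <- cell_lengths(traj_wt, "TD", file_index = file_index, time = t)
    pd <- cell_lengths(traj_wt, "PD", file_index = file_index, time = t)
    p_td <- if (length(ram) >= min_n && length(td) >= min_n) {
      compare_distributions(ram, td)$mwu_p
    } else {
      NA_real_
    }
    p_pd <- if (length(ram) >= min_n && length(pd) >= min_n) {
      compare_distributions(ram, pd)$mwu_p
    } else {
      NA_real_
    }
    tibble::tibble(
      time = t, n_ram = length(ram), n_td = length(td), n_pd = length(pd),
      p_td = p_td, p_pd = p_pd
    )
  })
  by_time <- dplyr::bind_rows(rows)

  # a time qualifies when the mutant RAM is indistinguishable from the Wt
  # TD while simultaneously separated from the Wt PD
  ok <- !is.na(by_time$p_td) & by_time$p_td > alpha &
    !is.na(by_time$p_pd) & by_time$p_pd <= alpha
  run <- longest_run(ok)
  if (is.null(run)) {
    window <- tibble::tibble(
      t1 = NA_real_, t2 = NA_real_, n_times = 0L,
      pd_separated = NA, empty = TRUE
    )
  } else {
    idx <- seq(run[1], run[2])
    p_pd_in <- by_time$p_pd[idx]
    window <- tibble::tibble(
      t1 = by_time$time[run[1]], t2 = by_time$time[run[2]],
      n_times = length(idx),
      pd_separated = all(!is.na(p_pd_in) & p_pd_in <= alpha),
      empty = FALSE
    )
  }
  structure(
    list(window = window, by_time = by_time, alpha = alpha),
    class = "indist_window"
  )
}

#' @export
print.indist_window <- function(x, ...) {
  w <- x$window
  if (w$empty) {
    cat("<indist_window> empty (no time with p >", x$alpha, "vs Wt TD)\n")
  } else {
    cat(sprintf(
      "<indist_window> t1 = %g, t2 = %g (%d times); PD separated throughout: %s\n",
      w$t1, w$t2, w$n_times, w$pd_separated
    ))
  }
  invisible(x)
}

# First longest run of TRUE values; NULL when none. Ties resolved to the
# earliest run.
longest_run <- function(x) {
  if (!any(x)) {
    return(NULL)
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  c(starts[best], ends[best])
}

#' Robustness sweep over cell-growth parameters
#'
#' Re-runs the paired wild-type / `mto2-2` simulations over a grid of cell
#' division length thresholds, elongation increments and final cell
#' lengths, and evaluates the four shared outcome features: (1) wild-type
#' growth is indeterminate while mutant growth is determinate; (2) the
#' mutant whole-root free Thr exceeds the wild type at the final matched
#' time; (3) mutant Thr at the stem cell niche is below the wild type; (4)
#' a non-empty Mann-Whitney indistinguishability window exists (mutant RAM
#' vs Wt TD, `p > alpha`) with simultaneous separation from the Wt PD
#' (`p <= alpha`).
#'
#' @param division_length_threshold,ez_increment,final_length Grid values;
#'   defaults a 2 x 2 x 2 sub-grid of the full sweep sets
#'   `{2,4,6,8,10} x {3..8} x {75,80,85,90}`.
#' @param t_max Simulated time per run (a.u.); default 8, long enough for
#'   the mutant plateau to complete under the slowest grid settings.
#' @param alpha Significance level for feature (4).
#' @param params_wt,params_mut Model parameters for the two genotypes.
#' @param gradients Expression gradients.
#' @return A tibble, one row per configuration, with the four feature
#'   booleans `wt_indet_mut_det`, `mut_total_thr_higher`,
#'   `mut_scn_deficient`, `window_found` and supporting numbers.
#' @export
robustness_sweep <- function(division_length_threshold = c(2, 4),
                             ez_increment = c(3, 8),
                             final_length = c(75, 90),
                             t_max = 8,
                             alpha = 0.05,
                             params_wt = thr_params(genotype = "Wt"),
                             params_mut = thr_params(genotype = "mto2-2"),
                             gradients = default_gradients()) {
  grid <- expand.grid(
    division_length_threshold = division_length_threshold,
    ez_increment = ez_increment,
    final_length = final_length,
    KEEP.OUT.ATTRS = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    mk <- function(genotype) {
      sim_config(
        division_length_threshold = row$division_length_threshold,
        ez_increment = row$ez_increment,
        final_length = row$final_length,
        genotype = genotype, t_max = t_max
      )
    }
    traj_wt <- simulate_root(mk("Wt"), params_wt, gradients)
    traj_mut <- simulate_root(mk("mto2-2"), params_mut, gradients)
    cls_wt <- classify_growth(traj_wt)$classification
    cls_mut <- classify_growth(traj_mut)$classification
    thr_wt <- total_free_thr(traj_wt)
    thr_mut <- total_free_thr(traj_mut)
    scn_wt <- thr_profile(params_wt, gradients, positions = 0)$thr
    scn_mut <- thr_profile(params_mut, gradients, positions = 0)$thr
    win <- find_indistinguishable_window(traj_mut, traj_wt, alpha = alpha)
    tibble::tibble(
      row,
      wt_classification = cls_wt, mut_classification = cls_mut,
      wt_indet_mut_det = cls_wt == "indeterminate" & cls_mut == "determinate",
      total_thr_wt = thr_wt, total_thr_mut = thr_mut,
      mut_total_thr_higher = thr_mut > thr_wt,
      mut_scn_deficient = scn_mut < scn_wt,
      window_t1 = win$window$t1, window_t2 = win$window$t2,
      window_found = !win$window$empty & isTRUE(win$window$pd_separated)
    )
  })
  dplyr::bind_rows(res)
}

#' Expression-scaling experiment
#'
#' Repeats the simulations with all expression gradients multiplied by a
#' common factor (graded shape preserved, level scaled) and classifies root
#' growth per scale and genotype. The division threshold is held at its
#' unscaled wild-type default so that scaling genuinely moves cells across
#' the gate: scaling wild-type expression to zero abolishes growth, while
#' sufficiently increased expression restores indeterminate growth in the
#' mutant.
#'
#' @param scales Non-negative multipliers applied to the gradients.
#' @param genotypes Genotypes to run (default both).
#' @param t_max Simulated time per run (a.u.).
#' @param config_args Named list of extra [sim_config()] arguments.
#' @return A tibble: `scale`, `genotype`, `classification`,
#'   `rel_growth_rate`, `final_length_grid`.
#' @export
expression_scaling_experiment <- function(scales = c(0, 0.25, 0.5, 1, 2, 4),
                                          genotypes = c("Wt", "mto2-2"),
                                          t_max = 8,
                                          config_args = list()) {
  if (any(scales < 0)) stop("`scales` must be >= 0", call. = FALSE)
  base_params <- thr_params(genotype = "Wt")
  theta <- default_theta(base_params, default_gradients(), "synthesis_only")
  grid <- expand.grid(
    scale = scales, genotype = genotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$scale[i]
    gt <- grid$genotype[i]
    cfg <- do.call(sim_config, c(
      list(genotype = gt, t_max = t_max, thr_division_threshold = theta),
      config_args
    ))
    traj <- simulate_root(
      cfg,
      params = thr_params(genotype = gt),
      gradients = default_gradients(scale = sc)
    )
    cls <- classify_growth(traj)
    tibble::tibble(
      scale = sc, genotype = gt,
      classification = cls$classification,
      rel_growth_rate = cls$rel_growth_rate,
      final_length_grid = dplyr::last(traj$growth$total_length)
    )
  })
  dplyr::bind_rows(res)
}
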