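#' Run the package's end-to-end reproduction checks
#'
#' Re-derives the headline model results from scratch with the package's
#' default study conditions and reports each as a named check with its
#' computed value, the expected relation and a pass flag:
#' * `whole_root_thr_ratio` — mutant/Wt whole-root free Thr at matched
#'   mid-growth time of the paired simulations (expected >= 1.5);
#' * `wt_msc_m2_rate` — fraction of synthetic wild-type-like profiles whose
#'   BIC-selected breakpoint count is 2 (expected >= 0.9);
#' * `mut_msc_m1_majority` — fraction of synthetic mutant-like profiles
#'   selecting one breakpoint (expected > 0.5);
#' * `init_ram_cells` — RAM cells per file in the initial condition
#'   (expected exactly 40: 32 PD + 8 TD);
#' * `f_rule` — the f values for smallest-profile sizes 13/24/25 (expected
#'   0.24/0.13/0.12);
#' * `robustness` — the four shared features on a reduced parameter grid;
#' * `wt_scn_max_rate` — fraction of sweep parameter sets with the
#'   wild-type Thr maximum at the stem cell niche (expected >= 0.95).
#'
#' @param seed Integer seed used for every stochastic component.
#' @param out_dir Optional directory; when given, a JSON report
#'   (`reproduction_report.json`) is written there.
#' @param n_profiles Synthetic profiles per cohort (default 100).
#' @param n_sweep Parameter sets in the gradient-pattern sweep (default
#'   1000).
#' @param robustness_grid Logical; run the 2 x 2 x 2 robustness sub-grid
#'   (slowest check; default TRUE).
#' @return A tibble of class `reproduction_report` with columns `check`,
#'   `value`, `expected`, `pass`.
#' @export
reproduce_all <- function(seed = 1L, out_dir = NULL, n_profiles = 100,
                          n_sweep = 1000, robustness_grid = TRUE) {
  seed <- as.integer(seed)
  checks <- list()
  add <- function(check, value, expected, pass) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, value = as.character(value), expected = expected,
      pass = pass
    )
  }

  # mutant/Wt whole-root Thr at matched mid-growth time
  ratio <- whole_root_thr_ratio()
  add("whole_root_thr_ratio", ratio, ">= 1.5", ratio >= 1.5)

  # MSC recovery on synthetic cohorts
  wt_cohort <- generate_cohort(profile_spec("wt_like"), k = n_profiles,
                               seed = seed)
  wt_m <- classify_sample(wt_cohort)$per_root$m
  add("wt_msc_m2_rate", mean(wt_m == 2), ">= 0.9", mean(wt_m == 2) >= 0.9)

  mut_cohort <- generate_cohort(profile_spec("mto2_like"), k = n_profiles,
                                seed = seed + 1L)
  mut_m <- classify_sample(mut_cohort)$per_root$m
  add("mut_msc_m1_majority", mean(mut_m == 1), "> 0.5", mean(mut_m == 1) > 0.5)

  # simulator initial condition
  st <- init_root(sim_config())
  n_ram <- length(cell_lengths(st, "RAM"))
  add("init_ram_cells", n_ram, "== 40", n_ram == 40L)

  # f rule against the published genotype/experiment values
  f_vals <- vapply(c(13, 24, 25), function(n) compute_f(rep(1, n)), 0)
  add(
    "f_rule", paste(sprintf("%.2f", f_vals), collapse = "/"), "0.24/0.13/0.12",
    isTRUE(all.equal(f_vals, c(0.24, 0.13, 0.12)))
  )

  if (robustness_grid) {
    rob <- robustness_sweep()
    all_ok <- all(
      rob$wt_indet_mut_det, rob$mut_total_thr_higher,
      rob$mut_scn_deficient, rob$window_found
    )
    add(
      "robustness", sum(
        rob$wt_indet_mut_det & rob$mut_total_thr_higher &
          rob$mut_scn_deficient & rob$window_found
      ),
      sprintf("== %d configs", nrow(rob)), all_ok
    )
  }

  sweep <- sweep_thr_parameters(n_sets = n_sweep, seed = seed)
  rate <- mean(sweep$wt_max_at_scn)
  add("wt_scn_max_rate", rate, ">= 0.95", rate >= 0.95)

  report <- dplyr::bind_rows(checks)
  class(report) <- c("reproduction_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, checks = report),
      file.path(out_dir, "reproduction_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' Mutant/wild-type whole-root free Thr ratio at matched time
#'
#' Runs the paired default simulations and returns the ratio of summed
#' per-cell free Thr (midpoint steady state x cell length, all files) of
#' the `mto2-2` root to the wild-type root at the same mid-growth time.
#'
#' @param time Matched comparison time (a.u.); default half of `t_max`.
#' @param t_max Simulated time (a.u.); default 5.
#' @param params_wt,params_mut Model parameters per genotype.
#' @param gradients Expression gradients.
#' @return The dimensionless fold ratio.
#' @export
whole_root_thr_ratio <- function(time = t_max / 2, t_max = 5,
                                 params_wt = thr_params(genotype = "Wt"),
                                 params_mut = thr_params(genotype = "mto2-2"),
                                 gradients = default_gradients()) {
  traj_wt <- simulate_root(
    sim_config(genotype = "Wt", t_max = t_max), params_wt, gradients
  )
  traj_mut <- simulate_root(
    sim_config(genotype = "mto2-2", t_max = t_max), params_mut, gradients
  )
  total_free_thr(traj_mut, time = time) / total_free_thr(traj_wt, time = time)
}
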