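test_that("the f rule reproduces the published two-decimal fractions", {
  expect_equal(compute_f(rep(1, 25)), 0.12)
  expect_equal(compute_f(rep(1, 24)), 0.13)
  expect_equal(compute_f(rep(1, 13)), 0.24)
  expect_equal(compute_f(rep(1, 300)), 0.01)
  # sample input: smallest profile governs
  sample_df <- dplyr::bind_rows(
    tibble::tibble(root_id = "a", cell_index = 1:25, length_um = 1),
    tibble::tibble(root_id = "b", cell_index = 1:40, length_um = 1)
  )
  expect_equal(compute_f(sample_df), 0.12)
  expect_error(compute_f(rep(1, 6)), "at least 7")
})

test_that("the h rule enforces 3 <= h < n/2 or raises", {
  expect_equal(compute_h(0.12, 25), 3L)
  expect_equal(compute_h(0.12, 100), 12L)
  expect_error(compute_h(0.24, 10), "below 3")
  expect_error(compute_h(0.58, 7), "n/2")
  # round-trip: f from a single profile always yields a feasible h
  for (n in 7:150) {
    h <- compute_h(compute_f(rep(1, n)), n)
    expect_gte(h, 3)
    expect_lt(h, n / 2)
  }
})

test_that("breakpoint placement is exact on noiseless piecewise-linear data", {
  y <- c(rep(5, 10), 20 + 2 * (1:10)) # flat then steep, junction at 10
  fit <- fit_breakpoints(y, m = 1, h = 3)
  expect_equal(fit$breakpoints, 10)
  expect_lt(fit$rss, 1e-18)
  # m = 0 equals the classic simple-regression RSS
  f0 <- fit_breakpoints(y, m = 0, h = 3)
  lmfit <- stats::lm(y ~ x, data = data.frame(x = seq_along(y), y = y))
  expect_equal(f0$rss, sum(stats::residuals(lmfit)^2), tolerance = 1e-10)
  expect_error(fit_breakpoints(y, m = 3, h = 6), "infeasible")
  expect_error(fit_breakpoints(c(y, -1), m = 1, h = 3), "positive")
})

test_that("dynamic programme equals the exhaustive-search oracle", {
  withr::with_seed(99, {
    for (i in 1:30) {
      n <- sample(9:30, 1)
      m <- sample(0:2, 1)
      h <- 3
      if ((m + 1) * h > n) m <- 0
      y <- abs(stats::rnorm(n, 10, 4)) + 0.5
      fit <- fit_breakpoints(y, m = m, h = h)
      oracle <- exhaustive_breakpoints(y, m, h)
      expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    }
  })
})

test_that("RSS is non-increasing in m and BIC selection is parsimonious on ties", {
  withr::with_seed(5, {
    for (i in 1:10) {
      y <- abs(stats::rnorm(25, 12, 5)) + 0.5
      r <- vapply(0:2, function(m) fit_breakpoints(y, m, h = 3)$rss, 0)
      expect_true(all(diff(r) <= 1e-9))
    }
  })
  # noiseless 2-regime data: m = 1 and m = 2 both reach RSS 0; the
  # smaller m wins the BIC tie
  y <- c(6 + 1.5 * (0:11), 25 + 12 * (0:9))
  sel <- select_breakpoints(y, h = 3)
  expect_equal(sel$m, 1L)
  expect_equal(sel$breakpoints, 12)
})

test_that("breakpoint placement is invariant to shifting and rescaling lengths", {
  withr::with_seed(21, {
    for (i in 1:10) {
      prof <- generate_profile(profile_spec("wt_like"), seed = i)
      y <- prof$length_um
      base <- select_breakpoints(y, h = 3)
      shifted <- select_breakpoints(y + 100, h = 3)
      scaled <- select_breakpoints(y * 7.3, h = 3)
      expect_equal(shifted$breakpoints, base$breakpoints)
      expect_equal(scaled$breakpoints, base$breakpoints)
      expect_equal(scaled$m, base$m) # BIC selection invariant to rescaling
    }
  })
})

test_that("domain annotation maps breakpoint counts onto PD/TD/EZ", {
  prof <- generate_profile(profile_spec("wt_like", noise_sd = 0), seed = 1)
  m2 <- annotate_domains(select_breakpoints(prof$length_um, h = 3))
  expect_equal(m2$model$m, 2L)
  expect_equal(sum(m2$domains$n_cells), nrow(prof))
  expect_equal(m2$domains$domain, c("PD", "TD", "EZ"))
  expect_equal(m2$domains$n_cells, c(25L, 10L, 12L))
  expect_equal(
    m2$domains$total_length_um,
    vapply(split(prof$length_um, m2$labels)[c("PD", "TD", "EZ")], sum, 0),
    ignore_attr = TRUE
  )

  prof1 <- generate_profile(profile_spec("mto2_like", noise_sd = 0), seed = 1)
  m1 <- annotate_domains(select_breakpoints(prof1$length_um, h = 3))
  expect_equal(m1$domains$domain, c("TD", "EZ"))
  expect_equal(m1$domains$n_cells[1], m1$model$breakpoints[1])

  flat <- generate_profile(profile_spec("exhausted", noise_sd = 0), seed = 1)
  m0 <- annotate_domains(fit_breakpoints(flat$length_um, m = 0, h = 3))
  expect_true(all(m0$labels == "undetermined"))
  expect_equal(nrow(m0$domains), 0L)

  # wild-type convention: force the two-breakpoint model
  forced <- annotate_domains(
    select_breakpoints(prof1$length_um, h = 3), force_m = 2
  )
  expect_equal(forced$model$m, 2L)
  expect_equal(forced$domains$domain, c("PD", "TD", "EZ"))
})

test_that("cohort classification recovers regime structure per genotype mode", {
  wt_cohort <- generate_cohort(
    profile_spec("wt_like", noise_sd = 0, between_root_cv = 0),
    k = 5, seed = 1
  )
  s <- classify_sample(wt_cohort)
  expect_true(all(s$per_root$m == 2))
  expect_equal(s$per_root$bp1, rep(25, 5))
  expect_equal(s$per_root$bp2, rep(35, 5))
  expect_equal(s$cohort$pct[s$cohort$m == 2], 100)
  # wt mode forces two breakpoints for every root
  mut_cohort <- generate_cohort(profile_spec("mto2_like"), k = 5, seed = 2)
  s_wt_mode <- classify_sample(mut_cohort, genotype_mode = "wt")
  expect_true(all(s_wt_mode$per_root$m == 2))
  # tidiers
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(nrow(glance(s)), nrow(s$cohort))
})
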