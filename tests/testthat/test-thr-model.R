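test_that("expression gradients evaluate, clamp at zero and respect scale", {
  g <- expression_gradient("MTO2", intercept = 10, slope = -10)
  expect_equal(expression_at(g, 1), 0)
  expect_equal(expression_at(g, 0), 10)
  g0 <- expression_gradient("TSY2", intercept = 0, slope = 0)
  expect_equal(expression_at(g0, c(0, 0.3, 1)), c(0, 0, 0))
  g2 <- expression_gradient("MTO2", intercept = 10, slope = -8, scale = 2)
  expect_equal(expression_at(g2, 0.5), 12) # 2 * (10 - 4)
  expect_error(expression_at(g, 1.5), "\\[0, 1\\]")
  expect_error(expression_at(g, -0.1), "\\[0, 1\\]")
})

test_that("synthesis-only steady state matches the closed form", {
  p <- thr_params(S = 1, Km1 = 10, Km2 = 1000, delta = 1)
  expect_equal(steady_state_synthesis(p, 0, 0), 0)
  # half-maximal Michaelis-Menten term: e_mto2 = Km1
  expect_equal(steady_state_synthesis(p, 10, 0), 0.5)
  expect_equal(steady_state_synthesis(p, 10, 10), 0.5 + 10 / 1010)
  # mutant drops the MTO2 term and compensates Km2
  pm <- thr_params(
    S = 1, Km1 = 10, Km2 = 1000, delta = 1,
    genotype = "mto2-2", tsy2_compensation = 250
  )
  expect_equal(steady_state_synthesis(pm, 10, 10), 10 / (4 + 10))
  expect_error(thr_params(S = -1), "strictly positive")
  expect_error(thr_params(delta = 0), "strictly positive")
  expect_error(steady_state_synthesis(p, -1, 0), ">= 0")
})

test_that("synthesis steady state is bounded and monotone in S and delta", {
  for (i in 1:25) {
    km1 <- stats::runif(1, 1, 1000)
    km2 <- stats::runif(1, 1, 1000)
    s <- stats::runif(1, 0.5, 5)
    d <- stats::runif(1, 1, 10)
    e1 <- stats::runif(1, 0, 20)
    e2 <- stats::runif(1, 0, 20)
    p <- thr_params(S = s, Km1 = km1, Km2 = km2, delta = d)
    v <- steady_state_synthesis(p, e1, e2)
    expect_gte(v, 0)
    expect_lte(v, 2 * s / d)
    p_up_s <- thr_params(S = 2 * s, Km1 = km1, Km2 = km2, delta = d)
    expect_gt(steady_state_synthesis(p_up_s, e1, e2) + 1e-15, v)
    p_up_d <- thr_params(S = s, Km1 = km1, Km2 = km2, delta = 2 * d)
    expect_lt(steady_state_synthesis(p_up_d, e1, e2), v + 1e-15)
  }
})

test_that("extended model reduces exactly to synthesis-only without catabolism", {
  p <- thr_params()
  ss <- steady_state_extended(p, 10, 10, 0, 0)
  expect_identical(ss$thr, steady_state_synthesis(p, 10, 10))
  expect_identical(ss$gly, 0)
  expect_identical(ss$ile, 0)
  # no production at all
  s0 <- steady_state_extended(p, 0, 0, 10, 10)
  expect_equal(unlist(s0), c(thr = 0, gly = 0, ile = 0))
})

test_that("extended steady state agrees with long-time ODE integration", {
  withr::with_seed(42, {
    for (i in 1:10) {
      p <- thr_params(
        S = 1,
        Km1 = stats::runif(1, 1, 1000), Km2 = stats::runif(1, 1, 1000),
        Km3 = stats::runif(1, 1, 100), Km4 = stats::runif(1, 1, 100),
        Km5 = stats::runif(1, 1, 100), delta = stats::runif(1, 1, 10)
      )
      e <- stats::runif(4, 0, 10)
      ss <- steady_state_extended(p, e[1], e[2], e[3], e[4])
      ode <- integrate_extended(p, e[1], e[2], e[3], e[4])
      expect_equal(unname(unlist(ss)), unname(ode), tolerance = 1e-6)
    }
  })
})

test_that("profiles respond to gradients and zero scaling kills all output", {
  p <- thr_params()
  prof <- thr_profile(p, default_gradients(), positions = seq(0, 1, 0.01))
  expect_s3_class(prof, "thr_profile")
  expect_true(all(prof$thr >= 0))
  expect_equal(which.max(prof$thr), 1L) # Wt maximum at the SCN
  expect_true(all(is.na(prof$gly)))
  pm <- thr_params(genotype = "mto2-2")
  prof_m <- thr_profile(pm, default_gradients(), positions = seq(0, 1, 0.01))
  expect_lt(prof_m$thr[1], prof$thr[1]) # SCN deficiency
  expect_gt(dplyr::last(prof_m$thr), dplyr::last(prof$thr)) # distal excess
  # zero expression scale drives every steady state to zero
  for (variant in c("synthesis_only", "extended")) {
    z <- thr_profile(p, default_gradients(scale = 0),
      positions = seq(0, 1, 0.25), variant = variant
    )
    expect_equal(z$thr, rep(0, 5))
  }
  expect_error(
    thr_profile(p, expression_gradient("MTO2", 10, -10)),
    "missing required expression gradient"
  )
})

test_that("pattern classification encodes the qualitative predictions", {
  mono <- structure(
    tibble::tibble(
      position = seq(0, 1, 0.25), thr = c(5, 4, 3, 2, 1),
      gly = NA_real_, ile = NA_real_
    ),
    class = c("thr_profile", "tbl_df", "tbl", "data.frame")
  )
  expect_true(classify_pattern(mono)$max_at_scn)
  expect_error(classify_pattern(mono[1:2, ]), "at least 3 positions")
  ext_wt <- thr_profile(thr_params(), variant = "extended")
  expect_true(classify_pattern(ext_wt)$gly_ile_max_at_scn)
  ext_mut <- thr_profile(thr_params(genotype = "mto2-2"), variant = "extended")
  flags <- classify_pattern(ext_mut)
  expect_true(flags$ez_elevated)
  expect_true(flags$scn_low_positive)
})
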