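test_that("distribution comparison handles identity, separation and small samples", {
  a <- c(4, 4, 5, 5, 6)
  expect_equal(compare_distributions(a, a)$mwu_p, 1)
  sep <- compare_distributions(1:20, 101:120)
  expect_lt(sep$mwu_p, 0.001)
  expect_lt(sep$t_p, 0.001)
  expect_error(compare_distributions(1:2, 1:10), "at least 3")
  # fully degenerate equal samples
  expect_equal(compare_distributions(c(4, 4, 4), c(4, 4, 4))$mwu_p, 1)
  # constant but different samples: complete separation
  res <- compare_distributions(c(4, 4, 4), c(9, 9, 9))
  expect_lt(res$mwu_p, 0.1)
  expect_equal(res$t_p, 0)
})

test_that("Mann-Whitney approximation tracks the exact enumeration", {
  withr::with_seed(11, {
    for (i in 1:40) {
      n <- sample(5:8, 1)
      m <- sample(5:8, 1)
      a <- stats::runif(n)
      b <- stats::runif(m) + stats::runif(1, -0.5, 0.5)
      p_pkg <- compare_distributions(a, b)$mwu_p
      expect_equal(p_pkg, approx_mwu_p(a, b), tolerance = 1e-10)
      expect_lt(abs(p_pkg - exact_mwu_p(a, b)), 0.02)
    }
  })
})

test_that("the mutant RAM matches Wt TD cells, not PD cells, during a time window", {
  wt <- simulate_root(sim_config(genotype = "Wt", t_max = 5))
  mut <- simulate_root(sim_config(genotype = "mto2-2", t_max = 5))
  win <- find_indistinguishable_window(mut, wt)
  expect_false(win$window$empty)
  expect_true(win$window$pd_separated)
  expect_gt(win$window$t1, 0)
  expect_lte(win$window$t2, 5)
  # inside the window: indistinguishable from TD, separated from PD
  idx <- win$by_time$time >= win$window$t1 & win$by_time$time <= win$window$t2
  expect_true(all(win$by_time$p_td[idx] > 0.05))
  expect_true(all(win$by_time$p_pd[idx] <= 0.05))
  # the Wt root separates its own PD and TD throughout steady growth
  late <- win$by_time$time[win$by_time$time >= 2]
  ps <- vapply(late[seq(1, length(late), 5)], function(t) {
    compare_distributions(
      cell_lengths(wt, "PD", time = t), cell_lengths(wt, "TD", time = t)
    )$mwu_p
  }, 0)
  expect_true(all(ps <= 0.05))
})
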