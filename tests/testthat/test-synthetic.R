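test_that("profile generation is seeded, sized and strictly positive", {
  spec <- profile_spec("wt_like")
  p1 <- generate_profile(spec, seed = 4)
  p2 <- generate_profile(spec, seed = 4)
  expect_identical(p1, p2)
  p3 <- generate_profile(spec, seed = 5)
  expect_false(identical(p1$length_um, p3$length_um))
  expect_equal(nrow(p1), sum(spec$segments$n_cells))
  expect_equal(p1$cell_index, seq_len(nrow(p1)))
  # truncation keeps lengths positive even under absurd noise
  noisy <- generate_profile(profile_spec("wt_like", noise_sd = 50), seed = 1)
  expect_true(all(noisy$length_um >= 0.5))
  # noiseless generation is exactly the piecewise-linear mean
  clean <- generate_profile(profile_spec("mto2_like", noise_sd = 0), seed = 1)
  expect_equal(clean$length_um[1:12], 6 + 1.5 * (0:11))
  expect_error(profile_spec("custom"), "segments")
  expect_error(
    profile_spec("custom", segments = data.frame(
      n_cells = 2, start_length = 5, slope = 1
    )),
    "at least 3 cells"
  )
})

test_that("cohorts are reproducible with controlled between-root variability", {
  spec <- profile_spec("wt_like")
  c1 <- generate_cohort(spec, k = 7, seed = 10)
  c2 <- generate_cohort(spec, k = 7, seed = 10)
  expect_identical(c1, c2)
  expect_equal(dplyr::n_distinct(c1$root_id), 7)
  # a wt-like cohort admits a feasible shared f/h for every root
  f <- compute_f(c1)
  for (id in unique(c1$root_id)) {
    expect_no_error(compute_h(f, sum(c1$root_id == id)))
  }
  # zero between-root variability: all roots share identical means
  c0 <- generate_cohort(
    profile_spec("mto2_like", noise_sd = 0, between_root_cv = 0),
    k = 3, seed = 1
  )
  lens <- split(c0$length_um, c0$root_id)
  expect_equal(lens[[1]], lens[[2]], ignore_attr = TRUE)
  expect_equal(lens[[2]], lens[[3]], ignore_attr = TRUE)
  expect_error(generate_cohort(spec, k = 0), ">= 1")
})

test_that("noiseless generation composed with MSC fitting recovers the junctions", {
  prof <- generate_profile(profile_spec("wt_like", noise_sd = 0), seed = 2)
  sel <- select_breakpoints(
    prof$length_um, h = compute_h(compute_f(prof), nrow(prof))
  )
  expect_equal(sel$m, 2L)
  expect_equal(sel$breakpoints, c(25, 35))
})

test_that("a mixed cohort is dominated by its majority regime class", {
  # mixing mirrors the observed 5/66/29 split of breakpoint counts
  mixed <- dplyr::bind_rows(
    generate_cohort(profile_spec("exhausted"), k = 5, seed = 31,
                    id_prefix = "ex"),
    generate_cohort(profile_spec("mto2_like"), k = 66, seed = 32,
                    id_prefix = "mut"),
    generate_cohort(profile_spec("wt_like"), k = 29, seed = 33,
                    id_prefix = "wt")
  )
  s <- classify_sample(mixed)
  pct <- function(m) {
    v <- s$cohort$pct[s$cohort$m == m]
    if (length(v) == 0) 0 else v
  }
  # all three regime classes are detected; the no-breakpoint class stays
  # near its 5% mixing fraction while the segmented classes dominate
  expect_true(all(0:2 %in% s$cohort$m))
  expect_lt(abs(pct(0) - 5), 10)
  expect_gt(pct(1), 30)
  expect_gt(pct(1) + pct(2), 85)
  # every root was analysed under the shared minimal-segment fraction
  expect_true(all(tidy(s)$h >= 3))
})
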