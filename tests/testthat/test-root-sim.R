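test_that("initial condition matches the default meristem layout", {
  st <- init_root(sim_config())
  expect_length(cell_lengths(st, "PD"), 32)
  expect_length(cell_lengths(st, "TD"), 8)
  expect_length(cell_lengths(st, "RAM"), 40)
  d <- 4
  expect_true(all(cell_lengths(st, "PD") >= d))
  expect_true(all(cell_lengths(st, "PD") < 2 * d))
  # RAM = PD then TD (partition, ordered rootward to shootward)
  expect_identical(
    cell_lengths(st, "RAM"),
    c(cell_lengths(st, "PD"), cell_lengths(st, "TD"))
  )
  # elongation zone seeded within the 7-10 cell range
  snap <- rootzone:::state_snapshot(st, files = 1)
  expect_true(sum(snap$type == "elongating") %in% 7:10)
  # both genotypes share the initial condition cell-by-cell
  st_mut <- init_root(sim_config(genotype = "mto2-2"))
  expect_identical(st$files, st_mut$files)
  expect_identical(st$zone, st_mut$zone)
})

test_that("stepping preserves tiling, conserves length at division and grows monotonically", {
  cfg <- sim_config(genotype = "Wt", t_max = 2)
  st <- init_root(cfg)
  thr_fn <- make_thr_profile_fn(thr_params(), axis_length = st$axis_length)
  theta <- 0.5 * thr_fn(0)
  prev_total <- sum(st$files[[1]]$length)
  prev_n <- length(st$files[[1]]$id)
  for (i in 1:20) {
    st <- step_root(st, thr_fn, theta)
    f <- st$files[[1]]
    # tiling: starts recomputed from cumulative lengths, all lengths >= 1
    expect_true(all(f$length >= 1))
    total <- sum(f$length)
    expect_gte(total, prev_total)
    expect_gte(length(f$id), prev_n)
    # QC cell never grows or divides; it stays the rootward-most cell
    expect_identical(f$type[1], rootzone:::.T_QC)
    expect_identical(f$length[1], 4L)
    # division capacity bookkeeping
    expect_true(all(f$divu <= 5L))
    expect_true(all(f$length <= cfg$final_length))
    # unique ids
    expect_false(any(duplicated(f$id)))
    prev_total <- total
    prev_n <- length(f$id)
  }
  # divisions happened and conserved length (total length only grew by
  # the recorded growth increments, never by splitting)
  expect_gt(prev_n, 42)
})

test_that("division requires doubling, Thr above threshold and spare capacity", {
  cfg <- sim_config(genotype = "Wt", t_max = 1)
  st <- init_root(cfg)
  thr_fn_hi <- function(grid_pos) rep(1, length(grid_pos))
  thr_fn_lo <- function(grid_pos) rep(0, length(grid_pos))

  # a PD cell at double its birth length with Thr above theta divides...
  st1 <- st
  st1$files <- lapply(st1$files, function(f) {
    f$length[3] <- 2L * f$birth[3]
    f
  })
  before <- length(st1$files[[1]]$id)
  parent_len <- st1$files[[1]]$length[3]
  st2 <- step_root(st1, thr_fn_hi, theta = 0.5)
  expect_gt(length(st2$files[[1]]$id), before)
  # ...with daughters summing to the parent length after its growth row
  # (division itself conserves length)
  expect_equal(
    st2$files[[1]]$length[3] + st2$files[[1]]$length[4],
    parent_len + 1L
  )

  # the same cell under low Thr does not divide
  st3 <- step_root(st1, thr_fn_lo, theta = 0.5)
  expect_equal(sum(st3$files[[1]]$type == rootzone:::.T_TA &
    st3$files[[1]]$divu > 0), 0)

  # a transit-amplifying cell that has used its five divisions never
  # divides again, whatever its size or Thr level
  st4 <- st
  st4$files <- lapply(st4$files, function(f) {
    f$divu[3] <- 5L
    f$length[3] <- 4L * f$birth[3]
    f
  })
  st5 <- step_root(st4, thr_fn_hi, theta = 0)
  # no division pushes divisions_used past 5, and the exhausted cell gains
  # no daughter (it stays the only cell at 5 divisions)
  expect_false(any(st5$files[[1]]$divu > 5L))
  expect_equal(sum(st5$files[[1]]$divu == 5L), 1L)
})

test_that("default simulations reproduce indeterminate Wt and determinate mutant growth", {
  wt <- simulate_root(sim_config(genotype = "Wt", t_max = 5))
  mut <- simulate_root(sim_config(genotype = "mto2-2", t_max = 5))
  expect_equal(classify_growth(wt)$classification, "indeterminate")
  expect_equal(classify_growth(mut)$classification, "determinate")
  # total length strictly increasing over the final 20% of Wt steps
  gl <- wt$growth$total_length
  late <- gl[seq(floor(0.8 * length(gl)), length(gl))]
  expect_true(all(diff(late) > 0))
  # growth curves are non-decreasing and times strictly increasing
  expect_true(all(diff(wt$growth$total_length) >= 0))
  expect_true(all(diff(mut$growth$time) > 0))
  # removing the Thr gate restores indeterminate growth in the mutant
  mut0 <- simulate_root(
    sim_config(genotype = "mto2-2", t_max = 5, thr_division_threshold = 0)
  )
  expect_equal(classify_growth(mut0)$classification, "indeterminate")
  # determinism: identical configs give identical trajectories
  wt2 <- simulate_root(sim_config(genotype = "Wt", t_max = 5))
  expect_identical(wt$growth, wt2$growth)
  # mutant RAM cells mid-simulation are at least as long as the Wt PD median
  ram_mut <- cell_lengths(mut, "RAM", time = 3)
  pd_wt <- cell_lengths(wt, "PD", time = 3)
  expect_gte(min(ram_mut), stats::median(pd_wt))
})

test_that("growth classification is invariant to halving the time step", {
  for (gt in c("Wt", "mto2-2")) {
    c1 <- classify_growth(
      simulate_root(sim_config(genotype = gt, t_max = 3))
    )$classification
    c2 <- classify_growth(
      simulate_root(sim_config(genotype = gt, t_max = 3, dt = 0.05))
    )$classification
    expect_identical(c1, c2)
  }
})

test_that("whole-root Thr scales linearly in S and vanishes without expression", {
  st <- init_root(sim_config())
  zero_fn <- function(grid_pos) rep(0, length(grid_pos))
  expect_equal(total_free_thr(st, zero_fn), 0)
  f1 <- make_thr_profile_fn(thr_params(S = 1), axis_length = st$axis_length)
  f2 <- make_thr_profile_fn(thr_params(S = 2), axis_length = st$axis_length)
  expect_equal(total_free_thr(st, f2), 2 * total_free_thr(st, f1))
})
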