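# Lattice-based root growth simulator.
#
# Each cell is a contiguous run of integer grid rows in a one-dimensional
# cell file anchored at the quiescent centre (QC). Cells grow by adding grid
# rows; proliferative cells in the proliferation domain (PD) divide when
# they double their birth length, provided local free Thr exceeds a
# threshold. Zone boundaries (PD / transition domain (TD) / elongation zone
# (EZ)) are fixed positions in the QC-anchored frame; a cell's zone is
# decided by its midpoint.

# cell type codes used internally
.TYPES <- c(
  "QC", "stem_initial", "transit_amplifying", "ta_exhausted",
  "elongating", "differentiated"
)
.T_QC <- 1L
.T_STEM <- 2L
.T_TA <- 3L
.T_EXH <- 4L
.T_EZ <- 5L
.T_DIFF <- 6L

#' Configuration of the lattice root simulator
#'
#' @param division_length_threshold Birth length of proliferative cells
#'   (grid units); cells divide on doubling it. The robustness sweeps use
#'   values in `{2, 4, 6, 8, 10}` (even values keep divisions symmetric).
#'   Default 4.
#' @param ram_growth_increment Grid rows added per reference time step (0.1
#'   a.u.) by cycling RAM cells. Default 1.
#' @param td_growth_increment Grid rows per reference step for
#'   non-proliferating RAM cells (TD cells, exhausted transit-amplifying
#'   cells and Thr-gated cells), which grow slowly toward
#'   `ram_max_length`. Default 3.
#' @param ez_increment Grid rows per reference step for elongating cells;
#'   sweep values `{3, ..., 8}`. Default 5.
#' @param final_length Length (grid units) at which an elongating cell
#'   differentiates and stops; sweep values `{75, 80, 85, 90}`. Default 80.
#' @param ram_max_length Maximal length of a RAM cell that is not
#'   elongating (grid units). Default `3 * division_length_threshold`,
#'   giving TD cells the 2-3x size of PD cells seen in real roots.
#' @param stem_cycle_factor Slow-down factor of the stem (initial) cell
#'   cycle relative to other PD cells. Default 2.
#' @param thr_division_threshold Free Thr level (a.u.) below which cell
#'   division (and cycle progression) is blocked. `NULL` (default) means
#'   half the wild-type steady-state Thr at the stem cell niche under the
#'   model parameters in use, computed when the simulation starts.
#' @param genotype `"Wt"` or `"mto2-2"`.
#' @param dt Time step (a.u.); default 0.1. Growth increments are defined
#'   per 0.1 a.u. reference step and accumulated fractionally, so halving
#'   `dt` leaves trajectories (and growth classification) unchanged.
#' @param t_max Simulated time (a.u.); default 5.
#' @param n_files Number of independent cell files (epidermis, cortex,
#'   endodermis, stele); default 4. Files follow identical deterministic
#'   rules.
#' @param n_pd,n_td,n_ez,n_tail Initial cell counts: PD transit-amplifying
#'   cells (32), TD cells (8), elongating cells (8) and differentiated tail
#'   cells (2).
#' @param snapshot_files Number of files for which per-cell snapshots are
#'   recorded (default 1, the cortex analysis file).
#' @param seed Integer, recorded for provenance; the default simulator is
#'   fully deterministic and does not consume random numbers.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(genotype = "mto2-2", t_max = 2)
sim_config <- function(division_length_threshold = 4,
                       ram_growth_increment = 1,
                       td_growth_increment = 3,
                       ez_increment = 5,
                       final_length = 80,
                       ram_max_length = 3 * division_length_threshold,
                       stem_cycle_factor = 2,
                       thr_division_threshold = NULL,
                       genotype = c("Wt", "mto2-2"),
                       dt = 0.1,
                       t_max = 5,
                       n_files = 4,
                       n_pd = 32,
                       n_td = 8,
                       n_ez = 8,
                       n_tail = 2,
                       snapshot_files = 1,
                       seed = 1L) {
  genotype <- match.arg(genotype)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  if (division_length_threshold < 1) {
    stop("`division_length_threshold` must be >= 1", call. = FALSE)
  }
  if (ram_max_length > final_length) {
    stop("`ram_max_length` must not exceed `final_length`", call. = FALSE)
  }
  structure(
    list(
      division_length_threshold = as.integer(division_length_threshold),
      ram_growth_increment = ram_growth_increment,
      td_growth_increment = td_growth_increment,
      ez_increment = ez_increment,
      final_length = as.integer(final_length),
      ram_max_length = as.integer(ram_max_length),
      stem_cycle_factor = stem_cycle_factor,
      thr_division_threshold = thr_division_threshold,
      genotype = genotype,
      dt = dt, t_max = t_max,
      n_files = as.integer(n_files),
      n_pd = as.integer(n_pd), n_td = as.integer(n_td),
      n_ez = as.integer(n_ez), n_tail = as.integer(n_tail),
      snapshot_files = as.integer(snapshot_files),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Build one initial cell file. Cells, QC-out: QC, stem initial, n_pd
# transit-amplifying cells (cell-cycle phases staggered within one cycle so
# divisions are asynchronous), n_td TD cells at twice the birth length, n_ez
# elongating cells graded toward final_length, and a short differentiated
# tail. Both genotypes share this state.
init_file <- function(config, id_offset = 0L) {
  d <- config$division_length_threshold
  pd_len <- d + floor(((seq_len(config$n_pd) - 1L) %% 4L) * d / 4)
  td_len <- rep(2L * d, config$n_td)
  ez_len <- round(seq(min(3L * d, config$final_length), config$final_length,
    length.out = config$n_ez + 1L
  ))[seq_len(config$n_ez)]
  tail_len <- rep(config$final_length, config$n_tail)
  len <- as.integer(c(d, d, pd_len, td_len, ez_len, tail_len))
  type <- c(
    .T_QC, .T_STEM, rep(.T_TA, config$n_pd), rep(.T_TA, config$n_td),
    rep(.T_EZ, config$n_ez), rep(.T_DIFF, config$n_tail)
  )
  n <- length(len)
  list(
    id = id_offset + seq_len(n),
    type = as.integer(type),
    length = len,
    birth = as.integer(rep(d, n)),
    divu = integer(n),
    acc = numeric(n)
  )
}

#' Initialise the in-silico root
#'
#' Builds the shared wild-type/mutant initial condition: per file one QC
#' cell, one stem (initial) cell, 32 PD transit-amplifying cells, 8 TD
#' cells, 8 elongating cells and a short differentiated tail, together with
#' the QC-anchored zone map consistent with those cells.
#'
#' @param config A [sim_config()].
#' @return A list of class `root_state` with elements `files` (per-file cell
#'   vectors), `zone` (`pd_end`, `td_end`, `ez_end` in grid units),
#'   `axis_length` (initial root length, the normalisation used to map grid
#'   positions onto the expression-gradient domain), `time` and `config`.
#' @export
#' @examples
#' st <- init_root(sim_config())
#' st$zone
init_root <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  f1 <- init_file(config)
  sen <- cumsum(f1$length)
  i_pd_last <- 2L + config$n_pd
  i_td_last <- i_pd_last + config$n_td
  i_ez_last <- i_td_last + config$n_ez
  zone <- list(
    pd_end = sen[i_pd_last],
    td_end = sen[i_td_last],
    ez_end = sen[i_ez_last]
  )
  if (!(0 < zone$pd_end && zone$pd_end < zone$td_end &&
    zone$td_end < zone$ez_end)) {
    stop("inconsistent zone map derived from initial cells", call. = FALSE)
  }
  axis_length <- sen[length(sen)]
  files <- lapply(seq_len(config$n_files), function(f) {
    init_file(config, id_offset = (f - 1L) * 100000L)
  })
  structure(
    list(
      files = files, zone = zone, axis_length = axis_length,
      time = 0, config = config, next_id = config$n_files * 100000L + 1L
    ),
    class = "root_state"
  )
}

# Free-Thr evaluator in grid coordinates: maps grid positions onto the
# normalised gradient domain using the initial axis length (clamped at 1)
# and returns the steady-state Thr of the chosen model variant. The
# extended variant is pre-tabulated on a fine grid and interpolated.
make_thr_fn <- function(params, gradients, axis_length,
                        variant = c("synthesis_only", "extended")) {
  variant <- match.arg(variant)
  if (variant == "synthesis_only") {
    force(params)
    force(gradients)
    function(grid_pos) {
      x <- pmin(pmax(grid_pos / axis_length, 0), 1)
      e <- eval_gradients(gradients, x, c("MTO2", "TSY2"))
      steady_state_synthesis(params, e$MTO2, e$TSY2)
    }
  } else {
    xs <- seq(0, 1, length.out = 201)
    prof <- thr_profile(params, gradients, positions = xs, variant = "extended")
    function(grid_pos) {
      x <- pmin(pmax(grid_pos / axis_length, 0), 1)
      stats::approx(xs, prof$thr, xout = x)$y
    }
  }
}

# One simulation step for a single cell file. Returns the updated file.
step_file <- function(f, zone, config, thr_fn, theta, dt_scale) {
  len <- f$length
  type <- f$type
  start <- cumsum(len) - len
  mid <- start + len / 2

  # zone transitions (positional, QC-anchored): any non-QC RAM cell whose
  # midpoint passed the RAM boundary starts elongating
  promote <- type %in% c(.T_STEM, .T_TA, .T_EXH) & mid > zone$td_end
  type[promote] <- .T_EZ

  thr <- thr_fn(mid)
  has_capacity <- type == .T_STEM | (type == .T_TA & f$divu < 5L)
  cycling <- has_capacity & mid <= zone$pd_end & thr >= theta

  # growth rates (grid rows per reference step), fractional accumulation
  rate <- numeric(length(len))
  rate[cycling] <- config$ram_growth_increment
  rate[cycling & type == .T_STEM] <-
    config$ram_growth_increment / config$stem_cycle_factor
  slow <- !cycling & type %in% c(.T_STEM, .T_TA, .T_EXH)
  rate[slow] <- config$td_growth_increment
  rate[type == .T_EZ] <- config$ez_increment

  acc <- f$acc + rate * dt_scale
  grow <- floor(acc + 1e-9)
  acc <- acc - grow
  len_old <- len

  # caps: slow-growing RAM cells stop at ram_max_length, elongating cells
  # at final_length (then differentiate); a cap limits growth but never
  # shrinks a cell
  cap <- rep.int(.Machine$integer.max, length(len))
  cap[slow] <- config$ram_max_length
  cap[type == .T_EZ] <- config$final_length
  len <- pmax(pmin(len_old + as.integer(grow), cap), len_old)
  acc[len >= cap] <- 0
  type[type == .T_EZ & len >= config$final_length] <- .T_DIFF

  # division: proliferative PD cells that doubled their birth length and
  # see free Thr above the threshold split into two daughters (rootward
  # daughter gets the extra row for odd parents)
  start <- cumsum(len) - len
  mid <- start + len / 2
  thr <- thr_fn(mid)
  has_capacity <- type == .T_STEM | (type == .T_TA & f$divu < 5L)
  divide <- has_capacity & mid <= zone$pd_end & len >= 2L * f$birth &
    thr >= theta

  if (!any(divide)) {
    f$length <- len
    f$type <- type
    f$acc <- acc
    return(f)
  }

  reps <- ifelse(divide, 2L, 1L)
  idx <- rep.int(seq_along(len), reps)
  pos_in_pair <- sequence(reps) # 1 = rootward, 2 = shootward
  new_len <- len[idx]
  is_div <- divide[idx]
  rootward <- is_div & pos_in_pair == 1L
  shootward <- is_div & pos_in_pair == 2L
  new_len[rootward] <- as.integer(ceiling(len[idx][rootward] / 2))
  new_len[shootward] <- as.integer(floor(len[idx][shootward] / 2))

  new_type <- type[idx]
  new_divu <- f$divu[idx]
  new_birth <- f$birth[idx]
  new_acc <- acc[idx]
  new_id <- f$id[idx]

  # transit-amplifying daughters inherit divisions_used + 1; at 5 they are
  # exhausted. Stem division is asymmetric: the rootward daughter remains a
  # stem cell, the shootward daughter becomes transit-amplifying.
  ta_d <- is_div & type[idx] == .T_TA
  new_divu[ta_d] <- f$divu[idx][ta_d] + 1L
  new_type[ta_d] <- ifelse(new_divu[ta_d] >= 5L, .T_EXH, .T_TA)
  stem_d <- is_div & type[idx] == .T_STEM
  new_type[stem_d & pos_in_pair == 1L] <- .T_STEM
  new_type[stem_d & pos_in_pair == 2L] <- .T_TA
  new_divu[stem_d] <- 0L
  new_birth[is_div] <- new_len[is_div]
  new_acc[is_div] <- 0

  if (any(new_len < 1L)) {
    stop("internal consistency error: cell with length < 1 after division",
      call. = FALSE
    )
  }

  list(
    id = new_id, type = new_type, length = new_len, birth = new_birth,
    divu = new_divu, acc = new_acc,
    n_new = sum(shootward)
  )
}

#' Advance the root state by one time step
#'
#' Applies, per cell file: zone transitions by midpoint position, growth
#' (QC cells never grow; cycling PD cells add rows toward doubling; stem
#' cells cycle `stem_cycle_factor` times slower; non-proliferating RAM
#' cells grow slowly toward `ram_max_length`; elongating cells add
#' `ez_increment` rows until `final_length`), and Thr-gated division in the
#' PD. Cell positions are recomputed by tiling (displacement growth).
#'
#' @param state A `root_state` (see [init_root()]).
#' @param thr_fn A function mapping grid positions to free Thr, as built
#'   internally by [simulate_root()]; see also [make_thr_profile_fn()].
#' @param theta Thr division threshold (a.u.).
#' @return The updated `root_state`.
#' @export
step_root <- function(state, thr_fn, theta) {
  config <- state$config
  dt_scale <- config$dt / 0.1
  new_files <- lapply(state$files, function(f) {
    out <- step_file(f, state$zone, config, thr_fn, theta, dt_scale)
    out
  })
  # assign fresh ids to shootward daughters so ids stay unique
  nid <- state$next_id
  for (k in seq_along(new_files)) {
    f <- new_files[[k]]
    if (!is.null(f$n_new) && f$n_new > 0) {
      dup <- duplicated(f$id)
      f$id[dup] <- nid + seq_len(sum(dup)) - 1L
      nid <- nid + sum(dup)
    }
    f$n_new <- NULL
    new_files[[k]] <- f
  }
  state$files <- new_files
  state$next_id <- nid
  state$time <- state$time + config$dt
  state
}

#' Expose the simulator's Thr evaluator
#'
#' Builds the function used by [simulate_root()] to look up steady-state
#' free Thr at a cell midpoint (grid units). Exported for inspection and
#' for computing thresholds.
#'
#' @inheritParams simulate_root
#' @param axis_length Normalisation length (grid units) mapping grid
#'   positions onto the \[0, 1\] gradient domain (clamped shootward).
#' @return `function(grid_pos) -> Thr a.u.`
#' @export
make_thr_profile_fn <- function(params, gradients = default_gradients(),
                                axis_length,
                                variant = c("synthesis_only", "extended")) {
  make_thr_fn(params, gradients, axis_length, variant)
}

# Default division threshold: half the wild-type steady-state Thr at the
# stem cell niche under the same kinetic constants.
default_theta <- function(params, gradients, variant) {
  wt <- params
  wt$genotype <- "Wt"
  prof <- thr_profile(wt, gradients, positions = 0, variant = variant)
  0.5 * prof$thr[1]
}

#' Simulate root growth
#'
#' Runs the lattice simulator from the shared initial condition to
#' `t_max`, recording total root length, cell counts, whole-root free Thr
#' and per-cell snapshots at every step. The simulator is deterministic.
#'
#' @param config A [sim_config()].
#' @param params A [thr_params()] whose genotype should match
#'   `config$genotype`; defaults to `thr_params(genotype = config$genotype)`.
#' @param gradients Expression gradients (see [default_gradients()]).
#' @param variant Thr model variant used for the gate.
#' @return A list of class `root_trajectory` with elements `growth` (tibble:
#'   `time`, `total_length`, `n_cells`, `total_thr`), `snapshots` (tibble of
#'   per-cell records for the analysis file(s)), `zone`, `axis_length`,
#'   `theta`, `config`, `params`.
#' @export
#' @examples
#' traj <- simulate_root(sim_config(t_max = 1))
#' dplyr::last(traj$growth$total_length)
simulate_root <- function(config,
                          params = thr_params(genotype = config$genotype),
                          gradients = default_gradients(),
                          variant = c("synthesis_only", "extended")) {
  stopifnot(inherits(config, "sim_config"))
  variant <- match.arg(variant)
  if (params$genotype != config$genotype) {
    stop("`params$genotype` must match `config$genotype`", call. = FALSE)
  }
  state <- init_root(config)
  thr_fn <- make_thr_fn(params, gradients, state$axis_length, variant)
  theta <- config$thr_division_threshold %||%
    default_theta(params, gradients, variant)

  n_steps <- max(0L, round(config$t_max / config$dt))
  rec_times <- numeric(n_steps + 1L)
  rec_len <- numeric(n_steps + 1L)
  rec_ncell <- integer(n_steps + 1L)
  rec_thr <- numeric(n_steps + 1L)
  snaps <- vector("list", n_steps + 1L)

  record <- function(state, i) {
    rec_times[i] <<- state$time
    rec_len[i] <<- sum(vapply(state$files, function(f) sum(f$length), 0))
    rec_ncell[i] <<- sum(vapply(state$files, function(f) length(f$id), 0L))
    rec_thr[i] <<- total_free_thr(state, thr_fn)
    snaps[[i]] <<- state_snapshot(state, files = seq_len(config$snapshot_files))
  }
  record(state, 1L)
  for (s in seq_len(n_steps)) {
    state <- step_root(state, thr_fn, theta)
    prev <- rec_len[s]
    record(state, s + 1L)
    if (rec_len[s + 1L] < prev) {
      stop("internal consistency error: total length decreased", call. = FALSE)
    }
  }

  growth <- tibble::tibble(
    time = rec_times, total_length = rec_len,
    n_cells = rec_ncell, total_thr = rec_thr
  )
  snapshots <- dplyr::bind_rows(snaps)
  structure(
    list(
      growth = growth, snapshots = snapshots, zone = state$zone,
      axis_length = state$axis_length, theta = theta, config = config,
      params = params, gradients = gradients, variant = variant,
      final_state = state
    ),
    class = "root_trajectory"
  )
}

#' @export
print.root_trajectory <- function(x, ...) {
  g <- classify_growth(x)
  cat(sprintf(
    "<root_trajectory> genotype %s, t = 0..%g (dt = %g)\n  final length %g grid units, %d cells, growth: %s\n",
    x$config$genotype, x$config$t_max, x$config$dt,
    dplyr::last(x$growth$total_length), dplyr::last(x$growth$n_cells),
    g$classification
  ))
  invisible(x)
}

# Per-cell snapshot of a root state as a tibble.
state_snapshot <- function(state, files = seq_along(state$files)) {
  rows <- lapply(files, function(k) {
    f <- state$files[[k]]
    start <- cumsum(f$length) - f$length
    tibble::tibble(
      time = state$time, file = k, cell_id = f$id,
      type = .TYPES[f$type], grid_start = start, length = f$length,
      birth_length = f$birth, divisions_used = f$divu
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract ordered cell lengths from a zone/domain
#'
#' Returns the lengths (grid units) of the cells whose midpoint lies in the
#' requested domain, ordered rootward to shootward. QC and stem (initial)
#' cells belong to the stem cell niche and are excluded from the PD/TD/RAM
#' domains.
#'
#' @param x A `root_state` or `root_trajectory`.
#' @param domain One of `"PD"`, `"TD"`, `"RAM"` (= PD + TD), `"EZ+DZ"`.
#' @param file_index Cell file to read (default 1, the cortex analysis
#'   file).
#' @param time For trajectories, the recorded time to read (default: the
#'   final time). The nearest recorded step is used.
#' @return Numeric vector of cell lengths (possibly empty).
#' @export
cell_lengths <- function(x, domain = c("RAM", "PD", "TD", "EZ+DZ"),
                         file_index = 1, time = NULL) {
  domain <- match.arg(domain)
  UseMethod("cell_lengths")
}

#' @export
cell_lengths.root_state <- function(x, domain = c("RAM", "PD", "TD", "EZ+DZ"),
                                    file_index = 1, time = NULL) {
  domain <- match.arg(domain)
  snap <- state_snapshot(x, files = file_index)
  domain_lengths(snap, x$zone, domain)
}

#' @export
cell_lengths.root_trajectory <- function(x,
                                         domain = c("RAM", "PD", "TD", "EZ+DZ"),
                                         file_index = 1, time = NULL) {
  domain <- match.arg(domain)
  snap <- snapshot_at(x, time)
  snap <- snap[snap$file == file_index, , drop = FALSE]
  domain_lengths(snap, x$zone, domain)
}

# Nearest recorded snapshot at a requested time.
snapshot_at <- function(traj, time = NULL) {
  times <- unique(traj$snapshots$time)
  t_use <- if (is.null(time)) max(times) else times[which.min(abs(times - time))]
  traj$snapshots[abs(traj$snapshots$time - t_use) < 1e-9, , drop = FALSE]
}

domain_lengths <- function(snap, zone, domain) {
  mid <- snap$grid_start + snap$length / 2
  niche <- snap$type %in% c("QC", "stem_initial")
  keep <- switch(domain,
    "PD" = !niche & mid <= zone$pd_end &
      snap$type %in% c("transit_amplifying", "ta_exhausted"),
    "TD" = !niche & mid > zone$pd_end & mid <= zone$td_end &
      snap$type %in% c("transit_amplifying", "ta_exhausted"),
    "RAM" = !niche & mid <= zone$td_end &
      snap$type %in% c("transit_amplifying", "ta_exhausted"),
    "EZ+DZ" = mid > zone$td_end
  )
  snap$length[keep][order(mid[keep])]
}

#' Whole-root free Thr content
#'
#' Sum over all cells (all files) of the midpoint steady-state Thr times
#' cell length.
#'
#' @param x A `root_state` or `root_trajectory`.
#' @param thr_fn For states, the Thr evaluator (grid position -> a.u.).
#' @param time For trajectories, the recorded time (default: final).
#' @return Total free Thr (a.u.).
#' @export
total_free_thr <- function(x, thr_fn = NULL, time = NULL) {
  UseMethod("total_free_thr")
}

#' @export
total_free_thr.root_state <- function(x, thr_fn = NULL, time = NULL) {
  if (is.null(thr_fn)) stop("`thr_fn` is required for a root_state", call. = FALSE)
  sum(vapply(x$files, function(f) {
    start <- cumsum(f$length) - f$length
    mid <- start + f$length / 2
    sum(thr_fn(mid) * f$length)
  }, 0))
}

#' @export
total_free_thr.root_trajectory <- function(x, thr_fn = NULL, time = NULL) {
  g <- x$growth
  if (is.null(time)) {
    return(dplyr::last(g$total_thr))
  }
  g$total_thr[which.min(abs(g$time - time))]
}

#' Classify a growth trajectory as determinate or indeterminate
#'
#' A root is classified determinate (growth plateau) when its relative
#' total-length increase over the trailing `window` a.u. of simulated time
#' falls below `tol` per a.u.
#'
#' @param traj A `root_trajectory`.
#' @param window Trailing window (a.u.); default 1.
#' @param tol Relative growth per a.u. below which the root is a plateau;
#'   default 0.001 (0.1 %).
#' @return A one-row tibble: `classification`, `rel_growth_rate`.
#' @export
classify_growth <- function(traj, window = 1, tol = 0.001) {
  g <- traj$growth
  t_end <- dplyr::last(g$time)
  i0 <- which.min(abs(g$time - (t_end - window)))
  l0 <- g$total_length[i0]
  l1 <- dplyr::last(g$total_length)
  span <- t_end - g$time[i0]
  rate <- if (span > 0) (l1 - l0) / l0 / span else 0
  tibble::tibble(
    classification = ifelse(rate < tol, "determinate", "indeterminate"),
    rel_growth_rate = rate
  )
}
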