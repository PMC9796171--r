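# Independent oracles used to validate the package's own implementations.

# Exhaustive search over all admissible placements of m breakpoints with
# minimal segment size h: the brute-force counterpart of the dynamic
# programme in fit_breakpoints().
exhaustive_breakpoints <- function(y, m, h) {
  n <- length(y)
  seg_rss <- function(i, j) {
    x <- i:j
    yy <- y[i:j]
    sum(stats::lm.fit(cbind(1, x), yy)$residuals^2)
  }
  if (m == 0) {
    return(list(breakpoints = integer(0), rss = seg_rss(1, n)))
  }
  # candidate breakpoint index sets (last index of each non-final segment)
  cands <- utils::combn(seq_len(n - 1), m, simplify = FALSE)
  best <- NULL
  best_rss <- Inf
  for (bp in cands) {
    ends <- c(bp, n)
    starts <- c(1, utils::head(ends, -1) + 1)
    if (any(ends - starts + 1 < h)) next
    rss <- sum(vapply(
      seq_along(ends),
      function(k) seg_rss(starts[k], ends[k]), 0
    ))
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- bp
    }
  }
  list(breakpoints = best, rss = best_rss)
}

# Exact two-sided Mann-Whitney p-value by brute-force enumeration of the
# U distribution over all assignments of ranks to the first sample
# (continuous data, no ties). Two-sided p doubles the smaller tail, capped
# at 1.
exact_mwu_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  all_ranks <- seq_len(n + m)
  u_all <- apply(combos, 2, function(idx) {
    sum(all_ranks[idx]) - n * (n + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Long-time numerical integration of the extended Thr/Gly/Ile ODE system,
# an independent route to the steady state solved algebraically in
# steady_state_extended().
integrate_extended <- function(params, e_mto2, e_tsy2, e_tha12, e_omr1,
                               t_end = 400) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  P <- params$delta *
    steady_state_synthesis(params, e_mto2, e_tsy2)
  a <- if (e_tha12 == 0) 0 else e_tha12 / (params$Km3 + e_tha12)
  b <- if (e_omr1 == 0) 0 else e_omr1 / (params$Km4 + e_omr1)
  rhs <- function(t, y, parms) {
    g <- params$Km5 / (params$Km5 + y[3])
    list(c(
      P - a * y[1] - b * g * y[1] - params$delta * y[1],
      a * y[1] - params$delta * y[2],
      b * g * y[1] - params$delta * y[3]
    ))
  }
  out <- deSolve::ode(
    y = c(0, 0, 0), times = c(0, t_end), func = rhs, parms = NULL,
    rtol = 1e-12, atol = 1e-14
  )
  stats::setNames(out[2, 2:4], c("thr", "gly", "ile"))
}

# Normal-approximation two-sided Mann-Whitney p (continuity corrected, no
# ties), written independently of compare_distributions() for closed-form
# agreement checks.
approx_mwu_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  sd <- sqrt(n * m * (n + m + 1) / 12)
  z <- (abs(u - mu) - 0.5) / sd
  2 * stats::pnorm(-max(z, 0))
}
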