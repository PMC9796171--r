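#' Parameters of the free-Thr steady-state model
#'
#' Houses the kinetic constants of the Thr synthesis/catabolism model. Thr is
#' produced from a constant substrate supply `S` (O-phosphohomoserine) by the
#' two threonine synthases MTO2 and TSY2 with Michaelis-Menten dependence on
#' enzyme level, and is consumed by a first-order usage/decay term `delta`
#' shared by Thr, Gly and Ile. The extended model adds catabolism by THA1/2
#' (producing Gly) and OMR1 (producing Ile, feedback-inhibited by Ile).
#'
#' In the `mto2-2` genotype the MTO2 production term is removed and the TSY2
#' half-activity constant `Km2` is divided by `tsy2_compensation`,
#' representing the putative compensatory activity of TSY2 in the mutant.
#'
#' @param S Substrate supply (a.u.), constant along the axis.
#' @param Km1,Km2 MTO2 / TSY2 activity at which Thr production is
#'   half-maximal (a.u.). Wild-type parameterisations keep `Km2 >= 100 * Km1`
#'   (the experimentally established two-orders-of-magnitude activity
#'   difference between the enzymes).
#' @param Km3,Km4 THA1/2 / OMR1 activity at which production of Thr-derived
#'   Gly / Ile is half-maximal (a.u.).
#' @param Km5 Ile level at which negative regulation of OMR1 is half-maximal
#'   (a.u.).
#' @param delta First-order usage rate for Thr, Gly and Ile (per a.u. time).
#' @param genotype `"Wt"` or `"mto2-2"`.
#' @param tsy2_compensation Dimensionless factor >= 1 applied to `Km2` (as a
#'   divisor) in the mutant only. The default 250 makes the default
#'   parameterisation pass the 1.5-fold whole-root Thr selection criterion.
#'
#' @return A list of class `thr_params`.
#' @export
#' @examples
#' thr_params()
#' thr_params(genotype = "mto2-2")
thr_params <- function(S = 1, Km1 = 10, Km2 = 1000, Km3 = 10, Km4 = 10,
                       Km5 = 10, delta = 1, genotype = c("Wt", "mto2-2"),
                       tsy2_compensation = 250) {
  genotype <- match.arg(genotype)
  vals <- c(
    S = S, Km1 = Km1, Km2 = Km2, Km3 = Km3, Km4 = Km4, Km5 = Km5,
    delta = delta
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rate/affinity parameters must be strictly positive",
      call. = FALSE
    )
  }
  if (!is.finite(tsy2_compensation) || tsy2_compensation < 1) {
    stop("`tsy2_compensation` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      S = S, Km1 = Km1, Km2 = Km2, Km3 = Km3, Km4 = Km4, Km5 = Km5,
      delta = delta, genotype = genotype,
      tsy2_compensation = tsy2_compensation
    ),
    class = "thr_params"
  )
}

#' @export
print.thr_params <- function(x, ...) {
  cat("<thr_params> genotype:", x$genotype, "\n")
  cat(sprintf(
    "  S = %g, delta = %g\n  Km1 = %g, Km2 = %g (tsy2_compensation = %g)\n  Km3 = %g, Km4 = %g, Km5 = %g\n",
    x$S, x$delta, x$Km1, x$Km2, x$tsy2_compensation, x$Km3, x$Km4, x$Km5
  ))
  invisible(x)
}

# Effective TSY2 half-activity constant: compensated in the mutant.
km2_effective <- function(params) {
  if (params$genotype == "mto2-2") params$Km2 / params$tsy2_compensation else params$Km2
}

#' Steady-state free Thr under the synthesis-only model
#'
#' Closed-form steady state of `d[Thr]/dt = S * [MTO2]/(Km1 + [MTO2]) +
#' S * [TSY2]/(Km2 + [TSY2]) - delta * [Thr]`. For genotype `"mto2-2"` the
#' MTO2 term is removed and `Km2` is divided by the compensation factor.
#'
#' @param params A [thr_params()] object.
#' @param e_mto2,e_tsy2 Expression (a.u.) of MTO2 and TSY2, vectors of equal
#'   length (or length 1).
#' @return Steady-state free Thr (a.u.); always in `[0, 2 * S / delta]`.
#' @export
#' @examples
#' steady_state_synthesis(thr_params(), e_mto2 = 10, e_tsy2 = 0) # = S/(2 delta)
steady_state_synthesis <- function(params, e_mto2, e_tsy2) {
  stopifnot(inherits(params, "thr_params"))
  if (any(e_mto2 < 0) || any(e_tsy2 < 0)) {
    stop("enzyme expression must be >= 0", call. = FALSE)
  }
  km2 <- km2_effective(params)
  tsy2_term <- ifelse(e_tsy2 == 0, 0, e_tsy2 / (km2 + e_tsy2))
  mto2_term <- if (params$genotype == "mto2-2") {
    0
  } else {
    ifelse(e_mto2 == 0, 0, e_mto2 / (params$Km1 + e_mto2))
  }
  (params$S / params$delta) * (mto2_term + tsy2_term)
}

#' Steady state of the extended Thr/Gly/Ile model
#'
#' Solves the steady state of the three-variable system
#' \deqn{d[Thr]/dt = P - a[Thr] - b g(Ile) [Thr] - \delta [Thr]}
#' \deqn{d[Gly]/dt = a[Thr] - \delta [Gly]}
#' \deqn{d[Ile]/dt = b g(Ile) [Thr] - \delta [Ile]}
#' where `P` is the genotype-dependent synthesis flux of the synthesis-only
#' model, `a = [THA12]/(Km3 + [THA12])`, `b = [OMR1]/(Km4 + [OMR1])` and
#' `g(Ile) = Km5/(Km5 + Ile)` is the Ile feedback on OMR1 activity.
#'
#' The steady state reduces to a single monotone scalar equation in Ile,
#' solved by safeguarded bisection ([stats::uniroot()]) to machine tolerance;
#' the residual time-derivatives of the returned state are checked to be
#' below `1e-8` relative to the production flux. With `e_tha12 = e_omr1 = 0`
#' the result equals [steady_state_synthesis()] exactly.
#'
#' @inheritParams steady_state_synthesis
#' @param e_tha12,e_omr1 Expression (a.u.) of THA1/2 and OMR1.
#' @return A tibble with columns `thr`, `gly`, `ile` (one row per position).
#' @export
#' @examples
#' p <- thr_params()
#' steady_state_extended(p, e_mto2 = 10, e_tsy2 = 10, e_tha12 = 10, e_omr1 = 10)
steady_state_extended <- function(params, e_mto2, e_tsy2, e_tha12, e_omr1) {
  stopifnot(inherits(params, "thr_params"))
  if (any(e_tha12 < 0) || any(e_omr1 < 0)) {
    stop("enzyme expression must be >= 0", call. = FALSE)
  }
  n <- max(length(e_mto2), length(e_tsy2), length(e_tha12), length(e_omr1))
  e_mto2 <- rep_len(e_mto2, n)
  e_tsy2 <- rep_len(e_tsy2, n)
  e_tha12 <- rep_len(e_tha12, n)
  e_omr1 <- rep_len(e_omr1, n)

  # production flux P = delta * synthesis-only steady state
  P <- params$delta * steady_state_synthesis(params, e_mto2, e_tsy2)
  a <- ifelse(e_tha12 == 0, 0, e_tha12 / (params$Km3 + e_tha12))
  b <- ifelse(e_omr1 == 0, 0, e_omr1 / (params$Km4 + e_omr1))
  delta <- params$delta
  Km5 <- params$Km5

  solve_one <- function(P_i, a_i, b_i) {
    if (P_i == 0) {
      return(c(thr = 0, gly = 0, ile = 0))
    }
    if (b_i == 0) {
      thr <- P_i / (delta + a_i)
      return(c(thr = thr, gly = thr * a_i / delta, ile = 0))
    }
    # F(I) = I - Thr(I) * b * g(I) / delta, strictly increasing in I
    fn <- function(I) {
      g <- Km5 / (Km5 + I)
      thr <- P_i / (delta + a_i + b_i * g)
      I - thr * b_i * g / delta
    }
    upper <- P_i * b_i / delta^2 + 1e-9
    root <- stats::uniroot(fn, c(0, upper), tol = 1e-13, maxiter = 2000L)
    ile <- root$root
    g <- Km5 / (Km5 + ile)
    thr <- P_i / (delta + a_i + b_i * g)
    c(thr = thr, gly = thr * a_i / delta, ile = ile)
  }

  out <- vapply(
    seq_len(n),
    function(i) solve_one(P[i], a[i], b[i]),
    numeric(3)
  )
  thr <- unname(out[1, ])
  gly <- unname(out[2, ])
  ile <- unname(out[3, ])

  # residual time-derivatives must vanish at the reported state
  g <- Km5 / (Km5 + ile)
  resid <- pmax(
    abs(P - a * thr - b * g * thr - delta * thr),
    abs(a * thr - delta * gly),
    abs(b * g * thr - delta * ile)
  )
  rel <- resid / pmax(P, .Machine$double.eps)
  if (any(rel > 1e-8)) {
    stop(sprintf(
      "extended steady-state solver did not converge (max relative residual %.3g)",
      max(rel)
    ), call. = FALSE)
  }
  tibble::tibble(thr = thr, gly = gly, ile = ile)
}

#' Predict the amino-acid profile along the root axis
#'
#' Evaluates the expression gradients at each position and returns the
#' per-position steady state of the chosen model variant. Position 0 is the
#' stem cell niche (SCN); position 1 the shootward end of the modelled axis.
#'
#' @param params A [thr_params()] object.
#' @param gradients A gradient tibble (see [default_gradients()]); must
#'   contain MTO2 and TSY2, plus THA12 and OMR1 for the extended variant.
#' @param positions Numeric vector of normalised positions; default 101
#'   evenly spaced points on \[0, 1\].
#' @param variant `"synthesis_only"` (closed form) or `"extended"`
#'   (numerical steady state with catabolism and Ile feedback).
#' @return A tibble of class `thr_profile` with columns `position`, `thr`,
#'   `gly`, `ile` (the latter two `NA` for the synthesis-only variant).
#' @export
#' @examples
#' thr_profile(thr_params(), default_gradients(), positions = seq(0, 1, 0.25))
thr_profile <- function(params, gradients = default_gradients(),
                        positions = seq(0, 1, length.out = 101),
                        variant = c("synthesis_only", "extended")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "thr_params"))
  if (variant == "synthesis_only") {
    e <- eval_gradients(gradients, positions, c("MTO2", "TSY2"))
    thr <- steady_state_synthesis(params, e$MTO2, e$TSY2)
    out <- tibble::tibble(
      position = positions, thr = thr,
      gly = NA_real_, ile = NA_real_
    )
  } else {
    e <- eval_gradients(gradients, positions, c("MTO2", "TSY2", "THA12", "OMR1"))
    ss <- steady_state_extended(params, e$MTO2, e$TSY2, e$THA12, e$OMR1)
    out <- tibble::tibble(
      position = positions, thr = ss$thr, gly = ss$gly, ile = ss$ile
    )
  }
  attr(out, "model_variant") <- variant
  attr(out, "genotype") <- params$genotype
  class(out) <- c("thr_profile", class(out))
  out
}

#' Classify the qualitative pattern of an amino-acid profile
#'
#' Encodes the qualitative gradient predictions as named booleans:
#' * `max_at_scn` — the Thr maximum sits at the SCN (first position), the
#'   wild-type synthesis-only signature;
#' * `ez_elevated` — the Thr maximum sits shootward of the RAM (in the
#'   EZ/early DZ region), the mutant signature;
#' * `scn_low_positive` — Thr at the SCN is above zero but below the RAM
#'   mean ("relatively low yet still higher than zero");
#' * `gly_ile_max_at_scn` — both catabolites peak at the SCN (extended model
#'   only; `NA` otherwise).
#'
#' @param profile A `thr_profile` tibble (see [thr_profile()]).
#' @param ram_end Normalised position of the shootward RAM boundary used for
#'   region classification (default 0.4, proportional to the simulator's
#'   zone map).
#' @return A one-row tibble of logical flags.
#' @export
classify_pattern <- function(profile, ram_end = 0.4) {
  stopifnot(is.data.frame(profile))
  if (nrow(profile) < 3) {
    stop("profile must contain at least 3 positions", call. = FALSE)
  }
  pos <- profile$position
  thr <- profile$thr
  i_max <- which.max(thr)
  ram <- pos <= ram_end
  extended <- !all(is.na(profile$gly))
  gly_ile <- if (extended) {
    which.max(profile$gly) == 1L && which.max(profile$ile) == 1L
  } else {
    NA
  }
  tibble::tibble(
    max_at_scn = i_max == 1L,
    ez_elevated = pos[i_max] > ram_end,
    scn_low_positive = thr[1] > 0 & thr[1] < mean(thr[ram]),
    gly_ile_max_at_scn = gly_ile
  )
}
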