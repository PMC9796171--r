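---
title: "Modelling threonine-gated root meristem growth and cell-length zonation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling threonine-gated root meristem growth and cell-length zonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootzone)
```

## The biological question

The *Arabidopsis thaliana* root grows from its apical meristem (RAM), whose
proliferation domain (PD) supplies new cells that transit a slow-growing
transition domain (TD) before elongating and differentiating. Hypomorphic
mutants of the threonine synthase gene *MTO2* (*TS1*) show determinate root
growth: the meristem is gradually consumed. `rootzone` implements three
connected analyses of this phenotype:

1. a steady-state model of free threonine (Thr) along the root axis, driven
   by the opposing expression gradients of the two threonine synthases
   (MTO2, RAM-enriched; TSY2, shootward-enriched), optionally extended with
   Thr catabolism by THA1/2 (to glycine) and OMR1 (to isoleucine, with Ile
   feedback inhibition of OMR1);
2. a deterministic lattice simulator of root growth in which local free Thr
   gates cell division, reproducing indeterminate wild-type (Wt) and
   determinate *mto2-2* growth from a shared initial condition; and
3. a multiple-structural-change (MSC) zonation analysis that segments
   cortical cell-length profiles into linear regimes, selects the number of
   breakpoints by BIC, and maps segments onto PD/TD/EZ domains.

A synthetic profile generator supplies cell-length cohorts with the
statistical structure the MSC analysis assumes, so the whole pipeline is
testable without microscopy data.

## The steady-state Thr model

Each cell (or axis position $x \in [0,1]$, with $x = 0$ the quiescent
centre) sees enzyme levels given by clamped linear gradients
$E_g(x) = s_g\,\max(0,\ a_g + b_g x)$. Thr synthesis is Michaelis–Menten in
enzyme level with a constant substrate supply $S$ (O-phosphohomoserine) and
a first-order usage term $\delta$:

$$\frac{d[\mathrm{Thr}]}{dt} = S\frac{[\mathrm{MTO2}]}{K_{m1}+[\mathrm{MTO2}]}
 + S\frac{[\mathrm{TSY2}]}{K_{m2}+[\mathrm{TSY2}]} - \delta\,[\mathrm{Thr}].$$

The closed-form steady state is bounded by $2S/\delta$. The extended model
adds two catabolic fluxes, first-order in Thr with Michaelis–Menten
dependence on enzyme level, and Ile feedback on OMR1 activity as the factor
$K_{m5}/(K_{m5}+[\mathrm{Ile}])$:

$$\frac{d[\mathrm{Thr}]}{dt} = P - a[\mathrm{Thr}] - b\,g(\mathrm{Ile})[\mathrm{Thr}] - \delta[\mathrm{Thr}],
\qquad
\frac{d[\mathrm{Gly}]}{dt} = a[\mathrm{Thr}] - \delta[\mathrm{Gly}],
\qquad
\frac{d[\mathrm{Ile}]}{dt} = b\,g(\mathrm{Ile})[\mathrm{Thr}] - \delta[\mathrm{Ile}],$$

with $a = [\mathrm{THA12}]/(K_{m3}+[\mathrm{THA12}])$,
$b = [\mathrm{OMR1}]/(K_{m4}+[\mathrm{OMR1}])$ and $P$ the synthesis flux
above. At steady state the system collapses to one monotone scalar equation
in Ile, which `steady_state_extended()` solves with `stats::uniroot()` at
tolerance `1e-13` on a bracket $[0,\ Pb/\delta^2]$; the returned state is
rejected unless all three residual time-derivatives are below $10^{-8}$
relative to $P$. Setting the catabolic enzyme levels to zero reduces the
extended model to the synthesis-only closed form exactly (same arithmetic
path, machine-identical). The test suite cross-checks the algebraic steady
state against long-time `deSolve` integration on random parameter sets.

The *mto2-2* genotype removes the MTO2 production term and divides $K_{m2}$
by a compensation factor representing up-regulated TSY2 activity.

### Default parameters and why

| parameter | default | meaning |
|---|---|---|
| `S`, `delta` | 1, 1 | arbitrary supply/usage scales; only ratios matter |
| `Km1`, `Km2` | 10, 1000 | Wt keeps `Km2 >= 100 * Km1`, the reported two-orders-of-magnitude activity difference between MTO2 and TSY2 |
| `Km3`, `Km4`, `Km5` | 10 each | mid-range of the 1–100 sweep interval |
| `tsy2_compensation` | 250 | chosen (analytically, from the closed form) so the default set satisfies the experimentally established ~1.5-fold whole-root Thr excess of the mutant; with the default gradients the position-integrated mutant/Wt ratio is then ≈ 1.74 |
| gradients | MTO2 10 − 10x; TSY2 1 + 9x; THA12, OMR1 8 − 8x | coefficients are not published; these reproduce the qualitative patterns (MTO2 high at the niche and falling, TSY2 the reverse, catabolic enzymes RAM-enriched) and are fully configurable |

With these defaults the model predicts the qualitative patterns the package
tests assert: Wt Thr maximal at the stem cell niche (SCN) and declining
shootward; mutant Thr low (but positive) at the SCN and maximal in the
elongation/differentiation region; Gly and Ile maximal at the SCN in the
extended Wt model. `sweep_thr_parameters()` explores Km over 1–1000 and
$\delta$ over 1–10 (1–100 for the catabolic constants) by Latin-hypercube
sampling — the published set counts (10,000 and 125,000) cannot both arise
from one integer grid, so free sampling with a user-set `n_sets` and seed is
used; Wt draws violating `Km2 >= 100 * Km1` are rejection-resampled
uniformly over the admissible region.

## The lattice root simulator

Each of `n_files` independent cell files is a column of cells, each cell a
run of integer grid rows anchored at the QC. Zone boundaries (`pd_end`,
`td_end`, `ez_end`) are fixed positions in the QC-anchored frame derived
from the initial condition; a cell's zone is decided by its midpoint. The
shared Wt/mutant initial state per file is: 1 QC cell, 1 stem (initial)
cell, 32 PD transit-amplifying cells, 8 TD cells, 8 elongating cells graded
toward the final length, and 2 differentiated tail cells.

Rules per time step (`dt = 0.1` a.u.; increments are defined per reference
step and accumulated fractionally, so halving `dt` changes nothing):

* cycling PD cells add one grid row per step (stem cells every
  `stem_cycle_factor` = 2 steps) and divide on reaching twice their birth
  length, provided free Thr at their midpoint is at or above the threshold
  $\theta$; the rootward daughter takes the extra row of an odd parent;
* stem divisions are asymmetric: the rootward daughter remains the stem
  cell (unlimited capacity), the shootward daughter becomes
  transit-amplifying with a capacity of five divisions; daughters at five
  divisions become exhausted and never divide again;
* non-proliferating RAM cells — TD-zone cells, exhausted cells, and cells
  whose cycle is blocked by the Thr gate — grow slowly
  (`td_growth_increment` = 3 rows/step) up to a maximal RAM cell length
  (`ram_max_length`, default three times the birth length);
* cells whose midpoint passes the RAM boundary elongate at `ez_increment`
  (default 5) rows/step until `final_length` (default 80), then
  differentiate and stop; the QC neither grows nor divides.

Design choices where the source material is silent, and their rationale:

* **Thr gate blocks the cycle, not just the division instant.** A gated
  cell pauses at its division-ready size and behaves like a TD cell
  (slow growth to `ram_max_length`). This matches the observed behaviour of
  mutant RAM cells — slow growth and endoreduplication instead of mitosis —
  and gives the mutant a strict growth plateau: without it the QC-anchored
  stem cell would keep adding rows forever and no plateau would exist.
* **Bounded RAM cell size.** Cells inside the RAM do not elongate
  indefinitely; rapid elongation is EZ-specific. `ram_max_length = 3 *
  division_length_threshold` makes TD cells two to three times the size of
  PD cells, the range seen in real roots.
* **Phase-staggered initial PD cells.** Initial PD lengths cycle over
  `d .. 2d - 1` so divisions are asynchronous from the start; identical
  initial lengths would synchronise every division wave.
* **$\theta$ default**: half the Wt steady-state Thr at the SCN under the
  parameters in use. This places the mutant stem cell below the gate and
  the whole Wt PD above it. It is exposed as
  `thr_division_threshold`; setting it to 0 removes the gate and restores
  indeterminate mutant growth (a control asserted in the tests).
* **Growth classification**: a root is determinate when its relative
  total-length increase over the trailing 1 a.u. falls below 0.1% per a.u.
  Under the rules above the mutant plateau is exact (zero growth), so the
  classification is insensitive to this tolerance.
* **Position mapping**: grid midpoints are divided by the initial root
  length and clamped to [0, 1]; cells produced beyond the initial axis see
  the shootward end of the expression gradients.

`find_indistinguishable_window()` compares, at every recorded time, the
mutant RAM cell-length distribution against the Wt TD and PD distributions
(Mann–Whitney U, normal approximation with tie and continuity correction —
appropriate for heavily tied grid-valued lengths; an unpaired Student's
t-test is also reported by `compare_distributions()`). A time qualifies
when the mutant RAM is indistinguishable from the Wt TD (`p > alpha`)
*and* separated from the Wt PD (`p <= alpha`); the window is the longest
contiguous run of qualifying times. Requiring both conditions makes the
window robust to the division-cohort waves of the deterministic lattice,
which can flip the TD-only comparison on single steps.

`robustness_sweep()` re-runs the paired simulations over a grid of division
thresholds {2,4,6,8,10}, elongation increments {3..8} and final lengths
{75,80,85,90} (the tests use a 2 × 2 × 2 sub-grid) and evaluates the four
shared outcomes: Wt indeterminate with mutant determinate; mutant
whole-root Thr above Wt; mutant SCN Thr below Wt; and a non-empty
indistinguishability window. Sweep runs use `t_max = 8` a.u. so that the
slowest grid corner (final length 90, increment 3) completes its plateau
inside the simulated interval; the single-run default remains `t_max = 5`.

## MSC zonation

For a sample of profiles, `compute_f()` sets the minimal-segment fraction
$f = \lceil 300/n_s \rceil / 100$ (the smallest two-decimal value with
$f\,n_s \ge 3$, where $n_s$ is the size of the smallest profile), and
`compute_h()` gives each root its minimal segment size
$h = \lfloor f n \rfloor$ subject to $3 \le h < n/2$; infeasible
combinations raise errors rather than clamping ($f n < 3$ cannot occur when
$f$ comes from the same sample).

`fit_breakpoints()` places $m$ breakpoints exactly, minimising the total
RSS of per-segment OLS lines (intercept and slope over 1-based cell index)
by dynamic programming over admissible segment ends; ties go to the
lexicographically smallest breakpoints. `select_breakpoints()` fits
$m = 0..2$ and keeps the minimum-BIC model, with ties resolved toward the
smaller $m$. The BIC convention is
$\mathrm{BIC} = -2\,\mathrm{LL} + k\log n$ with
$\mathrm{LL} = -\tfrac{n}{2}(\log 2\pi + \log(\mathrm{RSS}/n) + 1)$ and
$k = 2(m+1) + m + 1$ (segment coefficients, breakpoints, error variance).
Other reference implementations may count parameters differently, shifting
every BIC by a constant without changing selections. Domain annotation maps
$m = 2$ to PD | TD | EZ, $m = 1$ to TD | EZ (the whole RAM treated as TD),
and $m = 0$ to undetermined.

## Synthetic profiles

`generate_profile()` draws piecewise-linear mean structures plus additive
Gaussian noise (σ default 0.4 µm, truncated at 0.5 µm); presets give
three-regime wild-type-like, two-regime mutant-like and one-regime
exhausted profiles with PD cells of a few µm and EZ cells growing past
100 µm. `generate_cohort()` adds multiplicative between-root jitter
(CV 0.1) to segment starts and slopes. The generator emulates the mean
structure and noise of cortical cell-length profiles, not their biology:
cell sizes do not interact, regime boundaries are sharp, and noise is
homoscedastic. Passing tests therefore demonstrate correct recovery of
piecewise-linear structure at realistic noise, not performance on real
microscopy data, where regime transitions can be gradual and measurement
error scales with cell size. One consequence worth knowing: at the
mutant-like profile size (n ≈ 22) the BIC occasionally prefers an extra
breakpoint (about a quarter of noisy two-regime profiles), so cohort
percentages track, but do not equal, the generating mixture — the same
stringency the MSC approach shows on real cohorts.

## Problem sizes and numerical tolerances

The test suite and reproduction functions run the simulator to 5–8 a.u.
(50–80 steps, roughly 300–1100 cells across four files), sweep 1000
parameter sets, and analyse cohorts of 100 synthetic profiles — sizes
chosen so the full pipeline re-runs in about a minute while leaving every
selection rate far from its decision boundary. The extended steady state is
solved to `1e-13` bracket tolerance with residuals checked at `1e-8`
relative; the breakpoint DP uses a `1e-12` tie tolerance; `compute_h` adds
`1e-9` before flooring to absorb two-decimal floating-point error.

## Limitations

* Expression gradients are linear by construction; the model cannot encode
  non-monotone enzyme profiles without replacing the gradient type.
* The simulator is one-dimensional per file, with no radial signalling,
  root cap, or columella/lateral initials, and it is fully deterministic —
  the `seed` argument is provenance for future stochastic extensions.
* The Thr model assumes transcript level ∝ enzyme activity and a constant
  substrate pool; S-adenosylmethionine regulation of the synthases is
  deliberately out of scope.
* The Mann–Whitney p-value uses the tie-corrected normal approximation; for
  untied samples of size 3–4 it can deviate from the exact enumeration p by
  up to ≈ 0.04 (worst case enumerated in the tests), shrinking below 0.02
  from size 5 upward.

## Interfaces

All user-facing functions take and return data frames (tibbles) and
compose with the pipe; fitted objects provide `tidy()`, `glance()` and
`autoplot()` methods. Profiles move through plain TSV (`read_profiles()`,
`write_profiles()`, `validate_profiles()`), and `reproduce_all()` plus
`scripts/acceptance.R` (run with `--seed` and `--out`) are the scripted
entry points; the package is library-first and intentionally ships no
shell CLI beyond that script.
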