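# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted breakpoint model
#'
#' @param x An `msc_model`.
#' @param ... Unused.
#' @return A tibble with one row per fitted segment: `segment`, `start`,
#'   `end`, `n`, `intercept`, `slope`.
#' @method tidy msc_model
#' @export
tidy.msc_model <- function(x, ...) {
  x$segments
}

#' One-row summary of a fitted breakpoint model
#'
#' @param x An `msc_model`.
#' @param ... Unused.
#' @return A tibble: `n`, `h`, `m`, `breakpoints` (comma-separated), `rss`,
#'   `bic`.
#' @method glance msc_model
#' @export
glance.msc_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, h = x$h, m = x$m,
    breakpoints = paste(x$breakpoints, collapse = ","),
    rss = x$rss, bic = x$bic
  )
}

#' Tidy an MSC cohort analysis
#'
#' @param x An `msc_sample`.
#' @param ... Unused.
#' @return The per-root tibble (selected `m`, breakpoints, domain
#'   summaries).
#' @method tidy msc_sample
#' @export
tidy.msc_sample <- function(x, ...) {
  x$per_root
}

#' One-row-per-class summary of an MSC cohort analysis
#'
#' @param x An `msc_sample`.
#' @param ... Unused.
#' @return The cohort tibble of breakpoint-count percentages.
#' @method glance msc_sample
#' @export
glance.msc_sample <- function(x, ...) {
  x$cohort
}

#' Tidy a root growth trajectory
#'
#' @param x A `root_trajectory`.
#' @param ... Unused.
#' @return The growth tibble: `time`, `total_length`, `n_cells`,
#'   `total_thr`.
#' @method tidy root_trajectory
#' @export
tidy.root_trajectory <- function(x, ...) {
  x$growth
}

#' One-row summary of a root growth trajectory
#'
#' @param x A `root_trajectory`.
#' @param ... Unused.
#' @return A tibble: `genotype`, `t_max`, `final_length`, `n_cells`,
#'   `total_thr`, `classification`, `rel_growth_rate`.
#' @method glance root_trajectory
#' @export
glance.root_trajectory <- function(x, ...) {
  cls <- classify_growth(x)
  tibble::tibble(
    genotype = x$config$genotype,
    t_max = x$config$t_max,
    final_length = dplyr::last(x$growth$total_length),
    n_cells = dplyr::last(x$growth$n_cells),
    total_thr = dplyr::last(x$growth$total_thr),
    classification = cls$classification,
    rel_growth_rate = cls$rel_growth_rate
  )
}
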