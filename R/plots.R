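# ggplot2 autoplot() methods for the package's result types.

#' Plot an amino-acid profile along the root axis
#'
#' @param object A `thr_profile` (see [thr_profile()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thr_profile
#' @export
autoplot.thr_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("thr", "gly", "ile"),
    names_to = "species", values_to = "level"
  )
  long <- long[!is.na(long$level), , drop = FALSE]
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$position, y = .data$level, colour = .data$species)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "normalised position (0 = QC)",
      y = "steady-state level (a.u.)",
      colour = NULL,
      title = sprintf(
        "%s, %s model",
        attr(object, "genotype") %||% "profile",
        attr(object, "model_variant") %||% ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a root growth curve
#'
#' @param object A `root_trajectory`.
#' @param ... Unused.
#' @return A ggplot of total root length over time.
#' @method autoplot root_trajectory
#' @export
autoplot.root_trajectory <- function(object, ...) {
  ggplot2::ggplot(
    object$growth,
    ggplot2::aes(x = .data$time, y = .data$total_length)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "time (a.u.)", y = "total root length (grid units)",
      title = sprintf("%s root growth", object$config$genotype)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cell-length profile with its fitted segmented regression
#'
#' @param object An `msc_model` (see [fit_breakpoints()],
#'   [select_breakpoints()]).
#' @param ... Unused.
#' @return A ggplot of lengths over cell index with the fitted per-segment
#'   lines and breakpoint positions.
#' @method autoplot msc_model
#' @export
autoplot.msc_model <- function(object, ...) {
  pts <- tibble::tibble(
    cell_index = seq_len(object$n), length_um = object$lengths
  )
  seg_lines <- dplyr::bind_rows(lapply(
    seq_len(nrow(object$segments)),
    function(k) {
      s <- object$segments[k, ]
      tibble::tibble(
        segment = factor(s$segment),
        cell_index = c(s$start, s$end),
        length_um = s$intercept + s$slope * c(s$start, s$end)
      )
    }
  ))
  p <- ggplot2::ggplot(
    pts, ggplot2::aes(x = .data$cell_index, y = .data$length_um)
  ) +
    ggplot2::geom_point(size = 1.5, alpha = 0.7) +
    ggplot2::geom_line(
      data = seg_lines,
      ggplot2::aes(group = .data$segment),
      colour = "firebrick", linewidth = 0.9
    ) +
    ggplot2::labs(
      x = "cell index (from QC-adjacent cell)",
      y = "cell length (µm)",
      title = sprintf("segmented fit, m = %d", object$m)
    ) +
    ggplot2::theme_minimal()
  if (object$m > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$breakpoints + 0.5,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}
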