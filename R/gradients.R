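#' Linear expression gradients along the root axis
#'
#' Expression of each Thr-pathway enzyme gene is described by a linear
#' function of normalised position along the root axis, `scale * max(0,
#' intercept + slope * x)`, where `x = 0` is the quiescent centre (QC) and
#' `x = 1` the shootward end of the modelled axis. Evaluated expression is
#' clamped at zero, so a steep negative slope simply switches a gene off
#' shootward of the clamp point.
#'
#' @param gene Character vector of gene identifiers. Recognised genes are
#'   `"MTO2"`, `"TSY2"`, `"THA12"` and `"OMR1"`.
#' @param intercept Expression at the QC (arbitrary units, a.u.).
#' @param slope Change in expression per unit normalised position (a.u.).
#' @param scale Dimensionless multiplier applied after clamping; used by the
#'   expression-scaling simulations. Default 1.
#'
#' @return A tibble with columns `gene`, `intercept`, `slope`, `scale`.
#' @seealso [default_gradients()], [expression_at()]
#' @export
#' @examples
#' expression_gradient("MTO2", intercept = 10, slope = -10)
expression_gradient <- function(gene, intercept, slope, scale = 1) {
  stopifnot(is.character(gene), is.numeric(intercept), is.numeric(slope))
  if (any(scale < 0)) {
    stop("`scale` must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    gene = gene,
    intercept = as.numeric(intercept),
    slope = as.numeric(slope),
    scale = as.numeric(scale)
  )
}

#' Default expression gradients for the four modelled enzymes
#'
#' MTO2 (threonine synthase 1) is highest at the stem cell niche and decays
#' shootward; TSY2 (threonine synthase 2) shows the opposite gradient; the
#' catabolic enzymes THA1/2 and OMR1 are RAM-enriched. The coefficients are
#' configurable model inputs chosen to reproduce the qualitative patterns of
#' the published transcriptome-derived gradients (which are not printed as
#' numbers anywhere); see the package vignette for the rationale.
#'
#' @param scale Dimensionless multiplier applied to all four gradients
#'   (expression-scaling experiments). Default 1.
#' @return A tibble of gradients, one row per gene.
#' @export
#' @examples
#' default_gradients()
default_gradients <- function(scale = 1) {
  expression_gradient(
    gene = c("MTO2", "TSY2", "THA12", "OMR1"),
    intercept = c(10, 1, 8, 8),
    slope = c(-10, 9, -8, -8),
    scale = scale
  )
}

#' Evaluate an expression gradient at positions along the root
#'
#' @param gradients A gradient tibble as returned by [expression_gradient()]
#'   or [default_gradients()].
#' @param x Numeric vector of normalised positions in \[0, 1\].
#' @param gene If `gradients` holds several genes, the gene to evaluate.
#'
#' @return Numeric vector of expression values (a.u.), clamped at >= 0,
#'   the same length as `x`.
#' @export
#' @examples
#' expression_at(default_gradients(), c(0, 0.5, 1), gene = "MTO2")
expression_at <- function(gradients, x, gene = NULL) {
  stopifnot(is.data.frame(gradients))
  if (!is.null(gene)) {
    gradients <- gradients[gradients$gene == gene, , drop = FALSE]
  }
  if (nrow(gradients) != 1L) {
    stop("`gradients` must resolve to exactly one gene (use `gene = `)",
      call. = FALSE
    )
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("positions `x` must lie in [0, 1]", call. = FALSE)
  }
  gradients$scale * pmax(0, gradients$intercept + gradients$slope * x)
}

# Internal: evaluate all required gradients at positions, returning a list of
# numeric vectors keyed by gene. Missing genes raise a configuration error.
eval_gradients <- function(gradients, x, genes) {
  missing <- setdiff(genes, gradients$gene)
  if (length(missing) > 0) {
    stop(
      "missing required expression gradient(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  stats::setNames(
    lapply(genes, function(g) expression_at(gradients, x, gene = g)),
    genes
  )
}
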