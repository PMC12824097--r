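#' Nuclear-to-cytoplasmic intensity ratio
#'
#' The cytoplasmic region is the whole-cell mask minus the nuclear
#' mask (ROI_c = ROI_x - ROI_n). In `"mean-density"` mode (default)
#' each compartment's density is its mean pixel intensity; in
#' `"integrated-density"` mode it is the summed intensity (in which
#' case the ratio also reflects the compartment area ratio).
#'
#' @param image intensity matrix or single-slice
#'   [fluorescence_stack()].
#' @param nuclear_mask,cell_mask logical matrices; the nuclear mask
#'   must be strictly inside the cell mask.
#' @param mode `"mean-density"` or `"integrated-density"`.
#' @return An object of class `nc_ratio`: `nuclear_density`,
#'   `cytoplasmic_density`, `ratio`, `mode`. An empty cytoplasmic
#'   region yields `ratio = NA` (undefined), non-nested masks are an
#'   error.
#' @export
nuclear_cytoplasmic_ratio <- function(image, nuclear_mask, cell_mask,
                                      mode = c("mean-density",
                                               "integrated-density")) {
  mode <- match.arg(mode)
  if (inherits(image, "fluorescence_stack")) image <- .slice(image)
  if (!all(dim(image) == dim(nuclear_mask)) ||
      !all(dim(image) == dim(cell_mask)))
    stop("nuclear_cytoplasmic_ratio: shapes must match")
  if (any(nuclear_mask & !cell_mask))
    stop("nuclear_cytoplasmic_ratio: nuclear_mask must lie inside cell_mask")
  cyto_mask <- cell_mask & !nuclear_mask
  if (!any(nuclear_mask))
    stop("nuclear_cytoplasmic_ratio: empty nuclear mask")
  dens <- function(m) {
    if (mode == "mean-density") mean(image[m]) else sum(image[m])
  }
  nd <- dens(nuclear_mask)
  cd <- if (any(cyto_mask)) dens(cyto_mask) else NA_real_
  ratio <- if (is.finite(cd) && cd > 0) nd / cd else NA_real_
  structure(list(nuclear_density = nd, cytoplasmic_density = cd,
                 ratio = ratio, mode = mode),
            class = "nc_ratio")
}

#' @export
print.nc_ratio <- function(x, ...) {
  cat(sprintf("nc_ratio [%s]: nuclear %.4g / cytoplasmic %.4g = %.4g\n",
              x$mode, x$nuclear_density, x$cytoplasmic_density, x$ratio))
  invisible(x)
}

#' qPCR relative expression from CT values
#'
#' Delta-CT quantification: for each target-gene technical replicate,
#' `delta_ct = ct_target - mean(ct_housekeeping)` and relative
#' expression `2^(-delta_ct) * 100000`; per-replicate values are
#' transformed first and then averaged.
#'
#' @param ct_target target-gene CT replicates, cycles.
#' @param ct_housekeeping housekeeping-gene CT replicates, cycles.
#' @return An object of class `expression_record`: `delta_ct`
#'   (per replicate), `rel_expr_replicates`, `rel_expr` (their mean).
#' @examples
#' qpcr_relative_expression(25, 20)$rel_expr  # 3125
#' @export
qpcr_relative_expression <- function(ct_target, ct_housekeeping) {
  if (length(ct_target) == 0 || length(ct_housekeeping) == 0)
    stop("qpcr_relative_expression: inputs must be non-empty")
  delta <- ct_target - mean(ct_housekeeping)
  rel <- 2^(-delta) * 1e5
  structure(list(ct_target = ct_target,
                 ct_housekeeping = ct_housekeeping,
                 delta_ct = delta,
                 rel_expr_replicates = rel,
                 rel_expr = mean(rel)),
            class = "expression_record")
}

#' @export
print.expression_record <- function(x, ...) {
  cat(sprintf("expression_record: mean relative expression %.4g (n = %d)\n",
              x$rel_expr, length(x$rel_expr_replicates)))
  invisible(x)
}
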