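#' Detect fluorescence cluster peaks
#'
#' Local maxima (8-neighborhood) above a threshold, kept in descending
#' peak order with a minimum mutual separation, excluding peaks within
#' `edge_margin` of the image border (and outside an optional cell
#' mask). Edge-rejected peaks are counted in `excluded_edge`.
#'
#' @param fluor fluorescence image (matrix) or single-slice
#'   [fluorescence_stack()].
#' @param min_separation minimal center-to-center distance, px.
#' @param threshold absolute intensity threshold, or a quantile in
#'   (0, 1) when `threshold_quantile = TRUE`.
#' @param edge_margin border exclusion margin, px.
#' @param cell_mask optional logical matrix; peaks outside it are
#'   treated as edge-excluded.
#' @param threshold_quantile interpret `threshold` as a quantile.
#' @return An object of class `cluster_set`: `centers` (n x 2 matrix of
#'   (row, col)), `peak_values`, `excluded_edge`.
#' @export
detect_clusters <- function(fluor, min_separation = 5, threshold = 0.95,
                            edge_margin = 5L, cell_mask = NULL,
                            threshold_quantile = threshold < 1) {
  if (inherits(fluor, "fluorescence_stack")) fluor <- .slice(fluor)
  h <- nrow(fluor); w <- ncol(fluor)
  thr <- if (threshold_quantile) stats::quantile(fluor, threshold) else threshold
  # strict local maxima over the 8-neighborhood (ties toward first pixel)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- fluor
  is_max <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    is_max <- is_max & (fluor >= nb)
  }
  cand <- which(is_max & fluor > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(structure(list(centers = matrix(numeric(0), 0, 2),
                          peak_values = numeric(0), excluded_edge = 0L),
                     class = "cluster_set"))
  vals <- fluor[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- matrix(numeric(0), 0, 2); kv <- numeric(0); excl <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) > 0 &&
        any((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 < min_separation^2))
      next
    in_edge <- p[1] <= edge_margin || p[1] > h - edge_margin ||
      p[2] <= edge_margin || p[2] > w - edge_margin
    if (!in_edge && !is.null(cell_mask) && !cell_mask[p[1], p[2]])
      in_edge <- TRUE
    if (in_edge) { excl <- excl + 1L; next }
    keep <- rbind(keep, p); kv <- c(kv, vals[i])
  }
  rownames(keep) <- NULL
  colnames(keep) <- c("row", "col")
  structure(list(centers = keep, peak_values = kv, excluded_edge = excl),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d peaks (%d edge-excluded)\n",
              nrow(x$centers), x$excluded_edge))
  invisible(x)
}

#' Trace cluster positions back into pre-treatment coordinates
#'
#' Detects clusters on a post-treatment fluorescence frame and
#' translates their coordinates by `-shift` (from [register_frames()])
#' into the frame of the pre-treatment tension map, so baseline tension
#' can be read at the sites where ligand later binds. Centers falling
#' outside the map are dropped and counted.
#'
#' @param pre_map a [tension_map()] (defines the target frame bounds).
#' @param post_fluor post-treatment fluorescence image.
#' @param shift integer `c(dr, dc)` from [register_frames()].
#' @param ... passed to [detect_clusters()].
#' @return A `cluster_set` in pre-treatment coordinates with an extra
#'   field `dropped_oob`.
#' @export
baseline_backtrace <- function(pre_map, post_fluor, shift = c(0L, 0L), ...) {
  cs <- detect_clusters(post_fluor, ...)
  if (nrow(cs$centers) == 0) { cs$dropped_oob <- 0L; return(cs) }
  centers <- sweep(cs$centers, 2, shift, "-")
  d <- dim(pre_map$sigma_map)
  ok <- centers[, 1] >= 1 & centers[, 1] <= d[1] &
    centers[, 2] >= 1 & centers[, 2] <= d[2]
  cs$centers <- centers[ok, , drop = FALSE]
  cs$peak_values <- cs$peak_values[ok]
  cs$dropped_oob <- sum(!ok)
  cs
}
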