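#' Manders colocalization coefficients
#'
#' `m1` is the fraction of channel-1 intensity residing in pixels that
#' are foreground in both masks, relative to the total channel-1
#' intensity within its own mask; `m2` is symmetric.
#'
#' @param img1,img2 intensity images, same shape.
#' @param mask1,mask2 logical foreground masks, same shape.
#' @return List `m1`, `m2` in `[0, 1]`; an empty mask yields `NA` for
#'   the corresponding coefficient (undefined, not an error).
#' @export
manders_coefficients <- function(img1, img2, mask1, mask2) {
  if (!all(dim(img1) == dim(img2)) || !all(dim(img1) == dim(mask1)) ||
      !all(dim(img1) == dim(mask2)))
    stop("manders_coefficients: shapes must match")
  both <- mask1 & mask2
  m1 <- if (!any(mask1)) NA_real_ else sum(img1[both]) / sum(img1[mask1])
  m2 <- if (!any(mask2)) NA_real_ else sum(img2[both]) / sum(img2[mask2])
  list(m1 = m1, m2 = m2)
}

#' Select equatorial z slices from a cell-mask stack
#'
#' Keeps slices whose cell-mask area reaches at least `frac` of the
#' maximal slice area.
#'
#' @param cell_masks logical array H x W x Z (or a
#'   [fluorescence_stack()] whose first channel is a mask).
#' @param frac area fraction threshold.
#' @return Integer vector of slice indices.
#' @export
select_equatorial_slices <- function(cell_masks, frac = 0.8) {
  if (inherits(cell_masks, "fluorescence_stack"))
    cell_masks <- cell_masks$values[, , , 1, drop = FALSE] > 0
  if (length(dim(cell_masks)) == 4L) cell_masks <- cell_masks[, , , 1]
  areas <- apply(cell_masks, 3, sum)
  which(areas >= frac * max(areas))
}

#' Object-based endosome/actin colocalization fraction
#'
#' Per selected z slice: both channels are segmented by local
#' thresholding ([segment_channel()]), objects above the size cap are
#' removed from the actin channel ([remove_large_objects()], excluding
#' cortical actin), the two binary images are intersected, and the
#' intersection is labeled with 8-connectivity. The reported fraction
#' is the total number of colocalized objects over all slices divided
#' by the total number of endosomal objects over all slices. Manders
#' coefficients are accumulated over the same thresholded channels.
#'
#' @param endosome_stack,actin_stack single-channel
#'   [fluorescence_stack()]s of identical geometry, or one two-channel
#'   stack passed as `endosome_stack` (channels 1 = endosome,
#'   2 = actin) with `actin_stack = NULL`.
#' @param sensitivity local-threshold sensitivity factor.
#' @param area_cap actin object size cap, px.
#' @param slices slice selection (indices), default all.
#' @param window local-mean window for segmentation, px.
#' @return An object of class `coloc_result`: `n_endosome_total`,
#'   `n_coloc_total`, `fraction`, `manders_m1`, `manders_m2`, and the
#'   per-slice label maps.
#' @export
coloc_fraction <- function(endosome_stack, actin_stack = NULL,
                           sensitivity = 0.1, area_cap = 500,
                           slices = NULL, window = 31L) {
  if (is.null(actin_stack)) {
    if (dim(endosome_stack$values)[4] < 2L)
      stop("coloc_fraction: need two channels")
    actin_stack <- endosome_stack
    endo_ch <- 1L; actin_ch <- 2L
  } else {
    endo_ch <- 1L; actin_ch <- 1L
  }
  if (!all(dim(endosome_stack$values)[1:3] == dim(actin_stack$values)[1:3]))
    stop("coloc_fraction: stack geometries differ")
  nz <- dim(endosome_stack$values)[3]
  if (is.null(slices)) slices <- seq_len(nz)
  n_endo <- 0L; n_coloc <- 0L
  s1_tot <- s1_in <- s2_tot <- s2_in <- 0
  label_maps <- vector("list", length(slices))
  for (k in seq_along(slices)) {
    z <- slices[k]
    e_img <- .slice(endosome_stack, z, endo_ch)
    a_img <- .slice(actin_stack, z, actin_ch)
    e_mask <- segment_channel(e_img, sensitivity, window = window)
    a_mask <- segment_channel(a_img, sensitivity, window = window)
    a_mask <- remove_large_objects(a_mask, area_cap)
    e_lab <- label_objects(e_mask)
    overlap <- e_mask & a_mask
    c_lab <- label_objects(overlap)
    n_endo <- n_endo + e_lab$n_objects
    n_coloc <- n_coloc + c_lab$n_objects
    s1_tot <- s1_tot + sum(e_img[e_mask])
    s1_in <- s1_in + sum(e_img[overlap])
    s2_tot <- s2_tot + sum(a_img[a_mask])
    s2_in <- s2_in + sum(a_img[overlap])
    label_maps[[k]] <- list(slice = z, endosome = e_lab$labels,
                            coloc = c_lab$labels)
  }
  structure(list(n_endosome_total = n_endo, n_coloc_total = n_coloc,
                 fraction = if (n_endo > 0) n_coloc / n_endo else NA_real_,
                 manders_m1 = if (s1_tot > 0) s1_in / s1_tot else NA_real_,
                 manders_m2 = if (s2_tot > 0) s2_in / s2_tot else NA_real_,
                 label_maps = label_maps),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d / %d endosomal objects colocalized (fraction %.3f); M1 = %.3f, M2 = %.3f\n",
    x$n_coloc_total, x$n_endosome_total, x$fraction,
    x$manders_m1, x$manders_m2))
  invisible(x)
}
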