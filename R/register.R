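#' Integer-shift registration by normalized cross-correlation
#'
#' Finds the integer translation of `moving` that best matches
#' `reference` (template matching for stage-drift correction). The
#' shift maximizing the Pearson correlation of the overlapping region
#' is returned; ties are broken toward the smaller shift magnitude and
#' then lexicographically.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param max_shift maximal absolute shift searched, px.
#' @return Integer vector `c(dr, dc)`: the drift of `moving` relative
#'   to `reference` — a feature at `reference[i, j]` sits at
#'   `moving[i + dr, j + dc]`, so subtracting the shift maps moving
#'   coordinates back into the reference frame.
#' @export
register_frames <- function(reference, moving, max_shift = 10L) {
  if (!all(dim(reference) == dim(moving)))
    stop("register_frames: images must have the same shape")
  h <- nrow(reference); w <- ncol(reference)
  if (max_shift >= min(h, w))
    stop("register_frames: max_shift must be smaller than the image size")
  best <- c(0L, 0L); best_cc <- -Inf
  for (dr in -max_shift:max_shift) {
    ri <- max(1, 1 - dr):min(h, h - dr)
    mi <- ri + dr
    for (dc in -max_shift:max_shift) {
      rj <- max(1, 1 - dc):min(w, w - dc)
      mj <- rj + dc
      a <- reference[ri, rj]; b <- moving[mi, mj]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        cc <- if (isTRUE(all.equal(a, b))) 1 else -Inf
      } else cc <- stats::cor(as.vector(a), as.vector(b))
      if (cc > best_cc + 1e-12) {
        best <- c(dr, dc); best_cc <- cc
      } else if (abs(cc - best_cc) <= 1e-12) {
        cand <- c(dr, dc)
        if (sum(cand^2) < sum(best^2) ||
            (sum(cand^2) == sum(best^2) &&
             (cand[1] < best[1] ||
              (cand[1] == best[1] && cand[2] < best[2]))))
          best <- cand
      }
    }
  }
  as.integer(best)
}
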