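# shift a logical matrix by (dr, dc), padding with `fill`
.shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ri <- max(1, 1 + dr):min(h, h + dr)
  rj <- max(1, 1 + dc):min(w, w + dc)
  out[ri, rj] <- m[ri - dr, rj - dc]
  out
}

# binary erosion / dilation with the 3x3 cross structuring element
.erode_cross <- function(m) {
  m & .shift_mask(m, 1, 0) & .shift_mask(m, -1, 0) &
    .shift_mask(m, 0, 1) & .shift_mask(m, 0, -1)
}
.dilate_cross <- function(m) {
  m | .shift_mask(m, 1, 0) | .shift_mask(m, -1, 0) |
    .shift_mask(m, 0, 1) | .shift_mask(m, 0, -1)
}

# local mean via integral image with edge-normalized window counts
.local_mean <- function(img, window = 31L) {
  h <- nrow(img); w <- ncol(img)
  r <- window %/% 2L
  cs <- apply(img, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, h + 1, w + 1)
  S[2:(h + 1), 2:(w + 1)] <- cs
  i1 <- pmax(seq_len(h) - r, 1); i2 <- pmin(seq_len(h) + r, h)
  j1 <- pmax(seq_len(w) - r, 1); j2 <- pmin(seq_len(w) + r, w)
  A <- S[i2 + 1L, j2 + 1L, drop = FALSE]
  B <- S[i1, j2 + 1L, drop = FALSE]
  C <- S[i2 + 1L, j1, drop = FALSE]
  D <- S[i1, j1, drop = FALSE]
  tot <- A - B - C + D
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  tot / cnt
}

#' Segment a fluorescence channel by local-mean thresholding
#'
#' Foreground is where intensity exceeds the local mean (moving
#' `window` x `window` box) scaled by `1 + sensitivity`; an optional
#' despeckle pass — one binary erosion followed by one dilation with a
#' 3 x 3 cross element — removes isolated single pixels.
#'
#' @param slice 2-D intensity image.
#' @param sensitivity sensitivity factor in (0, 1); foreground requires
#'   `I > local_mean * (1 + sensitivity)`.
#' @param despeckle apply the erosion/dilation pass.
#' @param window local-mean window side, px.
#' @return Logical foreground mask.
#' @export
segment_channel <- function(slice, sensitivity = 0.1, despeckle = TRUE,
                            window = 31L) {
  if (!is.matrix(slice)) stop("segment_channel: input must be a 2-D image")
  if (sensitivity <= 0 || sensitivity >= 1)
    stop("segment_channel: sensitivity must lie in (0, 1)")
  mask <- slice > .local_mean(slice, window) * (1 + sensitivity)
  if (despeckle) mask <- .dilate_cross(.erode_cross(mask))
  mask
}

#' Label connected components with 8-connectivity
#'
#' Two-pass breadth-first labeling of foreground pixels; pixels
#' touching diagonally belong to the same object.
#'
#' @param mask logical matrix.
#' @return An object of class `labeled_objects`: `labels` (integer
#'   matrix, 0 = background, objects numbered consecutively), `areas`
#'   (px per object), `n_objects`, `connectivity = 8`.
#' @export
label_objects <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    labels[start] <- cur
    while (length(frontier) > 0) {
      r0 <- ((frontier - 1L) %% h) + 1L
      c0 <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(nb))) {
        r <- r0 + nb$dr[k]; cc <- c0 + nb$dc[k]
        ok <- r >= 1 & r <= h & cc >= 1 & cc <= w
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * h + r[ok]
        idx <- idx[mask[idx] & labels[idx] == 0L]
        if (length(idx)) {
          labels[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  areas <- if (cur > 0) as.integer(tabulate(labels[labels > 0], cur)) else integer(0)
  structure(list(labels = labels, areas = areas, n_objects = cur,
                 connectivity = 8L),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("labeled_objects: %d object(s), areas %s px\n", x$n_objects,
              paste(x$areas, collapse = ", ")))
  invisible(x)
}

#' Remove connected components above an area cap
#'
#' Drops 8-connected objects larger than `area_cap` pixels (cortical
#' actin presents as a single large continuous object and is excluded
#' this way); all other objects are untouched. Idempotent.
#'
#' @param mask logical matrix.
#' @param area_cap maximal object area kept, px.
#' @return Logical mask.
#' @export
remove_large_objects <- function(mask, area_cap = 500) {
  if (area_cap <= 0) stop("remove_large_objects: area_cap must be positive")
  lab <- label_objects(mask)
  if (lab$n_objects == 0) return(mask != 0)
  big <- which(lab$areas > area_cap)
  out <- mask != 0
  out[lab$labels %in% big] <- FALSE
  out
}
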