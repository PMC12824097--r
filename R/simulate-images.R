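# logical H x W disk mask; center = c(row, col)
.disk_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Simulate a TIRF-like fluorescence frame with Gaussian spots
#'
#' Sum of isotropic Gaussian spots (diffraction-limited ligand clusters)
#' on a constant background with additive Gaussian noise, clipped at 0.
#'
#' @param centers n x 2 matrix of (row, col) spot centers (1-based,
#'   may be fractional), or `NULL` for no spots.
#' @param amplitudes spot peak amplitudes, a.u. (recycled).
#' @param psf_sigma Gaussian spot width, px.
#' @param background constant background level, a.u.
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param shape image dimensions `c(H, W)`.
#' @param seed RNG seed.
#' @return A single-slice [fluorescence_stack()]; spot centers are kept
#'   in `$extra$centers`.
#' @export
simulate_tirf_frame <- function(centers = NULL, amplitudes = 200,
                                psf_sigma = 2, background = 10,
                                noise_sd = 0, shape = c(64L, 64L),
                                seed = NULL) {
  if (psf_sigma <= 0) stop("simulate_tirf_frame: psf_sigma must be positive")
  h <- shape[1]; w <- shape[2]
  img <- matrix(background, h, w)
  if (!is.null(centers) && NROW(centers) > 0) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    if (any(centers[, 1] < 1) || any(centers[, 1] > h) ||
        any(centers[, 2] < 1) || any(centers[, 2] > w))
      stop("simulate_tirf_frame: centers must lie inside the image")
    amplitudes <- rep_len(amplitudes, nrow(centers))
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
      img <- img + amplitudes[i] * exp(-d2 / (2 * psf_sigma^2))
    }
  }
  if (noise_sd > 0)
    img <- .with_seed(seed, img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  img[img < 0] <- 0
  fluorescence_stack(img, channels = "tirf",
                     extra = list(centers = centers, seed = seed))
}

# place n points in [margin, h-margin] x [margin, w-margin] with pairwise
# distance >= d_min; rejection sampling, error when overcrowded
.place_points <- function(n, h, w, margin, d_min, max_tries = 4000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: cannot satisfy the minimum object separation")
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(pts) == 0 ||
        all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >= d_min^2))
      pts <- rbind(pts, cand)
  }
  pts
}

#' Simulate a two-channel endosome/actin colocalization stack
#'
#' Builds a Z-stack whose first channel holds circular endosome blobs
#' and whose second channel holds actin patches, with exactly
#' `n_overlapping` actin patches overlapping endosomes plus
#' `n_actin_extra` free patches per slice. Distinct objects are placed
#' with generous separation so segmentation recovers the construction
#' exactly on noise-free output. An optional cortical ring (one large
#' channel-2 object hugging the image border, exceeding any reasonable
#' object-size cap) emulates cortical actin.
#'
#' @param n_endosomes endosome count per slice.
#' @param n_overlapping number of endosomes with an overlapping actin
#'   patch (`<= n_endosomes`).
#' @param n_actin_extra free actin patches per slice.
#' @param cortical_ring add the border ring to channel 2.
#' @param n_slices number of z slices.
#' @param shape image dimensions `c(H, W)`.
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param seed RNG seed.
#' @param radius blob radius, px.
#' @param background background level, a.u.
#' @param amplitude blob amplitude above background, a.u.
#' @return A two-channel [fluorescence_stack()] with `truth_masks` and
#'   `truth_overlap_fraction = n_overlapping / n_endosomes`.
#' @export
simulate_coloc_stack <- function(n_endosomes = 5L, n_overlapping = 3L,
                                 n_actin_extra = 2L, cortical_ring = FALSE,
                                 n_slices = 3L, shape = c(96L, 96L),
                                 noise_sd = 0, seed = NULL, radius = 3,
                                 background = 10, amplitude = 200) {
  if (n_overlapping > n_endosomes)
    stop("simulate_coloc_stack: n_overlapping must not exceed n_endosomes")
  h <- shape[1]; w <- shape[2]
  ring_margin <- if (cortical_ring) 8 else 0
  margin <- 2 * radius + 4 + ring_margin
  d_min <- 4 * radius + 5          # site separation: no unintended contact
  build <- function() {
    vals <- array(background, c(h, w, n_slices, 2))
    masks <- array(FALSE, c(h, w, n_slices, 2))
    for (z in seq_len(n_slices)) {
      sites <- .place_points(n_endosomes + n_actin_extra, h, w, margin, d_min)
      endo <- matrix(FALSE, h, w); actin <- matrix(FALSE, h, w)
      for (i in seq_len(n_endosomes)) {
        endo <- endo | .disk_mask(h, w, sites[i, ], radius)
        if (i <= n_overlapping) {
          th <- stats::runif(1, 0, 2 * pi)
          off <- sites[i, ] + radius * 0.7 * c(cos(th), sin(th))
          actin <- actin | .disk_mask(h, w, off, radius)
        }
      }
      if (n_actin_extra > 0)
        for (i in seq_len(n_actin_extra))
          actin <- actin | .disk_mask(h, w, sites[n_endosomes + i, ], radius)
      if (cortical_ring) {
        rr <- matrix(seq_len(h), h, w)
        cc <- matrix(seq_len(w), h, w, byrow = TRUE)
        bdist <- pmin(rr - 1, h - rr, cc - 1, w - cc)
        actin <- actin | (bdist >= 1 & bdist <= 3)
      }
      vals[, , z, 1] <- vals[, , z, 1] + amplitude * endo
      vals[, , z, 2] <- vals[, , z, 2] + amplitude * actin
      masks[, , z, 1] <- endo
      masks[, , z, 2] <- actin
    }
    if (noise_sd > 0)
      vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim(vals))
    vals[vals < 0] <- 0
    list(vals = vals, masks = masks)
  }
  out <- .with_seed(seed, build())
  fluorescence_stack(out$vals, channels = c("endosome", "actin"),
                     truth_masks = out$masks,
                     truth_overlap_fraction = n_overlapping / n_endosomes,
                     extra = list(seed = seed))
}

#' Simulate a cell image with nuclear and cytoplasmic compartments
#'
#' Draws pixel intensities at a constant nuclear mean inside the nuclear
#' mask and a constant cytoplasmic mean in the rest of the cell mask,
#' plus additive Gaussian noise; the masks are kept as ground truth for
#' nuclear-to-cytoplasmic ratio tests.
#'
#' @param nuclear_mean,cyto_mean region mean intensities, a.u.
#' @param nuclear_mask,cell_mask logical matrices; `nuclear_mask` must
#'   be strictly inside `cell_mask`. Defaults are concentric disks on a
#'   96 x 96 frame.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return A single-slice [fluorescence_stack()] with the masks in
#'   `$extra`.
#' @export
simulate_cell_image <- function(nuclear_mean = 200, cyto_mean = 50,
                                nuclear_mask = NULL, cell_mask = NULL,
                                noise_sd = 0, seed = NULL) {
  if (is.null(cell_mask)) cell_mask <- .disk_mask(96, 96, c(48, 48), 36)
  if (is.null(nuclear_mask))
    nuclear_mask <- .disk_mask(nrow(cell_mask), ncol(cell_mask),
                               c(48, 48), 14)
  if (!all(dim(nuclear_mask) == dim(cell_mask)))
    stop("simulate_cell_image: mask dimensions differ")
  if (any(nuclear_mask & !cell_mask) || !any(cell_mask & !nuclear_mask))
    stop("simulate_cell_image: nuclear_mask must be strictly inside cell_mask")
  h <- nrow(cell_mask); w <- ncol(cell_mask)
  img <- matrix(0, h, w)
  img[cell_mask] <- cyto_mean
  img[nuclear_mask] <- nuclear_mean
  if (noise_sd > 0)
    img <- .with_seed(seed, img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  img[img < 0] <- 0
  fluorescence_stack(img, channels = "stain",
                     extra = list(nuclear_mask = nuclear_mask,
                                  cell_mask = cell_mask, seed = seed))
}
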