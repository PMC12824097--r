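#' Line scans through cluster centers on a tension or SD_time map
#'
#' For each cluster center, extracts one row-wise and one column-wise
#' scan of `2 * half_length + 1` samples (11 by default) centered on
#' the peak, masked by the map's validity mask: filtered pixels
#' propagate as `NA`. Clusters closer than `half_length` to the border
#' are skipped with a warning.
#'
#' @param map a [tension_map()] or a plain matrix (all pixels valid).
#' @param centers a `cluster_set` or n x 2 matrix of (row, col).
#' @param half_length scan half length, px (default 5 -> 11 samples).
#' @param field `"sigma"` or `"sd_time"` when `map` is a tension_map.
#' @return List of per-cluster lists with `x` (row-wise scan) and `y`
#'   (column-wise scan), each a named numeric vector over offsets
#'   `-half_length:half_length`.
#' @export
line_scan_profiles <- function(map, centers, half_length = 5L,
                               field = c("sigma", "sd_time")) {
  field <- match.arg(field)
  if (inherits(map, "tension_map")) {
    vals <- if (field == "sigma") map$sigma_map else map$sd_time_map
    vals[!map$valid_mask] <- NA_real_
  } else vals <- as.matrix(map)
  if (inherits(centers, "cluster_set")) centers <- centers$centers
  centers <- matrix(as.integer(round(centers)), ncol = 2)
  h <- nrow(vals); w <- ncol(vals)
  off <- -half_length:half_length
  out <- list()
  for (k in seq_len(nrow(centers))) {
    r <- centers[k, 1]; cl <- centers[k, 2]
    if (r - half_length < 1 || r + half_length > h ||
        cl - half_length < 1 || cl + half_length > w) {
      warning("line_scan_profiles: cluster ", k,
              " too close to the border; skipped")
      next
    }
    sx <- vals[r, cl + off]           # along x (columns)
    sy <- vals[r + off, cl]           # along y (rows)
    names(sx) <- names(sy) <- off
    out[[length(out) + 1L]] <- list(x = sx, y = sy, center = c(r, cl))
  }
  out
}

#' Center-normalized radial average of cluster line scans
#'
#' Each scan is divided by its center value (so the profile is exactly
#' 1 at distance 0), then samples are pooled by absolute offset — the
#' two same-distance samples of each scan and of both scan directions
#' contribute jointly — and averaged per distance with the SEM over
#' contributing clusters.
#'
#' @param scans output of [line_scan_profiles()].
#' @param pixel_size pixel size, nm.
#' @param normalize_center divide each scan by its center value.
#' @return An object of class `cluster_profile`: data frame
#'   `profile` with `distance` (nm), `mean_norm` (dimensionless),
#'   `sem`, `n`; and `n_clusters`.
#' @export
radial_average <- function(scans, pixel_size = 65, normalize_center = TRUE) {
  if (length(scans) == 0) stop("radial_average: no scans supplied")
  half <- (length(scans[[1]]$x) - 1L) %/% 2L
  dists <- 0:half
  per_cluster <- list()
  for (sc in scans) {
    cx <- sc$x[half + 1L]
    if (!is.finite(cx) || (normalize_center && cx == 0)) {
      warning("radial_average: missing or zero center sample; scan dropped")
      next
    }
    x <- sc$x; y <- sc$y
    if (normalize_center) { x <- x / cx; y <- y / cx }
    # per-distance mean over the four same-distance samples of this cluster
    v <- vapply(dists, function(d) {
      if (d == 0) return(x[half + 1L])
      mean(c(x[half + 1L - d], x[half + 1L + d],
             y[half + 1L - d], y[half + 1L + d]), na.rm = TRUE)
    }, numeric(1))
    per_cluster[[length(per_cluster) + 1L]] <- v
  }
  if (length(per_cluster) == 0)
    stop("radial_average: all scans dropped (empty profile)")
  M <- do.call(rbind, per_cluster)
  mn <- apply(M, 2, mean, na.rm = TRUE)
  n_ok <- apply(M, 2, function(col) sum(is.finite(col)))
  sem <- apply(M, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(0)
    stats::sd(col) / sqrt(length(col))
  })
  structure(list(profile = data.frame(distance = dists * pixel_size,
                                      mean_norm = mn, sem = sem, n = n_ok),
                 n_clusters = length(per_cluster),
                 per_cluster = M,
                 pixel_size = pixel_size),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("cluster_profile over %d clusters:\n", x$n_clusters))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Maximal local tension surge around a cluster center
#'
#' Within a Euclidean radius of `radius_px` pixels (5 px = 325 nm at
#' 65 nm/px) of the center, computes the maximum of
#' `sigma(pixel) - sigma(center)` over valid pixels. When a baseline
#' map is given, also reports the mean tension over a
#' `window` x `window` (10 x 10) box around the center divided by the
#' same-window baseline mean.
#'
#' @param map a [tension_map()].
#' @param center `c(row, col)` cluster center.
#' @param radius_px surge search radius, px.
#' @param baseline_map optional pre-treatment [tension_map()].
#' @param window local-mean box side, px.
#' @return List `max_surge` (pN/um, `NA` when no valid pixel in the
#'   window), `local_mean_norm` (or `NA`), `n_valid`.
#' @export
tension_surge <- function(map, center, radius_px = 5, baseline_map = NULL,
                          window = 10L) {
  if (!inherits(map, "tension_map")) stop("tension_surge: need a tension_map")
  sig <- map$sigma_map
  sig[!map$valid_mask] <- NA_real_
  h <- nrow(sig); w <- ncol(sig)
  r <- center[1]; cl <- center[2]
  s_center <- sig[r, cl]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_win <- (rr - r)^2 + (cc - cl)^2 <= radius_px^2
  vals <- sig[in_win]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0 || !is.finite(s_center)) {
    max_surge <- NA_real_
  } else {
    max_surge <- max(vals - s_center)
  }
  local_mean_norm <- NA_real_
  if (!is.null(baseline_map)) {
    halfw <- window %/% 2L
    ii <- max(1, r - halfw + 1L):min(h, r + halfw)
    jj <- max(1, cl - halfw + 1L):min(w, cl + halfw)
    bs <- baseline_map$sigma_map
    bs[!baseline_map$valid_mask] <- NA_real_
    m_now <- mean(sig[ii, jj], na.rm = TRUE)
    m_base <- mean(bs[ii, jj], na.rm = TRUE)
    if (is.finite(m_now) && is.finite(m_base) && m_base != 0)
      local_mean_norm <- m_now / m_base
  }
  list(max_surge = max_surge, local_mean_norm = local_mean_norm,
       n_valid = length(vals))
}
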