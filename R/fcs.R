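#' Fit the 3D Gaussian one-component diffusion model to an FCS curve
#'
#' Least-squares fit of [fcs_model()] to a correlation curve. The
#' structural parameter S is fixed by default (single-curve fits leave
#' it poorly constrained; it is calibrated with a reference dye in
#' practice) and the triplet term is optional: with `triplet = FALSE`
#' the triplet amplitude K is fixed at 0.
#'
#' @param curve a [correlation_curve()].
#' @param s_struct_fixed fixed structural parameter, or `NULL` to fit
#'   it.
#' @param triplet fit the triplet term (K, tau_triplet).
#' @return An object of class `fcs_fit`: `n_particles`, `tau_d` (s),
#'   `s_struct`, `k_triplet`, `tau_triplet` (s), `r2`, `converged`.
#' @export
fit_fcs_curve <- function(curve, s_struct_fixed = 5, triplet = FALSE) {
  if (!inherits(curve, "correlation_curve"))
    stop("fit_fcs_curve: need a correlation_curve")
  tau <- curve$tau; g <- curve$g
  g0 <- max(g[1], 1e-12)
  n0 <- 1 / g0
  # tau at half the zero-lag amplitude, linear interpolation in log tau
  below <- which(g <= g0 / 2)
  tau_d0 <- if (length(below)) tau[below[1]] else stats::median(tau)
  fit_s <- is.null(s_struct_fixed)
  th0 <- log(c(n0, tau_d0,
               if (fit_s) 5 else NULL,
               if (triplet) c(0.1, tau_d0 / 50) else NULL))
  unpack <- function(th) {
    e <- exp(th)
    i <- 3L
    s_struct <- if (fit_s) { v <- e[i]; i <- i + 1L; v } else s_struct_fixed
    k <- 0; ts <- 2e-6
    if (triplet) { k <- e[i]; ts <- e[i + 1L] }
    list(n = e[1], tau_d = e[2], s = s_struct, k = k, ts = ts)
  }
  obj <- function(th) {
    p <- unpack(th)
    m <- fcs_model(tau, p$n, p$tau_d, p$s, p$k, p$ts)
    sum((m - g)^2)
  }
  opt <- tryCatch(
    stats::optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(opt)) {
    p <- unpack(th0)
    return(structure(list(n_particles = p$n, tau_d = p$tau_d, s_struct = p$s,
                          k_triplet = p$k, tau_triplet = p$ts,
                          r2 = NA_real_, converged = FALSE),
                     class = "fcs_fit"))
  }
  p <- unpack(opt$par)
  m <- fcs_model(tau, p$n, p$tau_d, p$s, p$k, p$ts)
  sst <- sum((g - mean(g))^2)
  r2 <- if (sst > 0) 1 - sum((m - g)^2) / sst else NA_real_
  structure(list(n_particles = p$n, tau_d = p$tau_d, s_struct = p$s,
                 k_triplet = p$k, tau_triplet = p$ts, r2 = r2,
                 converged = opt$convergence == 0),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(
    "fcs_fit: N = %.4g, tau_D = %.4g s, S = %.3g, K = %.3g, r^2 = %.5f\n",
    x$n_particles, x$tau_d, x$s_struct, x$k_triplet, x$r2))
  invisible(x)
}

#' Beam-waist calibration from a reference dye
#'
#' The diffusion time relates to the diffusion coefficient through
#' \eqn{\tau_D = \omega^2 / 4D}; measuring \eqn{\tau_D} for a dye of
#' known D (Rhodamine 6G in water, D = 2.8e-6 cm^2/s = 280 um^2/s)
#' gives the radial beam waist \eqn{\omega = \sqrt{4 D \tau_D}}.
#'
#' @param tau_d_ref measured reference diffusion time, s.
#' @param d_ref reference diffusion coefficient, um^2/s.
#' @return An object of class `fcs_calibration`: `omega` (um),
#'   `d_ref`, `tau_d_ref`.
#' @export
fcs_diffusion_calibration <- function(tau_d_ref, d_ref = 280) {
  if (tau_d_ref <= 0 || d_ref <= 0)
    stop("fcs_diffusion_calibration: inputs must be positive")
  structure(list(omega = sqrt(4 * d_ref * tau_d_ref),
                 d_ref = d_ref, tau_d_ref = tau_d_ref),
            class = "fcs_calibration")
}

#' Diffusion coefficient from a fitted diffusion time
#'
#' Inverts the beam-waist relation: \eqn{D = \omega^2 / 4\tau_D}.
#'
#' @param tau_d fitted diffusion time, s.
#' @param cal an [fcs_diffusion_calibration()].
#' @return Diffusion coefficient, um^2/s.
#' @export
diffusion_coefficient <- function(tau_d, cal) {
  if (tau_d <= 0) stop("diffusion_coefficient: tau_d must be positive")
  cal$omega^2 / (4 * tau_d)
}

#' Monomer count from a diffusion-time fold change
#'
#' Assuming diffusion scales with the inverse cube root of molecular
#' weight, a fold change `x` in diffusion time corresponds to `x^3`
#' associated monomers (real-valued; rounding is left to the caller).
#'
#' @param fold_change_tau_d diffusion-time fold change, `>= 1`.
#' @return Monomer count.
#' @examples
#' oligomer_count(1.4422)  # ~3
#' oligomer_count(1.8171)  # ~6
#' @export
oligomer_count <- function(fold_change_tau_d) {
  if (any(fold_change_tau_d < 1))
    stop("oligomer_count: fold change must be >= 1")
  fold_change_tau_d^3
}

#' Self-association verdict from particle-number trends
#'
#' A decrease in the fitted particle number N with increasing unlabeled
#' ligand concentration indicates self-association (labeled molecules
#' are absorbed into fewer, larger species). Tested with a one-sided
#' Spearman rank correlation of N against concentration order.
#'
#' @param n_values fitted N per concentration, in increasing
#'   concentration order.
#' @param concentrations optional concentration values (defaults to the
#'   index order).
#' @param alpha significance level.
#' @return List `verdict` (`"association"`, `"none"`, or
#'   `"insufficient-data"`), `rho`, `p`.
#' @export
particle_number_trend <- function(n_values, concentrations = NULL,
                                  alpha = 0.05) {
  if (length(n_values) < 3)
    return(list(verdict = "insufficient-data", rho = NA_real_, p = NA_real_))
  if (is.null(concentrations)) concentrations <- seq_along(n_values)
  if (stats::sd(n_values) == 0)
    return(list(verdict = "none", rho = 0, p = 1))
  ct <- suppressWarnings(
    stats::cor.test(concentrations, n_values, method = "spearman",
                    alternative = "less"))
  verdict <- if (ct$p.value < alpha && ct$estimate < 0) "association" else "none"
  list(verdict = verdict, rho = unname(ct$estimate), p = ct$p.value)
}
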