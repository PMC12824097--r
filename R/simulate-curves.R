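#' Simulate a small-angle scattering profile
#'
#' Ideal Guinier intensity \eqn{I(s) = I_0 \exp(-s^2 R_g^2/3)} for a
#' globular scatterer, or the rod cross-section form
#' \eqn{I(s) \propto \exp(-s^2 R_c^2/2)/s} when `rc` is given, with
#' optional multiplicative Gaussian noise and an optional interparticle
#' (structure-factor) suppression of the lowest-angle intensities, as
#' seen for mutually repelling charged particles in low-ionic-strength
#' solvent: the suppression multiplies intensity by
#' `1 - depth * exp(-(s / (0.25/rg))^2)`, pulling the profile below its
#' Guinier extrapolation as s approaches 0 while leaving the Guinier
#' window itself nearly untouched.
#'
#' @param rg radius of gyration, nm.
#' @param rc cross-section radius, nm, or `NULL` for the globular form;
#'   must satisfy `rc < rg`.
#' @param i0 forward-scattering intensity, a.u.
#' @param s_grid strictly increasing momentum-transfer grid, 1/nm.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param interparticle apply low-angle suppression.
#' @param suppression_depth maximal relative suppression at s = 0.
#' @param seed RNG seed.
#' @return A [scattering_profile()].
#' @export
simulate_scattering_profile <- function(rg = 5.63, rc = NULL, i0 = 100,
                                        s_grid = seq(0.02, 1, by = 0.002),
                                        noise_cv = 0, interparticle = FALSE,
                                        suppression_depth = 0.3,
                                        seed = NULL) {
  if (rg <= 0) stop("simulate_scattering_profile: rg must be positive")
  if (noise_cv < 0) stop("simulate_scattering_profile: noise_cv must be >= 0")
  if (!is.null(rc) && rc >= rg)
    stop("simulate_scattering_profile: rc must be smaller than rg")
  s <- s_grid
  I <- if (is.null(rc)) {
    i0 * exp(-s^2 * rg^2 / 3)
  } else {
    # normalized so the lowest-s point has intensity ~ i0
    i0 * (s[1] / s) * exp(-(s^2 - s[1]^2) * rc^2 / 2)
  }
  if (interparticle) I <- I * (1 - suppression_depth * exp(-(s * 4 * rg)^2))
  if (noise_cv > 0)
    I <- .with_seed(seed,
                    I * (1 + stats::rnorm(length(I), 0, noise_cv)))
  I[I <= 0] <- min(I[I > 0])
  sig <- if (noise_cv > 0) I * noise_cv else NULL
  scattering_profile(s, I, sigma_I = sig)
}

#' Single-component 3D Gaussian diffusion FCS model
#'
#' Autocorrelation of fluorescence fluctuations for one freely diffusing
#' species in a 3D Gaussian observation volume, with an optional triplet
#' blinking term:
#' \deqn{G(\tau) = \frac{1}{N}\left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'  \left(1+\frac{\tau}{S^2\tau_D}\right)^{-1/2}
#'  \left(1 + K e^{-\tau/\tau_S}\right)}
#'
#' @param tau lag times, s.
#' @param n_particles mean particle number N in the observation volume.
#' @param tau_d diffusion time, s.
#' @param s_struct structural parameter (axial/radial waist ratio).
#' @param k_triplet triplet amplitude K (0 disables the triplet term).
#' @param tau_triplet triplet relaxation time, s.
#' @return G(tau) values.
#' @export
fcs_model <- function(tau, n_particles, tau_d, s_struct = 5,
                      k_triplet = 0, tau_triplet = 2e-6) {
  if (n_particles <= 0 || tau_d <= 0 || s_struct <= 0 || tau_triplet <= 0)
    stop("fcs_model: parameters must be positive")
  g <- (1 / n_particles) * (1 + tau / tau_d)^(-1) *
    (1 + tau / (s_struct^2 * tau_d))^(-1 / 2)
  if (k_triplet != 0) g <- g * (1 + k_triplet * exp(-tau / tau_triplet))
  g
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates [fcs_model()] on a lag grid and applies multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @inheritParams fcs_model
#' @param tau_grid strictly increasing positive lag grid, s.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @param label curve label.
#' @return A [correlation_curve()].
#' @export
simulate_fcs_curve <- function(n_particles = 5, tau_d = 1e-4, s_struct = 5,
                               k_triplet = 0, tau_triplet = 2e-6,
                               tau_grid = 10^seq(-6.5, 0, length.out = 160),
                               noise_cv = 0, seed = NULL, label = "") {
  if (noise_cv < 0) stop("simulate_fcs_curve: noise_cv must be >= 0")
  g <- fcs_model(tau_grid, n_particles, tau_d, s_struct, k_triplet,
                 tau_triplet)
  if (noise_cv > 0)
    g <- .with_seed(seed, g * (1 + stats::rnorm(length(g), 0, noise_cv)))
  correlation_curve(tau_grid, g, label = label)
}
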