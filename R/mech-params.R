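# Boltzmann constant in pN um / K (1.380649e-23 J/K = 1.380649e-5 pN um/K)
.kB_pN_um <- 1.380649e-5

#' Mechanical parameter set of the membrane fluctuation model
#'
#' Bundles the physical parameters of the Helfrich-type description of
#' basal-membrane height fluctuations: effective membrane tension
#' \eqn{\sigma}, harmonic confinement \eqn{\gamma} (tethering of the
#' membrane near the substrate), effective cytoplasmic viscosity
#' \eqn{\eta_{eff}}, a dimensionless active-temperature multiplier A
#' capturing non-equilibrium enhancement of fluctuations, bending
#' rigidity \eqn{\kappa} (in units of \eqn{k_B T}), absolute temperature,
#' and the wavevector integration bounds.
#'
#' Defaults describe the basal membrane of an adherent cell imaged at
#' 65 nm/pixel: wavevectors from the ~5-um adhered-patch scale to the
#' pixel Nyquist scale (`q_min = pi / 5.2`, `q_max = pi / 0.065` 1/um),
#' `kappa = 15` kBT, 37 degrees C, confinement `gamma = 1e3` pN/um^3
#' (= 1e9 N/m^3, the strongly-adhered end of reported membrane
#' confinement) and `eta_eff = 100` Pa s (membrane-proximal effective
#' viscosity). These place the fluctuation relaxation knees at
#' 0.5-12 Hz — inside a 20-Hz sampling band, as they must be for
#' tension to be recoverable from such recordings — and give resting
#' SD_time of a few nm.
#'
#' @param sigma membrane tension, pN/um.
#' @param gamma confinement coefficient, pN/um^3.
#' @param eta_eff effective cytoplasmic viscosity, Pa s.
#' @param a_active dimensionless active temperature multiplier.
#' @param kappa bending rigidity in units of kB*T.
#' @param temperature absolute temperature, K.
#' @param q_min,q_max wavevector bounds, 1/um.
#' @return An object of class `mech_params`.
#' @examples
#' p <- mech_params(sigma = 500)
#' helfrich_psd(c(0.1, 1, 10), p)
#' @export
mech_params <- function(sigma = 500, gamma = 1e3, eta_eff = 100,
                        a_active = 1.5, kappa = 15,
                        temperature = 310.15,
                        q_min = pi / 5.2, q_max = pi / 0.065) {
  p <- list(sigma = sigma, gamma = gamma, eta_eff = eta_eff,
            a_active = a_active, kappa = kappa, temperature = temperature,
            q_min = q_min, q_max = q_max)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("mech_params: '", nm, "' must be a single positive finite number")
  }
  if (q_min >= q_max)
    stop("mech_params: q_min must be smaller than q_max")
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Membrane fluctuation model parameters\n")
  cat(sprintf("  tension sigma     : %g pN/um\n", x$sigma))
  cat(sprintf("  confinement gamma : %g pN/um^3\n", x$gamma))
  cat(sprintf("  viscosity eta_eff : %g Pa s\n", x$eta_eff))
  cat(sprintf("  active temp A     : %g\n", x$a_active))
  cat(sprintf("  kappa             : %g kBT\n", x$kappa))
  cat(sprintf("  temperature       : %g K\n", x$temperature))
  cat(sprintf("  q range           : [%g, %g] 1/um\n", x$q_min, x$q_max))
  invisible(x)
}

.is_mech_params <- function(x) inherits(x, "mech_params")

# kB*T in pN um for a parameter set
.kBT <- function(params) .kB_pN_um * params$temperature

# restoring coefficient E(q) = kappa q^3 + sigma q + gamma / q  [pN/um^2]
# q in 1/um; kappa converted from kBT units to pN um
.helfrich_Eq <- function(q, params) {
  kap <- params$kappa * .kBT(params)
  kap * q^3 + params$sigma * q + params$gamma / q
}

# Gauss-Legendre nodes/weights on [a, b]; cached per n
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  out <- list(x = x[ord], w = w[ord])
  .gl_cache[[key]] <- out
  out
}

#' Helfrich-model power spectral density of membrane height fluctuations
#'
#' Evaluates the temporal power spectral density of the height of an
#' overdamped, confined Helfrich membrane patch:
#' \deqn{PSD(f) = \frac{4\eta_{eff} A k_B T}{\pi}
#'   \int_{q_{min}}^{q_{max}}
#'   \frac{dq}{(4\eta_{eff}\,2\pi f)^2 + (\kappa q^3 + \sigma q + \gamma/q)^2}}
#' by deterministic Gauss-Legendre quadrature (relative accuracy better
#' than 1e-6 on the default node count). The confinement term enters the
#' squared restoring bracket as \eqn{\gamma/q}.
#'
#' Units: q in 1/um, sigma in pN/um, gamma in pN/um^3, eta_eff in Pa s
#' (= pN s/um^2), kappa in kBT; the returned power is in nm^2/Hz.
#'
#' @param freq frequency grid, Hz; strictly positive.
#' @param params a [mech_params()] object.
#' @param n_nodes quadrature node count.
#' @return Numeric vector of model power values, nm^2/Hz; strictly
#'   positive and strictly decreasing in `freq`.
#' @export
helfrich_psd <- function(freq, params, n_nodes = 128L) {
  if (!.is_mech_params(params)) params <- do.call(mech_params, as.list(params))
  if (!is.numeric(freq) || any(!is.finite(freq)) || any(freq <= 0))
    stop("helfrich_psd: freq must be positive and finite")
  gl <- .gauss_legendre(n_nodes)
  a <- params$q_min; b <- params$q_max
  q <- (b - a) / 2 * gl$x + (a + b) / 2
  w <- (b - a) / 2 * gl$w
  E2 <- .helfrich_Eq(q, params)^2                # [pN/um^2]^2
  damp2 <- (8 * pi * params$eta_eff * freq)^2    # (4 eta 2 pi f)^2
  # integral: for each f, sum_j w_j / (damp2 + E2_j)
  integral <- as.vector(outer(damp2, E2, "+")^(-1) %*% w)
  pref <- 4 * params$eta_eff * params$a_active * .kBT(params) / pi
  pref * integral * 1e6                          # um^2/Hz -> nm^2/Hz
}

#' Stationary height variance of the Helfrich model
#'
#' Closed-form frequency integral of [helfrich_psd()]: each wavevector
#' mode is a Lorentzian in f, so
#' \eqn{\int_0^\infty PSD(f)\,df = \frac{A k_B T}{4\pi}
#'   \int_{q_{min}}^{q_{max}} dq / E(q)} with
#' \eqn{E(q)=\kappa q^3+\sigma q+\gamma/q}; independent of viscosity.
#'
#' @param params a [mech_params()] object.
#' @param f_max optional upper frequency bound, Hz; when finite the
#'   integral is truncated at `f_max` (band-limited variance).
#' @param n_nodes quadrature node count.
#' @return Variance in nm^2.
#' @export
helfrich_variance <- function(params, f_max = Inf, n_nodes = 256L) {
  if (!.is_mech_params(params)) params <- do.call(mech_params, as.list(params))
  gl <- .gauss_legendre(n_nodes)
  a <- params$q_min; b <- params$q_max
  q <- (b - a) / 2 * gl$x + (a + b) / 2
  w <- (b - a) / 2 * gl$w
  E <- .helfrich_Eq(q, params)
  if (is.finite(f_max)) {
    # int_0^F df / (c^2 f^2 + E^2) = atan(cF/E)/(cE), c = 8 pi eta
    cc <- 8 * pi * params$eta_eff
    per_q <- atan(cc * f_max / E) / (cc * E)
    pref <- 4 * params$eta_eff * params$a_active * .kBT(params) / pi
    sum(w * per_q) * pref * 1e6
  } else {
    pref <- params$a_active * .kBT(params) / (4 * pi)
    sum(w / E) * pref * 1e6
  }
}
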