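#' Fit the Helfrich fluctuation model to a PSD estimate
#'
#' Least-squares fit of `log10(helfrich_psd(f))` to `log10(power)` with
#' tension, confinement and effective viscosity free; bending rigidity,
#' temperature and the q-range are always fixed. The active-temperature
#' multiplier A is fixed at its calibration value by default: A scales
#' the spectrum without changing its shape, and jointly rescaling
#' (sigma, gamma, eta_eff, A) leaves the model almost exactly invariant
#' when kappa is held, so a single spectrum cannot constrain A — the
#' situation is identical to the FCS structural parameter, which is
#' likewise calibrated rather than fitted per curve. Set
#' `fixed$a_active = NULL` to fit all four parameters (meaningful on
#' noiseless model curves).
#'
#' Spectra span decades in frequency and power, so the estimate is
#' pooled into log-spaced frequency bins (linear averaging of power,
#' inverse-variance weights proportional to the number of pooled
#' ordinates) and the fit minimizes the weighted residual of log10
#' power: high-frequency bins, individually noisy but numerous, are
#' averaged instead of dominating by count. Optimization runs in
#' log-parameter space from a coarse multi-start grid (the amplitude
#' offset is matched in closed form at each start), followed by
#' bounded quasi-Newton refinement and a Nelder-Mead polish.
#'
#' The coefficient of determination is computed on the (weighted)
#' log10-power domain, matching the fit domain.
#'
#' @param psd a [psd_estimate()].
#' @param fixed list with `kappa` (kBT units), `temperature` (K),
#'   `q_min`, `q_max` (1/um), and `a_active` (fixed active temperature;
#'   `NULL` to fit it).
#' @param bounds named list of `c(lower, upper)` bounds for `sigma`,
#'   `gamma`, `eta_eff`, `a_active`.
#' @param init optional named list of starting values; when given, the
#'   grid search is skipped.
#' @param freq_range optional `c(fmin, fmax)` restriction, Hz.
#' @param n_log_bins number of log-spaced frequency bins (`0` fits the
#'   raw grid unweighted).
#' @return An object of class `mechanical_fit` with fields `params`
#'   (a [mech_params()] holding fitted and fixed values), `r_squared`,
#'   `converged`, `residual_norm`.
#' @export
fit_helfrich <- function(psd,
                         fixed = list(kappa = 15, temperature = 310.15,
                                      q_min = pi / 5.2, q_max = pi / 0.065,
                                      a_active = 1.5),
                         bounds = list(sigma = c(1, 5e4),
                                       gamma = c(1, 1e8),
                                       eta_eff = c(0.01, 1e4),
                                       a_active = c(0.1, 50)),
                         init = NULL, freq_range = NULL, n_log_bins = 36L) {
  if (!inherits(psd, "psd_estimate"))
    stop("fit_helfrich: psd must be a psd_estimate")
  f <- psd$freq; P <- psd$power
  if (!is.null(freq_range)) {
    keep <- f >= freq_range[1] & f <= freq_range[2]
    f <- f[keep]; P <- P[keep]
  }
  keep <- is.finite(P) & P > 0
  f <- f[keep]; P <- P[keep]
  if (length(f) < 8L) stop("fit_helfrich: empty or too-short frequency range")
  if (n_log_bins > 0L && length(f) > n_log_bins) {
    edges <- 10^seq(log10(min(f)) - 1e-9, log10(max(f)) + 1e-9,
                    length.out = n_log_bins + 1L)
    bin <- findInterval(f, edges, rightmost.closed = TRUE)
    f <- as.vector(tapply(f, bin, mean))
    wt <- as.vector(tapply(P, bin, length))
    P <- as.vector(tapply(P, bin, mean))
  } else {
    wt <- rep(1, length(f))
  }
  logP <- log10(P)
  sst <- sum(wt * (logP - stats::weighted.mean(logP, wt))^2)

  fit_A <- is.null(fixed$a_active)
  A_fix <- if (fit_A) NA_real_ else fixed$a_active
  base <- mech_params(sigma = 100, gamma = 1e4, eta_eff = 10,
                      a_active = if (fit_A) 1 else A_fix,
                      kappa = fixed$kappa, temperature = fixed$temperature,
                      q_min = fixed$q_min, q_max = fixed$q_max)
  # free parameter vector: log10(sigma, gamma, eta_eff[, a_active])
  model_log10 <- function(th) {
    p <- base
    p$sigma <- 10^th[1]; p$gamma <- 10^th[2]; p$eta_eff <- 10^th[3]
    if (fit_A) p$a_active <- 10^th[4]
    log10(helfrich_psd(f, p))
  }
  obj <- function(th) {
    m <- model_log10(th)
    if (any(!is.finite(m))) return(1e12)
    sum(wt * (m - logP)^2)
  }
  lo <- log10(c(bounds$sigma[1], bounds$gamma[1], bounds$eta_eff[1],
                if (fit_A) bounds$a_active[1]))
  hi <- log10(c(bounds$sigma[2], bounds$gamma[2], bounds$eta_eff[2],
                if (fit_A) bounds$a_active[2]))
  clamp <- function(th) pmin(pmax(th, lo), hi)

  starts <- list()
  if (!is.null(init)) {
    th0 <- log10(c(init$sigma, init$gamma, init$eta_eff,
                   if (fit_A) init$a_active))
    starts[[1]] <- clamp(th0)
  } else {
    sig_g <- 10^seq(1.5, 3.8, length.out = 7)
    eta_g <- 10^seq(0.5, 3, length.out = 5)
    gam_g <- 10^seq(1, 5, length.out = 5)
    cand <- expand.grid(sigma = sig_g, gamma = gam_g, eta = eta_g)
    score <- numeric(nrow(cand))
    ths <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      th <- log10(c(cand$sigma[i], cand$gamma[i], cand$eta[i],
                    if (fit_A) 1))
      if (fit_A) {
        # A multiplies the PSD: closed-form offset match on log10 power
        m <- model_log10(th)
        th[4] <- clamp(replace(th, 4, stats::weighted.mean(logP - m, wt)))[4]
      }
      ths[[i]] <- th
      score[i] <- obj(th)
    }
    starts <- ths[order(score)[1:3]]
  }

  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 300, factr = 1e4)),
      error = function(e) list(par = th0, value = obj(th0), convergence = 52L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  pol <- stats::optim(best$par, function(th) obj(clamp(th)),
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
  if (pol$value <= best$value)
    best <- list(par = clamp(pol$par), value = pol$value,
                 convergence = pol$convergence)

  th <- clamp(best$par)
  p <- base
  p$sigma <- 10^th[1]; p$gamma <- 10^th[2]; p$eta_eff <- 10^th[3]
  if (fit_A) p$a_active <- 10^th[4]
  ss_res <- best$value
  r2 <- if (sst > 0) 1 - ss_res / sst else NA_real_
  structure(list(params = p,
                 r_squared = r2,
                 converged = isTRUE(best$convergence == 0) && is.finite(r2),
                 residual_norm = sqrt(ss_res),
                 n_points = length(f),
                 a_active_fitted = fit_A),
            class = "mechanical_fit")
}

#' @export
print.mechanical_fit <- function(x, ...) {
  cat(sprintf(
    "mechanical_fit: sigma = %.4g pN/um, gamma = %.4g pN/um^3, eta_eff = %.4g Pa s, A = %.3g%s\n",
    x$params$sigma, x$params$gamma, x$params$eta_eff, x$params$a_active,
    if (x$a_active_fitted) "" else " (fixed)"))
  cat(sprintf("  r^2 (log10 power) = %.5f, converged = %s\n",
              x$r_squared, x$converged))
  invisible(x)
}
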