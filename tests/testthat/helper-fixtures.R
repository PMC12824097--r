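# shared fixtures and independent oracles

default_fixed <- function(a_active = 1.5) {
  list(kappa = 15, temperature = 310.15, q_min = pi / 5.2,
       q_max = pi / 0.065, a_active = a_active)
}

# psd_estimate holding an exact model curve (no noise)
model_psd <- function(params, fmax = 10, nf = 256L) {
  f <- seq_len(nf) * fmax / nf
  structure(list(freq = f, power = helfrich_psd(f, params),
                 method = "model", n_frames = 2048L, sampling_rate = 2 * fmax),
            class = "psd_estimate")
}

# adaptive-quadrature oracle for the Helfrich PSD (independent of the
# package's Gauss-Legendre path)
helfrich_psd_oracle <- function(f, p) {
  kBT <- 1.380649e-5 * p$temperature
  vapply(f, function(ff) {
    integrand <- function(q)
      1 / ((8 * pi * p$eta_eff * ff)^2 +
             (p$kappa * kBT * q^3 + p$sigma * q + p$gamma / q)^2)
    val <- stats::integrate(integrand, p$q_min, p$q_max,
                            rel.tol = 1e-10)$value
    4 * p$eta_eff * p$a_active * kBT / pi * val * 1e6
  }, numeric(1))
}

# flood-fill connected-components oracle via igraph (8- or 4-connectivity)
count_components_oracle <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  h <- nrow(mask)
  rr <- ((idx - 1) %% h) + 1
  cc <- ((idx - 1) %/% h) + 1
  pos <- stats::setNames(seq_along(idx), idx)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1) else
      data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  edges <- integer(0)
  for (k in seq_len(nrow(nb))) {
    r2 <- rr + nb$dr[k]; c2 <- cc + nb$dc[k]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= ncol(mask)
    id2 <- (c2[ok] - 1) * h + r2[ok]
    from <- seq_along(idx)[ok]
    present <- as.character(id2) %in% names(pos)
    if (any(present))
      edges <- c(edges, rbind(from[present],
                              pos[as.character(id2[present])]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$no)
}

# brute-force Mann-Whitney enumeration oracle (two-sided)
mw_exact_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
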