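# Shared fixture builders and independent reference implementations of the
# closed-form optics, written directly from the diffusion solutions so the
# package's compiled code can be checked against them.

C_MMPS <- 0.299792458  # mm per ps

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_reff <- function(n) -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n

# independent semi-infinite time-domain reflectance (extrapolated boundary)
ref_td <- function(t_ps, mua, musp, rho, n_tissue = 1.4) {
  v <- C_MMPS / n_tissue
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  reff <- ref_reff(n_tissue)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  zp <- z0 + 2 * zb
  q <- 4 * D * v * t_ps
  0.5 * (4 * pi * D * v)^-1.5 * t_ps^-2.5 * exp(-mua * v * t_ps - rho^2 / q) *
    (z0 * exp(-z0^2 / q) + zp * exp(-zp^2 / q))
}

# independent semi-infinite correlation-diffusion g1 (Brownian dynamics)
ref_g1 <- function(tau, mua, musp, bfi_cm2s, rho, n_tissue = 1.4,
                   lambda_nm = 785) {
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  reff <- ref_reff(n_tissue)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  k0 <- 2 * pi * n_tissue / (lambda_nm * 1e-6)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * (bfi_cm2s * 100) * tau)
  K0 <- sqrt(3 * mua * musp)
  g <- exp(-K * r1) / r1 - exp(-K * r2) / r2
  g / (exp(-K0 * r1) / r1 - exp(-K0 * r2) / r2)
}

TBINS <- (seq_len(400) - 0.5) * 25  # default 25-ps x 400-bin grid

make_irf_shape <- function(t0 = 1250, sigma = 100, t_ps = TBINS) {
  s <- dnorm(t_ps, t0, sigma)
  s / sum(s)
}

# synthetic DTOF from the package forward model (round-trip fixtures)
make_dtof <- function(mua, musp, total = 5e5, bg = 2, noise = TRUE,
                      irf_n = make_irf_shape(), rho = 30,
                      wavelength = 830) {
  p <- optical_properties(wavelength, mua, musp)
  geom <- medium_geometry(rho)
  cv <- convolve_with_irf(td_reflectance(p, geom, TBINS), irf_n, 25)
  ex <- total * cv / sum(cv) + bg
  counts <- if (noise) rpois(length(ex), ex) else ex
  dtof_record(0, wavelength, 25, counts)
}

TAU60 <- 10^seq(-7, -2, length.out = 60)

make_g2rec <- function(bfi, beta, props, geom = medium_geometry(25),
                       noise_sd = 0, count_rate = 50, tau = TAU60) {
  g1 <- dcs_g1(props, geom, dcs_config(bfi, beta), tau)
  g2 <- 1 + beta * g1^2
  if (noise_sd > 0) g2 <- g2 + rnorm(length(g2), sd = noise_sd * (0.3 + g1))
  g2_record(0, tau, g2, count_rate)
}

# brute-force signed-rank p-value by full enumeration of sign assignments
brute_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  sums <- signs %*% r
  p_ge <- mean(sums >= v - 1e-9)
  p_le <- mean(sums <= v + 1e-9)
  switch(alternative, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# small synthetic session for pipeline tests (minutes-scale)
tiny_protocol <- function() protocol_spec(baseline_min = 6,
                                          transfusion_min = 12,
                                          post_min = 8, draw_offset_min = 2)
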