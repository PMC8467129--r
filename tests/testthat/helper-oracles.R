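# Independent oracles used by several test files. Each deliberately takes a
# different computational route from the package implementation.

# Mie coefficients from half-integer-order Bessel functions (besselJ /
# besselY) and the direct Riccati-Bessel formulae for an, bn -- no
# logarithmic-derivative recurrence, unlike the implementation.
oracle_mie <- function(x, m) {
  psi <- function(n, x) sqrt(pi * x / 2) * besselJ(x, n + 0.5)
  chi <- function(n, x) -sqrt(pi * x / 2) * besselY(x, n + 0.5)
  mx <- m * x
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  an <- bn <- complex(nmax)
  for (n in seq_len(nmax)) {
    ps_x <- psi(n, x); ps_x1 <- psi(n - 1, x)
    ps_m <- psi(n, mx); ps_m1 <- psi(n - 1, mx)
    xi_x <- complex(real = ps_x, imaginary = -chi(n, x))
    xi_x1 <- complex(real = ps_x1, imaginary = -chi(n - 1, x))
    dpsx <- ps_x1 - n * ps_x / x   # derivative of psi_n at x
    dpsm <- ps_m1 - n * ps_m / mx
    dxix <- xi_x1 - n * xi_x / x
    an[n] <- (m * ps_m * dpsx - ps_x * dpsm) /
      (m * ps_m * dxix - xi_x * dpsm)
    bn[n] <- (ps_m * dpsx - m * ps_x * dpsm) /
      (ps_m * dxix - m * xi_x * dpsm)
  }
  nn <- seq_len(nmax)
  qsca <- (2 / x^2) * sum((2 * nn + 1) * (Mod(an)^2 + Mod(bn)^2))
  n1 <- nn[-nmax]
  gnum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                Re(an[n1] * Conj(an[n1 + 1]) + bn[n1] * Conj(bn[n1 + 1]))) +
    sum((2 * nn + 1) / (nn * (nn + 1)) * Re(an * Conj(bn)))
  list(qsca = qsca, g = 4 * gnum / (x^2 * qsca))
}

# Pinhole-composition oracle for the projector geometry: builds the full
# 3x3 rotation and intersects rays explicitly, one point at a time.
oracle_pixel_to_plane <- function(u, v, fu, fv, cu, cv, h, alpha_deg,
                                  beta_deg) {
  a <- alpha_deg * pi / 180; b <- beta_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  d <- (rx %*% ry) %*% c((u - cu) / fu, (v - cv) / fv, -1)
  t <- -h / d[3]
  c(t * d[1], t * d[2])
}

# Brute-force grid search over the inversion bounds.
oracle_grid_invert <- function(fx, rd, n_grid = 200,
                               mua_rng = c(1e-6, 5), musp_rng = c(1e-3, 10),
                               medium = sfdi::medium_constants()) {
  muas <- exp(seq(log(mua_rng[1]), log(mua_rng[2]), length.out = n_grid))
  musps <- exp(seq(log(musp_rng[1]), log(musp_rng[2]), length.out = n_grid))
  best <- list(ssr = Inf)
  for (mua in muas) {
    rd_grid <- vapply(musps, function(musp) {
      sum((sfdi::diffuse_reflectance(mua, musp, fx, medium) - rd)^2)
    }, numeric(1))
    j <- which.min(rd_grid)
    if (rd_grid[j] < best$ssr) {
      best <- list(mua = mua, musp = musps[j], ssr = rd_grid[j])
    }
  }
  best
}

# Convenience: simulate, demodulate and invert one homogeneous scene,
# returning recovered properties (median over valid pixels).
recover_properties <- function(mua, musp, fx_list = c(0, 0.042, 0.084, 0.14),
                               size = 12L, noise_sigma = 0, seed = 1L) {
  spec <- sfdi::scene_spec(matrix(mua, size, size),
                           matrix(musp, size, size),
                           fx_list, noise_sigma = noise_sigma, seed = seed)
  stacks <- sfdi::simulate_stack(spec)
  demod <- sfdi::demodulate_acquisition(stacks$sample, stacks$reference,
                                        fx_list, rd_ref = spec$rd_ref)
  rd_med <- vapply(demod$rd, stats::median, numeric(1L), na.rm = TRUE)
  sfdi::invert_point(fx_list, rd_med,
                     medium = sfdi::medium_constants(n = spec$n))
}
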