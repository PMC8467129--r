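#' Absorption coefficient from collimated transmittance (Beer-Lambert)
#'
#' `mua = -ln(T) / d` for a pure absorber measured in a cuvette of path
#' length `d`.
#'
#' @param t Collimated transmittance, in (0, 1].
#' @param d Optical path length, mm (> 0).
#' @return Absorption coefficient, mm^-1.
#' @export
#' @examples
#' beer_lambert_mua(exp(-1), 1)  # 1 mm^-1
beer_lambert_mua <- function(t, d) {
  if (any(!is.finite(t)) || any(t <= 0) || any(t > 1)) {
    stop("transmittance must lie in (0, 1]", call. = FALSE)
  }
  if (any(d <= 0)) stop("path length must be > 0", call. = FALSE)
  -log(t) / d
}

#' Mie efficiencies of a homogeneous sphere
#'
#' Scattering efficiency, asymmetry parameter and extinction efficiency
#' from the Mie series, computed with the logarithmic-derivative
#' downward recurrence and Riccati-Bessel upward recurrences. The series
#' is truncated at the Wiscombe criterion
#' `nmax = x + 4 x^(1/3) + 2`.
#'
#' @param x Size parameter `pi * d * n_medium / lambda` (> 0).
#' @param m Relative refractive index `n_particle / n_medium`; may be
#'   complex for absorbing particles.
#' @return List with `qsca`, `g`, `qext`, `nmax`.
#' @export
mie_efficiencies <- function(x, m) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  if (x > 1e4) stop("size parameter overflow (x > 1e4)", call. = FALSE)
  m <- as.complex(m)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  # logarithmic derivative D_n(mx), downward recurrence
  nstart <- max(nmax, ceiling(Mod(mx))) + 16L
  d <- complex(nstart + 1L)
  for (n in nstart:1L) {
    rn <- (n + 1) / mx
    d[n] <- rn - 1 / (d[n + 1L] + rn)
  }
  an <- bn <- complex(nmax)
  psi_nm1 <- cos(x); psi_n <- sin(x)   # psi_{n-1}, psi_n rolling
  chi_nm1 <- -sin(x); chi_n <- cos(x)
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi_n - psi_nm1
    chi <- (2 * n - 1) / x * chi_n - chi_nm1
    xi <- complex(real = psi, imaginary = -chi)
    xi_prev <- complex(real = psi_n, imaginary = -chi_n)
    fa <- d[n] / m + n / x
    fb <- m * d[n] + n / x
    an[n] <- (fa * psi - psi_n) / (fa * xi - xi_prev)
    bn[n] <- (fb * psi - psi_n) / (fb * xi - xi_prev)
    psi_nm1 <- psi_n; psi_n <- psi
    chi_nm1 <- chi_n; chi_n <- chi
  }
  nn <- seq_len(nmax)
  qsca <- (2 / x^2) * sum((2 * nn + 1) * (Mod(an)^2 + Mod(bn)^2))
  qext <- (2 / x^2) * sum((2 * nn + 1) * Re(an + bn))
  n1 <- nn[-nmax]
  g_num <- sum(n1 * (n1 + 2) / (n1 + 1) *
                 Re(an[n1] * Conj(an[n1 + 1L]) + bn[n1] * Conj(bn[n1 + 1L]))) +
    sum((2 * nn + 1) / (nn * (nn + 1)) * Re(an * Conj(bn)))
  g <- 4 * g_num / (x^2 * qsca)
  list(qsca = qsca, g = g, qext = qext, nmax = nmax)
}

#' Reduced scattering coefficient of a dilute sphere suspension
#'
#' Mie-theory reduced scattering for monodisperse spheres in the
#' independent-scattering (dilute) regime:
#' `mus = Qsca * (pi d^2 / 4) * N` with number density
#' `N = 6 vf / (pi d^3)`, and `musp = mus * (1 - g)`. The result is
#' exactly linear in the volume fraction.
#'
#' @param diameter_nm Particle diameter, nm.
#' @param n_particle Particle refractive index (real or complex).
#' @param n_medium Medium refractive index.
#' @param wavelength_nm Vacuum wavelength, nm.
#' @param volume_fraction Particle volume fraction (dimensionless, e.g.
#'   0.001 for 0.1 %); must be << 1 for the dilute assumption.
#' @return Reduced scattering coefficient, mm^-1.
#' @export
#' @examples
#' mie_reduced_scattering(500, 2.49, 1.33, 527, 0.001)
mie_reduced_scattering <- function(diameter_nm, n_particle, n_medium,
                                   wavelength_nm, volume_fraction) {
  stopifnot(diameter_nm > 0, n_medium > 0, wavelength_nm > 0,
            volume_fraction >= 0)
  if (volume_fraction == 0) return(0)
  if (volume_fraction > 0.05) {
    warning("volume fraction > 5 %: independent-scattering assumption is doubtful")
  }
  x <- pi * diameter_nm * n_medium / wavelength_nm
  eff <- mie_efficiencies(x, n_particle / n_medium)
  d_mm <- diameter_nm * 1e-6
  mus <- 1.5 * volume_fraction * eff$qsca / d_mm
  mus * (1 - eff$g)
}

#' Liquid phantom recipe series
#'
#' The eighteen-phantom calibration design: set 1 (#1-#9) fixes the
#' TiO2 scatterer at 0.1 % volume fraction and steps the ink absorber
#' from 0.004 % to 0.02 % in 0.002 % increments; set 2 (#10-#18) fixes
#' ink at 0.006 % and steps TiO2 from 0.04 % to 0.2 % in 0.02 %
#' increments.
#'
#' @return Data frame with columns `label`, `set`, `ink_vf_percent`,
#'   `tio2_vf_percent`.
#' @export
phantom_series <- function() {
  set1 <- data.frame(
    label = paste0("#", 1:9), set = 1L,
    ink_vf_percent = seq(0.004, 0.02, by = 0.002),
    tio2_vf_percent = 0.1)
  set2 <- data.frame(
    label = paste0("#", 10:18), set = 2L,
    ink_vf_percent = 0.006,
    tio2_vf_percent = seq(0.04, 0.2, by = 0.02))
  rbind(set1, set2)
}

#' Ink absorption per volume fraction (synthetic reference spectrum)
#'
#' Interpolates the packaged synthetic ink extinction table
#' (`extdata/ink_extinction_synthetic.csv`) to the requested
#' wavelengths. The table's magnitudes are spectrally plausible
#' stand-ins for an uncharacterised carbon-black ink, not measured
#' values; reference absorption built from it is reproducible in
#' structure (exact linearity in ink fraction) but not traceable in
#' magnitude.
#'
#' @param wavelength_nm Wavelength(s), nm, within the table range.
#' @return Absorption coefficient per 1 % ink volume fraction, mm^-1.
#' @export
ink_absorption_per_percent <- function(wavelength_nm) {
  path <- system.file("extdata", "ink_extinction_synthetic.csv",
                      package = "sfdi", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (any(wavelength_nm < min(tab$wavelength_nm)) ||
      any(wavelength_nm > max(tab$wavelength_nm))) {
    stop("wavelength outside the tabulated ink spectrum", call. = FALSE)
  }
  stats::approx(tab$wavelength_nm, tab$mua_per_vf_percent,
                xout = wavelength_nm)$y
}

#' Reference optical properties of the phantom series
#'
#' Combines the linear ink absorption model (absorption proportional to
#' ink volume fraction) with Mie-theory reduced scattering of the TiO2
#' suspension to produce per-phantom, per-wavelength reference values.
#'
#' @param series Data frame from [phantom_series()] (or a subset).
#' @param wavelengths_nm Wavelengths, nm. Default the six acquisition
#'   bands c(460, 503, 527, 630, 658, 675).
#' @param tio2_diameter_nm TiO2 particle diameter, nm (synthetic default
#'   500).
#' @param n_tio2 TiO2 refractive index (synthetic default 2.49).
#' @param n_water Medium refractive index (default 1.33).
#' @return Data frame: series columns plus `wavelength_nm`, `mua_ref`,
#'   `musp_ref` (both mm^-1).
#' @export
phantom_reference_values <- function(series = phantom_series(),
                                     wavelengths_nm = c(460, 503, 527,
                                                        630, 658, 675),
                                     tio2_diameter_nm = 500,
                                     n_tio2 = 2.49, n_water = 1.33) {
  out <- merge(series, data.frame(wavelength_nm = wavelengths_nm))
  out$mua_ref <- ink_absorption_per_percent(out$wavelength_nm) *
    out$ink_vf_percent
  musp_unit <- vapply(wavelengths_nm, function(wl) {
    mie_reduced_scattering(tio2_diameter_nm, n_tio2, n_water, wl,
                           volume_fraction = 0.01)
  }, numeric(1L))
  names(musp_unit) <- as.character(wavelengths_nm)
  # linear in volume fraction, so scale the 1 % value
  out$musp_ref <- musp_unit[as.character(out$wavelength_nm)] *
    out$tio2_vf_percent
  rownames(out) <- NULL
  out[order(out$wavelength_nm, out$set, out$label), ]
}
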