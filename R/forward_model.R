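#' Medium boundary constants
#'
#' Bundles the refractive index of the turbid medium and the linear
#' coefficient of the empirical polynomial for the effective reflection
#' coefficient at the air/medium boundary.
#'
#' @param n Refractive index of the medium (dimensionless, must be > 1).
#'   Default 1.35, a common value for aqueous phantoms and soft plant tissue.
#' @param reff_linear_coeff Linear coefficient multiplying `n` in the
#'   effective-reflection polynomial. Default 0.0636, the standard
#'   diffusion-theory value.
#'
#' @return An object of class `medium_constants`.
#' @seealso [effective_reflection_coefficient()], [diffuse_reflectance()]
#' @export
#' @examples
#' medium_constants(n = 1.4)
medium_constants <- function(n = 1.35, reff_linear_coeff = 0.0636) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 1) {
    stop("`n` must be a single finite number > 1", call. = FALSE)
  }
  if (!is.numeric(reff_linear_coeff) || length(reff_linear_coeff) != 1L) {
    stop("`reff_linear_coeff` must be a single number", call. = FALSE)
  }
  structure(list(n = n, reff_linear_coeff = reff_linear_coeff),
            class = "medium_constants")
}

#' @export
print.medium_constants <- function(x, ...) {
  cat(sprintf("Medium constants: n = %.4g, Reff linear coefficient = %.4g\n",
              x$n, x$reff_linear_coeff))
  cat(sprintf("  Reff = %.5f, A = %.5f\n",
              effective_reflection_coefficient(x$n, x$reff_linear_coeff),
              proportionality_constant(
                effective_reflection_coefficient(x$n, x$reff_linear_coeff))))
  invisible(x)
}

#' Optical property pair
#'
#' Constructs a validated (absorption, reduced scattering) pair in mm^-1.
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, mm^-1 (> 0).
#' @return An object of class `optical_properties` with fields `mua`, `musp`.
#' @export
#' @examples
#' optical_properties(0.02, 1.2)
optical_properties <- function(mua, musp) {
  stopifnot(is.numeric(mua), is.numeric(musp),
            length(mua) == 1L, length(musp) == 1L)
  if (!is.finite(mua) || mua < 0) {
    stop("`mua` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(musp) || musp <= 0) {
    stop("`musp` must be finite and > 0", call. = FALSE)
  }
  structure(list(mua = mua, musp = musp), class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties: mua = %.5g mm^-1, musp = %.5g mm^-1\n",
              x$mua, x$musp))
  invisible(x)
}

#' Effective reflection coefficient at the medium boundary
#'
#' Empirical polynomial in the refractive index capturing internal
#' reflection at the air/medium interface:
#' `Reff = coeff * n + 0.668 + 0.71 / n - 1.44 / n^2`.
#'
#' The default linear coefficient is 0.0636; the result must land in (0, 1)
#' to be a physical reflection coefficient, and the function errors when it
#' does not (e.g. with a coefficient of 0.636, which produces Reff > 1 for
#' any realistic `n`).
#'
#' @param n Refractive index (> 1). May be a vector.
#' @param coeff Linear coefficient of `n`. Default 0.0636.
#' @return Effective reflection coefficient(s) in (0, 1).
#' @export
#' @examples
#' effective_reflection_coefficient(1.4)
effective_reflection_coefficient <- function(n, coeff = 0.0636) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 1)) {
    stop("`n` must be finite and > 1", call. = FALSE)
  }
  reff <- coeff * n + 0.668 + 0.71 / n - 1.44 / n^2
  if (any(reff <= 0) || any(reff >= 1)) {
    stop(sprintf(
      "effective reflection coefficient %.5g outside (0, 1); unphysical n/coefficient combination",
      reff[which(reff <= 0 | reff >= 1)[1L]]), call. = FALSE)
  }
  reff
}

#' Proportionality constant of the diffusion reflectance model
#'
#' `A = (1 - Reff) / (2 * (1 + Reff))`, the boundary proportionality
#' constant entering the spatial-frequency-domain diffuse reflectance.
#' A lies in (0, 0.5) for physical Reff; Reff = 0 gives the limit 0.5.
#'
#' @param reff Effective reflection coefficient(s) in [0, 1).
#' @return Proportionality constant(s) A.
#' @export
#' @examples
#' proportionality_constant(effective_reflection_coefficient(1.4))
proportionality_constant <- function(reff) {
  if (!is.numeric(reff) || any(!is.finite(reff)) ||
      any(reff < 0) || any(reff >= 1)) {
    stop("`reff` must lie in [0, 1)", call. = FALSE)
  }
  (1 - reff) / (2 * (1 + reff))
}

#' Diffusion-approximation diffuse reflectance at a spatial frequency
#'
#' Forward model of the modulation transfer of a homogeneous turbid medium
#' under sinusoidal illumination:
#' \deqn{R_d(f_x) = \frac{3 A \mu_s' / \mu_{tr}}
#'   {(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'},
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a \mu_{tr}}} and
#' \eqn{\mu_{eff}' = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}}.
#'
#' Rd is dimensionless, lies in (0, 1], decreases monotonically in both
#' `fx` and `mua`, and increases in `musp`. At `fx = 0` and `mua = 0` the
#' model collapses analytically to 1.
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0). Vectorised.
#' @param musp Reduced scattering coefficient, mm^-1 (> 0). Vectorised.
#' @param fx Spatial frequency, mm^-1 (>= 0). Vectorised.
#' @param medium A [medium_constants()] object.
#' @return Diffuse reflectance value(s), recycled over the inputs.
#' @export
#' @examples
#' diffuse_reflectance(0.02, 1.2, fx = c(0, 0.05, 0.1))
diffuse_reflectance <- function(mua, musp, fx, medium = medium_constants()) {
  stopifnot(inherits(medium, "medium_constants"))
  if (any(mua < 0) || any(musp <= 0) || any(fx < 0)) {
    stop("require mua >= 0, musp > 0, fx >= 0", call. = FALSE)
  }
  reff <- effective_reflection_coefficient(medium$n, medium$reff_linear_coeff)
  a <- proportionality_constant(reff)
  mutr <- mua + musp
  mueff <- sqrt(3 * mua * mutr)
  mueff_p <- sqrt(mueff^2 + (2 * pi * fx)^2)
  ratio <- mueff_p / mutr
  3 * a * (musp / mutr) / ((ratio + 1) * (ratio + 3 * a))
}
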