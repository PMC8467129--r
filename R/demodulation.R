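#' Three-phase amplitude demodulation
#'
#' Recovers the per-pixel AC amplitude envelope from three images acquired
#' under sinusoidal illumination phase-shifted by 0, 2*pi/3 and 4*pi/3:
#' `Mac = (2/3) * sqrt((I1-I2)^2 + (I2-I3)^2 + (I1-I3)^2)`.
#'
#' Note on scaling: with the 2/3 coefficient used here the result equals
#' sqrt(2) times the true sinusoid amplitude (the sum of squared pairwise
#' differences of a three-phase sinusoid of amplitude a is 4.5 a^2). The
#' constant is irrelevant downstream because [calibrate_reflectance()] takes
#' the ratio of sample to whiteboard envelopes, where it cancels; only code
#' using `Mac` in isolation needs to divide by sqrt(2).
#'
#' The demodulation is insensitive to the DC offset of the stack and
#' invariant under cyclic permutation of the three phases.
#'
#' @param i1,i2,i3 Intensity images (numeric matrices of identical
#'   dimensions) at phase shifts 0, 2*pi/3, 4*pi/3.
#' @return Matrix of AC amplitude envelopes (>= 0), same shape as inputs.
#' @export
#' @examples
#' three_phase_amplitude(matrix(3), matrix(2), matrix(1))  # (2/3)*sqrt(6)
three_phase_amplitude <- function(i1, i2, i3) {
  i1 <- as.matrix(i1); i2 <- as.matrix(i2); i3 <- as.matrix(i3)
  if (!identical(dim(i1), dim(i2)) || !identical(dim(i2), dim(i3))) {
    stop("phase images must share identical dimensions", call. = FALSE)
  }
  (2 / 3) * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i1 - i3)^2)
}

#' Calibrate reflectance against the standard whiteboard
#'
#' Per-pixel diffuse reflectance from the ratio of demodulated AC
#' envelopes of the sample and of a reference whiteboard of known
#' reflectance: `Rd = (Mac / Mac_ref) * rd_ref`.
#'
#' Pixels where the reference envelope falls below `floor_frac` times its
#' maximum cannot be normalised reliably and are masked (`NA`), never
#' returned as infinities; masks propagate through downstream inversion.
#'
#' @param mac_sample Sample AC envelope (matrix).
#' @param mac_ref Whiteboard AC envelope (matrix, same shape).
#' @param rd_ref Whiteboard reflectance, default 0.99.
#' @param floor_frac Masking floor as a fraction of `max(mac_ref)`,
#'   default 1e-6.
#' @return Matrix of calibrated reflectance; masked pixels are `NA`.
#' @export
calibrate_reflectance <- function(mac_sample, mac_ref, rd_ref = 0.99,
                                  floor_frac = 1e-6) {
  mac_sample <- as.matrix(mac_sample); mac_ref <- as.matrix(mac_ref)
  if (!identical(dim(mac_sample), dim(mac_ref))) {
    stop("sample and reference envelopes must share dimensions", call. = FALSE)
  }
  floor <- floor_frac * max(mac_ref, na.rm = TRUE)
  rd <- (mac_sample / mac_ref) * rd_ref
  rd[!is.finite(rd) | mac_ref <= floor] <- NA_real_
  rd
}

#' Planar (DC) reflectance calibration
#'
#' The zero-frequency channel cannot be demodulated (three identical
#' phases give a null envelope); it is calibrated directly from the ratio
#' of the sample image to the full-white reference image:
#' `Rac = (Iac / Iref) * rd_ref`.
#'
#' @param i_ac Sample image under planar (unmodulated) illumination.
#' @param i_ref Whiteboard image under the same illumination.
#' @param rd_ref Whiteboard reflectance, default 0.99.
#' @param floor_frac Masking floor as a fraction of `max(i_ref)`.
#' @return Matrix of planar reflectance; dark reference pixels are `NA`.
#' @export
planar_reflectance <- function(i_ac, i_ref, rd_ref = 0.99,
                               floor_frac = 1e-6) {
  i_ac <- as.matrix(i_ac); i_ref <- as.matrix(i_ref)
  if (!identical(dim(i_ac), dim(i_ref))) {
    stop("sample and reference images must share dimensions", call. = FALSE)
  }
  floor <- floor_frac * max(i_ref, na.rm = TRUE)
  rd <- (i_ac / i_ref) * rd_ref
  rd[!is.finite(rd) | i_ref <= floor] <- NA_real_
  rd
}

#' Demodulate and calibrate a full acquisition
#'
#' Convenience wrapper running [three_phase_amplitude()] +
#' [calibrate_reflectance()] on every modulated frequency of an
#' acquisition, and [planar_reflectance()] on the DC channel.
#'
#' @param sample Named list of stacks as produced by [simulate_stack()]:
#'   per frequency either a list of three phase images or a single planar
#'   image for fx = 0.
#' @param reference Whiteboard stacks of identical structure.
#' @param fx_list Numeric vector of spatial frequencies, mm^-1, one per
#'   stack element.
#' @param rd_ref Whiteboard reflectance, default 0.99.
#' @return List with `fx_list` and `rd`, a list of calibrated reflectance
#'   images (one per frequency).
#' @export
demodulate_acquisition <- function(sample, reference, fx_list,
                                   rd_ref = 0.99) {
  stopifnot(length(sample) == length(fx_list),
            length(reference) == length(fx_list))
  rd <- vector("list", length(fx_list))
  for (k in seq_along(fx_list)) {
    if (fx_list[k] == 0) {
      rd[[k]] <- planar_reflectance(sample[[k]], reference[[k]], rd_ref)
    } else {
      mac_s <- three_phase_amplitude(sample[[k]][[1L]], sample[[k]][[2L]],
                                     sample[[k]][[3L]])
      mac_r <- three_phase_amplitude(reference[[k]][[1L]], reference[[k]][[2L]],
                                     reference[[k]][[3L]])
      rd[[k]] <- calibrate_reflectance(mac_s, mac_r, rd_ref)
    }
  }
  list(fx_list = fx_list, rd = rd)
}
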