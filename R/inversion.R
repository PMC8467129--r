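#' Invert a multi-frequency reflectance spectrum to optical properties
#'
#' Fits the diffusion-approximation forward model [diffuse_reflectance()]
#' to calibrated reflectance measured at two or more spatial frequencies,
#' by bounded Levenberg-Marquardt least squares, returning the absorption
#' and reduced scattering coefficients minimising the sum of squared
#' residuals.
#'
#' The fit starts at (mua, musp) = (0.01, 1.0) mm^-1 and retries once from
#' (0.1, 0.5) when convergence is poor; bounds are mua in [1e-6, 5] and
#' musp in [1e-3, 10] mm^-1. Non-convergence is reported through the
#' `converged` flag and diagnostics, not as an error.
#'
#' @param fx Spatial frequencies, mm^-1 (>= 2 distinct values).
#' @param rd Calibrated reflectance at each frequency (same length,
#'   values in [0, 1.1]; `NA`s are dropped pairwise).
#' @param medium A [medium_constants()] object.
#' @param lower,upper Bounds on (mua, musp), mm^-1.
#' @param start Initial (mua, musp); a second start is tried automatically.
#' @return List with `mua`, `musp`, `residual` (residual sum of squares),
#'   `converged`, and `message`.
#' @export
#' @examples
#' fx <- c(0, 0.042, 0.084, 0.14)
#' rd <- diffuse_reflectance(0.02, 1.2, fx)
#' invert_point(fx, rd)
invert_point <- function(fx, rd, medium = medium_constants(),
                         lower = c(1e-6, 1e-3), upper = c(5, 10),
                         start = c(0.01, 1.0)) {
  stopifnot(length(fx) == length(rd))
  keep <- is.finite(fx) & is.finite(rd)
  fx <- fx[keep]; rd <- rd[keep]
  if (length(unique(fx)) < 2L) {
    return(list(mua = NA_real_, musp = NA_real_, residual = NA_real_,
                converged = FALSE,
                message = "ill-posed: fewer than 2 distinct frequencies"))
  }
  if (any(rd < 0) || any(rd > 1.1)) {
    stop("reflectance values must lie in [0, 1.1]", call. = FALSE)
  }
  resid_fn <- function(p) {
    diffuse_reflectance(p[1L], p[2L], fx, medium) - rd
  }
  run_fit <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  }
  fit <- run_fit(start)
  ssr <- if (is.null(fit)) Inf else fit$deviance
  # multi-start retry guards against the shallow valley at low absorption
  if (is.null(fit) || ssr > 1e-10) {
    fit2 <- run_fit(c(0.1, 0.5))
    if (!is.null(fit2) && (is.null(fit) || fit2$deviance < ssr)) {
      fit <- fit2
      ssr <- fit2$deviance
    }
  }
  if (is.null(fit)) {
    return(list(mua = NA_real_, musp = NA_real_, residual = NA_real_,
                converged = FALSE, message = "optimiser failed"))
  }
  list(mua = unname(fit$par[1L]), musp = unname(fit$par[2L]),
       residual = ssr,
       converged = fit$info %in% 1:4,
       message = fit$message)
}

#' Invert co-registered reflectance images to coefficient maps
#'
#' Applies [invert_point()] at every pixel (or every `bin` x `bin`
#' superpixel) of a set of co-registered calibrated reflectance images,
#' one per spatial frequency, producing absorption and reduced scattering
#' maps. Pixels masked (`NA`) at any frequency propagate as masked output.
#'
#' @param rd_images List of reflectance matrices, one per frequency, all
#'   of identical shape.
#' @param fx Spatial frequencies, mm^-1, one per image.
#' @param medium A [medium_constants()] object.
#' @param bin Superpixel edge in pixels; 1 (default) fits every pixel,
#'   larger values average each `bin` x `bin` block before fitting and
#'   return maps at the binned resolution.
#' @return List with matrices `mua`, `musp`, `residual`, and logical
#'   `converged`.
#' @export
invert_map <- function(rd_images, fx, medium = medium_constants(), bin = 1L) {
  stopifnot(length(rd_images) == length(fx), length(fx) >= 2L)
  dims <- lapply(rd_images, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L) {
    stop("reflectance images must be co-registered (equal shapes)",
         call. = FALSE)
  }
  if (bin > 1L) {
    rd_images <- lapply(rd_images, bin_image, bin = bin)
  }
  nr <- nrow(rd_images[[1L]]); nc <- ncol(rd_images[[1L]])
  cube <- array(unlist(rd_images), dim = c(nr, nc, length(fx)))
  mua <- musp <- resid <- matrix(NA_real_, nr, nc)
  conv <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      spec <- cube[i, j, ]
      if (anyNA(spec)) next
      f <- invert_point(fx, spec, medium)
      mua[i, j] <- f$mua; musp[i, j] <- f$musp
      resid[i, j] <- f$residual; conv[i, j] <- isTRUE(f$converged)
    }
  }
  list(mua = mua, musp = musp, residual = resid, converged = conv)
}

#' Block-average an image
#'
#' Averages non-overlapping `bin` x `bin` blocks; trailing rows/columns
#' that do not fill a block are dropped. `NA` pixels poison their block,
#' so masks are preserved conservatively.
#'
#' @param img Numeric matrix.
#' @param bin Block edge, pixels.
#' @return Matrix of block means.
#' @export
bin_image <- function(img, bin = 2L) {
  bin <- as.integer(bin)
  stopifnot(bin >= 1L)
  if (bin == 1L) return(img)
  nr <- (nrow(img) %/% bin) * bin
  nc <- (ncol(img) %/% bin) * bin
  if (nr < bin || nc < bin) stop("image smaller than one block", call. = FALSE)
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(img, dim = c(bin, nr %/% bin, bin, nc %/% bin))
  apply(a, c(2L, 4L), mean)
}

#' Linear system correction factor from phantom measurements
#'
#' Mean ratio of reference to measured coefficient over a calibration set
#' of phantoms: `k = mean(ref / measured)`. Applied multiplicatively as
#' `calibrated = k * measured` to remove the linearity error of the
#' system (e.g. from scatterer precipitation).
#'
#' @param ref Reference coefficient values (length m >= 1).
#' @param measured Measured coefficient values (same length, > 0).
#' @return Scalar correction ratio k.
#' @export
#' @examples
#' linear_correction(c(1, 2), c(2, 2))  # 0.75
linear_correction <- function(ref, measured) {
  stopifnot(length(ref) == length(measured), length(ref) >= 1L)
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured values must be finite and > 0", call. = FALSE)
  }
  mean(ref / measured)
}

#' Apply a linear correction factor
#'
#' @param measured Measured coefficient values.
#' @param k Correction ratio from [linear_correction()].
#' @return Calibrated values `k * measured`.
#' @export
apply_correction <- function(measured, k) k * measured
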