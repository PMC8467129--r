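#' Projector geometry
#'
#' Pinhole model of the structured-light projector: intrinsics in pixels,
#' mounting height above the target plane in mm, and mounting angles in
#' degrees. The optical axis points down toward the plane; positive pitch
#' tilts it toward the camera. Roll is assumed zero (the mount constrains
#' it).
#'
#' The defaults are a calibrated bench instance (focal lengths ~2120 px,
#' principal point offset typical of an offset projection lens, height
#' 527 mm, pitch 20 deg, yaw 0.5 deg) with a native resolution of
#' 1280 x 800.
#'
#' @param fu,fv Horizontal/vertical focal lengths, pixels (> 0).
#' @param cu,cv Optical centre coordinates, pixels.
#' @param h Height above the target plane, mm (> 0).
#' @param alpha Pitch angle, degrees (|alpha| < 90).
#' @param beta Yaw angle, degrees (|beta| < 90).
#' @param size Projector resolution as (rows, cols), default c(800, 1280).
#' @return An object of class `projector_geometry`.
#' @export
projector_geometry <- function(fu = 2116.8, fv = 2122.4,
                               cu = 670.4, cv = -186.8,
                               h = 527, alpha = 20, beta = 0.5,
                               size = c(800L, 1280L)) {
  stopifnot(fu > 0, fv > 0, h > 0, abs(alpha) < 90, abs(beta) < 90,
            length(size) == 2L, all(size >= 1))
  structure(list(fu = fu, fv = fv, cu = cu, cv = cv, h = h,
                 alpha = alpha, beta = beta, size = as.integer(size)),
            class = "projector_geometry")
}

#' @export
print.projector_geometry <- function(x, ...) {
  cat(sprintf(
    "Projector geometry: fu=%.1f fv=%.1f cu=%.1f cv=%.1f px; h=%.0f mm; pitch=%.2f deg; yaw=%.2f deg; %dx%d px\n",
    x$fu, x$fv, x$cu, x$cv, x$h, x$alpha, x$beta, x$size[1L], x$size[2L]))
  invisible(x)
}

# rotation of the projector frame: pitch about x, then yaw about y
.keystone_rotation <- function(geom) {
  a <- geom$alpha * pi / 180
  b <- geom$beta * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b),
                 0, 1, 0,
                 -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rx %*% ry
}

#' Map projector pixels to points on the target plane
#'
#' Casts the ray through each projector pixel (pinhole model, optical
#' axis along -z in the projector frame), rotates it by pitch then yaw,
#' and intersects it with the horizontal plane `h` mm below the
#' projector. With zero angles, the principal pixel (cu, cv) lands at the
#' world origin and coordinates scale as h/f (similar triangles).
#'
#' @param px Pixel coordinates: a length-2 vector (u, v) or an n x 2
#'   matrix, u = column axis, v = row axis.
#' @param geom A [projector_geometry()].
#' @return n x 2 matrix of (x, y) plane coordinates in mm.
#' @export
image_to_world <- function(px, geom) {
  stopifnot(inherits(geom, "projector_geometry"))
  px <- matrix(as.numeric(px), ncol = 2L)
  r <- .keystone_rotation(geom)
  d <- cbind((px[, 1L] - geom$cu) / geom$fu,
             (px[, 2L] - geom$cv) / geom$fv,
             -1)
  dw <- d %*% t(r)
  if (any(dw[, 3L] >= 0)) {
    stop("ray parallel to or away from the target plane", call. = FALSE)
  }
  tt <- -geom$h / dw[, 3L]
  cbind(x = tt * dw[, 1L], y = tt * dw[, 2L])
}

#' Map target-plane points to projector pixels
#'
#' Exact inverse of [image_to_world()] on its domain: rotates the plane
#' point (x, y, -h) back into the projector frame and applies the
#' perspective division.
#'
#' @param pt Plane coordinates: a length-2 vector (x, y) in mm or an
#'   n x 2 matrix.
#' @param geom A [projector_geometry()].
#' @return n x 2 matrix of (u, v) pixel coordinates.
#' @export
world_to_image <- function(pt, geom) {
  stopifnot(inherits(geom, "projector_geometry"))
  pt <- matrix(as.numeric(pt), ncol = 2L)
  r <- .keystone_rotation(geom)
  p <- cbind(pt[, 1L], pt[, 2L], -geom$h) %*% r  # == t(R) %*% p per point
  if (any(p[, 3L] >= 0)) {
    stop("point behind the projector", call. = FALSE)
  }
  cbind(u = geom$cu + geom$fu * p[, 1L] / (-p[, 3L]),
        v = geom$cv + geom$fv * p[, 2L] / (-p[, 3L]))
}

#' Sinusoidal fringe pattern specification
#'
#' @param period_px Fringe generation period, pixels (> 1).
#' @param phase Phase offset, radians. Three-phase sets use
#'   0, 2*pi/3, 4*pi/3.
#' @param size Pattern size as (rows, cols).
#' @return An object of class `sinusoid_spec`.
#' @export
sinusoid_spec <- function(period_px, phase = 0, size = c(800L, 1280L)) {
  stopifnot(period_px > 1, length(size) == 2L, all(size >= 1))
  structure(list(period_px = period_px, phase = phase,
                 size = as.integer(size)),
            class = "sinusoid_spec")
}

#' Generate an ideal sinusoidal fringe pattern
#'
#' Values in [0, 1]: `0.5 + 0.5 * cos(2*pi*(col - 1)/period + phase)`.
#' Fringes vary along image columns and are constant along rows.
#'
#' @param spec A [sinusoid_spec()].
#' @return Numeric matrix of the requested size.
#' @export
generate_sinusoid <- function(spec) {
  stopifnot(inherits(spec, "sinusoid_spec"))
  u <- seq_len(spec$size[2L]) - 1
  row_vals <- 0.5 + 0.5 * cos(2 * pi * u / spec$period_px + spec$phase)
  matrix(row_vals, nrow = spec$size[1L], ncol = spec$size[2L], byrow = TRUE)
}

# plane-referenced fringe value at world coordinates, anchored so that at
# zero angles the corrected image reproduces generate_sinusoid() exactly
.plane_fringe <- function(x, spec, geom) {
  period_mm <- spec$period_px * geom$h / geom$fu
  x0 <- geom$h * (1 - geom$cu) / geom$fu  # world x of column 1 at zero angles
  0.5 + 0.5 * cos(2 * pi * (x - x0) / period_mm + spec$phase)
}

#' Keystone pre-correction of a fringe pattern
#'
#' Builds the projector image whose projection through `geom` yields
#' undistorted fringes on the target plane (inverse perspective
#' transformation): each projector pixel is mapped through
#' [image_to_world()] and assigned the value of the ideal plane-referenced
#' sinusoid at the landing point. Because the sinusoid is analytic, the
#' resampling is exact (no interpolation error). With zero angles the
#' output equals [generate_sinusoid()] of the same spec.
#'
#' @param spec A [sinusoid_spec()]; the output uses the projector's
#'   native resolution from `geom`.
#' @param geom A [projector_geometry()] holding the angles to pre-correct.
#' @return Corrected pattern matrix (rows x cols of `geom$size`).
#' @export
correct_pattern <- function(spec, geom) {
  stopifnot(inherits(spec, "sinusoid_spec"),
            inherits(geom, "projector_geometry"))
  nr <- geom$size[1L]; nc <- geom$size[2L]
  px <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), times = nc))
  w <- image_to_world(px, geom)
  matrix(.plane_fringe(w[, 1L], spec, geom), nrow = nr, ncol = nc)
}

#' Simulate the camera view of a projected pattern
#'
#' Renders what a downward-looking camera sees on the target plane when a
#' pattern pre-corrected for `assumed` angles is projected through the
#' `true` geometry. The camera field of view is centred on the footprint
#' of the true principal ray; pattern values are evaluated analytically
#' through the composed map (plane -> true projector pixel -> assumed
#' plane fringe), and points falling outside the projector frame are
#' masked `NA`.
#'
#' @param spec A [sinusoid_spec()].
#' @param true_geom Projector geometry actually realised.
#' @param assumed_geom Geometry assumed when pre-correcting (equal to
#'   `true_geom` for perfect correction); `NULL` projects the uncorrected
#'   ideal pattern.
#' @param fov_mm Camera field of view on the plane, mm (square).
#' @param cam_px Camera image edge, pixels.
#' @return `cam_px` x `cam_px` reflectance-like matrix in [0, 1].
#' @export
simulate_projection <- function(spec, true_geom, assumed_geom = NULL,
                                fov_mm = 100, cam_px = 120L) {
  stopifnot(inherits(true_geom, "projector_geometry"))
  centre <- image_to_world(c(true_geom$size[2L] / 2,
                             true_geom$size[1L] / 2), true_geom)
  # grid of world points seen by the camera
  xs <- centre[1L] + seq(-fov_mm / 2, fov_mm / 2, length.out = cam_px)
  ys <- centre[2L] + seq(-fov_mm / 2, fov_mm / 2, length.out = cam_px)
  w <- cbind(rep(xs, each = cam_px), rep(ys, times = cam_px))
  uv <- world_to_image(w, true_geom)
  inside <- uv[, 1L] >= 1 & uv[, 1L] <= true_geom$size[2L] &
    uv[, 2L] >= 1 & uv[, 2L] <= true_geom$size[1L]
  vals <- rep(NA_real_, nrow(w))
  if (is.null(assumed_geom)) {
    # uncorrected: projector shows the ideal pixel-space sinusoid
    vals[inside] <- 0.5 + 0.5 * cos(2 * pi * (uv[inside, 1L] - 1) /
                                      spec$period_px + spec$phase)
  } else {
    wp <- image_to_world(uv[inside, , drop = FALSE], assumed_geom)
    vals[inside] <- .plane_fringe(wp[, 1L], spec, assumed_geom)
  }
  matrix(vals, nrow = cam_px, ncol = cam_px)  # rows = y, cols = x
}

#' Fringe-uniformity (keystone correction) error
#'
#' Mean over columns of the per-column standard deviation of the min-max
#' normalised image. Perfectly corrected fringes vary only along columns,
#' every column is constant, and the error is zero. The metric is
#' invariant to global affine intensity changes because of the
#' normalisation.
#'
#' @param img Numeric matrix; `NA` pixels are ignored.
#' @param std Standard deviation convention: `"sample"` (n-1 denominator,
#'   default, R's [stats::sd()]) or `"population"`.
#' @return Scalar error (dimensionless, in normalised intensity units).
#' @export
keystone_error <- function(img, std = c("sample", "population")) {
  std <- match.arg(std)
  img <- as.matrix(img)
  if (length(img) == 0L || all(is.na(img))) {
    stop("empty image", call. = FALSE)
  }
  rng <- range(img, na.rm = TRUE)
  norm <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng) else img * 0
  col_sd <- apply(norm, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) return(NA_real_)
    s <- stats::sd(col)
    if (std == "population") s <- s * sqrt((length(col) - 1) / length(col))
    s
  })
  mean(col_sd, na.rm = TRUE)
}

#' Sweep candidate correction angles for the minimum fringe error
#'
#' Evaluates a fringe-error function over a grid of (pitch, yaw)
#' candidate angles and returns the minimiser with the full error
#' surface. Ties are broken toward the lowest pitch, then the lowest
#' yaw, with a warning (a flat surface indicates no keystone distortion
#' to correct).
#'
#' @param ep_fun Function `(alpha, beta) -> ep` returning the fringe
#'   error of the correction candidate, e.g. built from
#'   [simulate_projection()] + [keystone_error()] or from acquired
#'   reflectance images.
#' @param alphas Candidate pitch angles, degrees (default 12-22 step 1).
#' @param betas Candidate yaw angles, degrees (default 0-1 step 0.1).
#' @return List with `alpha`, `beta`, `ep` (the minimum), `surface`
#'   (matrix alphas x betas), and `tie` flag.
#' @export
angle_sweep <- function(ep_fun, alphas = 12:22, betas = seq(0, 1, by = 0.1)) {
  stopifnot(length(alphas) >= 1L, length(betas) >= 1L)
  surface <- matrix(NA_real_, length(alphas), length(betas),
                    dimnames = list(alpha = alphas, beta = betas))
  for (i in seq_along(alphas)) {
    for (j in seq_along(betas)) {
      surface[i, j] <- ep_fun(alphas[i], betas[j])
    }
  }
  best <- min(surface)
  hits <- which(surface <= best, arr.ind = TRUE)
  tie <- nrow(hits) > 1L
  if (tie) {
    warning("flat error surface: tie broken toward lowest pitch, then yaw")
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  }
  list(alpha = alphas[hits[1L, 1L]], beta = betas[hits[1L, 2L]],
       ep = best, surface = surface, tie = tie)
}
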