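# run fn with a deterministic RNG stream, restoring the caller's stream
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Synthetic acquisition scene specification
#'
#' Ground truth and acquisition settings for the simulator: per-pixel
#' optical property maps, the frequencies to project, camera gain and
#' noise, and the pixel scale tying image columns to millimetres on the
#' sample plane (default 400 px per 26 mm, the bench ROI scale).
#'
#' @param mua_map,musp_map Ground-truth coefficient maps, mm^-1
#'   (co-registered matrices; `NA` marks masked pixels).
#' @param fx_list Spatial frequencies to simulate, mm^-1 (0 = planar).
#' @param n Refractive index of the medium. Default 1.35.
#' @param rd_ref Whiteboard reflectance. Default 0.99.
#' @param gain Camera scale (arbitrary linear units; 16-bit-like
#'   default 6e4).
#' @param noise_sigma Additive Gaussian noise, as a fraction of `gain`.
#' @param px_per_mm Pixel scale of the image columns, px/mm.
#' @param seed RNG seed; the same spec renders bit-identical stacks.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(mua_map, musp_map, fx_list,
                       n = 1.35, rd_ref = 0.99, gain = 6e4,
                       noise_sigma = 0, px_per_mm = 400 / 26,
                       seed = 1L) {
  mua_map <- as.matrix(mua_map); musp_map <- as.matrix(musp_map)
  stopifnot(identical(dim(mua_map), dim(musp_map)),
            noise_sigma >= 0, gain > 0, px_per_mm > 0,
            all(fx_list >= 0))
  ok <- !is.na(mua_map) & !is.na(musp_map)
  if (any(mua_map[ok] < 0) || any(musp_map[ok] <= 0)) {
    stop("unmasked map values must satisfy mua >= 0, musp > 0",
         call. = FALSE)
  }
  structure(list(mua_map = mua_map, musp_map = musp_map,
                 fx_list = as.numeric(fx_list), n = n, rd_ref = rd_ref,
                 gain = gain, noise_sigma = noise_sigma,
                 px_per_mm = px_per_mm, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Simulate sample and whiteboard acquisition stacks
#'
#' Renders the forward model into camera intensity stacks: for each
#' modulated frequency, three phase images
#' `Ik = gain * (0.5 + 0.5 * Rd(x, fx) * cos(2*pi*fx*x_mm + 2*pi*k/3))`
#' plus additive Gaussian noise; for the planar channel (fx = 0), a
#' single image `gain * Rd`. The whiteboard stack uses the reference
#' reflectance at every frequency. Doubling the gain leaves calibrated
#' reflectance unchanged (it cancels in the whiteboard ratio), and the
#' same seed renders bit-identical output.
#'
#' @param scene A [scene_spec()].
#' @return List with `sample` and `reference` (per frequency: a list of
#'   three phase matrices, or one planar matrix for fx = 0), plus
#'   `fx_list`.
#' @export
simulate_stack <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  medium <- medium_constants(n = scene$n)
  nr <- nrow(scene$mua_map); nc <- ncol(scene$mua_map)
  x_mm <- (seq_len(nc) - 1) / scene$px_per_mm
  mask <- is.na(scene$mua_map) | is.na(scene$musp_map)
  mua <- ifelse(mask, 0.01, scene$mua_map)
  musp <- ifelse(mask, 1, scene$musp_map)
  no_mask <- matrix(FALSE, nr, nc)
  .with_seed(scene$seed, function() {
    render <- function(rd_map, fx, msk) {
      noise <- function() {
        if (scene$noise_sigma == 0) 0
        else matrix(stats::rnorm(nr * nc, sd = scene$noise_sigma * scene$gain),
                    nr, nc)
      }
      if (fx == 0) {
        img <- scene$gain * rd_map + noise()
        img[msk] <- NA_real_
        return(img)
      }
      phase_mm <- matrix(2 * pi * fx * x_mm, nr, nc, byrow = TRUE)
      lapply(0:2, function(k) {
        img <- scene$gain *
          (0.5 + 0.5 * rd_map * cos(phase_mm + 2 * pi * k / 3)) + noise()
        img[msk] <- NA_real_
        img
      })
    }
    sample <- vector("list", length(scene$fx_list))
    reference <- vector("list", length(scene$fx_list))
    ref_map <- matrix(scene$rd_ref, nr, nc)
    for (i in seq_along(scene$fx_list)) {
      fx <- scene$fx_list[i]
      rd <- matrix(diffuse_reflectance(mua, musp, fx, medium), nr, nc)
      sample[[i]] <- render(rd, fx, mask)
      reference[[i]] <- render(ref_map, fx, no_mask)
    }
    list(sample = sample, reference = reference, fx_list = scene$fx_list)
  })
}

#' Synthetic fruit-damage scene
#'
#' Ground-truth optical property maps for one fruit surface of a given
#' damage class. Damaged tissue absorbs more and scatters less than
#' normal tissue; each class has a characteristic lesion geometry and
#' effect size (bruise: disc, +15 % mua / -20 % musp; scratch: thin
#' stripes, +22 % / -30 % over a smaller footprint, so bruise and
#' scratch have nearly equal region-mean contrast -- both are minor
#' damage and are deliberately hard to tell apart by mean values alone;
#' abrasion: broad speckled patch, +40 % / -20 %, the serious class).
#' Background level, lesion placement and effect sizes carry seeded
#' jitter, so two seeds give different scenes with the same class
#' statistics. The effect sizes are synthetic stand-ins chosen to be
#' physiologically plausible, not measured contrasts.
#'
#' @param class_label One of `"normal"`, `"bruised"`, `"scratched"`,
#'   `"abraded"`.
#' @param seed RNG seed.
#' @param size Map size (rows, cols). Default c(48, 48).
#' @param mua_bg,musp_bg Mean background coefficients, mm^-1 (defaults
#'   0.025 and 1.3, plausible pear-flesh values in the green band).
#' @return List with `mua_map`, `musp_map`, `lesion_mask` (logical),
#'   `class_label`.
#' @export
make_damage_scene <- function(class_label = c("normal", "bruised",
                                              "scratched", "abraded"),
                              seed = 1L, size = c(48L, 48L),
                              mua_bg = 0.025, musp_bg = 1.3) {
  class_label <- match.arg(class_label)
  nr <- size[1L]; nc <- size[2L]
  .with_seed(seed, function() {
    # inter-fruit variability of a single batch at equal ripeness
    mua0 <- mua_bg * stats::rnorm(1L, 1, 0.02)
    musp0 <- musp_bg * stats::rnorm(1L, 1, 0.02)
    # smooth per-pixel texture
    mua <- matrix(mua0 * (1 + stats::rnorm(nr * nc, 0, 0.02)), nr, nc)
    musp <- matrix(musp0 * (1 + stats::rnorm(nr * nc, 0, 0.02)), nr, nc)
    mask <- matrix(FALSE, nr, nc)
    if (class_label != "normal") {
      cx <- stats::runif(1L, 0.35, 0.65) * nc
      cy <- stats::runif(1L, 0.35, 0.65) * nr
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      if (class_label == "bruised") {
        # a 20 mm impact ball against the 26 mm field: the disc spans
        # most of the analysed region
        r <- stats::runif(1L, 0.32, 0.38) * min(nr, nc)
        mask <- (rows - cy)^2 + (cols - cx)^2 <= r^2
        eff <- c(mua = 0.15, musp = -0.20)
      } else if (class_label == "scratched") {
        # razor strokes crossing the whole field
        n_str <- sample(4:6, 1L)
        offs <- sort(stats::runif(n_str, -0.30, 0.30) * nr)
        slope <- stats::runif(1L, 0.2, 0.4)
        for (o in offs) {
          mask <- mask | abs(rows - (cy + o) - slope * (cols - cx)) < 1
        }
        eff <- c(mua = 0.22, musp = -0.30)
      } else {
        # sandpaper rub: broad speckled patch, the most severe damage
        r <- stats::runif(1L, 0.34, 0.40) * min(nr, nc)
        patch <- (rows - cy)^2 + (cols - cx)^2 <= r^2
        speckle <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
        mask <- patch & speckle
        eff <- c(mua = 0.40, musp = -0.20)
      }
      jit <- stats::rnorm(2L, 1, 0.05)
      mua[mask] <- mua[mask] * (1 + eff["mua"] * jit[1L])
      musp[mask] <- musp[mask] * (1 + eff["musp"] * jit[2L])
    }
    list(mua_map = mua, musp_map = musp, lesion_mask = mask,
         class_label = class_label)
  })
}

#' Simulate a 1-D fringe reflectance profile
#'
#' Cosine profile for exercising the fringe-period estimator:
#' `0.5 + 0.4 * cos(2*pi*x / (period_px * bias))` plus optional Gaussian
#' noise. A multiplicative `bias` stretches the realised period, which
#' the period estimator should recover as `period_px * bias`.
#'
#' @param period_px Nominal fringe period, pixels (>= 2).
#' @param length Profile length, samples (> 0).
#' @param bias Multiplicative period bias (default 1 = unbiased optics).
#' @param noise Gaussian noise standard deviation in reflectance units.
#' @param seed RNG seed.
#' @return Numeric vector of length `length`.
#' @export
simulate_fringe_profile <- function(period_px, length, bias = 1,
                                    noise = 0, seed = 1L) {
  stopifnot(period_px >= 2, bias > 0, noise >= 0)
  if (length <= 0) stop("profile length must be > 0", call. = FALSE)
  x <- seq_len(length) - 1
  .with_seed(seed, function() {
    0.5 + 0.4 * cos(2 * pi * x / (period_px * bias)) +
      stats::rnorm(length, sd = noise)
  })
}
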