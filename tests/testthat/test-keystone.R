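test_that("pixel-plane transforms are exact mutual inverses", {
  set.seed(5)
  g <- projector_geometry(alpha = 18, beta = 0.6)
  px <- cbind(runif(1000, 1, 1280), runif(1000, 1, 800))
  round_trip <- world_to_image(image_to_world(px, g), g)
  expect_lt(max(abs(round_trip - px)), 1e-9)
})

test_that("the pinhole composition matches the independent oracle", {
  g <- projector_geometry(fu = 2116.8, fv = 2122.4, cu = 670.4,
                          cv = -186.8, h = 527, alpha = 20, beta = 0.5)
  set.seed(9)
  for (i in 1:20) {
    u <- runif(1, 1, 1280); v <- runif(1, 1, 800)
    expect_equal(as.numeric(image_to_world(c(u, v), g)),
                 oracle_pixel_to_plane(u, v, g$fu, g$fv, g$cu, g$cv,
                                       g$h, g$alpha, g$beta),
                 tolerance = 1e-12)
  }
})

test_that("zero-angle geometry reduces to pure perspective scaling", {
  g <- projector_geometry(alpha = 0, beta = 0)
  expect_equal(as.numeric(image_to_world(c(g$cu, g$cv), g)), c(0, 0))
  w <- image_to_world(c(g$cu + 100, g$cv + 50), g)
  expect_equal(as.numeric(w), c(100 * g$h / g$fu, 50 * g$h / g$fv))
  g2 <- projector_geometry(alpha = 0, beta = 0, h = 2 * g$h)
  expect_equal(as.numeric(image_to_world(c(g$cu + 100, g$cv + 50), g2)),
               2 * as.numeric(w))
  # paper-scale calibrated instance is accepted
  expect_s3_class(projector_geometry(2116.8, 2122.4, 670.4, -186.8,
                                     527, 18, 0.6), "projector_geometry")
})

test_that("sinusoid generation has the stated period, phases and mean", {
  spec <- sinusoid_spec(40, size = c(10L, 400L))
  pat <- generate_sinusoid(spec)
  expect_true(all(pat >= 0 & pat <= 1))
  maxima <- which(diff(sign(diff(pat[1, ]))) == -2) + 1
  expect_equal(unique(diff(maxima)), 40)
  expect_equal(mean(pat[1, 1:400]), 0.5, tolerance = 1e-12)
  # three-phase set members are cyclic shifts by Tp/3
  p2 <- generate_sinusoid(sinusoid_spec(30, phase = 2 * pi / 3,
                                        size = c(1L, 90L)))
  p1 <- generate_sinusoid(sinusoid_spec(30, size = c(1L, 90L)))
  shift <- c(p1[1, 11:90], p1[1, 1:10])  # shift by Tp/3 = 10
  expect_equal(p2[1, 1:80], shift[1:80], tolerance = 1e-12)
})

test_that("keystone pre-correction is the identity at zero angles", {
  g <- projector_geometry(alpha = 0, beta = 0, size = c(60L, 200L))
  spec <- sinusoid_spec(40, size = c(60L, 200L))
  expect_equal(correct_pattern(spec, g), generate_sinusoid(spec),
               tolerance = 1e-10)
})

test_that("fringe-uniformity error matches hand arithmetic and affine invariance", {
  img <- cbind(c(0, 0, 0), c(1, 0.5, 0))
  expect_equal(keystone_error(img), (0 + sd(c(1, 0.5, 0))) / 2)
  expect_equal(keystone_error(img), 0.25)  # sample std convention
  expect_equal(keystone_error(img, std = "population"),
               sqrt(1 / 6) / 2, tolerance = 1e-12)
  expect_equal(keystone_error(img + 3.2), keystone_error(img))
  expect_equal(keystone_error(img * 7 - 1), keystone_error(img))
  expect_equal(keystone_error(matrix(rep(1:5, each = 3), 3, 5)), 0)
  expect_error(keystone_error(matrix(NA_real_, 2, 2)), "empty")
})

test_that("correct pre-correction yields flatter fringes than wrong or no correction", {
  true_g <- projector_geometry(alpha = 20, beta = 0.5, size = c(200L, 320L))
  spec <- sinusoid_spec(10, size = c(200L, 320L))
  ep_at <- function(a, b) {
    assumed <- projector_geometry(alpha = a, beta = b,
                                  size = true_g$size)
    keystone_error(simulate_projection(spec, true_g, assumed,
                                       fov_mm = 60, cam_px = 80L))
  }
  ep_true <- ep_at(20, 0.5)
  ep_none <- keystone_error(simulate_projection(spec, true_g, NULL,
                                                fov_mm = 60, cam_px = 80L))
  expect_lt(ep_true, 1e-8)       # exact correction -> column-constant
  expect_lt(ep_true, ep_none)
  expect_lt(ep_true, ep_at(18, 0.5))
  expect_lt(ep_true, ep_at(20, 0.0))
})

test_that("angle sweep finds the true angles and breaks ties deterministically", {
  true_g <- projector_geometry(alpha = 20, beta = 0.5, size = c(120L, 200L))
  spec <- sinusoid_spec(12, size = c(120L, 200L))
  ep_fun <- function(a, b) {
    assumed <- projector_geometry(alpha = a, beta = b, size = true_g$size)
    keystone_error(simulate_projection(spec, true_g, assumed,
                                       fov_mm = 50, cam_px = 48L))
  }
  res <- angle_sweep(ep_fun, alphas = 18:22, betas = seq(0.3, 0.7, 0.1))
  expect_equal(res$alpha, 20)
  expect_equal(res$beta, 0.5)
  expect_equal(dim(res$surface), c(5L, 5L))
  # flat surface -> first grid point with a tie warning
  expect_warning(flat <- angle_sweep(function(a, b) 1,
                                     alphas = 1:3, betas = c(0, 0.5)),
                 "tie")
  expect_equal(c(flat$alpha, flat$beta), c(1, 0))
  one <- angle_sweep(function(a, b) a + b, alphas = 4, betas = 0.2)
  expect_equal(c(one$alpha, one$beta), c(4, 0.2))
})
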