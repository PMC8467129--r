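test_that("inversion recovers forward-model spectra to high precision", {
  fx <- c(0, 0.042, 0.084, 0.14)
  rd <- diffuse_reflectance(0.02, 1.2, fx)
  f <- invert_point(fx, rd)
  expect_true(f$converged)
  expect_lt(abs(f$mua / 0.02 - 1), 1e-3)
  expect_lt(abs(f$musp / 1.2 - 1), 1e-3)
})

test_that("degenerate spectra are flagged, not thrown", {
  f <- invert_point(c(0.05, 0.05, 0.05), c(0.4, 0.4, 0.4))
  expect_false(f$converged)
  expect_true(is.na(f$mua))
  expect_match(f$message, "ill-posed")
  expect_error(invert_point(c(0, 0.1), c(0.5, 1.5)), "\\[0, 1.1\\]")
})

test_that("optimiser beats the brute-force grid oracle on every test spectrum", {
  fx <- c(0, 0.028, 0.056, 0.084, 0.112, 0.14)
  cases <- list(c(0.01, 0.8), c(0.1, 1.5), c(0.3, 2.5))
  for (truth in cases) {
    rd <- diffuse_reflectance(truth[1], truth[2], fx)
    f <- invert_point(fx, rd)
    g <- oracle_grid_invert(fx, rd, n_grid = 200)
    expect_lte(f$residual, g$ssr + 1e-15)
    expect_lt(abs(f$mua / truth[1] - 1), 1e-3)
    # grid resolution limits the oracle; optimum must sit near its cell
    expect_lt(abs(log(f$mua / g$mua)), log(5 / 1e-6) / 200 * 2)
  }
})

test_that("random draws invert within 0.1% noiseless and 5% median at 1% noise", {
  set.seed(11)
  n_draw <- 50
  muas <- runif(n_draw, 0.005, 0.5)
  musps <- runif(n_draw, 0.3, 3)
  fx <- sfdi_frequencies()
  err_clean <- err_noisy <- matrix(NA_real_, n_draw, 2)
  for (i in seq_len(n_draw)) {
    rd <- diffuse_reflectance(muas[i], musps[i], fx)
    f <- invert_point(fx, rd)
    err_clean[i, ] <- abs(c(f$mua / muas[i], f$musp / musps[i]) - 1)
    rd_n <- pmin(rd * (1 + rnorm(length(fx), 0, 0.01)), 1.1)
    fn <- invert_point(fx, rd_n)
    err_noisy[i, ] <- abs(c(fn$mua / muas[i], fn$musp / musps[i]) - 1)
  }
  expect_lt(max(err_clean), 0.001)
  expect_lt(median(err_noisy[, 1]), 0.05)
  expect_lt(median(err_noisy[, 2]), 0.05)
})

test_that("map inversion is spatially exact and propagates masks", {
  fx <- c(0, 0.042, 0.084, 0.14)
  rd_imgs <- lapply(fx, function(f)
    matrix(diffuse_reflectance(0.05, 1.8, f), 6, 6))
  maps <- invert_map(rd_imgs, fx)
  ref <- invert_point(fx, vapply(rd_imgs, function(m) m[1, 1], numeric(1)))
  expect_equal(max(abs(maps$mua - ref$mua)), 0, tolerance = 1e-10)
  expect_equal(max(abs(maps$musp - ref$musp)), 0, tolerance = 1e-10)
  # mask at one frequency propagates
  rd_imgs[[2]][3, 4] <- NA
  maps2 <- invert_map(rd_imgs, fx)
  expect_true(is.na(maps2$mua[3, 4]) && is.na(maps2$musp[3, 4]))
  # fully masked input -> fully masked output
  blank <- lapply(fx, function(f) matrix(NA_real_, 3, 3))
  maps3 <- invert_map(blank, fx)
  expect_true(all(is.na(maps3$mua)))
  expect_error(invert_map(list(matrix(0.5, 2, 2), matrix(0.5, 3, 3)),
                          fx[1:2]), "co-registered")
})

test_that("two-region damage scene inverts to both ground truths", {
  s <- make_damage_scene("bruised", seed = 3, size = c(24L, 24L))
  fx <- c(0, 0.042, 0.084, 0.14)
  spec <- scene_spec(s$mua_map, s$musp_map, fx)
  stacks <- simulate_stack(spec)
  demod <- demodulate_acquisition(stacks$sample, stacks$reference, fx)
  maps <- invert_map(demod$rd, fx, medium = medium_constants(n = spec$n))
  for (region in list(s$lesion_mask, !s$lesion_mask)) {
    expect_lt(abs(mean(maps$mua[region]) / mean(s$mua_map[region]) - 1),
              0.005)
    expect_lt(abs(mean(maps$musp[region]) / mean(s$musp_map[region]) - 1),
              0.005)
  }
  expect_gt(mean(maps$mua[s$lesion_mask]), mean(maps$mua[!s$lesion_mask]))
  expect_lt(mean(maps$musp[s$lesion_mask]), mean(maps$musp[!s$lesion_mask]))
})

test_that("linear correction is the mean reference/measured ratio", {
  expect_equal(linear_correction(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(linear_correction(c(2, 4), c(1, 2)), 2)
  expect_equal(linear_correction(c(1, 2), c(2, 2)), 0.75)
  expect_error(linear_correction(c(1, 2), c(0, 2)), "> 0")
  # a known multiplicative system bias b is removed exactly
  ref <- c(0.5, 1, 1.5, 2)
  b <- 1.17
  k <- linear_correction(ref, ref * b)
  expect_equal(apply_correction(ref * b, k) / ref, rep(1, 4))
})

test_that("block binning averages exactly and preserves the mean", {
  m <- matrix(1:16, 4, 4)
  b <- bin_image(m, 2)
  expect_equal(dim(b), c(2L, 2L))
  expect_equal(b[1, 1], mean(m[1:2, 1:2]))
  expect_equal(mean(b), mean(m))
  expect_error(bin_image(matrix(1, 1, 1), 2), "smaller than one block")
})
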