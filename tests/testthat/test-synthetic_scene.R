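test_that("the simulator is deterministic and gain-invariant after calibration", {
  fx <- c(0, 0.042, 0.14)
  mk <- function(gain, seed = 4L) {
    scene_spec(matrix(0.04, 8, 8), matrix(1.1, 8, 8), fx,
               gain = gain, noise_sigma = 0.005, seed = seed)
  }
  s1 <- simulate_stack(mk(6e4))
  s2 <- simulate_stack(mk(6e4))
  expect_identical(s1, s2)  # same seed -> bit-identical
  s3 <- simulate_stack(mk(6e4, seed = 5L))
  expect_false(identical(s1$sample[[2]][[1]], s3$sample[[2]][[1]]))
  # doubling the gain leaves calibrated reflectance unchanged (noiseless)
  a <- simulate_stack(scene_spec(matrix(0.04, 8, 8), matrix(1.1, 8, 8),
                                 fx, gain = 6e4))
  b <- simulate_stack(scene_spec(matrix(0.04, 8, 8), matrix(1.1, 8, 8),
                                 fx, gain = 1.2e5))
  ra <- demodulate_acquisition(a$sample, a$reference, fx)
  rb <- demodulate_acquisition(b$sample, b$reference, fx)
  for (k in seq_along(fx)) expect_equal(ra$rd[[k]], rb$rd[[k]])
})

test_that("full-pipeline recovery: exact noiseless, bounded at 1% noise", {
  set.seed(21)
  for (i in 1:5) {
    mua <- runif(1, 0.005, 0.5); musp <- runif(1, 0.3, 3)
    f <- recover_properties(mua, musp, seed = i)
    expect_lt(abs(f$mua / mua - 1), 0.001)
    expect_lt(abs(f$musp / musp - 1), 0.001)
  }
  errs <- vapply(1:10, function(i) {
    mua <- runif(1, 0.01, 0.4); musp <- runif(1, 0.5, 2.5)
    f <- recover_properties(mua, musp, noise_sigma = 0.01, seed = 100 + i)
    max(abs(c(f$mua / mua, f$musp / musp) - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("damage scenes have class-specific lesions with the stated contrast", {
  norm <- make_damage_scene("normal", seed = 1)
  expect_false(any(norm$lesion_mask))
  for (cl in c("bruised", "scratched", "abraded")) {
    s <- make_damage_scene(cl, seed = 2)
    expect_gt(sum(s$lesion_mask), 0)
    expect_gt(mean(s$mua_map[s$lesion_mask]),
              mean(s$mua_map[!s$lesion_mask]))
    expect_lt(mean(s$musp_map[s$lesion_mask]),
              mean(s$musp_map[!s$lesion_mask]))
  }
})

test_that("lesion placement varies across seeds while class statistics hold", {
  scenes <- lapply(1:20, function(i) make_damage_scene("bruised", seed = i))
  centres <- t(vapply(scenes, function(s) {
    w <- which(s$lesion_mask, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  expect_gt(sd(centres[, 1]), 1)  # placement actually moves
  expect_gt(sd(centres[, 2]), 1)
  contrast <- vapply(scenes, function(s) {
    mean(s$mua_map[s$lesion_mask]) / mean(s$mua_map[!s$lesion_mask]) - 1
  }, numeric(1))
  expect_equal(mean(contrast), 0.15, tolerance = 0.05)
  expect_true(all(contrast > 0.05 & contrast < 0.3))
})

test_that("fringe profile simulation honours period, bias and guards", {
  p <- simulate_fringe_profile(100, length = 600L)
  expect_lt(abs(estimate_pixel_period(p) - 100), 0.5)
  pb <- simulate_fringe_profile(100, length = 600L, bias = 1.02)
  expect_lt(abs(estimate_pixel_period(pb) / 102 - 1), 0.005)
  expect_error(simulate_fringe_profile(100, length = 0L), "> 0")
  expect_identical(simulate_fringe_profile(50, 200L, noise = 0.01, seed = 9),
                   simulate_fringe_profile(50, 200L, noise = 0.01, seed = 9))
})

test_that("masked scene pixels propagate through the simulated stack", {
  mua <- matrix(0.03, 6, 6); mua[2, 2] <- NA
  musp <- matrix(1.2, 6, 6); musp[2, 2] <- NA
  st <- simulate_stack(scene_spec(mua, musp, c(0, 0.1)))
  expect_true(is.na(st$sample[[1]][2, 2]))
  expect_true(is.na(st$sample[[2]][[1]][2, 2]))
  expect_false(anyNA(st$reference[[2]][[1]]))
})
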