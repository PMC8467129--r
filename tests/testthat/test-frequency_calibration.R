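test_that("pixel period estimation recovers known periods to sub-pixel accuracy", {
  prof <- simulate_fringe_profile(158.2, length = 1000L)
  expect_lt(abs(estimate_pixel_period(prof) - 158.2), 0.5)
  # amplitude scaling leaves the estimate unchanged
  expect_equal(estimate_pixel_period(prof * 37 + 2),
               estimate_pixel_period(prof))
  # a 2% multiplicative bias shows up as a 2% longer measured period
  prof_b <- simulate_fringe_profile(100, length = 800L, bias = 1.02)
  expect_lt(abs(estimate_pixel_period(prof_b) / 102 - 1), 0.005)
  expect_error(estimate_pixel_period(rep(1, 500)), "constant")
  expect_error(estimate_pixel_period(simulate_fringe_profile(400, 500L)),
               "two fringe minima")
})

test_that("checkerboard scaling reproduces the bench worked example", {
  tr <- camera_to_actual_period(158.2, xr = 5, xc_mean = 78.3)
  expect_equal(tr, 10.1, tolerance = 0.005)
  rrp <- period_ratio(40, tr)
  expect_equal(rrp * 1000, 3960, tolerance = 0.5)  # pixel per metre
  # identities
  expect_equal(camera_to_actual_period(78.3, 5, 78.3), 5)
  expect_equal(camera_to_actual_period(2 * 158.2, 5, 78.3), 2 * tr)
  expect_equal(period_ratio(10, 10), 1)
  expect_equal(period_ratio(40, tr) * tr, 40)
})

test_that("target periods translate to generation periods at the synthesis resolution", {
  rrp <- 3.96
  tp <- projection_period_for_target(1 / 0.14, rrp)
  expect_equal(tp, 28.3, tolerance = 0.05)
  expect_equal(projection_period_for_target(20, rrp, resolution_px = 0.1),
               79.2, tolerance = 1e-9)
  expect_equal(projection_period_for_target(10, rrp),
               2 * projection_period_for_target(5, rrp), tolerance = 0.11)
  expect_error(projection_period_for_target(Inf, rrp), "planar")
  expect_error(projection_period_for_target(0.2, rrp), "not representable")
})

test_that("period percentage error is symmetric and zero at agreement", {
  expect_equal(period_percentage_error(10, 10), 0)
  expect_equal(period_percentage_error(10, 9.8), 2)
  expect_equal(period_percentage_error(10, 10.2), 2)
})

test_that("two-step calibration removes a multiplicative period bias in one update", {
  rrp0 <- 3.96        # nominal px/mm
  px_per_mm_cam <- 15 # camera scale
  bias <- 1.02
  measure <- function(tp) {
    realized_mm <- tp / rrp0 * bias
    prof <- simulate_fringe_profile(realized_mm * px_per_mm_cam,
                                    length = 1500L, seed = round(tp * 10))
    camera_to_actual_period(estimate_pixel_period(prof),
                            xr = 5, xc_mean = 5 * px_per_mm_cam)
  }
  tre <- 1 / sfdi_frequencies()[-1]  # drop the planar channel
  res <- two_step_calibration(rrp0, tre, measure, fov_mm = 150)
  # with a 150 mm field, nine frequencies carry enough fringes to measure
  expect_equal(sum(res$measured), 9)
  expect_true(all(res$fx[res$measured] > 0.014))
  m <- res$measured
  expect_equal(mean(res$et1[m]), 2, tolerance = 0.15)
  expect_lt(mean(res$et2[m]), 0.2)
  expect_lt(mean(res$et2[m]), mean(res$et1[m]))
  # extrapolated ratios exist for the unmeasured low frequencies
  expect_false(anyNA(res$rrp_k))
})

test_that("two-step calibration is a fixed point for unbiased optics", {
  rrp0 <- 4
  measure <- function(tp) tp / rrp0   # exact linear optics
  res <- two_step_calibration(rrp0, c(10, 20, 30), measure, fov_mm = 100)
  expect_lt(max(res$et1), 1.5)  # only the 0.1 px synthesis quantisation
  expect_lt(max(res$et2), 1.5)
  # a failing measurement flags its frequency and leaves others intact
  measure2 <- function(tp) if (abs(tp - 40) < 1) stop("glitch") else tp / rrp0
  res2 <- two_step_calibration(rrp0, c(10, 20, 30), measure2, fov_mm = 100)
  expect_false(res2$measured[1])
  expect_true(all(res2$measured[2:3]))
})

test_that("the protocol frequency list is the sixteen reference frequencies", {
  fx <- sfdi_frequencies()
  expect_length(fx, 16)
  expect_equal(fx[1], 0)
  expect_equal(max(fx), 0.14)
  expect_true(all(diff(fx) > 0))
})
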