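test_that("body-cavity segmentation matches phantom truth", {
  ct <- default_ct()
  expect_error(segment_body_cavity(new_volume(array(0, c(8, 8, 8)), rep(4, 3))),
               "air")
  cav <- segment_body_cavity(ct)
  nonair <- ct$data > 0.015
  expect_true(all(!(cav$data > 0 & !nonair)))  # subset of non-air
  # truth cavity: body minus wall labels
  fr <- frame_at_phase(build_phantom(), 1)
  lab <- fr$labels$data
  truth <- lab > 0 & lab != 9 & lab != 10
  expect_gte(dice(cav$data > 0, truth), 0.8)
})

test_that("rROI is the cavity dilated anteriorly by the configured distance", {
  ct <- default_ct()
  cav <- cached("cavity", segment_body_cavity(ct))
  expect_equal(build_rroi(cav, dilation_mm = 0)$data, cav$data)
  # single voxel, 5-mm isotropic: 50 mm -> column of 11 voxels
  single <- new_volume(array(0L, c(15, 15, 15)), rep(5, 3))
  single$data[8, 3, 8] <- 1L
  col <- build_rroi(single, 50)
  expect_identical(sum(col$data), 11L)
  expect_true(all(which(col$data > 0, arr.ind = TRUE)[, 2] %in% 3:13))
  # default call: anterior overhang = 50 mm within one voxel
  rroi <- build_rroi(cav, 50)
  over <- rep(NA_real_, dim(cav)[3])
  for (k in seq_len(dim(cav)[3])) {
    if (!any(cav$data[, , k] > 0)) next
    jc <- max(which(apply(cav$data[, , k] > 0, 2, any)))
    jr <- max(which(apply(rroi$data[, , k] > 0, 2, any)))
    over[k] <- (jr - jc) * cav$spacing[2]
  }
  expect_lte(max(over, na.rm = TRUE), 50)
  expect_gte(max(over, na.rm = TRUE), 50 - cav$spacing[2])
  expect_error(build_rroi(new_volume(array(0L, c(4, 4, 4)), rep(4, 3))),
               "empty")
})

test_that("COD is the per-bin mean of in-rROI TOF positions", {
  # hand-built events in a fully-covering rROI
  rroi <- new_volume(array(1L, c(40, 40, 40)), rep(10, 3))
  mk_ev <- function(t_ms, y, tof) tibble::tibble(
    t_ms = as.integer(t_ms), d1x = -300, d1y = y, d1z = 0,
    d2x = 300, d2y = y, d2z = 0, tof_offset = tof)
  ev <- dplyr::bind_rows(
    mk_ev(10, 10, 20), mk_ev(20, -10, -20),    # bin 1: symmetric pair
    mk_ev(150, 5, 0), mk_ev(160, 7, 0), mk_ev(170, 9, 0))  # bin 2
  lm <- urmc:::new_listmode(ev, list(scanner = scanner_geometry(),
                                     duration_s = 0.3))
  trace <- extract_cod(lm, rroi, bin_ms = 100)
  expect_identical(nrow(trace), 3L)
  expect_equal(trace$c_x[1], 0)
  expect_equal(trace$c_y[1], 0)
  expect_equal(trace$c_y[2], 7)
  expect_identical(trace$counts, c(2L, 3L, 0L))
  expect_false(trace$valid[3])
  expect_error(extract_cod(lm, new_volume(array(0L, c(4, 4, 4)), rep(4, 3))),
               "empty")
})

test_that("a 60-s list-mode yields 600 uniform 100-ms COD bins", {
  ev <- tibble::tibble(t_ms = c(0L, 30000L, 59999L), d1x = -300, d1y = 0,
                       d1z = 0, d2x = 300, d2y = 0, d2z = 0, tof_offset = 0)
  lm <- urmc:::new_listmode(ev, list(scanner = scanner_geometry(),
                                     duration_s = 60))
  rroi <- new_volume(array(1L, c(40, 40, 40)), rep(10, 3))
  trace <- extract_cod(lm, rroi)
  expect_identical(nrow(trace), 600L)
  expect_equal(unique(round(diff(trace$time_s), 10)), 0.1)
})

test_that("conditioning preserves clean signals and removes drift", {
  t <- seq(0.05, 120, by = 0.1)
  sine <- 2 * sin(2 * pi * t / 4)
  tr <- tibble::tibble(time_s = t, c_y = sine)
  out <- condition_signal(tr)
  expect_lt(sqrt(mean((out$amplitude - sine)^2)) / sqrt(mean(sine^2)), 0.05)
  expect_equal(median(out$amplitude), 0, tolerance = 1e-9)
  # 2 mm/min linear drift is removed by the moving-median baseline
  tr2 <- tibble::tibble(time_s = t, c_y = sine + 2 * t / 60)
  out2 <- condition_signal(tr2)
  expect_gte(cor(out2$amplitude, sine), 0.99)
  # degenerate inputs
  expect_error(condition_signal(tibble::tibble(time_s = t, c_y = rep(1, length(t)))),
               "no respiratory signal")
  expect_error(condition_signal(tr[1:100, ]), "at least")
})

test_that("COD responds linearly to event coordinates", {
  rroi <- new_volume(array(1L, c(40, 40, 40)), rep(10, 3))
  set.seed(11)
  y <- runif(20, -50, 50)
  mk <- function(yv) tibble::tibble(
    t_ms = 0L, d1x = -300, d1y = yv, d1z = 0, d2x = 300, d2y = yv, d2z = 0,
    tof_offset = 0)
  lm1 <- urmc:::new_listmode(dplyr::bind_rows(lapply(y, mk)),
                             list(scanner = scanner_geometry(), duration_s = 0.1))
  lm2 <- urmc:::new_listmode(dplyr::bind_rows(lapply(2 * y, mk)),
                             list(scanner = scanner_geometry(), duration_s = 0.1))
  c1 <- extract_cod(lm1, rroi)$c_y[1]
  c2 <- extract_cod(lm2, rroi)$c_y[1]
  expect_equal(c2, 2 * c1, tolerance = 1e-9)
})

test_that("rROI suppresses out-of-cavity noise in the respiratory signal", {
  # phantom with an FDG-avid brain analog outside the rROI
  phb <- build_phantom(phantom_config(brain = TRUE))
  lmb <- cached("brain_lm", {
    simulate_listmode(phb, scanner_geometry(), 40, 8000, seed = 303)
  })
  ct <- render_ct(phb, 1)
  cav <- segment_body_cavity(ct)
  rroi <- build_rroi(cav)
  s_t <- waveform_phase(phb$waveform, (seq_len(400) - 0.5) * 0.1)
  all_roi <- new_volume(array(1L, dim(ct$data)), ct$spacing, ct$origin)
  r_with <- cor(condition_signal(extract_cod(lmb, rroi),
                                 min_duration_s = 20)$amplitude, s_t)
  r_without <- cor(condition_signal(extract_cod(lmb, all_roi),
                                    min_duration_s = 20)$amplitude, s_t)
  expect_gte(r_with, r_without)
})

test_that("periodogram locates the breathing frequency of a conditioned trace", {
  lm <- moving_listmode_40s()
  ct <- default_ct()
  rroi <- build_rroi(cached("cavity", segment_body_cavity(ct)))
  sig <- condition_signal(extract_cod(lm, rroi))
  pk <- signal_peak_frequency(sig)
  expect_lt(abs(pk$freq_hz - 0.25), pk$freq_resolution_hz + 1e-9)
})
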