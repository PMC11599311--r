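test_that("SUV follows the body-weight definition", {
  vol <- uniform_volume(5000, c(6, 6, 6), 4)
  meta <- subject_meta(weight_kg = 70, injected_dose_mbq = 280)
  suv <- suv_image(vol, meta, decay_correct = FALSE)
  expect_equal(unique(as.numeric(suv$data)), 5000 * 70000 / 2.8e8)
  expect_equal(unique(as.numeric(
    suv_image(uniform_volume(0, c(4, 4, 4), 4), meta)$data)), 0)
  # doubling the dose halves the SUV
  meta2 <- subject_meta(weight_kg = 70, injected_dose_mbq = 560)
  expect_equal(suv_image(vol, meta2)$data, suv_image(vol, meta)$data / 2)
  # decay correction scales by 2^(delay / half-life)
  suv_dc <- suv_image(vol, meta, decay_correct = TRUE)
  expect_equal(unique(as.numeric(suv_dc$data)),
               5000 * 70000 / (2.8e8 * 2^(-60 / 109.77)))
  expect_error(suv_image(vol, modifyList(meta, list(weight_kg = -1))),
               "positive")
})

test_that("lesion size categories follow the published volume bands", {
  expect_identical(as.character(categorize_lesion(c(3, 7, 15))),
                   c("small", "medium", "large"))
  # closed boundaries
  expect_identical(as.character(categorize_lesion(c(5, 10, 0.1, 0.05))),
                   c("small", "medium", "excluded", "excluded"))
  expect_error(categorize_lesion(-1), "negative")
})

test_that("lesion statistics summarise the SUV distribution in the ROI", {
  suv <- uniform_volume(2, c(10, 10, 10), 4)
  roi <- array(FALSE, c(10, 10, 10)); roi[4:6, 4:6, 4:6] <- TRUE
  st <- lesion_stats(suv, roi)
  expect_equal(st$suv_max, 2)
  expect_equal(st$suv_mean, 2)
  expect_equal(st$volume_ml, 27 * 64 / 1000)
  suv$data[5, 5, 5] <- 3; suv$data[5, 5, 6] <- 1
  st2 <- lesion_stats(suv, roi)
  expect_equal(st2$suv_max, 3)
  expect_gte(st2$suv_max, st2$suv_mean)
  expect_error(lesion_stats(suv, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("paired t-test reproduces hand calculations and edge conventions", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, p = 1, df = 2, mean_diff = 0))
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$p, 2 * stats::pt(-3.4641016, df = 2), tolerance = 1e-6)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:2), "paired")
  zv <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_identical(zv$p, 0)
  expect_identical(zv$t, Inf)
})

test_that("organ amplitudes take the field maximum inside deformed masks", {
  grid <- uniform_volume(0, c(16, 16, 16), 4)
  z <- array(0, dim(grid$data))
  zero_field <- urmc:::new_field(z, z, z, grid)
  organ <- array(FALSE, dim(grid$data)); organ[6:10, 6:10, 6:10] <- TRUE
  out0 <- organ_motion_amplitude(list(liver = organ), zero_field, zero_field)
  expect_equal(out0$amplitude_mm, 0)
  # uniform 12-mm z field inside the organ
  gz <- z; gz[organ] <- 12
  gate_field <- urmc:::new_field(z, z, gz, grid)
  expect_equal(organ_motion_amplitude(list(liver = organ), zero_field,
                                      gate_field)$amplitude_mm, 12)
  # max of {3, 8, 5}
  gz2 <- z; gz2[6, 6, 6] <- 3; gz2[7, 7, 7] <- 8; gz2[8, 8, 8] <- 5
  gate_field2 <- urmc:::new_field(z, z, gz2, grid)
  expect_equal(organ_motion_amplitude(list(liver = organ), zero_field,
                                      gate_field2)$amplitude_mm, 8)
  # empty deformed mask is skipped with a warning
  empty <- array(FALSE, dim(grid$data))
  expect_warning(out <- organ_motion_amplitude(list(gone = empty), zero_field,
                                               gate_field), "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("cohort averages use per-subject maxima", {
  per <- tibble::tibble(subject = c(1, 2), organ = c("liver", "liver"),
                        amplitude_mm = c(10, 20))
  out <- cohort_average(per)
  expect_equal(out$mean_mm, 15)
  expect_equal(out$sd_mm, sd(c(10, 20)))
  expect_equal(out$sd_mm, 7.07, tolerance = 1e-2)
  one <- cohort_average(per[1, ])
  expect_equal(one$sd_mm, 0)
  expect_true(one$single_subject)
  expect_error(cohort_average(per[0, ]), "no per-subject")
})

test_that("threshold segmentation recovers a hot sphere at 41% of its peak", {
  vol <- uniform_volume(1, c(20, 20, 20), 4)
  co <- voxel_coords(vol)
  vol$data <- 1 + 10 * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * 8^2))
  search <- co$x^2 + co$y^2 + co$z^2 < 30^2
  seg <- segment_lesion_threshold(vol, search)
  expect_true(seg[10, 10, 10] || seg[11, 11, 11])
  expect_true(all(vol$data[seg] >= 0.41 * max(vol$data)))
})

test_that("axial FWHM of a Gaussian blob matches its analytic width", {
  vol <- uniform_volume(0, c(24, 24, 24), 4)
  co <- voxel_coords(vol)
  sigma <- 9
  vol$data <- exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * sigma^2))
  roi <- co$x^2 + co$y^2 + co$z^2 < 10^2
  expect_equal(axial_fwhm(vol, roi), 2.355 * sigma, tolerance = 0.1)
})
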