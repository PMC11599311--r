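test_that("waveform phase stays in [0,1], is periodic and starts at end-expiration", {
  for (k in c(1, 2, 3)) {
    wv <- resp_waveform(period = 4, shape_exponent = k)
    t <- seq(0, 60, by = 0.01)
    s <- waveform_phase(wv, t)
    expect_gte(min(s), 0)
    expect_lte(max(s), 1)
    expect_equal(waveform_phase(wv, 0), 0)
    expect_equal(waveform_phase(wv, 13), waveform_phase(wv, 13 + 4),
                 tolerance = 1e-12)
  }
  # jittered waveform stays bounded too
  wj <- resp_waveform(jitter_sd = 0.2, seed = 9)
  sj <- waveform_phase(wj, seq(0, 120, by = 0.05))
  expect_gte(min(sj), 0)
  expect_lte(max(sj), 1)
})

test_that("default phantom contains the expected anatomy", {
  fr <- frame_at_phase(build_phantom(), 0)
  labs <- unique(as.integer(fr$labels$data))
  tab <- label_table()
  for (org in c("lung_l", "lung_r", "liver", "body"))
    expect_true(tab$label[tab$organ == org] %in% labs)
  expect_true(101L %in% labs)  # first lesion
  expect_true(all(fr$activity$data >= 0))
  expect_true(all(fr$mu$data >= 0))
  # lung mu below soft-tissue mu
  lung <- organ_mask(fr$labels, "lung_l")
  liver <- organ_mask(fr$labels, "liver")
  expect_lt(max(fr$mu$data[lung]), min(fr$mu$data[liver]))
})

test_that("invalid configurations are rejected", {
  expect_error(build_phantom(phantom_config(spacing = c(-1, 4, 4))),
               "positive")
  bad <- phantom_config(lesions = list(list(center = c(300, 0, 0),
                                            diameter = 10, uptake_ratio = 5)))
  expect_error(build_phantom(bad), "outside the body")
})

test_that("voxelised lesion volume matches the analytic sphere (2-mm grid)", {
  cfg <- phantom_config(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2),
                        lesions = list(list(center = c(0, 0, 0), diameter = 10,
                                            uptake_ratio = 5)))
  fr <- frame_at_phase(build_phantom(cfg), 0)
  les <- organ_mask(fr$labels, "lesion_1")
  # brute-force oracle: count voxel centres inside the sphere
  co <- voxel_coords(fr$labels)
  oracle <- sum(co$x^2 + co$y^2 + co$z^2 <= 25)
  expect_identical(sum(les), oracle)
  vol_mm3 <- sum(les) * prod(cfg$spacing)
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.15)
})

test_that("motion model translates lesion and liver and conserves activity", {
  ph <- build_phantom()
  fr0 <- frame_at_phase(ph, 0)
  fr1 <- frame_at_phase(ph, 1)
  expect_equal(fr0$truth_field$dz$data, array(0, dim(fr0$labels$data)))
  les0 <- organ_mask(fr0$labels, "lesion_1")
  les1 <- organ_mask(fr1$labels, "lesion_1")
  co <- voxel_coords(fr0$labels)
  # 20-mm programmed SI shift, within half a voxel
  expect_lt(abs((mean(co$z[les0]) - mean(co$z[les1])) - 20), 2)
  # lesion activity conserved under pure translation (<= 1%)
  expect_lt(abs(sum(fr1$activity$data[les1]) / sum(fr0$activity$data[les0]) - 1),
            0.01)
  # time sampling at a multiple of the period reproduces the reference
  frT <- sample_frame(ph, 8)  # period 4 s
  expect_equal(frT$activity$data, fr0$activity$data)
})

test_that("truth field warps the reference into any phase frame", {
  ph <- build_phantom()
  fr0 <- frame_at_phase(ph, 0)
  for (s in c(0.4, 1)) {
    fr <- frame_at_phase(ph, s)
    w <- warp_image(fr0$activity,
                    structure(list(dx = fr$truth_field$dx,
                                   dy = fr$truth_field$dy,
                                   dz = fr$truth_field$dz,
                                   fixed = NULL, moving = NULL),
                              class = "rmc_field"))
    nrmse <- sqrt(mean((w$data - fr$activity$data)^2)) / max(fr0$activity$data)
    expect_lt(nrmse, 0.05)
  }
})

test_that("CT rendering reproduces phase geometry and rejects bad phases", {
  ph <- build_phantom()
  expect_error(render_ct(ph, 1.2), "phase")
  expect_error(render_ct(ph, -0.1), "phase")
  ct0 <- render_ct(ph, 0)
  expect_equal(ct0$data, frame_at_phase(ph, 0)$mu$data)
  # diaphragm (liver top slice) moves by si_amplitude / spacing slices
  top_slice <- function(s) {
    liv <- organ_mask(frame_at_phase(ph, s)$labels, "liver")
    max(which(apply(liv, 3, any)))
  }
  expect_equal(top_slice(0) - top_slice(1), 20 / 4)
  # mu histogram contains the configured tissue values
  mus <- unique(as.numeric(ct0$data))
  expect_true(all(c(0, 0.03, 0.096) %in% mus))
})
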