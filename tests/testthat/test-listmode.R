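test_that("zero activity yields an empty event stream", {
  act0 <- c(body = 0, lung_l = 0, lung_r = 0, liver = 0, spleen = 0,
            stomach = 0, kidney_l = 0, kidney_r = 0, chest_wall = 0,
            abdominal_wall = 0, brain = 0, air = 0)
  ph <- build_phantom(phantom_config(activity = act0, lesions = list()))
  lm <- simulate_listmode(ph, scanner_geometry(), 1, 1000, seed = 1)
  expect_identical(nrow(lm$events), 0L)
})

test_that("simulator preconditions are enforced", {
  ph <- static_phantom()
  expect_error(simulate_listmode(ph, scanner_geometry(ring_radius = 100),
                                 1, 100), "ring radius")
  expect_error(simulate_listmode(ph, scanner_geometry(), -1, 100), "duration")
})

test_that("accepted count concentrates at the requested Poisson rate", {
  lm <- static_listmode_20s()  # 20 s x 8000 cps
  lambda <- 20 * 8000
  expect_lt(abs(nrow(lm$events) - lambda), 4 * sqrt(lambda))
  # timestamps non-decreasing and inside the scan
  expect_true(!is.unsorted(lm$events$t_ms))
  expect_true(all(lm$events$t_ms >= 0 & lm$events$t_ms < 20000))
})

test_that("detectors lie on the scanner cylinder and offsets respect the chord", {
  lm <- static_listmode_20s()
  ev <- lm$events
  r1 <- sqrt(ev$d1x^2 + ev$d1y^2)
  r2 <- sqrt(ev$d2x^2 + ev$d2y^2)
  expect_lt(max(abs(r1 - 300)) / 300, 1e-6)
  expect_lt(max(abs(r2 - 300)) / 300, 1e-6)
  expect_true(all(abs(ev$d1z) <= 200 & abs(ev$d2z) <= 200))
  half <- sqrt((ev$d2x - ev$d1x)^2 + (ev$d2y - ev$d1y)^2 +
                 (ev$d2z - ev$d1z)^2) / 2
  expect_true(all(abs(ev$tof_offset) <= half + 1e-9))
})

test_that("TOF noise matches the configured positional resolution", {
  lm <- cached("point_lm", {
    simulate_listmode(point_source_phantom(), scanner_geometry(),
                      duration_s = 5, mean_rate_cps = 4000, seed = 6)
  })
  # point source at a voxel centre: the true offset is ~0, so the offset sd
  # is the TOF blur along the LOR, fwhm / 2.355 = 19.1 mm (plus small
  # quantisation and in-voxel jitter variance)
  expect_lt(abs(sd(lm$events$tof_offset) - 45 / 2.355) / (45 / 2.355), 0.1)
})

test_that("attenuation integrals follow Beer-Lambert along known chords", {
  # uniform mu box; analytic optical depth for axis-aligned chords
  mu <- uniform_volume(0.096, c(40, 40, 40), 4)  # 160-mm cube
  a <- rbind(c(-300, 0, 0), c(0, -300, 0))
  b <- rbind(c(300, 0, 0), c(0, 300, 0))
  att <- urmc:::cpp_line_integral(a, b, as.numeric(mu$data), dim(mu$data),
                                  mu$spacing, mu$origin, 1)
  expect_equal(att, rep(0.096 * 16, 2), tolerance = 0.02)
  # mu = 0 gives no thinning: accepted rate equals the geometric rate
  p0 <- point_source_phantom()
  p0$config$mu <- c(soft = 0, lung = 0, air = 0)
  lm0 <- simulate_listmode(p0, scanner_geometry(), 2, 2000, seed = 7)
  expect_lt(abs(nrow(lm0$events) - 4000), 4 * sqrt(4000))
})

test_that("tof_position places events along the LOR", {
  lm <- tiny_listmode()
  pos <- tof_position(lm)
  # det1 (-300,0,-50), det2 (300,0,50), offset +30 toward det2
  u <- c(600, 0, 100) / sqrt(600^2 + 100^2)
  expect_equal(pos[1, ], c(0, 0, 0) + 30 * u, tolerance = 1e-9)
  # det1 (0,-300,0), det2 (0,300,10), offset -75
  u2 <- c(0, 600, 10) / sqrt(600^2 + 100)
  expect_equal(pos[2, ], c(0, 0, 5) - 75 * u2, tolerance = 1e-9)
  # zero offset -> midpoint
  expect_equal(pos[3, ], c(0, 0, 5), tolerance = 1e-9)
  bad <- lm
  bad$events$d2x[1] <- bad$events$d1x[1]
  bad$events$d2y[1] <- bad$events$d1y[1]
  bad$events$d2z[1] <- bad$events$d1z[1]
  expect_error(tof_position(bad), "degenerate")
})

test_that("binary and CSV round trips are exact", {
  lm <- tiny_listmode()
  p <- tempfile(fileext = ".ulm")
  write_listmode(lm, p)
  lm2 <- read_listmode(p)
  expect_identical(lm2$events, lm$events)
  expect_equal(lm2$header$duration_s, lm$header$duration_s)
  expect_equal(unclass(lm2$header$scanner), unclass(lm$header$scanner))
  # empty set keeps its header
  lm0 <- urmc:::new_listmode(lm$events[0, ], modifyList(lm$header,
                                                        list(n_events = 0L)))
  write_listmode(lm0, p)
  expect_identical(nrow(read_listmode(p)$events), 0L)
  # CSV debug dialect: 3 data rows x 8 numeric columns
  pc <- tempfile(fileext = ".csv")
  write_listmode(lm, pc, format = "csv")
  lines <- readLines(pc)
  expect_true(startsWith(lines[1], "# "))
  lm3 <- read_listmode(pc, format = "csv")
  expect_equal(as.data.frame(lm3$events), as.data.frame(lm$events),
               tolerance = 1e-12)
  expect_identical(ncol(lm3$events), 8L)
  unlink(c(p, pc))
})

test_that("corrupted binary files fail with an offset in the message", {
  lm <- tiny_listmode()
  p <- tempfile(fileext = ".ulm")
  write_listmode(lm, p)
  raw <- readBin(p, raw(), file.info(p)$size)
  writeBin(raw[1:(length(raw) - 13)], p)  # truncate mid-record
  expect_error(read_listmode(p), "byte offset")
  writeBin(as.raw(c(1, 2, 3, 4)), p)
  expect_error(read_listmode(p), "magic|offset")
  unlink(p)
})
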