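test_that("forward projection of a uniform image matches numeric quadrature", {
  img <- uniform_volume(3, c(20, 20, 20), 4)  # 80-mm cube of value 3
  lm <- tiny_listmode()
  y <- forward_project(img, lm, scanner = scanner_geometry(), step_mm = 0.5)
  # oracle: integrate value x Gaussian pdf over the in-grid portion of the LOR
  ev <- lm$events
  sigma <- 45 / (2 * sqrt(2 * log(2)))
  for (e in 1:3) {
    d1 <- c(ev$d1x[e], ev$d1y[e], ev$d1z[e])
    d2 <- c(ev$d2x[e], ev$d2y[e], ev$d2z[e])
    L <- sqrt(sum((d2 - d1)^2))
    u <- (d2 - d1) / L
    tq <- L / 2 + ev$tof_offset[e]
    inside <- function(t) {
      p <- sweep(outer(t, u), 2, d1, `+`)
      apply(abs(p) <= 40, 1, all)  # cube half-width 40 mm (with half-voxel rim)
    }
    oracle <- stats::integrate(function(t)
      3 * inside(t) * stats::dnorm(t, tq, sigma), tq - 3.5 * sigma,
      tq + 3.5 * sigma, subdivisions = 500)$value
    expect_equal(y[e], oracle, tolerance = 0.02)
  }
  # mu = 0 leaves the projection unchanged
  mu0 <- uniform_volume(0, c(20, 20, 20), 4)
  expect_equal(forward_project(img, lm, mu = mu0, scanner = scanner_geometry(),
                               step_mm = 0.5), y)
})

test_that("forward and backward TOF projectors are exact adjoints", {
  set.seed(31)
  grid <- uniform_volume(0, c(16, 16, 16), 4)
  x <- vol_like(grid, array(runif(16^3), dim(grid$data)))
  lm <- static_listmode_20s()
  ev <- lm$events[sample.int(nrow(lm$events), 200), ]
  yw <- runif(200)
  Ax <- forward_project(x, ev, scanner = scanner_geometry())
  Aty <- backproject_events(ev, yw, grid, scanner = scanner_geometry())
  lhs <- sum(Ax * yw)
  rhs <- sum(x$data * Aty$data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("MLEM reaches closed-form and brute-force ML solutions", {
  # single-voxel system with unit sensitivity: estimate = N after 1 iteration
  ax_ev <- tibble::tibble(t_ms = 0L, d1x = -300, d1y = 0, d1z = 0,
                          d2x = 300, d2y = 0, d2z = 0, tof_offset = 0)
  ev <- ax_ev[rep(1, 5), ]
  lmN <- urmc:::new_listmode(ev, list(scanner = scanner_geometry(),
                                      duration_s = 1))
  grid1 <- new_volume(array(0, c(1, 1, 1)), c(50, 50, 50), c(0, 0, 0))
  sens1 <- vol_like(grid1, array(1, c(1, 1, 1)))
  rec <- mlem_reconstruct(lmN, grid1, n_iter = 1, n_subsets = 1,
                          sensitivity = sens1, calibrate = FALSE,
                          post_filter_mm = 0, support_frac = 0)
  expect_equal(as.numeric(rec$data), 5, tolerance = 1e-9)

  # 2-voxel, 3-LOR toy system vs a brute-force grid search of the Poisson
  # log-likelihood with the projector's own weights
  grid2 <- new_volume(array(0, c(2, 1, 1)), c(40, 40, 40), c(-20, 0, 0))
  ev3 <- tibble::tibble(
    t_ms = c(0L, 1L, 2L),
    d1x = c(-300, -300, 0), d1y = c(0, 0, -300), d1z = 0,
    d2x = c(300, 300, 0), d2y = c(0, 0, 300), d2z = 0,
    tof_offset = c(-20, 20, 0))  # LORs along x (two) and along y through x=0
  lm3 <- urmc:::new_listmode(ev3, list(scanner = scanner_geometry(),
                                       duration_s = 1))
  # per-event weights p_ej from unit-voxel forward projections
  P <- vapply(1:2, function(j) {
    unit <- grid2
    unit$data[j, 1, 1] <- 1
    forward_project(unit, lm3, scanner = scanner_geometry(), step_mm = 0.5)
  }, numeric(3))
  S <- c(1, 1)
  rec2 <- mlem_reconstruct(lm3, grid2, n_iter = 400, n_subsets = 1,
                           sensitivity = vol_like(grid2, array(S, c(2, 1, 1))),
                           calibrate = FALSE, post_filter_mm = 0,
                           support_frac = 0, step_mm = 0.5)
  ll <- function(x) sum(log(P %*% x)) - sum(S * x)
  gr <- as.matrix(expand.grid(x1 = seq(0.01, 6, by = 0.01),
                              x2 = seq(0.01, 6, by = 0.01)))
  best <- gr[which.max(apply(gr, 1, ll)), ]
  expect_equal(as.numeric(rec2$data), as.numeric(best), tolerance = 0.01)
})

test_that("MLEM keeps images non-negative and the likelihood non-decreasing", {
  lm <- static_listmode_20s()
  small <- urmc:::new_listmode(lm$events[seq_len(5000), ], lm$header)
  grid <- urmc:::listmode_grid(lm)
  rec <- mlem_reconstruct(small, grid, n_iter = 4, n_subsets = 1,
                          calibrate = FALSE, post_filter_mm = 0,
                          sens_seed = 41, track_loglik = TRUE)
  expect_true(all(rec$data >= 0))
  ll <- attr(rec, "loglik")
  expect_length(ll, 4L)
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
  expect_error(mlem_reconstruct(urmc:::new_listmode(lm$events[0, ], lm$header),
                                grid), "empty")
})

test_that("NAC reconstruction shows the central attenuation artifact", {
  lm <- static_listmode_20s()
  grid <- urmc:::listmode_grid(lm)
  nac <- cached("static_nac", {
    mlem_reconstruct(lm, grid, n_iter = 3, n_subsets = 8, calibrate = FALSE,
                     sens_seed = 42)
  })
  fr <- frame_at_phase(static_phantom(), 0)
  lab <- fr$labels$data
  centre <- organ_mask(fr$labels, "liver")          # deep tissue
  edge <- lab == 9L | lab == 10L                    # wall rind
  true_ratio <- mean(fr$activity$data[centre]) / mean(fr$activity$data[edge])
  nac_ratio <- mean(nac$data[centre]) / mean(nac$data[edge])
  expect_lt(nac_ratio, true_ratio)
})

test_that("AC with the true mu recovers the lesion-to-background ratio", {
  # large lesion so the check is not dominated by partial volume
  cfg <- phantom_config(
    waveform = resp_waveform(si_amplitude = 0, ap_amplitude = 0),
    lesions = list(list(center = c(35, 5, -40), diameter = 24,
                        uptake_ratio = 8)))
  ph <- build_phantom(cfg)
  lm <- simulate_listmode(ph, scanner_geometry(), 20, 8000, seed = 305)
  grid <- urmc:::listmode_grid(lm)
  mu <- oracle_mu(ph, 0)
  rec <- mlem_reconstruct(lm, grid, n_iter = 3, n_subsets = 8, mu = mu,
                          sens_seed = 43, post_filter_mm = 0)
  fr <- frame_at_phase(ph, 0)
  les <- erode_mask <- organ_mask(fr$labels, "lesion_1")
  liv <- organ_mask(fr$labels, "liver")
  true_ratio <- (8 * 5000) / 6000
  rec_ratio <- mean(rec$data[les]) / mean(rec$data[liv])
  expect_lt(abs(rec_ratio - true_ratio) / true_ratio, 0.15)
})
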