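test_that("mutual information has its analytic values on crafted inputs", {
  # self-MI equals the marginal entropy
  ct <- default_ct()
  mask <- ct$data >= 0
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  tabs <- table(cut(ct$data[mask], 32)) / sum(mask)
  expect_equal(mutual_information(ct, ct, mask = mask), h(as.numeric(tabs)),
               tolerance = 0.05)
  # constant image -> zero information
  const <- vol_like(ct, array(1, dim(ct$data)))
  expect_equal(mutual_information(const, ct, mask = mask), 0)
  # hand-evaluated 2x2 joint distribution (0.4, 0.1 / 0.1, 0.4)
  a <- new_volume(array(rep(c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1), 10), c(10, 10, 1)),
                  c(1, 1, 1))
  b <- new_volume(array(rep(c(0, 0, 0, 0, 1, 1, 0, 1, 1, 1), 10), c(10, 10, 1)),
                  c(1, 1, 1))
  expect_equal(mutual_information(a, b, mask = array(TRUE, c(10, 10, 1))),
               2 * 0.4 * log(0.4 / 0.25) + 2 * 0.1 * log(0.1 / 0.25),
               tolerance = 1e-9)
})

test_that("reference-gate selection maximises MI with the CT", {
  ph <- build_phantom()
  ct <- render_ct(ph, 0.55)
  expect_error(select_reference_gate(list(), ct), "no gated")
  expect_identical(as.integer(select_reference_gate(list(oracle_mu(ph, 0.2)), ct)),
                   0L)
  phases <- c(0.05, 0.3, 0.55, 0.9)
  mus <- lapply(phases, oracle_mu, phantom = ph)
  sel <- select_reference_gate(mus, ct)
  expect_identical(as.integer(sel), 2L)
  # matches a brute-force MI ranking
  mi <- vapply(mus, mutual_information, 0, b = ct)
  expect_identical(as.integer(sel), which.max(mi) - 1L)
})

test_that("registration is near-identity for identical inputs and recovers translations", {
  ph <- build_phantom()
  mu0 <- oracle_mu(ph, 0)
  f0 <- register_nonrigid(mu0, mu0)
  expect_lt(max(abs(urmc:::field_magnitude(f0))), 0.1 * mean(mu0$spacing))
  # 8-mm translated Gaussian blob
  d <- c(24, 24, 24)
  mk <- function(cz) {
    g <- new_volume(array(0, d), rep(4, 3))
    co <- voxel_coords(g)
    g$data <- exp(-((co$x)^2 + (co$y)^2 + (co$z - cz)^2) / (2 * 18^2))
    g
  }
  f <- register_nonrigid(mk(0), mk(-8), register_config(smooth_mm = 0))
  blob <- mk(0)$data > 0.4
  expect_lt(abs(mean(f$dz$data[blob]) - (-8)) / 8, 0.2)
  ssd <- attr(f, "ssd")
  expect_lte(ssd["after"], ssd["before"])
  # non-overlapping supports -> zero field with a warning
  za <- new_volume(array(0, d), rep(4, 3)); za$data[2, 2, 2] <- 1
  zb <- new_volume(array(0, d), rep(4, 3)); zb$data[20, 20, 20] <- 1
  expect_warning(fz <- register_nonrigid(za, zb), "overlap")
  expect_equal(max(abs(urmc:::field_magnitude(fz))), 0)
})

test_that("warping follows the pulling convention", {
  set.seed(51)
  img <- new_volume(array(runif(16^3), c(16, 16, 16)), rep(4, 3))
  z <- array(0, dim(img$data))
  idf <- urmc:::new_field(z, z, z, img)
  expect_equal(warp_image(img, idf)$data, img$data)
  # uniform +2-voxel (8 mm) translation along z equals an index shift
  tf <- urmc:::new_field(z, z, z + 8, img)
  w <- warp_image(img, tf)
  expect_equal(w$data[, , 1:14], img$data[, , 3:16], tolerance = 1e-12)
  expect_true(all(w$data >= 0))
})

test_that("consolidation is the count-weighted mean", {
  a <- uniform_volume(1, c(6, 6, 6), 4)
  b <- uniform_volume(3, c(6, 6, 6), 4)
  expect_equal(consolidate(list(a, a), c(10, 90))$data, a$data)
  expect_equal(unique(as.numeric(consolidate(list(a, b), c(100, 300))$data)),
               2.5)
  expect_equal(consolidate(list(a, b), c(7, 7))$data,
               (a$data + b$data) / 2)
  small <- uniform_volume(1, c(5, 5, 5), 4)
  expect_error(consolidate(list(a, small), c(1, 1)), "grid")
})

test_that("field inversion solves the fixed-point equation", {
  grid <- uniform_volume(0, c(20, 20, 20), 4)
  co <- voxel_coords(grid)
  # smooth analytic field
  dz <- 6 * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * 30^2))
  f <- urmc:::new_field(array(0, dim(dz)), array(0, dim(dz)), dz, grid)
  inv <- invert_field(f, tol_mm = 0.05)
  # composing d with its inverse should vanish away from the boundary
  comp <- warp_image(f$dz, inv)$data + inv$dz$data
  interior <- array(FALSE, dim(dz)); interior[5:16, 5:16, 5:16] <- TRUE
  expect_lt(max(abs(comp[interior])), 0.15)
})

test_that("PET-CT alignment improves mu-map agreement and preserves identity", {
  ph <- build_phantom()
  mu0 <- oracle_mu(ph, 0)
  lam <- vol_like(mu0, mu0$data * 1000)
  al <- align_pet_ct(lam, mu0, mu0)
  expect_lt(max(abs(al$lambda_urmc$data - lam$data)) / max(lam$data), 0.01)
  mu_ct <- oracle_mu(ph, 0.35)
  al2 <- align_pet_ct(lam, mu0, mu_ct)
  expect_gte(al2$mi_after, al2$mi_before)
})
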