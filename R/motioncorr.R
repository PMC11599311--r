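#' Shannon mutual information between two volumes
#'
#' Computed from the joint histogram over masked voxels, with bins spanning
#' the robust (0.5-99.5 percentile) intensity range of each image; natural
#' logarithm, so the result is in nats. A constant image inside the mask
#' gives 0.
#'
#' @param a,b `rmc_volume`s on the same grid.
#' @param bins histogram bins per axis.
#' @param mask optional logical array; defaults to voxels where either image
#'   is positive (the body support for mu maps).
#' @return mutual information in nats (`>= 0`).
#' @export
mutual_information <- function(a, b, bins = 32, mask = NULL) {
  if (!same_grid(a, b)) stop("images must share a grid")
  if (is.null(mask)) mask <- a$data > 0 | b$data > 0
  if (!any(mask)) stop("empty mask")
  x <- a$data[mask]
  y <- b$data[mask]
  cutbin <- function(v) {
    r <- as.numeric(quantile(v, c(0.005, 0.995)))
    if (diff(r) <= 0) return(rep(1L, length(v)))
    pmin(bins, pmax(1L, 1L + floor((v - r[1]) / diff(r) * bins)))
  }
  bx <- cutbin(x)
  by <- cutbin(y)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins, byrow = TRUE))
  py <- colSums(matrix(p, bins, bins, byrow = TRUE))
  nz <- p > 0
  outer_p <- as.numeric(t(outer(px, py)))
  sum(p[nz] * log(p[nz] / outer_p[nz]))
}

#' Select the reference gate by mutual information with the CT mu map
#'
#' The reference gate is the gate whose attenuation map is closest to the CT
#' in respiratory phase, quantified as the maximiser of the mutual
#' information between the gated mu map and the CT mu map. Ties break toward
#' the lower gate index.
#'
#' @param mu_gates list of gated attenuation `rmc_volume`s (index g+1 holds
#'   gate g).
#' @param mu_ct CT attenuation `rmc_volume` (gates are resampled to its grid
#'   if needed).
#' @param bins histogram bins for the MI estimate.
#' @return 0-based reference gate index, with attribute `mi` (per-gate MI).
#' @export
select_reference_gate <- function(mu_gates, mu_ct, bins = 32) {
  if (length(mu_gates) == 0) stop("no gated attenuation maps supplied")
  mi <- vapply(mu_gates, function(m) {
    if (!same_grid(m, mu_ct)) m <- resample_volume(m, mu_ct)
    mutual_information(m, mu_ct, bins = bins)
  }, 0)
  ref <- which.max(mi) - 1L   # which.max returns the first (lowest) maximiser
  attr(ref, "mi") <- mi
  ref
}

#' Registration configuration
#'
#' @param levels multi-resolution pyramid depth.
#' @param iterations per-level iteration counts, coarse to fine.
#' @param sigma_field_vox Gaussian regularisation of the accumulated field,
#'   voxels.
#' @param sigma_fluid_vox Gaussian smoothing of each update (fluid-like),
#'   voxels.
#' @param max_step_vox per-iteration update cap, voxels.
#' @param smooth_mm image pre-smoothing before matching, mm.
#' @param robust_q robust-maximum quantile for intensity normalisation.
#' @param symmetric use the mean of the fixed and warped-moving gradients as
#'   the demons force (better large-displacement behaviour).
#' @return config list for [register_nonrigid()].
#' @export
register_config <- function(levels = 3, iterations = c(150, 100, 50),
                            sigma_field_vox = 1.25, sigma_fluid_vox = 0.5,
                            max_step_vox = 1, smooth_mm = 4,
                            robust_q = 0.995, symmetric = TRUE) {
  list(levels = levels, iterations = rep(iterations, length.out = levels),
       sigma_field_vox = sigma_field_vox, sigma_fluid_vox = sigma_fluid_vox,
       max_step_vox = max_step_vox, smooth_mm = smooth_mm,
       robust_q = robust_q, symmetric = symmetric)
}

new_field <- function(dx, dy, dz, grid, fixed = NULL, moving = NULL) {
  mk <- function(a, ax) new_volume(array(a, dim(grid$data)), grid$spacing,
                                   grid$origin, list(kind = paste0("field_", ax)))
  structure(list(dx = mk(dx, "x"), dy = mk(dy, "y"), dz = mk(dz, "z"),
                 fixed = fixed, moving = moving), class = "rmc_field")
}

#' @export
print.rmc_field <- function(x, ...) {
  mag <- sqrt(x$dx$data^2 + x$dy$data^2 + x$dz$data^2)
  cat(sprintf("<rmc_field> %s, |d| max %.2f mm, mean %.2f mm\n",
              paste(dim(x$dx$data), collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

field_magnitude <- function(field) {
  sqrt(field$dx$data^2 + field$dy$data^2 + field$dz$data^2)
}

robust_normalize <- function(vol, q) {
  pos <- vol$data[vol$data > 0]
  if (length(pos) == 0) return(vol)
  m <- as.numeric(quantile(pos, q))
  if (m <= 0) return(vol)
  vol_like(vol, pmin(vol$data / m, 1.5))
}

downsample_vol <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol$data)
  nd <- as.integer(ceiling(d / f))
  ns <- vol$spacing * f
  no <- vol$origin + (f - 1) / 2 * vol$spacing
  out <- cpp_resample_grid(as.numeric(vol$data), d, vol$spacing, vol$origin,
                           nd, ns, no)
  new_volume(array(out, nd), ns, no, vol$tags)
}

central_gradient <- function(a, spacing) {
  d <- dim(a)
  g <- function(axis) {
    hi <- shift_num(a, axis, 1L)    # a[i+1] (edge-replicated)
    lo <- shift_num(a, axis, -1L)   # a[i-1]
    (hi - lo) / (2 * spacing[axis])
  }
  list(gx = g(1L), gy = g(2L), gz = g(3L))
}

shift_num <- function(a, axis, by) {
  # shift with edge replication
  d <- dim(a)
  n <- d[axis]
  idx <- pmin(n, pmax(1L, seq_len(n) + by))
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

demons_level <- function(fixed, moving, field, iters, cfg) {
  sp <- fixed$spacing
  dims <- dim(fixed$data)
  grf <- central_gradient(fixed$data, sp)
  kappa <- 1 / mean(sp)^2
  max_step <- cfg$max_step_vox * mean(sp)
  smooth3 <- function(fx, fy, fz, s_vox) {
    if (s_vox <= 0) return(list(fx, fy, fz))
    sv <- rep(s_vox, 3)
    list(array(cpp_gauss_smooth(as.numeric(fx), dims, sv), dims),
         array(cpp_gauss_smooth(as.numeric(fy), dims, sv), dims),
         array(cpp_gauss_smooth(as.numeric(fz), dims, sv), dims))
  }
  warp_now <- function(fx, fy, fz)
    array(cpp_warp_pull(as.numeric(moving$data), dims, sp, fixed$origin,
                        as.numeric(fx), as.numeric(fy), as.numeric(fz)), dims)
  fx <- field[[1]]; fy <- field[[2]]; fz <- field[[3]]
  w <- warp_now(fx, fy, fz)
  best_ssd <- sum((w - fixed$data)^2)
  best <- list(fx, fy, fz)
  for (i in seq_len(iters)) {
    diff <- fixed$data - w
    gr <- if (isTRUE(cfg$symmetric)) {
      gm <- central_gradient(w, sp)
      list(gx = (grf$gx + gm$gx) / 2, gy = (grf$gy + gm$gy) / 2,
           gz = (grf$gz + gm$gz) / 2)
    } else grf
    g2 <- gr$gx^2 + gr$gy^2 + gr$gz^2
    denom <- g2 + kappa * diff^2
    scale <- ifelse(denom > 1e-12, diff / denom, 0)
    ux <- scale * gr$gx; uy <- scale * gr$gy; uz <- scale * gr$gz
    mag <- sqrt(ux^2 + uy^2 + uz^2)
    over <- mag > max_step
    if (any(over)) {
      f <- max_step / mag[over]
      ux[over] <- ux[over] * f; uy[over] <- uy[over] * f
      uz[over] <- uz[over] * f
    }
    u <- smooth3(ux, uy, uz, cfg$sigma_fluid_vox)
    fx <- fx + u[[1]]; fy <- fy + u[[2]]; fz <- fz + u[[3]]
    sm <- smooth3(fx, fy, fz, cfg$sigma_field_vox)
    fx <- sm[[1]]; fy <- sm[[2]]; fz <- sm[[3]]
    w <- warp_now(fx, fy, fz)
    ssd <- sum((w - fixed$data)^2)
    if (ssd < best_ssd) {
      best_ssd <- ssd
      best <- list(fx, fy, fz)
    }
  }
  best
}

#' Demons-style non-rigid registration
#'
#' Multi-resolution (3-level) demons registration with sum-of-squared
#' -difference matching and Gaussian field regularisation, suited to the two
#' single-modal problems in this pipeline (gated PET to reference-gate PET,
#' and reference-gate mu map to CT mu map). Intensities are robust-max
#' normalised and lightly smoothed before matching. Returns the pulling
#' displacement field (output voxel `x` samples the moving image at
#' `x + d(x)`, mm, world axes). The returned field never increases the SSD:
#' the best field over the iteration history is kept, and a zero field (with
#' a warning) is returned when the image supports do not overlap.
#'
#' @param fixed,moving `rmc_volume`s on the same grid.
#' @param config a [register_config()].
#' @return an `rmc_field`, with attribute `ssd` = `c(before, after)`.
#' @export
register_nonrigid <- function(fixed, moving, config = register_config()) {
  if (!same_grid(fixed, moving)) stop("fixed and moving must share a grid")
  overlap <- (fixed$data > 0) & (moving$data > 0)
  zero_field <- function() {
    z <- array(0, dim(fixed$data))
    f <- new_field(z, z, z, fixed, fixed$tags, moving$tags)
    attr(f, "ssd") <- rep(sum((fixed$data - moving$data)^2), 2)
    f
  }
  if (!any(overlap)) {
    warning("image supports do not overlap; returning a zero field")
    return(zero_field())
  }
  fx0 <- robust_normalize(fixed, config$robust_q)
  mv0 <- robust_normalize(moving, config$robust_q)
  if (config$smooth_mm > 0) {
    fx0 <- smooth_volume(fx0, config$smooth_mm)
    mv0 <- smooth_volume(mv0, config$smooth_mm)
  }
  ssd_before <- sum((fx0$data - mv0$data)^2)
  factors <- 2^((config$levels - 1):0)
  field <- NULL
  for (li in seq_along(factors)) {
    f <- factors[li]
    fl <- downsample_vol(fx0, f)
    ml <- downsample_vol(mv0, f)
    if (is.null(field)) {
      z <- array(0, dim(fl$data))
      field <- list(z, z, z)
    } else {
      field <- lapply(field_prev_vols, function(v) {
        r <- cpp_resample_grid(as.numeric(v$data), dim(v$data), v$spacing,
                               v$origin, dim(fl$data), fl$spacing, fl$origin)
        array(r, dim(fl$data))
      })
    }
    field <- demons_level(fl, ml, field, config$iterations[li], config)
    field_prev_vols <- lapply(field, function(a)
      new_volume(a, fl$spacing, fl$origin))
  }
  out <- new_field(field[[1]], field[[2]], field[[3]], fx0,
                   fixed$tags, moving$tags)
  warped <- warp_image(mv0, out)
  ssd_after <- sum((fx0$data - warped$data)^2)
  if (ssd_after > ssd_before) {
    out <- zero_field()
    ssd_after <- ssd_before
  }
  attr(out, "ssd") <- c(before = ssd_before, after = ssd_after)
  out
}

#' Warp an image with a displacement field
#'
#' Pulling-convention resampling: output voxel `x` samples the image at
#' `x + d(x)`; out-of-grid samples are 0; trilinear interpolation (which
#' preserves non-negativity).
#'
#' @param image `rmc_volume` in the field's moving frame.
#' @param field an `rmc_field` on the same grid.
#' @param check_frames error if image and field carry mismatched frame tags.
#' @return warped `rmc_volume`.
#' @export
warp_image <- function(image, field, check_frames = FALSE) {
  if (!same_grid(image, field$dx)) stop("image and field grids differ")
  if (check_frames && !is.null(field$moving) && !is.null(image$tags$gate) &&
      !is.null(field$moving$gate) &&
      !identical(image$tags$gate, field$moving$gate))
    stop("field moving-frame tag does not match the image frame")
  out <- cpp_warp_pull(as.numeric(image$data), dim(image$data),
                       image$spacing, image$origin,
                       as.numeric(field$dx$data), as.numeric(field$dy$data),
                       as.numeric(field$dz$data))
  vol_like(image, out)
}

#' Consolidate warped gate images into the motion-corrected image
#'
#' Count-weighted voxelwise mean of the warped gated images; with equal-count
#' gates this is essentially the plain mean, and the result stays in
#' activity units.
#'
#' @param warped_gates list of `rmc_volume`s on a common grid.
#' @param gate_counts per-gate event counts (weights).
#' @param reference_gate reference gate index recorded in the tags.
#' @return consolidated `rmc_volume`.
#' @export
consolidate <- function(warped_gates, gate_counts, reference_gate = NULL) {
  stopifnot(length(warped_gates) >= 1,
            length(gate_counts) == length(warped_gates))
  if (any(gate_counts <= 0)) stop("gate counts must be positive")
  g1 <- warped_gates[[1]]
  for (g in warped_gates[-1])
    if (!same_grid(g1, g)) stop("gate images are on mismatched grids")
  w <- gate_counts / sum(gate_counts)
  acc <- array(0, dim(g1$data))
  for (i in seq_along(warped_gates))
    acc <- acc + w[i] * warped_gates[[i]]$data
  new_volume(acc, g1$spacing, g1$origin,
             list(kind = "emission", ac = TRUE, motion_corrected = TRUE,
                  reference_gate = reference_gate))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `g(x) = -d(x + g(x))` to the given tolerance, giving the inverse
#' pulling field (used to reslice CT-space organ masks into the reference
#' gate frame).
#'
#' @param field an `rmc_field`.
#' @param tol_mm convergence tolerance on the max update, mm.
#' @param max_iter iteration cap.
#' @return inverse `rmc_field`.
#' @export
invert_field <- function(field, tol_mm = 0.1, max_iter = 50) {
  grid <- field$dx
  dims <- dim(grid$data)
  gx <- array(0, dims); gy <- gx; gz <- gx
  for (i in seq_len(max_iter)) {
    sample_d <- function(comp)
      array(cpp_warp_pull(as.numeric(comp$data), dims, grid$spacing,
                          grid$origin, as.numeric(gx), as.numeric(gy),
                          as.numeric(gz)), dims)
    nx <- -sample_d(field$dx)
    ny <- -sample_d(field$dy)
    nz <- -sample_d(field$dz)
    delta <- max(abs(nx - gx), abs(ny - gy), abs(nz - gz))
    gx <- nx; gy <- ny; gz <- nz
    if (delta < tol_mm) break
  }
  new_field(gx, gy, gz, grid, field$moving, field$fixed)
}

#' Align the motion-corrected PET to the CT
#'
#' Rather than multi-modal PET-to-CT registration, the residual PET-CT
#' misalignment is solved as a single-modal registration between the
#' reference-gate attenuation map and the CT attenuation map; the resulting
#' displacement field then deforms the motion-corrected PET into CT space.
#'
#' @param lambda_rmc motion-corrected emission `rmc_volume` (reference-gate
#'   frame).
#' @param mu_ref_gate reference-gate attenuation map (same frame).
#' @param mu_ct CT attenuation map.
#' @param config a [register_config()].
#' @return list: `lambda_urmc` (CT space), `field` (alignment field),
#'   `mi_before`, `mi_after` (MI between the warped/unwarped reference mu
#'   and the CT mu).
#' @export
align_pet_ct <- function(lambda_rmc, mu_ref_gate, mu_ct,
                         config = register_config()) {
  if (!same_grid(lambda_rmc, mu_ref_gate))
    stop("lambda_rmc and mu_ref_gate must share the reference-gate grid")
  if (!same_grid(mu_ref_gate, mu_ct)) {
    mu_ref_gate <- resample_volume(mu_ref_gate, mu_ct)
    lambda_rmc <- resample_volume(lambda_rmc, mu_ct)
  }
  field <- register_nonrigid(fixed = mu_ct, moving = mu_ref_gate, config)
  mi_before <- mutual_information(mu_ref_gate, mu_ct)
  warped_mu <- warp_image(mu_ref_gate, field)
  mi_after <- mutual_information(warped_mu, mu_ct)
  lambda_urmc <- warp_image(lambda_rmc, field)
  lambda_urmc$tags <- c(lambda_rmc$tags[setdiff(names(lambda_rmc$tags), "kind")],
                        list(kind = "emission", space = "CT"))
  list(lambda_urmc = lambda_urmc, field = field,
       mi_before = mi_before, mi_after = mi_after)
}
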