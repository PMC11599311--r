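#' Respiratory waveform model
#'
#' Normalised breathing phase \eqn{s(t) = ((1 - \cos 2\pi t/T)/2)^k \in [0,1]},
#' with `s = 0` at end-expiration (the reference phase) and `s = 1` at peak
#' inspiration. The shape exponent `k >= 1` lengthens the end-expiration
#' plateau, matching the asymmetric breathing seen in free-breathing
#' acquisitions. Optional seeded per-cycle Gaussian amplitude jitter and a
#' slow superior-inferior baseline drift (mm/min) are supported.
#'
#' @param period breathing period, seconds.
#' @param si_amplitude peak superior-inferior displacement of the diaphragm
#'   and abdominal organs, mm.
#' @param ap_amplitude peak anterior displacement of the chest/abdominal
#'   wall, mm.
#' @param shape_exponent unitless `>= 1`; larger values lengthen expiration.
#' @param drift_rate slow additive superior-inferior drift, mm/min.
#' @param jitter_sd per-cycle amplitude jitter (sd of a Gaussian factor with
#'   mean 1); 0 disables it.
#' @param seed seed for the jitter stream.
#' @return a `resp_waveform` object with a `phase_fn` closure mapping time
#'   (s) to phase in `[0,1]`.
#' @export
resp_waveform <- function(period = 4, si_amplitude = 20, ap_amplitude = 10,
                          shape_exponent = 2, drift_rate = 0,
                          jitter_sd = 0, seed = 1L) {
  stopifnot(period > 0, shape_exponent >= 1, si_amplitude >= 0,
            ap_amplitude >= 0, jitter_sd >= 0)
  jitter <- NULL
  if (jitter_sd > 0) {
    rng <- local({ set.seed(as.integer(seed)); rnorm(10000, 1, jitter_sd) })
    jitter <- pmax(0, rng)
  }
  phase_fn <- function(t) {
    s <- ((1 - cos(2 * pi * t / period)) / 2)^shape_exponent
    if (!is.null(jitter)) {
      cyc <- pmin(floor(t / period) + 1, length(jitter))
      s <- pmin(1, pmax(0, s * jitter[cyc]))
    }
    s
  }
  structure(list(period = period, si_amplitude = si_amplitude,
                 ap_amplitude = ap_amplitude,
                 shape_exponent = shape_exponent, drift_rate = drift_rate,
                 jitter_sd = jitter_sd, seed = seed, phase_fn = phase_fn),
            class = "resp_waveform")
}

#' @rdname resp_waveform
#' @param waveform a `resp_waveform`.
#' @param t time in seconds (vectorised).
#' @export
waveform_phase <- function(waveform, t) waveform$phase_fn(t)

#' Subject metadata
#'
#' Defaults follow a typical whole-body FDG protocol (injection of roughly
#' 276 MBq, imaging 60 min post-injection, F-18 half-life 109.77 min).
#'
#' @param weight_kg body weight, kg.
#' @param injected_dose_mbq injected activity, MBq.
#' @param uptake_delay_min minutes from injection to scan start.
#' @param half_life_min tracer half-life, minutes.
#' @return a `subject_meta` list.
#' @export
subject_meta <- function(weight_kg = 65, injected_dose_mbq = 276,
                         uptake_delay_min = 60, half_life_min = 109.77) {
  vals <- c(weight_kg, injected_dose_mbq, uptake_delay_min, half_life_min)
  if (any(vals <= 0)) stop("all subject metadata fields must be positive")
  structure(list(weight_kg = weight_kg, injected_dose_mbq = injected_dose_mbq,
                 uptake_delay_min = uptake_delay_min,
                 half_life_min = half_life_min), class = "subject_meta")
}

# organ label codes used in phantom label volumes
PHANTOM_LABELS <- c(air = 0L, body = 1L, lung_l = 2L, lung_r = 3L,
                    liver = 4L, spleen = 5L, stomach = 6L, kidney_l = 7L,
                    kidney_r = 8L, chest_wall = 9L, abdominal_wall = 10L,
                    brain = 11L)
LESION_LABEL_BASE <- 100L

#' Organ label code table
#' @return tibble of label codes and organ names (lesions are coded
#'   `100 + lesion index`).
#' @export
label_table <- function() {
  tibble::tibble(label = unname(PHANTOM_LABELS), organ = names(PHANTOM_LABELS))
}

#' Phantom configuration
#'
#' Parameters of the 4D breathing thoracoabdominal phantom: grid, organ
#' geometry (ellipsoids in mm from the FOV centre; X lateral, Y anterior,
#' Z superior), 511-keV attenuation coefficients, relative FDG-like activity
#' concentrations (Bq/mL), lesion list and breathing waveform.
#'
#' @param dim grid size `c(nx, ny, nz)`.
#' @param spacing voxel spacing mm, length 3.
#' @param lesions list of lesions, each `list(center = c(x,y,z) mm,
#'   diameter = mm, uptake_ratio = multiple of soft-tissue activity)`; an
#'   optional `activity` field (Bq/mL) overrides the ratio.
#' @param waveform a [resp_waveform()].
#' @param brain include an FDG-avid brain/head analog superior to the torso
#'   (a high-uptake structure outside the respiratory ROI).
#' @param meta a [subject_meta()].
#' @param ... overrides for geometry/tissue defaults (see source).
#' @return config list for [build_phantom()].
#' @export
phantom_config <- function(dim = c(64L, 64L, 96L), spacing = c(4, 4, 4),
                           lesions = list(list(center = c(35, 5, -15),
                                               diameter = 10,
                                               uptake_ratio = 8)),
                           waveform = resp_waveform(),
                           brain = FALSE,
                           meta = subject_meta(), ...) {
  cfg <- list(
    dim = as.integer(dim), spacing = as.numeric(spacing),
    lesions = lesions, waveform = waveform, brain = brain, meta = meta,
    # torso outline: elliptic cylinder, z range in mm
    body_a = 110, body_b = 80, torso_z = c(-184, 120),
    wall_frac = 0.82,          # elliptical radius where the wall rind starts
    diaphragm_z = -5,          # reference liver dome / diaphragm position
    lung_top_z = 113,          # superior end of the motion ramp
    # organ ellipsoids: center, semi-axes (mm)
    organs = list(
      lung_l   = list(center = c(-48, -5, 55),  semi = c(36, 50, 58)),
      lung_r   = list(center = c(48, -5, 55),   semi = c(36, 50, 58)),
      liver    = list(center = c(35, 5, -53),   semi = c(50, 55, 48)),
      spleen   = list(center = c(-62, -8, -38), semi = c(24, 28, 32)),
      stomach  = list(center = c(-25, 22, -45), semi = c(28, 28, 30)),
      kidney_l = list(center = c(-42, -35, -118), semi = c(18, 20, 32)),
      kidney_r = list(center = c(42, -35, -118),  semi = c(18, 20, 32))),
    brain_center = c(0, -10, 158), brain_radius = 28,
    neck_radius = 22, neck_z = c(120, 135),
    mu = c(soft = 0.096, lung = 0.03, air = 0),   # 1/cm at 511 keV
    activity = c(body = 5000, lung_l = 1000, lung_r = 1000, liver = 6000,
                 spleen = 6000, stomach = 4000, kidney_l = 8000,
                 kidney_r = 8000, chest_wall = 4000, abdominal_wall = 4000,
                 brain = 50000, air = 0))
  modifyList(cfg, list(...))
}

#' Build a 4D breathing phantom
#'
#' Validates the configuration and returns a generator object that renders a
#' [sample_frame()] (activity, attenuation, organ/lesion labels and the
#' ground-truth displacement field) at any time point. Motion model: organs
#' below the diaphragm and diaphragm-adjacent lesions translate inferiorly by
#' `si_amplitude * s(t)` (lesions purely, so lesion activity is conserved);
#' lung tissue stretches between the displaced diaphragm and the static lung
#' apex; the anterior chest/abdominal wall advances by `ap_amplitude * s(t)`.
#' All rendering is analytic at the displaced geometry, so the truth field is
#' voxelisation-exact.
#'
#' @param config a [phantom_config()].
#' @return an `rmc_phantom` object.
#' @export
build_phantom <- function(config = phantom_config()) {
  if (any(config$spacing <= 0)) stop("voxel spacing must be strictly positive")
  for (i in seq_along(config$lesions)) {
    les <- config$lesions[[i]]
    ctr <- les$center
    rho2 <- (ctr[1] / config$body_a)^2 + (ctr[2] / config$body_b)^2
    if (rho2 > 1 || ctr[3] < config$torso_z[1] || ctr[3] > config$torso_z[2])
      stop(sprintf("lesion %d centre (%s) lies outside the body", i,
                   paste(ctr, collapse = ", ")))
    if (les$diameter <= 0) stop("lesion diameter must be positive")
  }
  structure(list(config = config, waveform = config$waveform,
                 meta = config$meta), class = "rmc_phantom")
}

#' @export
print.rmc_phantom <- function(x, ...) {
  cat(sprintf("<rmc_phantom> %s grid @ %s mm, %d lesion(s), period %.3g s, SI %.3g mm\n",
              paste(x$config$dim, collapse = "x"),
              paste(x$config$spacing, collapse = "x"),
              length(x$config$lesions), x$waveform$period,
              x$waveform$si_amplitude))
  invisible(x)
}

phantom_activity_from_labels <- function(cfg, lab) {
  lut <- numeric(LESION_LABEL_BASE + length(cfg$lesions) + 1)
  for (nm in names(cfg$activity))
    lut[PHANTOM_LABELS[[nm]] + 1] <- cfg$activity[[nm]]
  for (i in seq_along(cfg$lesions)) {
    les <- cfg$lesions[[i]]
    lut[LESION_LABEL_BASE + i + 1] <-
      if (!is.null(les$activity)) les$activity
      else les$uptake_ratio * cfg$activity[["body"]]
  }
  array(lut[lab + 1L], dim(lab))
}

phantom_mu_from_labels <- function(cfg, lab) {
  lut <- rep(cfg$mu[["soft"]], LESION_LABEL_BASE + length(cfg$lesions) + 1)
  lut[PHANTOM_LABELS[["air"]] + 1] <- cfg$mu[["air"]]
  lut[PHANTOM_LABELS[["lung_l"]] + 1] <- cfg$mu[["lung"]]
  lut[PHANTOM_LABELS[["lung_r"]] + 1] <- cfg$mu[["lung"]]
  array(lut[lab + 1L], dim(lab))
}

# labels on a tensor grid of reference coordinates (1-D axis vectors);
# organs are evaluated only inside their bounding boxes.
phantom_ref_labels_grid <- function(cfg, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  lab <- array(PHANTOM_LABELS[["air"]], c(nx, ny, nz))
  rho2 <- outer((xs / cfg$body_a)^2, (ys / cfg$body_b)^2, `+`)
  torso_k <- which(zs >= cfg$torso_z[1] & zs <= cfg$torso_z[2])
  in2 <- rho2 <= 1
  wall2 <- in2 & rho2 > cfg$wall_frac^2
  body_sl <- array(PHANTOM_LABELS[["air"]], c(nx, ny))
  body_sl[in2] <- PHANTOM_LABELS[["body"]]
  chest_sl <- body_sl; chest_sl[wall2] <- PHANTOM_LABELS[["chest_wall"]]
  abd_sl <- body_sl; abd_sl[wall2] <- PHANTOM_LABELS[["abdominal_wall"]]
  for (k in torso_k)
    lab[, , k] <- if (zs[k] > cfg$diaphragm_z) chest_sl else abd_sl
  add_ellipsoid <- function(lab, center, semi, code) {
    tx <- ((xs - center[1]) / semi[1])^2
    ty <- ((ys - center[2]) / semi[2])^2
    tz <- ((zs - center[3]) / semi[3])^2
    ix <- which(tx < 1); iy <- which(ty < 1); iz <- which(tz < 1)
    if (!length(ix) || !length(iy) || !length(iz)) return(lab)
    sub <- outer(outer(tx[ix], ty[iy], `+`), tz[iz], `+`) <= 1
    # restrict to the torso so organs never spill outside the body
    sub <- sub & array(in2[ix, iy], dim(sub)) &
      rep(zs[iz] >= cfg$torso_z[1] & zs[iz] <= cfg$torso_z[2],
          each = length(ix) * length(iy))
    box <- lab[ix, iy, iz, drop = FALSE]
    box[sub] <- code
    lab[ix, iy, iz] <- box
    lab
  }
  for (org in names(cfg$organs)) {
    o <- cfg$organs[[org]]
    lab <- add_ellipsoid(lab, o$center, o$semi, PHANTOM_LABELS[[org]])
  }
  if (isTRUE(cfg$brain)) {
    neck2 <- outer(xs^2, (ys - cfg$brain_center[2])^2, `+`) <= cfg$neck_radius^2
    for (k in which(zs > cfg$neck_z[1] & zs <= cfg$neck_z[2])) {
      sl <- lab[, , k]; sl[neck2] <- PHANTOM_LABELS[["body"]]
      lab[, , k] <- sl
    }
    r <- cfg$brain_radius
    lab <- add_sphere(lab, xs, ys, zs, cfg$brain_center, r,
                      PHANTOM_LABELS[["brain"]], clip_torso = FALSE)
  }
  for (i in seq_along(cfg$lesions)) {
    les <- cfg$lesions[[i]]
    lab <- add_sphere(lab, xs, ys, zs, les$center, les$diameter / 2,
                      LESION_LABEL_BASE + i, clip_torso = FALSE)
  }
  lab
}

add_sphere <- function(lab, xs, ys, zs, center, r, code, clip_torso) {
  tx <- (xs - center[1])^2; ty <- (ys - center[2])^2; tz <- (zs - center[3])^2
  r2 <- r^2
  ix <- which(tx < r2); iy <- which(ty < r2); iz <- which(tz < r2)
  if (!length(ix) || !length(iy) || !length(iz)) return(lab)
  sub <- outer(outer(tx[ix], ty[iy], `+`), tz[iz], `+`) <= r2
  box <- lab[ix, iy, iz, drop = FALSE]
  box[sub] <- code
  lab[ix, iy, iz] <- box
  lab
}

# 1-D pulling displacements: dz depends only on z, dy only on y (dx = 0)
phantom_pull_1d <- function(cfg, wv, ys, zs, s, t = 0) {
  d_si <- wv$si_amplitude * s + wv$drift_rate * t / 60
  d_ap <- wv$ap_amplitude * s
  zd <- cfg$diaphragm_z - d_si
  zt <- cfg$lung_top_z
  dz <- numeric(length(zs))
  dz[zs <= zd] <- d_si
  ramp <- zs > zd & zs < zt
  if (d_si != 0)
    dz[ramp] <- d_si * (zt - zs[ramp]) / (zt - cfg$diaphragm_z + d_si)
  y_in <- cfg$wall_frac * cfg$body_b
  dy <- numeric(length(ys))
  if (d_ap != 0)
    dy <- -d_ap * pmin(pmax((ys - y_in) / (cfg$body_b - y_in), 0), 1)
  list(dy = dy, dz = dz)
}

render_phantom_frame <- function(phantom, s, t = 0) {
  cfg <- phantom$config
  d <- cfg$dim
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * cfg$spacing[1]
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * cfg$spacing[2]
  zs <- (seq_len(d[3]) - (d[3] + 1) / 2) * cfg$spacing[3]
  d1 <- phantom_pull_1d(cfg, phantom$waveform, ys, zs, s, t)
  lab <- phantom_ref_labels_grid(cfg, xs, ys + d1$dy, zs + d1$dz)
  act <- phantom_activity_from_labels(cfg, lab)
  mu <- phantom_mu_from_labels(cfg, lab)
  dfx <- array(0, d)
  dfy <- array(rep(rep(d1$dy, each = d[1]), times = d[3]), d)
  dfz <- array(rep(d1$dz, each = d[1] * d[2]), d)
  mk <- function(a, tags) new_volume(a, cfg$spacing, tags = tags)
  structure(list(
    activity = mk(act, list(kind = "activity", phase = s)),
    mu = mk(mu, list(kind = "mu", phase = s)),
    labels = mk(lab, list(kind = "labels", phase = s)),
    truth_field = list(dx = mk(dfx, list(kind = "field_x", phase = s)),
                       dy = mk(dfy, list(kind = "field_y", phase = s)),
                       dz = mk(dfz, list(kind = "field_z", phase = s))),
    phase = s, t = t), class = "rmc_frame")
}

#' Render the phantom at a time point
#'
#' @param phantom an `rmc_phantom`.
#' @param t time in seconds (`t >= 0`).
#' @return an `rmc_frame`: activity (Bq/mL), mu (1/cm), labels, the exact
#'   pulling displacement field (mm, frame -> reference) and the phase.
#' @export
sample_frame <- function(phantom, t) {
  stopifnot(inherits(phantom, "rmc_phantom"), t >= 0)
  s <- phantom$waveform$phase_fn(t)
  render_phantom_frame(phantom, s, t)
}

#' Render the phantom at a fixed phase
#'
#' @param phantom an `rmc_phantom`.
#' @param phase phase in `[0,1]`; `0` is the end-expiration reference.
#' @return an `rmc_frame` (no drift/jitter; pure phase rendering).
#' @export
frame_at_phase <- function(phantom, phase) {
  stopifnot(inherits(phantom, "rmc_phantom"))
  if (phase < 0 || phase > 1) stop("phase must lie in [0, 1]")
  render_phantom_frame(phantom, phase, 0)
}

#' CT attenuation map at an arbitrary respiratory phase
#'
#' Emulates the CT snapshot of a PET/CT acquisition: a single attenuation map
#' frozen at one breathing phase. Setting `phase` near 1 reproduces the
#' deep-inspiration CT that mismatches free-breathing PET (the PET gates
#' rarely reach peak inspiration, so misalignment persists after gating).
#'
#' @param phantom an `rmc_phantom`.
#' @param phase phase in `[0,1]`.
#' @return an `rmc_volume` mu map (1/cm), tagged as CT.
#' @export
render_ct <- function(phantom, phase) {
  if (phase < 0 || phase > 1) stop("CT phase must lie in [0, 1]")
  fr <- frame_at_phase(phantom, phase)
  v <- fr$mu
  v$tags <- list(kind = "mu", source = "CT", phase = phase)
  v
}

#' Binary mask of one organ or lesion from a label volume
#'
#' @param labels label `rmc_volume` from an `rmc_frame`.
#' @param organ organ name from [label_table()], or `"lesion_<i>"`.
#' @return logical array.
#' @export
organ_mask <- function(labels, organ) {
  code <- if (grepl("^lesion_", organ)) {
    LESION_LABEL_BASE + as.integer(sub("^lesion_", "", organ))
  } else PHANTOM_LABELS[[organ]]
  labels$data == code
}

#' Write phantom frame volumes and config to disk
#'
#' Volumes as NIfTI, configuration as YAML, subject metadata as JSON.
#'
#' @param phantom an `rmc_phantom`.
#' @param frame an `rmc_frame`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_phantom_frame <- function(phantom, frame, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    activity = file.path(dir, "activity.nii.gz"),
    mu = file.path(dir, "mu.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    field_x = file.path(dir, "truth_field_x.nii.gz"),
    field_y = file.path(dir, "truth_field_y.nii.gz"),
    field_z = file.path(dir, "truth_field_z.nii.gz"))
  write_volume(frame$activity, paths[["activity"]])
  write_volume(frame$mu, paths[["mu"]])
  lab <- frame$labels; lab$data <- array(as.numeric(lab$data), dim(lab$data))
  write_volume(lab, paths[["labels"]])
  write_volume(frame$truth_field$dx, paths[["field_x"]])
  write_volume(frame$truth_field$dy, paths[["field_y"]])
  write_volume(frame$truth_field$dz, paths[["field_z"]])
  cfg <- phantom$config
  cfg$waveform <- cfg$waveform[c("period", "si_amplitude", "ap_amplitude",
                                 "shape_exponent", "drift_rate", "jitter_sd",
                                 "seed")]
  cfg$meta <- NULL
  yaml::write_yaml(cfg, file.path(dir, "phantom_config.yaml"))
  jsonlite::write_json(unclass(phantom$meta), file.path(dir, "subject_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
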