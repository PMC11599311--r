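#' Cylindrical TOF scanner geometry
#'
#' @param ring_radius detector ring radius, mm.
#' @param axial_half_length half the axial field of view, mm.
#' @param tof_fwhm positional TOF resolution along the LOR, mm (FWHM).
#' @param tof_bin_width TOF quantisation bin width, mm.
#' @return a `scanner_geometry` list.
#' @export
scanner_geometry <- function(ring_radius = 300, axial_half_length = 200,
                             tof_fwhm = 45, tof_bin_width = 10) {
  stopifnot(ring_radius > 0, axial_half_length > 0, tof_fwhm > 0,
            tof_bin_width > 0)
  structure(list(ring_radius = ring_radius,
                 axial_half_length = axial_half_length,
                 tof_fwhm = tof_fwhm, tof_bin_width = tof_bin_width),
            class = "scanner_geometry")
}

new_listmode <- function(events, header) {
  structure(list(header = header, events = events), class = "rmc_listmode")
}

#' @export
print.rmc_listmode <- function(x, ...) {
  cat(sprintf("<rmc_listmode> %d events over %.3g s", nrow(x$events),
              x$header$duration_s))
  if (!is.null(x$header$gate)) cat(sprintf(", gate %d", x$header$gate))
  cat("\n")
  invisible(x)
}

listmode_grid <- function(lm) {
  g <- lm$header$grid
  new_volume(array(0, g$dim), g$spacing, g$origin)
}

#' Simulate a TOF list-mode acquisition of a breathing phantom
#'
#' Events are drawn from an inhomogeneous Poisson process whose spatial
#' intensity follows the phantom activity at each 10-ms simulation step
#' (finer than the 100-ms respiratory binning, so intra-bin motion is
#' negligible). Each emission gets an isotropic LOR, detector intersections
#' with the scanner cylinder, attenuation thinning by the survival probability
#' `exp(-integral of mu)` along the full chord (so NAC reconstructions show
#' attenuation artifacts), and a TOF offset = true emission offset + Gaussian
#' noise of FWHM `tof_fwhm`, quantised to `tof_bin_width`. `mean_rate_cps` is
#' the *accepted* coincidence rate: a seeded Monte-Carlo pilot estimates the
#' geometric + attenuation acceptance and scales the emission rate
#' accordingly. Trues only: no randoms or scatter are simulated.
#'
#' @param phantom an `rmc_phantom`.
#' @param scanner a [scanner_geometry()].
#' @param duration_s scan duration, seconds.
#' @param mean_rate_cps mean accepted coincidence rate, counts/s.
#' @param seed RNG seed (all randomness flows through R's RNG).
#' @param n_phase_frames number of precomputed phase frames.
#' @param step_ms simulation time step, ms.
#' @param attn_step_mm ray-sampling step for attenuation integrals, mm.
#' @param pilot_n Monte-Carlo size for the initial acceptance estimate.
#' @return an `rmc_listmode`: a tibble of events (`t_ms`, `d1x..d1z`,
#'   `d2x..d2z` detector coordinates in mm from the FOV centre, `tof_offset`
#'   in mm, positive toward detector 2) plus a header (scanner, duration,
#'   subject metadata, grid, calibration total activity).
#' @export
simulate_listmode <- function(phantom, scanner, duration_s, mean_rate_cps,
                              seed = 1L, n_phase_frames = 13L, step_ms = 10,
                              attn_step_mm = 4, pilot_n = 20000L) {
  stopifnot(inherits(phantom, "rmc_phantom"),
            inherits(scanner, "scanner_geometry"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (mean_rate_cps <= 0) stop("mean_rate_cps must be positive")
  cfg <- phantom$config
  half_ext <- (cfg$dim - 1) / 2 * cfg$spacing
  if (scanner$ring_radius <= sqrt(sum(half_ext[1:2]^2)))
    stop("scanner ring radius is smaller than the phantom transaxial extent")
  set.seed(as.integer(seed))

  # phase frame library
  s_grid <- seq(0, 1, length.out = n_phase_frames)
  frames <- lapply(s_grid, function(s) frame_at_phase(phantom, s))
  ref <- frames[[1]]
  total_act_bq <- sum(ref$activity$data) * voxel_volume_ml(ref$activity)
  grid_info <- list(dim = cfg$dim, spacing = cfg$spacing,
                    origin = ref$activity$origin)
  header <- list(scanner = scanner, duration_s = duration_s,
                 mean_rate_cps = mean_rate_cps, meta = unclass(phantom$meta),
                 grid = grid_info, total_activity_bq = total_act_bq,
                 seed = as.integer(seed),
                 tof_sign = "positive toward det2")
  empty <- tibble::tibble(t_ms = integer(), d1x = double(), d1y = double(),
                          d1z = double(), d2x = double(), d2y = double(),
                          d2z = double(), tof_offset = double())
  if (total_act_bq <= 0) {
    header$n_events <- 0L
    return(new_listmode(empty, header))
  }

  co <- voxel_coords(ref$activity)
  sample_emissions <- function(frame, n) {
    act <- as.numeric(frame$activity$data)
    cp <- cumsum(act)
    idx <- findInterval(runif(n) * cp[length(cp)], cp) + 1L
    cbind(co$x[idx] + (runif(n) - 0.5) * cfg$spacing[1],
          co$y[idx] + (runif(n) - 0.5) * cfg$spacing[2],
          co$z[idx] + (runif(n) - 0.5) * cfg$spacing[3])
  }
  iso_dirs <- function(n) {
    cz <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - cz^2))
    cbind(r * cos(phi), r * sin(phi), cz)
  }
  project <- function(frame, pts, dirs) {
    cpp_project_events(pts, dirs, scanner$ring_radius,
                       scanner$axial_half_length,
                       as.numeric(frame$mu$data), cfg$dim, cfg$spacing,
                       ref$activity$origin, attn_step_mm)
  }

  # initial acceptance estimate (refined adaptively as batches accrue)
  pp <- project(ref, sample_emissions(ref, pilot_n), iso_dirs(pilot_n))
  p_acc <- mean(pp$accept * exp(-pp$attn))
  if (p_acc <= 0) stop("no events survive the scanner geometry")

  n_steps <- as.integer(ceiling(duration_s * 1000 / step_ms))
  t_centers <- ((seq_len(n_steps)) - 0.5) * step_ms / 1000
  s_t <- phantom$waveform$phase_fn(t_centers)
  frame_idx <- pmin(n_phase_frames,
                    pmax(1L, round(s_t * (n_phase_frames - 1)) + 1L))
  # accepted counts are Poisson at the requested rate per simulation step;
  # emissions are rejection-sampled until each frame group reaches its target
  counts <- rpois(n_steps, mean_rate_cps * step_ms / 1000)

  parts <- vector("list", n_phase_frames)
  for (f in seq_len(n_phase_frames)) {
    steps_f <- which(frame_idx == f)
    n_f <- sum(counts[steps_f])
    if (n_f == 0) next
    acc <- list()
    n_have <- 0L
    while (n_have < n_f) {
      n_try <- as.integer(ceiling((n_f - n_have) / p_acc * 1.2)) + 100L
      pts <- sample_emissions(frames[[f]], n_try)
      prj <- project(frames[[f]], pts, iso_dirs(n_try))
      keep <- prj$accept & (runif(n_try) < exp(-prj$attn))
      p_acc <- max(1e-4, 0.5 * p_acc + 0.5 * mean(keep))
      if (!any(keep)) next
      acc[[length(acc) + 1]] <- list(d1 = prj$det1[keep, , drop = FALSE],
                                     d2 = prj$det2[keep, , drop = FALSE],
                                     off = prj$offset[keep])
      n_have <- n_have + sum(keep)
    }
    d1 <- do.call(rbind, lapply(acc, `[[`, "d1"))[seq_len(n_f), , drop = FALSE]
    d2 <- do.call(rbind, lapply(acc, `[[`, "d2"))[seq_len(n_f), , drop = FALSE]
    off <- unlist(lapply(acc, `[[`, "off"))[seq_len(n_f)]
    step_of <- rep(steps_f, counts[steps_f])
    off <- off + rnorm(n_f, 0, scanner$tof_fwhm / (2 * sqrt(2 * log(2))))
    off <- round(off / scanner$tof_bin_width) * scanner$tof_bin_width
    half_chord <- sqrt(rowSums((d2 - d1)^2)) / 2
    off <- pmin(pmax(off, -half_chord), half_chord)
    t_ms <- as.integer((step_of - 1L) * step_ms + floor(runif(n_f) * step_ms))
    parts[[f]] <- tibble::tibble(
      t_ms = t_ms, d1x = d1[, 1], d1y = d1[, 2], d1z = d1[, 3],
      d2x = d2[, 1], d2y = d2[, 2], d2z = d2[, 3], tof_offset = off)
  }
  events <- dplyr::bind_rows(parts)
  if (nrow(events) == 0) events <- empty
  events <- dplyr::arrange(events, .data$t_ms)
  header$n_events <- nrow(events)
  new_listmode(events, header)
}

#' TOF-estimated annihilation position of each event
#'
#' The midpoint of the LOR plus the signed TOF offset along the unit vector
#' from detector 1 toward detector 2.
#'
#' @param events an `rmc_listmode` or its event tibble.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
tof_position <- function(events) {
  ev <- if (inherits(events, "rmc_listmode")) events$events else events
  d1 <- cbind(ev$d1x, ev$d1y, ev$d1z)
  d2 <- cbind(ev$d2x, ev$d2y, ev$d2z)
  d <- d2 - d1
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0)) stop("degenerate LOR: det1 equals det2")
  (d1 + d2) / 2 + d / len * ev$tof_offset
}

LM_MAGIC <- charToRaw("ULM1")

listmode_header_json <- function(lm) {
  h <- lm$header
  h$scanner <- unclass(h$scanner)
  h$record_layout <- list(
    fields = c("t_ms:int32", "d1x:float64", "d1y:float64", "d1z:float64",
               "d2x:float64", "d2y:float64", "d2z:float64",
               "tof_offset:float64"),
    record_bytes = 60L, endian = "little")
  jsonlite::toJSON(h, auto_unbox = TRUE, digits = NA)
}

parse_listmode_header <- function(txt) {
  h <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  h$scanner <- do.call(scanner_geometry, as.list(h$scanner))
  if (!is.null(h$grid)) h$grid <- lapply(h$grid, as.numeric)
  if (!is.null(h$grid$dim)) h$grid$dim <- as.integer(h$grid$dim)
  h
}

#' Write / read a list-mode set
#'
#' Binary format: 4-byte magic `ULM1`, a little-endian int32 header length, a
#' JSON header (scanner geometry, duration, subject metadata, record layout,
#' TOF sign convention), then fixed-width 60-byte records (int32 `t_ms` + 7
#' little-endian float64 fields). Round trips are bit exact. A CSV debug
#' dialect (`format = "csv"`) stores the header as a single `#`-prefixed JSON
#' comment line followed by 8 numeric columns.
#'
#' @param lm an `rmc_listmode`.
#' @param path file path.
#' @param format `"binary"` or `"csv"`.
#' @return `write_listmode` returns `path` invisibly; `read_listmode` an
#'   `rmc_listmode`.
#' @export
write_listmode <- function(lm, path, format = c("binary", "csv")) {
  format <- match.arg(format)
  ev <- lm$events
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", listmode_header_json(lm)), con)
    utils::write.csv(ev, con, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(as.character(listmode_header_json(lm)))
  writeBin(LM_MAGIC, con)
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  if (nrow(ev) > 0) {
    m <- t(as.matrix(ev[, c("d1x", "d1y", "d1z", "d2x", "d2y", "d2z",
                            "tof_offset")]))
    raw_t <- writeBin(as.integer(ev$t_ms), raw(), size = 4L, endian = "little")
    raw_d <- writeBin(as.numeric(m), raw(), size = 8L, endian = "little")
    rec <- raw(60L * nrow(ev))
    ti <- rep(seq_len(4L), nrow(ev)) +
      rep((seq_len(nrow(ev)) - 1L) * 60L, each = 4L)
    rec[ti] <- raw_t
    di <- rep(seq_len(56L) + 4L, nrow(ev)) +
      rep((seq_len(nrow(ev)) - 1L) * 60L, each = 56L)
    rec[di] <- raw_d
    writeBin(rec, con)
  }
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path, format = c("binary", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    if (!startsWith(lines[1], "# "))
      stop("malformed CSV list-mode header: missing '# ' JSON line")
    header <- parse_listmode_header(sub("^# ", "", lines[1]))
    ev <- utils::read.csv(text = lines[-1])
    ev <- tibble::as_tibble(ev)
    ev$t_ms <- as.integer(ev$t_ms)
    return(new_listmode(ev, header))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 4L)
  if (!identical(magic, LM_MAGIC))
    stop("malformed list-mode header at byte offset 0: bad magic")
  hlen <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (length(hlen) == 0 || hlen <= 0)
    stop("malformed list-mode header at byte offset 4: bad header length")
  hraw <- readBin(con, raw(), hlen)
  if (length(hraw) < hlen)
    stop(sprintf("truncated list-mode header at byte offset %d", 8 + length(hraw)))
  header <- parse_listmode_header(rawToChar(hraw))
  body <- readBin(con, raw(), n = file.info(path)$size)
  if (length(body) %% 60L != 0)
    stop(sprintf("truncated list-mode record at byte offset %d",
                 8 + hlen + (length(body) %/% 60L) * 60L))
  n <- length(body) %/% 60L
  if (n == 0) {
    ev <- tibble::tibble(t_ms = integer(), d1x = double(), d1y = double(),
                         d1z = double(), d2x = double(), d2y = double(),
                         d2z = double(), tof_offset = double())
  } else {
    ti <- rep(seq_len(4L), n) + rep((seq_len(n) - 1L) * 60L, each = 4L)
    di <- rep(seq_len(56L) + 4L, n) + rep((seq_len(n) - 1L) * 60L, each = 56L)
    t_ms <- readBin(body[ti], integer(), n, size = 4L, endian = "little")
    dd <- matrix(readBin(body[di], numeric(), n * 7L, size = 8L,
                         endian = "little"), nrow = 7L)
    ev <- tibble::tibble(t_ms = t_ms, d1x = dd[1, ], d1y = dd[2, ],
                         d1z = dd[3, ], d2x = dd[4, ], d2y = dd[5, ],
                         d2z = dd[6, ], tof_offset = dd[7, ])
  }
  if (!is.null(header$n_events) && header$n_events != nrow(ev))
    stop(sprintf("event count mismatch: header says %d, found %d records",
                 header$n_events, nrow(ev)))
  new_listmode(ev, header)
}
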