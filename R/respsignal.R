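mask_volume <- function(vol, mask, tags) {
  new_volume(array(as.integer(mask), dim(vol$data)), vol$spacing, vol$origin,
             tags)
}

shift_mask <- function(m, axis, by) {
  # shift a logical array by `by` voxels along axis, zero-filled
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by >= 0) seq(1 + by, n) else seq_len(n + by)
  ix <- function(sel) switch(axis, `1` = list(sel, TRUE, TRUE),
                             `2` = list(TRUE, sel, TRUE),
                             `3` = list(TRUE, TRUE, sel))
  do.call(`[<-`, c(list(out), ix(dst), list(do.call(`[`, c(list(m), ix(src))))))
}

erode_box <- function(mask, r_vox) {
  out <- mask
  for (axis in 1:3) {
    r <- r_vox[axis]
    if (r < 1) next
    acc <- out
    for (k in seq_len(r)) {
      acc <- acc & shift_mask(out, axis, k) & shift_mask(out, axis, -k)
    }
    out <- acc
  }
  out
}

largest_component <- function(mask) {
  lab <- cpp_label3d(as.integer(mask), dim(mask))
  n <- attr(lab, "n_components")
  if (n == 0) return(array(FALSE, dim(mask)))
  counts <- tabulate(lab, nbins = n)
  array(lab == which.max(counts), dim(mask))
}

#' Rule-based body-cavity segmentation from an attenuation map
#'
#' Stands in for a learned cavity segmenter behind the same interface: the
#' body is the largest connected non-air component of the mu map,
#' hole-filled; the cavity is the body eroded by a configurable rind and
#' restricted to the axial range running from the lung apex down through the
#' abdominopelvic region (a fixed extension below the lung base). Any
#' callable `function(mu_ct, ...) -> mask volume` may replace it in the
#' pipeline via `pipeline_config(cavity_fn = ...)`.
#'
#' @param mu_ct attenuation map `rmc_volume` (1/cm).
#' @param rind_mm erosion rind, mm.
#' @param air_threshold mu below this is air, 1/cm.
#' @param lung_mu_range mu range classified as lung tissue, 1/cm.
#' @param abdominal_extension_mm how far below the lung base the
#'   abdominopelvic range extends, mm.
#' @return binary cavity mask as an `rmc_volume` (0/1), tagged.
#' @export
segment_body_cavity <- function(mu_ct, rind_mm = 15, air_threshold = 0.015,
                                lung_mu_range = c(0.015, 0.06),
                                abdominal_extension_mm = 350) {
  nonair <- mu_ct$data > air_threshold
  if (!any(nonair)) stop("all-air attenuation map: no body to segment")
  body <- largest_component(nonair)
  body <- array(cpp_fill_holes(as.integer(body), dim(body)) > 0, dim(body))
  r_vox <- pmax(0L, floor(rind_mm / mu_ct$spacing))
  cavity <- erode_box(body, r_vox)
  # axial restriction: lung apex down to lung base minus the abdominal extent
  lung <- body & mu_ct$data > lung_mu_range[1] & mu_ct$data < lung_mu_range[2]
  lung_slices <- which(apply(lung, 3, sum) > 20)
  if (length(lung_slices) > 0) {
    zs <- mu_ct$origin[3] + (seq_len(dim(body)[3]) - 1) * mu_ct$spacing[3]
    z_hi <- zs[max(lung_slices)]
    z_lo <- zs[min(lung_slices)] - abdominal_extension_mm
    keep <- zs >= z_lo & zs <= z_hi
    cavity[, , !keep] <- FALSE
  }
  if (!any(cavity)) stop("empty cavity mask after erosion")
  mask_volume(mu_ct, cavity, list(kind = "cavity", rind_mm = rind_mm))
}

#' Respiratory region of interest: dorsoventral dilation of the cavity
#'
#' Extends every cavity voxel anteriorly (+Y) by `floor(dilation_mm /
#' spacing_y)` voxels, clipped to the volume; no other direction is touched.
#' Only events TOF-positioned inside this rROI contribute to the COD signal.
#'
#' @param cavity cavity mask `rmc_volume` from [segment_body_cavity()].
#' @param dilation_mm anterior dilation, mm (default 50).
#' @param direction only `"anterior"` is supported.
#' @return binary rROI `rmc_volume`, tagged with its provenance.
#' @export
build_rroi <- function(cavity, dilation_mm = 50, direction = "anterior") {
  stopifnot(direction == "anterior", dilation_mm >= 0)
  m <- cavity$data > 0
  if (!any(m)) stop("empty cavity mask")
  n <- floor(dilation_mm / cavity$spacing[2])
  out <- m
  for (k in seq_len(n)) out <- out | shift_mask(m, 2L, k)
  mask_volume(cavity, out,
              list(kind = "rroi", cavity = cavity$tags$kind,
                   dilation_mm = dilation_mm, direction = direction))
}

#' Centroid-of-distribution trace from TOF-positioned events
#'
#' At fixed intervals (100 ms by default) the TOF-estimated positions of all
#' events falling inside the rROI are averaged, producing the 3-D COD trace
#' `(C_x, C_y, C_z)`. Bins with no qualifying events are flagged invalid and
#' linearly interpolated.
#'
#' @param listmode an `rmc_listmode`.
#' @param rroi rROI mask `rmc_volume`.
#' @param bin_ms bin width, ms.
#' @return tibble with `bin`, `time_s` (bin centres), `c_x`, `c_y`, `c_z`
#'   (mm), `counts`, `valid`; attributes `bin_ms` and `n_events_rroi`.
#' @export
extract_cod <- function(listmode, rroi, bin_ms = 100) {
  ev <- listmode$events
  if (nrow(ev) == 0) stop("empty list-mode set")
  if (!any(rroi$data > 0)) stop("empty rROI")
  pos <- tof_position(ev)
  memb <- sample_volume(rroi, pos) >= 0.5
  n_bins <- as.integer(ceiling(listmode$header$duration_s * 1000 / bin_ms))
  bin <- pmin(n_bins, ev$t_ms %/% bin_ms + 1L)
  keep <- memb
  if (!any(keep)) stop("no events fall inside the rROI")
  counts <- tabulate(bin[keep], nbins = n_bins)
  sums <- rowsum(pos[keep, , drop = FALSE], bin[keep])
  cod <- matrix(NA_real_, n_bins, 3)
  cod[as.integer(rownames(sums)), ] <- sums / counts[as.integer(rownames(sums))]
  valid <- counts > 0
  if (!any(valid)) stop("all COD bins are empty")
  fill <- function(v) {
    if (all(valid)) return(v)
    approx(which(valid), v[valid], xout = seq_len(n_bins), rule = 2)$y
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    time_s = (seq_len(n_bins) - 0.5) * bin_ms / 1000,
    c_x = fill(cod[, 1]), c_y = fill(cod[, 2]), c_z = fill(cod[, 3]),
    counts = counts, valid = valid)
  attr(out, "bin_ms") <- bin_ms
  attr(out, "n_events_rroi") <- sum(keep)
  out
}

#' Condition the COD trace into a respiratory amplitude signal
#'
#' `C_y` minus a slow baseline (a linear trend plus a zero-phase Butterworth
#' low-pass with cutoff `1 / baseline_window_s`, removing tracer-kinetic and
#' positional drift without distorting the respiratory band), then a
#' zero-phase Butterworth low-pass confined to the physiological respiratory
#' band, median-centred, and oriented so that larger amplitude means more
#' inspiration (anterior chest displacement increases `C_y`; the polarity
#' convention is recorded and downstream equal-count gating depends only on
#' amplitude ordering).
#'
#' @param trace COD tibble from [extract_cod()] (needs `time_s`, `c_y`;
#'   `counts`/`valid` used when present).
#' @param baseline_window_s baseline timescale, s; drifts slower than this
#'   are removed.
#' @param lowpass_hz Butterworth low-pass cutoff, Hz (0 disables; the
#'   default passes all physiological breathing rates).
#' @param filter_order Butterworth order.
#' @param min_variance minimum signal variance, mm^2; below it the trace is
#'   rejected as containing no respiratory signal.
#' @param polarity `+1` or `-1` sign convention.
#' @param min_duration_s minimum valid signal span required, s.
#' @return tibble `time_s`, `amplitude` (mm), `counts`, `valid`; attributes
#'   `polarity` and `bin_s`.
#' @export
condition_signal <- function(trace, baseline_window_s = 30, lowpass_hz = 0.6,
                             filter_order = 3, min_variance = 0.01,
                             polarity = 1, min_duration_s = 30) {
  stopifnot(all(c("time_s", "c_y") %in% names(trace)))
  y <- trace$c_y
  n <- length(y)
  valid <- if ("valid" %in% names(trace)) trace$valid else rep(TRUE, n)
  bin_s <- if (n > 1) trace$time_s[2] - trace$time_s[1] else 1
  if (sum(valid) * bin_s < min_duration_s)
    stop(sprintf("need at least %g s of valid signal", min_duration_s))
  nyq <- 1 / (2 * bin_s)
  trend <- stats::fitted(stats::lm(y ~ trace$time_s))
  base_hz <- 1.5 / baseline_window_s
  baseline <- trend
  if (base_hz < nyq && n > 20) {
    bl <- signal::butter(2, base_hz / nyq)
    baseline <- trend + as.numeric(signal::filtfilt(bl, y - trend))
  }
  sig <- y - baseline
  if (lowpass_hz > 0 && lowpass_hz < nyq) {
    bf <- signal::butter(filter_order, lowpass_hz / nyq)
    sig <- as.numeric(signal::filtfilt(bf, sig))
  }
  sig <- sig - median(sig)
  if (stats::var(sig) < min_variance)
    stop("no respiratory signal detected (variance below threshold)")
  out <- tibble::tibble(time_s = trace$time_s, amplitude = polarity * sig,
                        counts = if ("counts" %in% names(trace)) trace$counts
                                 else rep(1L, n),
                        valid = valid)
  attr(out, "polarity") <- polarity
  attr(out, "bin_s") <- bin_s
  out
}

#' Periodogram peak frequency of a conditioned signal
#'
#' @param signal conditioned signal tibble (or numeric vector with `bin_s`).
#' @param bin_s sampling interval, s (taken from the tibble when omitted).
#' @return list with `freq_hz` (peak frequency) and `freq_resolution_hz`.
#' @export
signal_peak_frequency <- function(signal, bin_s = NULL) {
  x <- if (is.numeric(signal)) signal else signal$amplitude
  if (is.null(bin_s)) bin_s <- attr(signal, "bin_s")
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) / (n * bin_s)
  half <- 2:floor(n / 2)
  list(freq_hz = freqs[half][which.max(sp[half])],
       freq_resolution_hz = 1 / (n * bin_s))
}

#' Plot a COD trace or conditioned respiratory signal
#'
#' @param x tibble from [extract_cod()] or [condition_signal()].
#' @param component which COD component(s) to show for a raw trace.
#' @return a ggplot object.
#' @export
plot_respiratory_signal <- function(x, component = c("c_y", "c_x", "c_z")) {
  if ("amplitude" %in% names(x)) {
    return(ggplot2::ggplot(x, ggplot2::aes(.data$time_s, .data$amplitude)) +
             ggplot2::geom_line(colour = "steelblue") +
             ggplot2::labs(x = "time (s)", y = "respiratory amplitude (mm)") +
             ggplot2::theme_minimal())
  }
  component <- intersect(component, names(x))
  long <- tidyr::pivot_longer(x[, c("time_s", component)],
                              cols = dplyr::all_of(component),
                              names_to = "component", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$mm,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "COD (mm)") +
    ggplot2::theme_minimal()
}
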