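#' Standardised uptake value image
#'
#' Body-weight SUV: activity concentration (Bq/mL) times body weight (g)
#' over the injected dose (Bq), the dose decay-corrected to scan start using
#' the tracer half-life and the uptake delay (disable with
#' `decay_correct = FALSE`).
#'
#' @param emission calibrated emission `rmc_volume` (Bq/mL).
#' @param meta a [subject_meta()].
#' @param decay_correct decay-correct the dose to scan start.
#' @return SUV `rmc_volume` (unitless).
#' @export
suv_image <- function(emission, meta, decay_correct = TRUE) {
  if (meta$weight_kg <= 0 || meta$injected_dose_mbq <= 0)
    stop("weight and injected dose must be positive")
  dose_bq <- meta$injected_dose_mbq * 1e6
  if (decay_correct)
    dose_bq <- dose_bq * 2^(-meta$uptake_delay_min / meta$half_life_min)
  out <- vol_like(emission, emission$data * (meta$weight_kg * 1000) / dose_bq)
  out$tags$kind <- "suv"
  out
}

#' Lesion size category from volume
#'
#' Small: 0.1 < v <= 5 mL; medium: 5 < v <= 10 mL; large: v > 10 mL;
#' v <= 0.1 mL is below the analysis floor and excluded. The shared 5.0-mL
#' endpoint is closed on the small side.
#'
#' @param volume_ml lesion volume(s), mL.
#' @return factor with levels `excluded`, `small`, `medium`, `large`.
#' @export
categorize_lesion <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("lesion volume cannot be negative")
  cut(volume_ml, breaks = c(-Inf, 0.1, 5, 10, Inf),
      labels = c("excluded", "small", "medium", "large"), right = TRUE)
}

#' SUV statistics within a lesion ROI
#'
#' @param suv_volume SUV `rmc_volume`.
#' @param roi logical array (or 0/1 `rmc_volume`) on the same grid.
#' @return tibble with `suv_max`, `suv_mean`, `volume_ml`, `category`.
#' @export
lesion_stats <- function(suv_volume, roi) {
  m <- if (inherits(roi, "rmc_volume")) roi$data > 0 else roi
  if (!any(m)) stop("empty lesion ROI")
  vals <- suv_volume$data[m]
  vol_ml <- sum(m) * voxel_volume_ml(suv_volume)
  tibble::tibble(suv_max = max(vals), suv_mean = mean(vals),
                 volume_ml = vol_ml, category = categorize_lesion(vol_ml))
}

#' Two-sided paired t-test
#'
#' Thin, edge-case-hardened surface over [stats::t.test()]: all-zero
#' differences give `t = 0, p = 1`; zero-variance differences with nonzero
#' mean give `t = +-Inf, p = 0`.
#'
#' @param x,y paired numeric vectors (by lesion), length `>= 2`.
#' @return tibble with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(tibble::tibble(t = 0, p = 1, df = n - 1, mean_diff = 0))
    return(tibble::tibble(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                          mean_diff = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Per-organ respiratory motion amplitude
#'
#' Organ ROIs delineated in CT space are resliced into the reference-gate
#' frame using the inverse of the PET-CT alignment field; within each
#' deformed organ the amplitude is the maximum magnitude of the
#' inspiration-expiration displacement field (the registration field between
#' the extreme respiratory gates). One value per organ per subject.
#'
#' @param organ_masks_ct named list of logical arrays or 0/1 `rmc_volume`s in
#'   CT space.
#' @param alignment_field the PET-CT alignment `rmc_field` (fixed = CT,
#'   moving = reference gate).
#' @param gate_field_extremes `rmc_field` between the extreme gates
#'   (end-expiration vs end-inspiration).
#' @param subject optional subject label recorded in the output.
#' @return tibble with `organ`, `amplitude_mm`, `n_voxels` (organs whose
#'   deformed mask is empty are skipped with a warning).
#' @export
organ_motion_amplitude <- function(organ_masks_ct, alignment_field,
                                   gate_field_extremes, subject = NA) {
  inv <- invert_field(alignment_field)
  grid <- alignment_field$dx
  mag <- field_magnitude(gate_field_extremes)
  rows <- purrr::map(names(organ_masks_ct), function(org) {
    m <- organ_masks_ct[[org]]
    md <- if (inherits(m, "rmc_volume")) m$data else m
    mv <- new_volume(array(as.numeric(md), dim(md)), grid$spacing, grid$origin)
    deformed <- warp_image(mv, inv)$data >= 0.5
    if (!any(deformed)) {
      warning(sprintf("organ '%s': empty mask after deformation, skipped", org))
      return(NULL)
    }
    tibble::tibble(subject = subject, organ = org,
                   amplitude_mm = max(mag[deformed]),
                   n_voxels = sum(deformed))
  })
  dplyr::bind_rows(rows)
}

#' Cohort mean and SD of per-subject organ amplitudes
#'
#' Per organ: the per-subject maxima averaged across subjects, with the
#' sample SD (reported as 0 with `single_subject = TRUE` when only one
#' subject contributes).
#'
#' @param per_subject tibble with columns `organ` and `amplitude_mm` (one row
#'   per organ per subject).
#' @return tibble with `organ`, `mean_mm`, `sd_mm`, `n`, `single_subject`.
#' @export
cohort_average <- function(per_subject) {
  if (is.null(per_subject) || nrow(per_subject) == 0)
    stop("no per-subject amplitudes supplied")
  per_subject |>
    dplyr::group_by(.data$organ) |>
    dplyr::summarise(mean_mm = mean(.data$amplitude_mm),
                     sd_mm = ifelse(dplyr::n() > 1, sd(.data$amplitude_mm), 0),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(single_subject = .data$n == 1)
}

#' Threshold-based lesion segmentation surrogate
#'
#' Segments a lesion as the connected component, containing the hottest
#' voxel of a search region, of voxels above a fixed fraction (41% by
#' default) of that local maximum.
#'
#' @param suv_volume SUV `rmc_volume`.
#' @param search_mask logical array restricting the search.
#' @param frac threshold fraction of the local SUV maximum.
#' @return logical array lesion mask.
#' @export
segment_lesion_threshold <- function(suv_volume, search_mask, frac = 0.41) {
  v <- suv_volume$data
  if (!any(search_mask)) stop("empty search mask")
  peak <- max(v[search_mask])
  above <- v >= frac * peak
  lab <- cpp_label3d(as.integer(above), dim(v))
  peak_idx <- which(v == peak & search_mask)[1]
  array(lab == lab[peak_idx], dim(v))
}

#' Axial full width at half maximum of a lesion profile
#'
#' Averages the axial (Z) intensity profiles over the lesion ROI's in-plane
#' footprint (robust against single-column noise at desk-scale counts),
#' subtracts the within-window background (25th percentile) and measures the
#' width at half the background-corrected peak by linear interpolation.
#'
#' @param image `rmc_volume`.
#' @param roi logical array locating the lesion.
#' @param window_mm half-length of the profile window, mm.
#' @return FWHM in mm (`NA` if no half crossing lies inside the window).
#' @export
axial_fwhm <- function(image, roi, window_mm = 48) {
  m <- if (inherits(roi, "rmc_volume")) roi$data > 0 else roi
  idx <- which(m, arr.ind = TRUE)
  fp <- unique(idx[, 1:2, drop = FALSE])
  kc <- round(mean(idx[, 3]))
  d <- dim(image$data)
  nwin <- round(window_mm / image$spacing[3])
  ks <- max(1, kc - nwin):min(d[3], kc + nwin)
  prof <- rep(0, length(ks))
  for (r in seq_len(nrow(fp)))
    prof <- prof + image$data[fp[r, 1], fp[r, 2], ks]
  prof <- prof / nrow(fp)
  bg <- as.numeric(quantile(prof, 0.25))
  pk_i <- which.max(prof)
  half <- bg + (prof[pk_i] - bg) / 2
  cross <- function(seq_idx) {
    for (i in seq_idx) {
      j <- i + 1
      if ((prof[i] - half) * (prof[j] - half) <= 0 && prof[i] != prof[j])
        return(i + (half - prof[i]) / (prof[j] - prof[i]))
    }
    NA_real_
  }
  left <- cross(rev(seq_len(pk_i - 1)))
  right <- cross(pk_i:(length(prof) - 1))
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * image$spacing[3]
}
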