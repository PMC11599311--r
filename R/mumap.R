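#' Rule-based per-gate attenuation map from a NAC reconstruction
#'
#' Deterministic surrogate standing in for a learned estimator behind the
#' same interface: the body outline is taken from the gated NAC image
#' (threshold at a fraction of its robust maximum, largest component,
#' hole-filled) and assigned soft-tissue mu; connected low-activity regions
#' in the eroded thoracic interior larger than a volume threshold are
#' assigned lung mu; everything outside the body is 0. The output is aligned
#' to the NAC image by construction. Thresholds were tuned on the bundled
#' phantom (NAC images suppress deep tissue, so the lung search is
#' restricted axially); any callable `function(lambda_nac, gate_phase) ->
#' rmc_volume` can replace the surrogate in the pipeline via
#' `pipeline_config(mu_estimator = ...)`.
#'
#' @param lambda_nac gated NAC emission `rmc_volume` (non-negative).
#' @param soft_mu,lung_mu tissue attenuation values, 1/cm at 511 keV.
#' @param threshold_frac body threshold as a fraction of the robust maximum.
#' @param robust_q quantile used as the robust maximum.
#' @param lung_min_ml minimum volume of an interior low-activity component to
#'   be called lung, mL.
#' @param lung_frac low-activity threshold as a fraction of the median body
#'   activity.
#' @param lung_z_min_mm lungs are searched only above this axial position.
#' @param interior_erode_mm erosion of the body before the lung search, mm.
#' @param smooth_mm pre-smoothing of the NAC image, mm (0 if the input is
#'   already heavily filtered).
#' @return attenuation `rmc_volume` with values in `{0, lung_mu, soft_mu}`,
#'   tagged `source = "surrogate"`.
#' @export
estimate_mu_surrogate <- function(lambda_nac, soft_mu = 0.096, lung_mu = 0.03,
                                  threshold_frac = 0.2, robust_q = 0.99,
                                  lung_min_ml = 50, lung_frac = 0.65,
                                  lung_z_min_mm = -60, interior_erode_mm = 8,
                                  smooth_mm = 4) {
  vals <- lambda_nac$data
  if (!any(vals > 0)) stop("empty NAC image: cannot estimate a mu map")
  sm <- if (smooth_mm > 0) smooth_volume(lambda_nac, smooth_mm) else lambda_nac
  rmax <- as.numeric(quantile(sm$data[sm$data > 0], robust_q))
  body <- sm$data > threshold_frac * rmax
  body <- largest_component(body)
  body <- array(cpp_fill_holes(as.integer(body), dim(body)) > 0, dim(body))
  if (!any(body)) stop("empty body mask")
  med <- median(sm$data[body])
  interior <- erode_box(body, pmax(1L, floor(interior_erode_mm /
                                               lambda_nac$spacing)))
  d <- dim(body)
  zs <- lambda_nac$origin[3] + (seq_len(d[3]) - 1) * lambda_nac$spacing[3]
  zmask <- array(rep(zs > lung_z_min_mm, each = d[1] * d[2]), d)
  low <- interior & zmask & sm$data < lung_frac * med
  lab <- cpp_label3d(as.integer(low), dim(low))
  ncomp <- attr(lab, "n_components")
  mu <- array(0, dim(vals))
  mu[body] <- soft_mu
  if (ncomp > 0) {
    sizes <- tabulate(lab, nbins = ncomp) * voxel_volume_ml(lambda_nac)
    keep <- which(sizes >= lung_min_ml)
    if (length(keep)) mu[array(lab, dim(low)) %in% keep] <- lung_mu
  }
  new_volume(mu, lambda_nac$spacing, lambda_nac$origin,
             list(kind = "mu", source = "surrogate",
                  gate = lambda_nac$tags$gate))
}

#' Ground-truth per-gate attenuation map from the phantom
#'
#' Renders the phantom's true mu at a given phase (typically a gate's mean
#' programmed phase), enabling isolation tests of downstream stages from
#' mu-estimation error.
#'
#' @param phantom an `rmc_phantom`.
#' @param gate_phase phase in `[0,1]`.
#' @return attenuation `rmc_volume` tagged `source = "oracle"`.
#' @export
oracle_mu <- function(phantom, gate_phase) {
  v <- render_ct(phantom, gate_phase)
  v$tags$source <- "oracle"
  v
}

#' Piecewise-linear CT number to 511-keV mu conversion
#'
#' Standard bilinear HU conversion for external CT input: water-like slope
#' below 0 HU, bone-like slope above.
#'
#' @param hu `rmc_volume` (or array) of CT numbers.
#' @param mu_water water mu at 511 keV, 1/cm.
#' @param bone_slope slope above 0 HU, 1/cm per 1000 HU.
#' @return attenuation `rmc_volume` (1/cm), clipped at 0.
#' @export
hu_to_mu <- function(hu, mu_water = 0.096, bone_slope = 0.0425) {
  v <- if (inherits(hu, "rmc_volume")) hu$data else hu
  mu <- ifelse(v <= 0, mu_water * (1 + v / 1000),
               mu_water + bone_slope * v / 1000)
  mu <- pmax(mu, 0)
  if (inherits(hu, "rmc_volume")) {
    out <- vol_like(hu, mu, tags = list(kind = "mu", source = "CT"))
    out
  } else mu
}
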