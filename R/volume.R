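#' Lightweight 3-D volume container
#'
#' `rmc_volume` wraps a numeric 3-D array with voxel spacing (mm) and the
#' world origin (mm from the scanner field-of-view centre) of the centre of
#' voxel `[1,1,1]`. Axes follow the patient convention used throughout the
#' package: X lateral, Y anterior-posterior (+Y anterior), Z superior-inferior
#' (+Z superior). Arrays are stored `dim = c(nx, ny, nz)`.
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world position (mm) of voxel `[1,1,1]`.
#'   Defaults to centring the grid on the FOV centre.
#' @param tags named list of free-form provenance tags (gate index, AC/NAC,
#'   source, ...).
#' @return an `rmc_volume` object.
#' @export
new_volume <- function(data, spacing, origin = NULL, tags = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), tags = tags),
            class = "rmc_volume")
}

#' @export
dim.rmc_volume <- function(x) dim(x$data)

#' @export
print.rmc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rmc_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (length(x$tags)) {
    tg <- vapply(x$tags, function(t) paste(format(t), collapse = ","), "")
    cat("  tags:", paste(names(tg), tg, sep = "=", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

vol_like <- function(vol, data, tags = vol$tags) {
  new_volume(array(data, dim(vol$data)), vol$spacing, vol$origin, tags)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of every voxel centre
#'
#' @param vol an `rmc_volume`.
#' @return list of arrays `x`, `y`, `z` (mm), each shaped like the volume.
#' @export
voxel_coords <- function(vol) {
  d <- dim(vol$data)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  list(x = array(rep(xs, times = d[2] * d[3]), d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Sample a volume at arbitrary world coordinates (trilinear)
#'
#' @param vol an `rmc_volume`.
#' @param coords n x 3 matrix of world mm coordinates.
#' @return numeric vector of length n; 0 outside the grid.
#' @export
sample_volume <- function(vol, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  cpp_sample_world(as.numeric(vol$data), dim(vol$data), vol$spacing,
                   vol$origin, coords)
}

#' Resample a volume onto another volume's grid
#'
#' @param vol volume to resample.
#' @param target `rmc_volume` defining the output grid (values ignored).
#' @return `rmc_volume` on the target grid.
#' @export
resample_volume <- function(vol, target) {
  out <- cpp_resample_grid(as.numeric(vol$data), dim(vol$data), vol$spacing,
                           vol$origin, dim(target$data), target$spacing,
                           target$origin)
  new_volume(array(out, dim(target$data)), target$spacing, target$origin,
             vol$tags)
}

#' Write / read a volume as NIfTI
#'
#' The affine encodes the mm-from-FOV-centre world convention (diagonal
#' spacing, translation = origin).
#'
#' @param vol an `rmc_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `rmc_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  new_volume(array(as.numeric(img), dim(img)[1:3]),
             spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4])
}

#' Gaussian smoothing of a volume
#'
#' @param vol an `rmc_volume`.
#' @param sigma_mm Gaussian sigma in mm (scalar or length-3).
#' @return smoothed `rmc_volume`.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  sigma_vox <- rep(sigma_mm, length.out = 3) / vol$spacing
  out <- cpp_gauss_smooth(as.numeric(vol$data), dim(vol$data), sigma_vox)
  vol_like(vol, out)
}

#' Plot an axial/coronal/sagittal slice of a volume
#'
#' @param object an `rmc_volume`.
#' @param plane one of "coronal", "axial", "sagittal".
#' @param index slice index (defaults to the mid-slice).
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.rmc_volume <- function(object, plane = c("coronal", "axial", "sagittal"),
                                index = NULL, ...) {
  plane <- match.arg(plane)
  d <- dim(object$data)
  ax <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  if (is.null(index)) index <- ceiling(d[ax] / 2)
  sl <- switch(plane,
               sagittal = object$data[index, , ],
               coronal  = object$data[, index, ],
               axial    = object$data[, , index])
  df <- tibble::tibble(
    h = rep(seq_len(nrow(sl)), times = ncol(sl)),
    v = rep(seq_len(ncol(sl)), each = nrow(sl)),
    value = as.numeric(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$h, .data$v, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s slice %d", plane, index),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
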