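#' In-memory 3-D image volume
#'
#' Minimal container for the normalisation contracts: a 3-D intensity array,
#' per-axis voxel spacing in mm, and an optional binary brain mask of the
#' same shape. Voxel centres sit at `(i - 0.5) * spacing` (corner-aligned,
#' half-open extent).
#'
#' @param data 3-D numeric array.
#' @param spacing positive numeric length 3 (mm per axis).
#' @param mask optional logical/0-1 array of identical shape.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_radboot("voxel spacing must be three positive values", "radboot_config")
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(data)))
    mask <- array(as.logical(mask), dim(data))
  }
  structure(list(data = data, spacing = spacing, mask = mask),
            class = "image_volume")
}

#' Z-score intensity normalisation at three standard deviations
#'
#' Standardises the entire scan by the mean and standard deviation of the
#' in-mask (brain) voxels, then clips the result to `[-3, 3]`. The unclipped
#' variant is available with `clip = Inf`.
#'
#' @param vol an [image_volume()]; a mask is required (use a full-volume mask
#'   to normalise by the whole scan).
#' @param clip clip bound in standard deviations; default 3.
#' @return A normalised `image_volume`.
#' @export
zscore_normalize <- function(vol, clip = 3) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(vol$mask) || !any(vol$mask))
    stop_radboot("z-score normalisation needs a non-empty mask",
                 "radboot_degenerate")
  v <- vol$data[vol$mask]
  mu <- mean(v)
  sigma <- sd(v)
  if (!is.finite(sigma) || sigma == 0)
    stop_radboot("in-mask intensities are constant (zero variance)",
                 "radboot_degenerate")
  z <- (vol$data - mu) / sigma
  if (is.finite(clip)) z <- pmin(pmax(z, -clip), clip)
  image_volume(array(z, dim(vol$data)), vol$spacing, vol$mask)
}

#' Trilinear resampling to an isotropic grid
#'
#' Resamples onto an axis-aligned grid at `target_spacing_mm` covering the
#' original extent, with the output origin anchored at the input origin
#' (corner alignment). Values are trilinearly interpolated between voxel
#' centres; positions beyond the first/last centre clamp to the edge value,
#' so there is no extrapolation outside the input range. The mask, when
#' present, is resampled by nearest neighbour.
#'
#' @param vol an [image_volume()].
#' @param target_spacing_mm positive scalar (or length-3) target spacing.
#' @return A resampled `image_volume`.
#' @export
resample_isotropic <- function(vol, target_spacing_mm = 0.5) {
  stopifnot(inherits(vol, "image_volume"))
  ts <- as.numeric(target_spacing_mm)
  if (length(ts) == 1) ts <- rep(ts, 3)
  if (any(!is.finite(ts)) || any(ts <= 0))
    stop_radboot("target spacing must be positive", "radboot_config")
  d <- dim(vol$data)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / ts - 1e-9)))

  # fractional index (1-based, voxel-centre convention) of each output centre
  # along each axis, clamped to [1, d] so edges are clamped, not extrapolated
  ax_idx <- lapply(1:3, function(a) {
    centers <- ((seq_len(nd[a]) - 0.5) * ts[a])
    pmin(pmax(centers / vol$spacing[a] + 0.5, 1), d[a])
  })
  lo <- lapply(1:3, function(a) pmax(1L, as.integer(floor(ax_idx[[a]] + 1e-12))))
  lo <- lapply(1:3, function(a) pmin(lo[[a]], max(1L, d[a] - 1L)))
  fr <- lapply(1:3, function(a) {
    f <- ax_idx[[a]] - lo[[a]]
    if (d[a] == 1L) f[] <- 0
    pmin(pmax(f, 0), 1)
  })

  ix <- lo[[1]]; fx <- fr[[1]]
  iy <- lo[[2]]; fy <- fr[[2]]
  iz <- lo[[3]]; fz <- fr[[3]]
  x1 <- pmin(ix + 1L, d[1]); y1 <- pmin(iy + 1L, d[2]); z1 <- pmin(iz + 1L, d[3])

  g <- expand.grid(x = seq_along(ix), y = seq_along(iy), z = seq_along(iz))
  at <- function(xi, yi, zi) vol$data[cbind(xi[g$x], yi[g$y], zi[g$z])]
  wx <- fx[g$x]; wy <- fy[g$y]; wz <- fz[g$z]
  vals <-
    at(ix, iy, iz) * (1 - wx) * (1 - wy) * (1 - wz) +
    at(x1, iy, iz) * wx       * (1 - wy) * (1 - wz) +
    at(ix, y1, iz) * (1 - wx) * wy       * (1 - wz) +
    at(x1, y1, iz) * wx       * wy       * (1 - wz) +
    at(ix, iy, z1) * (1 - wx) * (1 - wy) * wz +
    at(x1, iy, z1) * wx       * (1 - wy) * wz +
    at(ix, y1, z1) * (1 - wx) * wy       * wz +
    at(x1, y1, z1) * wx       * wy       * wz
  out <- array(vals, nd)

  mask_out <- NULL
  if (!is.null(vol$mask)) {
    nn <- lapply(1:3, function(a) pmin(pmax(round(ax_idx[[a]]), 1L), d[a]))
    mask_out <- array(vol$mask[cbind(nn[[1]][g$x], nn[[2]][g$y], nn[[3]][g$z])], nd)
  }
  image_volume(out, ts, mask_out)
}

#' Fixed-bin-count intensity discretisation
#'
#' Equal-width binning over `[min, max]` of the supplied values (fixed bin
#' count, not fixed bin width), as used for texture-feature gray levels.
#' The maximum value is assigned to the top bin; indices run from 1 to
#' `n_bins`. Constant input collapses to a single bin with a warning.
#'
#' @param values numeric vector (a region of interest's intensities).
#' @param n_bins number of bins, default 64.
#' @return Integer vector of bin indices in `[1, n_bins]`.
#' @export
discretize_fixed_bins <- function(values, n_bins = 64) {
  stopifnot(n_bins >= 2)
  if (!any(is.finite(values)))
    stop_radboot("no finite values to discretise", "radboot_degenerate")
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (hi == lo) {
    warning("constant input: all values assigned to bin 1")
    return(rep(1L, length(values)))
  }
  idx <- floor((values - lo) / (hi - lo) * n_bins) + 1L
  pmin(as.integer(idx), as.integer(n_bins))
}
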