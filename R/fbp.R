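# frequency-domain Ram-Lak ramp, |omega| in cycles per length unit, on an
# FFT grid zero-padded to the next power of two >= 2 * n; no apodization
.ramp_profile <- function(n, dr) {
  p <- 2^ceiling(log2(2 * n))
  k <- c(0:(p / 2), (p / 2 - 1):1)
  list(n_pad = p, h = k / (p * dr))
}

# ramp-filter each view (row) of a sinogram value matrix
.filter_views <- function(values, dr) {
  n <- ncol(values)
  rp <- .ramp_profile(n, dr)
  pad <- matrix(0, nrow(values), rp$n_pad)
  pad[, seq_len(n)] <- values
  ft <- t(apply(pad, 1, stats::fft))
  ft <- sweep(ft, 2, rp$h, `*`)
  filt <- t(apply(ft, 1, function(z) Re(stats::fft(z, inverse = TRUE)))) /
    rp$n_pad
  filt[, seq_len(n), drop = FALSE]
}

# linear interpolation of one filtered view at arbitrary radial positions,
# zero outside the detector
.interp_view <- function(q, offsets, r) {
  dr <- offsets[2] - offsets[1]
  pos <- (r - offsets[1]) / dr + 1
  lo <- floor(pos)
  w <- pos - lo
  v <- numeric(length(r))
  ok <- lo >= 1 & lo < length(q)
  v[ok] <- q[lo[ok]] * (1 - w[ok]) + q[lo[ok] + 1] * w[ok]
  edge <- lo == length(q) & w < 1e-12
  v[edge] <- q[length(q)]
  v
}

# backproject filtered views onto arbitrary (x, y) points
.backproject <- function(filt, geom, x, y) {
  angles <- geom_angles(geom)
  offsets <- geom_offsets(geom)
  acc <- numeric(length(x))
  for (a in seq_along(angles)) {
    r <- x * cos(angles[a]) + y * sin(angles[a])
    acc <- acc + .interp_view(filt[a, ], offsets, r)
  }
  # pi/N_theta both for a 180-degree span (delta-theta weight) and for the
  # redundant 360-degree span (delta-theta / 2)
  wt <- (geom$angle_range * pi / 180) / geom$n_angles *
    min(1, 180 / geom$angle_range)
  acc * wt
}

#' Filtered backprojection reconstruction
#'
#' Classical direct reconstruction: each view is ramp-filtered (frequency
#' domain Ram-Lak, zero-padded to at least twice the radial length, no
#' apodization window) and backprojected with linear interpolation onto the
#' pixel centers of the target grid. Serves as the reference reconstructor
#' and as the generator of intermediate training labels.
#'
#' @param sino A [sinogram()].
#' @param grid An [image_grid()] defining the output raster; its fov should
#'   match the sinogram geometry.
#' @return An [image_grid()] holding the reconstruction.
#' @export
fbp_reconstruct <- function(sino, grid) {
  stopifnot(inherits(sino, "sinogram"), inherits(grid, "image_grid"))
  geom <- sino$geom
  filt <- .filter_views(sino$values, geom$fov / geom$n_channels)
  ctr <- grid_centers(grid)
  xy <- expand.grid(y = ctr$y, x = ctr$x)   # column-major: y fastest
  vals <- .backproject(filt, geom, xy$x, xy$y)
  image_grid(grid$n_x, grid$n_y, grid$fov,
             values = matrix(vals, grid$n_y, grid$n_x))
}

#' Filtered backprojection onto an anisotropic stage grid
#'
#' Evaluates the full-data FBP reconstruction on the `N_t x N_r` grid of one
#' stage angle: the grid axes are the radial (`r`) and depth (`t`) directions
#' of the frame rotated by the stage angle, with radial spacing `fov / N_r`
#' and depth spacing `alpha`. Each anisotropic voxel value is the mean of the
#' FBP image over the voxel's depth extent (sub-sampled along `t`), which
#' makes it the training label for the partial line integrals (stored as mean
#' attenuation) of that stage and angle. With pixel-sized depth bins and
#' stage angle zero this reduces to `fbp_reconstruct` on the isotropic grid.
#'
#' @param sino A [sinogram()] (full data, all measured angles).
#' @param stage A [stage_spec()].
#' @param angle_index Which stage angle to reconstruct for (1-based,
#'   `<= stage$n_theta`).
#' @return A numeric `N_t x N_r` matrix (rows = depth bins, columns = radial
#'   bins) of mean attenuation values.
#' @export
fbp_anisotropic <- function(sino, stage, angle_index) {
  stopifnot(inherits(sino, "sinogram"), inherits(stage, "stage_spec"))
  if (angle_index < 1 || angle_index > stage$n_theta) {
    stop("fbp_anisotropic: angle_index out of range")
  }
  geom <- sino$geom
  filt <- .filter_views(sino$values, geom$fov / geom$n_channels)
  th <- stage_angles(stage)[angle_index]
  rr <- stage_offsets(stage)
  tt <- stage_depths(stage)
  dpix <- stage$fov / stage$n_r
  n_sub <- max(1L, min(8L, as.integer(round(stage$alpha / dpix))))
  sub <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5) * stage$alpha

  er <- c(cos(th), sin(th))
  et <- c(-sin(th), cos(th))
  acc <- matrix(0, stage$n_t, stage$n_r)
  grd <- expand.grid(t = tt, r = rr)          # t fastest: column-major N_t x N_r
  for (m in seq_len(n_sub)) {
    x <- grd$r * er[1] + (grd$t + sub[m]) * et[1]
    y <- grd$r * er[2] + (grd$t + sub[m]) * et[2]
    acc <- acc + matrix(.backproject(filt, geom, x, y), stage$n_t, stage$n_r)
  }
  acc / n_sub
}
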