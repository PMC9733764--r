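#' Image grid
#'
#' A square-pixel raster holding the attenuation image `f(x, y)`. The grid
#' covers the field of view `[-fov/2, fov/2]^2`; pixel `(i, j)` (1-based,
#' row `i` = y, column `j` = x) has its center at
#' `(-fov/2 + (j - 0.5) * delta, -fov/2 + (i - 0.5) * delta)` with
#' `delta = fov / n_x`. All grids are half-open: a pixel owns its lower edge.
#'
#' @param n_x,n_y Pixel counts along x (columns) and y (rows). Pixels must be
#'   square, so `fov / n_x == fov / n_y` is required, i.e. `n_x == n_y`
#'   whenever both are given.
#' @param fov Physical side length of the field of view (arbitrary length
#'   unit). Defaults to `n_x`, making the pixel the unit of length.
#' @param values Optional numeric matrix of attenuation values
#'   (`n_y` rows, `n_x` columns); defaults to zeros.
#' @return An object of class `image_grid` with elements `n_x`, `n_y`, `fov`,
#'   and `values`.
#' @examples
#' g <- image_grid(8)
#' pixel_size(g)
#' @export
image_grid <- function(n_x, n_y = n_x, fov = n_x, values = NULL) {
  stopifnot(n_x >= 1, n_y >= 1, fov > 0)
  if (abs(fov / n_x - fov / n_y) > 1e-12 * fov) {
    stop("image_grid: pixels must be square (fov/n_x == fov/n_y)")
  }
  if (is.null(values)) {
    values <- matrix(0, n_y, n_x)
  } else {
    values <- as.matrix(values)
    if (nrow(values) != n_y || ncol(values) != n_x) {
      stop("image_grid: `values` must be an n_y x n_x matrix")
    }
  }
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 fov = as.numeric(fov), values = values),
            class = "image_grid")
}

#' @rdname image_grid
#' @param grid An `image_grid`.
#' @export
pixel_size <- function(grid) grid$fov / grid$n_x

#' Pixel center coordinates of an image grid
#'
#' @param grid An `image_grid`.
#' @return List with numeric vectors `x` (column centers) and `y` (row
#'   centers), both increasing from `-fov/2`.
#' @export
grid_centers <- function(grid) {
  d <- pixel_size(grid)
  list(x = -grid$fov / 2 + (seq_len(grid$n_x) - 0.5) * d,
       y = -grid$fov / 2 + (seq_len(grid$n_y) - 0.5) * d)
}

#' @rawNamespace S3method(print, image_grid)
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, fov = %g (pixel = %g)\n",
              x$n_y, x$n_x, x$fov, pixel_size(x)))
  invisible(x)
}

#' Parallel-beam projection geometry
#'
#' View angles are uniformly spaced over `[0, angle_range)` degrees, measured
#' counter-clockwise from the +x axis. Detector channels are symmetric about
#' the rotation axis: channel `k` (1-based) sits at radial offset
#' `(k - (n_channels + 1)/2) * fov / n_channels`.
#'
#' @param n_channels Number of detector bins `N_r`.
#' @param n_angles Number of view angles `N_theta`.
#' @param fov Field-of-view side length; the channel spacing is
#'   `fov / n_channels`.
#' @param angle_range Angular span in degrees (default 360; 180 also
#'   supported). Parallel-beam data over 360 degrees are redundant but this is
#'   the default acquisition emulated here.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_channels, n_angles, fov = n_channels,
                                angle_range = 360) {
  stopifnot(n_channels >= 1, n_angles >= 1, fov > 0, angle_range > 0)
  structure(list(n_channels = as.integer(n_channels),
                 n_angles = as.integer(n_angles),
                 fov = as.numeric(fov),
                 angle_range = as.numeric(angle_range)),
            class = "projection_geometry")
}

#' View angles and channel offsets of a projection geometry
#'
#' @param geom A `projection_geometry`.
#' @return `geom_angles`: angles in radians; `geom_offsets`: radial channel
#'   centers in length units.
#' @export
geom_angles <- function(geom) {
  (seq_len(geom$n_angles) - 1) / geom$n_angles *
    geom$angle_range * pi / 180
}

#' @rdname geom_angles
#' @export
geom_offsets <- function(geom) {
  d <- geom$fov / geom$n_channels
  (seq_len(geom$n_channels) - (geom$n_channels + 1) / 2) * d
}

#' @rawNamespace S3method(print, projection_geometry)
print.projection_geometry <- function(x, ...) {
  cat(sprintf(
    "<projection_geometry> %d channels x %d angles over %g deg, fov = %g\n",
    x$n_channels, x$n_angles, x$angle_range, x$fov))
  invisible(x)
}

#' Sinogram container
#'
#' Line-integral measurements `p(r, theta)` stored as an
#' `n_angles x n_channels` matrix (rows = view angles, columns = radial
#' channels), in units of attenuation times length.
#'
#' @param values Numeric matrix of shape `(n_angles, n_channels)`.
#' @param geom The `projection_geometry` the values were measured under.
#' @return An object of class `sinogram` with elements `values` and `geom`.
#' @export
sinogram <- function(values, geom) {
  values <- as.matrix(values)
  stopifnot(inherits(geom, "projection_geometry"))
  if (nrow(values) != geom$n_angles || ncol(values) != geom$n_channels) {
    stop("sinogram: `values` must be n_angles x n_channels")
  }
  if (!all(is.finite(values))) stop("sinogram: values must be finite")
  structure(list(values = values, geom = geom), class = "sinogram")
}

#' @rawNamespace S3method(print, sinogram)
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d channels, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Partial line-integral stack
#'
#' Intermediate-domain data `q(t, theta, r)`: line integrals restricted to a
#' window of width `alpha` centered at depth `t` along each ray, stored as
#' mean attenuation over the window (integral divided by `alpha`) so that
#' intermediate data and image voxels share units. Values form an array of
#' dimension `(N_t, N_theta, N_r)`. Depth bins tile `[-fov/2, fov/2)` without
#' overlap; bin `j` (1-based) is centered at `t_j = -fov/2 + (j - 0.5) * alpha`
#' with `alpha = fov / N_t`.
#'
#' @param values Numeric array `(N_t, N_theta, N_r)`.
#' @param stage The [stage_spec()] describing the grid.
#' @return An object of class `partial_stack` with elements `values`, `stage`,
#'   `alpha`, and depth-bin centers `t`.
#' @export
partial_stack <- function(values, stage) {
  stopifnot(inherits(stage, "stage_spec"))
  values <- as.array(values)
  dims <- c(stage$n_t, stage$n_theta, stage$n_r)
  if (length(dim(values)) != 3L || !all(dim(values) == dims)) {
    stop("partial_stack: `values` must have dim (N_t, N_theta, N_r)")
  }
  structure(list(values = values, stage = stage, alpha = stage$alpha,
                 t = stage_depths(stage)),
            class = "partial_stack")
}

#' @rawNamespace S3method(print, partial_stack)
print.partial_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<partial_stack> %d depths x %d angles x %d channels, alpha = %g\n",
              d[1], d[2], d[3], x$alpha))
  invisible(x)
}
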