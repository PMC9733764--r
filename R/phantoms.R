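# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# classical ten-ellipse head phantom, parameters on the unit disk:
# additive intensity, semi-axes a/b, center, rotation (degrees)
.shepp_logan_table <- function() {
  data.frame(
    intensity = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0 = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0 = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0))
}

#' Ellipse phantom
#'
#' A list of ellipses, each with center, semi-axes, rotation and additive
#' intensity, scaled to a field of view. Ellipse phantoms are used in place
#' of clinical images because their Radon transform has a closed form, which
#' provides a projector oracle independent of ray tracing.
#'
#' @param params Data frame with columns `intensity`, `a`, `b`, `x0`, `y0`,
#'   `phi` (degrees), all spatial quantities in units of the fov half-width
#'   (i.e. on the unit disk).
#' @param fov Field-of-view side length the phantom is scaled to.
#' @return An object of class `ellipse_phantom`.
#' @export
ellipse_phantom <- function(params, fov) {
  need <- c("intensity", "a", "b", "x0", "y0", "phi")
  stopifnot(all(need %in% names(params)), fov > 0)
  structure(list(params = params[need], fov = as.numeric(fov)),
            class = "ellipse_phantom")
}

#' @rawNamespace S3method(print, ellipse_phantom)
print.ellipse_phantom <- function(x, ...) {
  cat(sprintf("<ellipse_phantom> %d ellipses, fov = %g\n",
              nrow(x$params), x$fov))
  invisible(x)
}

#' Rasterize an ellipse phantom onto an image grid
#'
#' Pixel values are the sum of the intensities of all ellipses containing the
#' pixel center (optionally anti-aliased by supersampling each pixel).
#'
#' @param phantom An [ellipse_phantom()].
#' @param grid An [image_grid()] (its fov must match the phantom's).
#' @param supersample Square-root of the number of sample points per pixel
#'   (1 = pixel centers only).
#' @return An [image_grid()] with the rasterized values.
#' @export
rasterize_phantom <- function(phantom, grid, supersample = 1L) {
  stopifnot(inherits(phantom, "ellipse_phantom"), inherits(grid, "image_grid"))
  if (abs(phantom$fov - grid$fov) > 1e-9 * grid$fov) {
    stop("rasterize_phantom: phantom and grid must share the same fov")
  }
  ctr <- grid_centers(grid)
  d <- pixel_size(grid)
  ss <- as.integer(supersample)
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * d
  vals <- matrix(0, grid$n_y, grid$n_x)
  half <- phantom$fov / 2
  pp <- phantom$params
  for (sy in sub) for (sx in sub) {
    x <- ctr$x + sx
    y <- ctr$y + sy
    acc <- matrix(0, grid$n_y, grid$n_x)
    for (k in seq_len(nrow(pp))) {
      phi <- pp$phi[k] * pi / 180
      xs <- outer(rep(1, grid$n_y), x) - pp$x0[k] * half
      ys <- outer(y, rep(1, grid$n_x)) - pp$y0[k] * half
      xr <- xs * cos(phi) + ys * sin(phi)
      yr <- -xs * sin(phi) + ys * cos(phi)
      inside <- (xr / (pp$a[k] * half))^2 + (yr / (pp$b[k] * half))^2 <= 1
      acc <- acc + pp$intensity[k] * inside
    }
    vals <- vals + acc
  }
  image_grid(grid$n_x, grid$n_y, grid$fov, values = vals / ss^2)
}

#' Shepp-Logan head phantom
#'
#' The standard ten-ellipse head phantom rasterized on a grid; intensities
#' lie in `[0, 2]`.
#'
#' @param grid An [image_grid()].
#' @param supersample Anti-aliasing factor passed to [rasterize_phantom()].
#' @return An [image_grid()] holding the phantom.
#' @export
shepp_logan <- function(grid, supersample = 1L) {
  rasterize_phantom(shepp_logan_phantom(grid$fov), grid, supersample)
}

#' @rdname shepp_logan
#' @param fov Field-of-view side length.
#' @export
shepp_logan_phantom <- function(fov) {
  ellipse_phantom(.shepp_logan_table(), fov)
}

#' Random ellipse phantoms
#'
#' Seeded random phantoms standing in for clinical training images: each
#' phantom is a background disk plus `n_ellipses` random ellipses fully
#' contained in the circle inscribed in the field of view. Intensities are
#' uniform in `[-0.5, 1]` on top of a 0.5 background, so typical pixel values
#' are of order one.
#'
#' @param grid An [image_grid()] defining the raster.
#' @param n_ellipses Number of random ellipses (default 6).
#' @param seed Integer seed; the phantom is a pure function of
#'   `(parameters, seed)`.
#' @return A list with the `ellipse_phantom` (`phantom`) and its rasterized
#'   [image_grid()] (`image`).
#' @export
random_ellipses <- function(grid, n_ellipses = 6L, seed = 1L) {
  stopifnot(n_ellipses >= 1)
  params <- with_seed(seed, {
    a <- runif(n_ellipses, 0.05, 0.45)
    b <- runif(n_ellipses, 0.05, 0.45)
    rmax <- pmax(a, b)
    rho <- runif(n_ellipses, 0, pmax(0, 0.95 - rmax))
    ang <- runif(n_ellipses, 0, 2 * pi)
    data.frame(
      intensity = c(0.5, runif(n_ellipses, -0.5, 1)),
      a = c(0.95, a), b = c(0.95, b),
      x0 = c(0, rho * cos(ang)), y0 = c(0, rho * sin(ang)),
      phi = c(0, runif(n_ellipses, 0, 180)))
  })
  ph <- ellipse_phantom(params, grid$fov)
  list(phantom = ph, image = rasterize_phantom(ph, grid))
}

#' Analytic sinogram of an ellipse phantom
#'
#' Closed-form parallel-beam projections: an ellipse with semi-axes `(a, b)`,
#' rotation `phi` and intensity `A` projects at angle `theta` and offset `r`
#' to `2 A a b sqrt(s - tau^2) / s` where `s = a^2 cos^2(theta - phi) +
#' b^2 sin^2(theta - phi)` and `tau` is the offset relative to the projected
#' center. Summed over ellipses this is the exact Radon transform of the
#' ideal (non-rasterized) phantom.
#'
#' @param phantom An [ellipse_phantom()].
#' @param geom A [projection_geometry()] with the phantom's fov.
#' @return A [sinogram()].
#' @export
ellipse_sinogram <- function(phantom, geom) {
  stopifnot(inherits(phantom, "ellipse_phantom"),
            inherits(geom, "projection_geometry"))
  if (abs(phantom$fov - geom$fov) > 1e-9 * geom$fov) {
    stop("ellipse_sinogram: phantom and geometry must share the same fov")
  }
  angles <- geom_angles(geom)
  offsets <- geom_offsets(geom)
  half <- phantom$fov / 2
  pp <- phantom$params
  vals <- matrix(0, geom$n_angles, geom$n_channels)
  for (k in seq_len(nrow(pp))) {
    a <- pp$a[k] * half; b <- pp$b[k] * half
    phi <- pp$phi[k] * pi / 180
    cs <- cos(angles - phi); sn <- sin(angles - phi)
    s <- a^2 * cs^2 + b^2 * sn^2                     # per angle
    rc <- pp$x0[k] * half * cos(angles) + pp$y0[k] * half * sin(angles)
    tau <- outer(-rc, offsets, `+`)                  # angle x offset
    disc <- pmax(sweep(-tau^2, 1, s, `+`), 0)
    vals <- vals + 2 * pp$intensity[k] * a * b * sqrt(disc) / s
  }
  sinogram(vals, geom)
}

#' Insert measurement noise into a sinogram
#'
#' Additive white Gaussian noise with standard deviation
#' `level * max(abs(values))`, emulating additional measurement noise on
#' reprojected images. `level = 0` returns the input unchanged.
#'
#' @param sino A [sinogram()].
#' @param level Noise level as a fraction of the maximum absolute sinogram
#'   value (default 0.01).
#' @param seed Integer seed.
#' @return A [sinogram()] with noise added.
#' @export
insert_noise <- function(sino, level = 0.01, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), level >= 0)
  if (level == 0) return(sino)
  sigma <- level * max(abs(sino$values))
  noisy <- with_seed(seed, {
    sino$values + matrix(rnorm(length(sino$values), sd = sigma),
                         nrow(sino$values), ncol(sino$values))
  })
  sinogram(noisy, sino$geom)
}
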