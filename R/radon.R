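# cache of system matrices keyed by geometry parameters; exact ray tracing is
# deterministic, so reuse across calls (training projects many images under
# one geometry)
.radon_cache <- new.env(parent = emptyenv())

.radon_key <- function(nx, ny, fov, angles, offsets, s0, s1) {
  paste(nx, ny, signif(fov, 12), length(angles), length(offsets),
        signif(sum(angles) + sum(offsets), 12), signif(s0, 12),
        signif(s1, 12), sep = "|")
}

#' Radon system matrix
#'
#' Sparse matrix `A` of exact ray/pixel intersection lengths so that
#' `A %*% as.vector(image)` equals the vector of line integrals. Rays are
#' enumerated angle-fastest, matching the column-major layout of the
#' `(n_angles, n_channels)` sinogram matrix. An optional depth window
#' `[s0, s1]` restricts the integrals to a segment along each ray, which is
#' how partial line integrals are formed.
#'
#' @param grid An [image_grid()] (only its dimensions and fov are used).
#' @param geom A [projection_geometry()] sharing the grid's fov.
#' @param window Optional numeric `c(s0, s1)` depth window; default unbounded.
#' @param cache Reuse a previously built matrix for identical parameters.
#' @return A `dgCMatrix` with `n_angles * n_channels` rows and
#'   `n_x * n_y` columns.
#' @export
radon_operator <- function(grid, geom, window = NULL, cache = TRUE) {
  stopifnot(inherits(grid, "image_grid"), inherits(geom, "projection_geometry"))
  if (abs(grid$fov - geom$fov) > 1e-9 * grid$fov) {
    stop("radon_operator: image and geometry must share the same fov")
  }
  if (is.null(window)) {
    window <- c(-grid$fov, grid$fov)   # spans any chord of the fov square
  }
  angles <- geom_angles(geom)
  offsets <- geom_offsets(geom)
  key <- .radon_key(grid$n_x, grid$n_y, grid$fov, angles, offsets,
                    window[1], window[2])
  if (cache && !is.null(.radon_cache[[key]])) return(.radon_cache[[key]])
  tr <- siddon_trace(grid$n_x, grid$n_y, grid$fov, angles, offsets,
                     window[1], window[2])
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(geom$n_angles * geom$n_channels,
                                     grid$n_x * grid$n_y))
  if (cache) .radon_cache[[key]] <- A
  A
}

#' Forward projection (Radon transform)
#'
#' Computes the exact line integrals of the piecewise-constant pixel image
#' along every ray of the geometry: the parallel-beam CT forward model
#' `p(r, theta) = integral of f along the ray at offset r, angle theta`.
#'
#' @param image An [image_grid()].
#' @param geom A [projection_geometry()] with the same fov as `image`.
#' @return A [sinogram()].
#' @examples
#' g <- image_grid(16)
#' g$values[6:10, 6:10] <- 1
#' p <- radon_forward(g, projection_geometry(16, 8, fov = 16))
#' @export
radon_forward <- function(image, geom) {
  A <- radon_operator(image, geom)
  p <- as.numeric(A %*% as.vector(image$values))
  sinogram(matrix(p, geom$n_angles, geom$n_channels), geom)
}

#' Partial line integrals of an image
#'
#' Restricts each line integral to the depth window of width `alpha` centered
#' at each depth bin `t_j` of the stage: the intermediate representation
#' between the sinogram (one bin covering the whole ray) and the image
#' (pixel-sized bins). Values are stored as mean attenuation over the window
#' (integral divided by `alpha`), so the stack shares units with image voxels.
#' Summing `alpha * q` over depth bins recovers the full sinogram value of
#' each ray, and with a single depth bin `alpha * q` equals the original
#' measurement.
#'
#' @param image An [image_grid()].
#' @param stage A [stage_spec()] with the same fov as the image.
#' @return A [partial_stack()] of dimension `(N_t, N_theta, N_r)`.
#' @export
partial_line_integrals <- function(image, stage) {
  stopifnot(inherits(image, "image_grid"), inherits(stage, "stage_spec"))
  if (stage$alpha <= 0) stop("partial_line_integrals: alpha must be positive")
  if (abs(image$fov - stage$fov) > 1e-9 * image$fov) {
    stop("partial_line_integrals: stage fov must match the image fov")
  }
  geom <- projection_geometry(stage$n_r, stage$n_theta, fov = stage$fov,
                              angle_range = stage$angle_range)
  depths <- stage_depths(stage)
  f <- as.vector(image$values)
  q <- array(0, c(stage$n_t, stage$n_theta, stage$n_r))
  for (j in seq_len(stage$n_t)) {
    A <- radon_operator(image, geom,
                        window = depths[j] + c(-0.5, 0.5) * stage$alpha)
    q[j, , ] <- matrix(as.numeric(A %*% f),
                       stage$n_theta, stage$n_r) / stage$alpha
  }
  partial_stack(q, stage)
}
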