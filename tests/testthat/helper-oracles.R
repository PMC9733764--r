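# Independent oracles used to check the package's operators. These are
# deliberately naive implementations sharing no code with the package.

# dense ray-sampling projector: walk each ray in small steps, look up the
# pixel under each sample point, and sum value * step
oracle_radon <- function(image, geom, oversample = 10) {
  d <- image$fov / image$n_x
  step <- d / oversample
  s_grid <- seq(-image$fov * 0.75, image$fov * 0.75, by = step)
  angles <- geom_angles(geom)
  offsets <- geom_offsets(geom)
  out <- matrix(0, geom$n_angles, geom$n_channels)
  for (a in seq_along(angles)) {
    ca <- cos(angles[a]); sa <- sin(angles[a])
    for (k in seq_along(offsets)) {
      x <- offsets[k] * ca - s_grid * sa
      y <- offsets[k] * sa + s_grid * ca
      ix <- floor((x + image$fov / 2) / d) + 1
      iy <- floor((y + image$fov / 2) / d) + 1
      ok <- ix >= 1 & ix <= image$n_x & iy >= 1 & iy <= image$n_y
      out[a, k] <- sum(image$values[cbind(iy[ok], ix[ok])]) * step
    }
  }
  out
}

# dense sampling of the continuous (non-rasterized) ellipse phantom
oracle_ellipse_radon <- function(phantom, geom, step_frac = 0.02) {
  half <- phantom$fov / 2
  step <- step_frac * phantom$fov
  s_grid <- seq(-phantom$fov * 0.75, phantom$fov * 0.75, by = step)
  angles <- geom_angles(geom)
  offsets <- geom_offsets(geom)
  pp <- phantom$params
  out <- matrix(0, geom$n_angles, geom$n_channels)
  for (a in seq_along(angles)) {
    ca <- cos(angles[a]); sa <- sin(angles[a])
    for (k in seq_along(offsets)) {
      x <- offsets[k] * ca - s_grid * sa
      y <- offsets[k] * sa + s_grid * ca
      v <- numeric(length(x))
      for (e in seq_len(nrow(pp))) {
        phi <- pp$phi[e] * pi / 180
        xs <- x - pp$x0[e] * half
        ys <- y - pp$y0[e] * half
        xr <- xs * cos(phi) + ys * sin(phi)
        yr <- -xs * sin(phi) + ys * cos(phi)
        v <- v + pp$intensity[e] *
          ((xr / (pp$a[e] * half))^2 + (yr / (pp$b[e] * half))^2 <= 1)
      }
      out[a, k] <- sum(v) * step
    }
  }
  out
}

# exhaustive enumeration of the geometric gather neighborhood: triple loop
# over output neurons, neighboring input angles, and stencil offsets
oracle_pattern_count <- function(stage_in, stage_out, extents = c(3, 5, 3)) {
  th_in <- stage_angles(stage_in)
  th_out <- stage_angles(stage_out)
  period <- stage_in$angle_range * pi / 180
  cdist <- function(a, b) {
    d <- abs(a - b) %% period
    min(d, period - d)
  }
  t_out <- stage_depths(stage_out)
  r_out <- stage_offsets(stage_out)
  dr_in <- stage_in$fov / stage_in$n_r
  ht <- (extents[1] - 1) / 2
  ha <- (extents[2] - 1) / 2
  count <- 0
  for (b in seq_len(stage_out$n_theta)) {
    near <- which.min(vapply(th_in, cdist, numeric(1), b = th_out[b]))
    offs <- if (extents[2] >= stage_in$n_theta) {
      0:(stage_in$n_theta - 1)
    } else -ha:ha
    for (oo in offs) {
      a <- (near - 1 + oo) %% stage_in$n_theta + 1
      delta <- th_out[b] - th_in[a]
      for (ot in seq_len(stage_out$n_t)) for (orr in seq_len(stage_out$n_r)) {
        tp <- r_out[orr] * sin(delta) + t_out[ot] * cos(delta)
        rp <- r_out[orr] * cos(delta) - t_out[ot] * sin(delta)
        at <- min(max(ceiling((tp + stage_in$fov / 2) / stage_in$alpha), 1),
                  stage_in$n_t)
        ar <- min(max(ceiling(rp / dr_in + stage_in$n_r / 2), 1),
                  stage_in$n_r)
        hr <- (extents[3] - 1) / 2
        nt_ok <- sum((at + (-ht:ht)) >= 1 & (at + (-ht:ht)) <= stage_in$n_t)
        nr_ok <- sum((ar + (-hr:hr)) >= 1 & (ar + (-hr:hr)) <= stage_in$n_r)
        count <- count + nt_ok * nr_ok
      }
    }
  }
  count
}

# windowed SSIM by direct sliding-window loops (Gaussian 11x11, sigma 1.5)
oracle_ssim <- function(a, b, dynamic_range = diff(range(a))) {
  g <- outer(exp(-((-5:5)^2) / 4.5), exp(-((-5:5)^2) / 4.5))
  g <- g / sum(g)
  L <- if (dynamic_range == 0) 1 else dynamic_range
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  vals <- c()
  for (i in 6:(nrow(a) - 5)) for (j in 6:(ncol(a) - 5)) {
    wa <- a[(i - 5):(i + 5), (j - 5):(j + 5)]
    wb <- b[(i - 5):(i + 5), (j - 5):(j + 5)]
    mua <- sum(g * wa); mub <- sum(g * wb)
    va <- sum(g * wa^2) - mua^2
    vb <- sum(g * wb^2) - mub^2
    vab <- sum(g * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + c1) * (2 * vab + c2)) /
                ((mua^2 + mub^2 + c1) * (va + vb + c2)))
  }
  mean(vals)
}

# small shared fixtures
disk_image <- function(n, radius, fov = n) {
  g <- image_grid(n, fov = fov)
  ctr <- grid_centers(g)
  g$values <- outer(ctr$y, ctr$x,
                    function(y, x) as.numeric(x^2 + y^2 <= radius^2))
  g
}

random_image <- function(n, seed, fov = n) {
  set.seed(seed)
  image_grid(n, fov = fov, values = matrix(rnorm(n * n), n, n))
}
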