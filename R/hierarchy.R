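#' Stage specification
#'
#' One level of the hierarchy: a `(N_t, N_theta, N_r)` grid of partial line
#' integrals with depth-window width `alpha = fov / N_t`. Level 0 is the
#' sinogram layout (`N_t = 1`, window spanning the whole field of view); the
#' final level is the image layout (`N_theta = 1`, `alpha` equal to one pixel).
#'
#' @param n_t Number of depth bins.
#' @param n_theta Number of view angles at this stage.
#' @param n_r Number of radial bins.
#' @param fov Field-of-view side length shared by all stages of a schedule.
#' @param angle_range Angular span in degrees the stage angles are spread over.
#' @param level Level index `L` (0 = sinogram domain).
#' @return An object of class `stage_spec` with the fields above plus `alpha`.
#' @export
stage_spec <- function(n_t, n_theta, n_r, fov = n_r, angle_range = 360,
                       level = NA_integer_) {
  stopifnot(n_t >= 1, n_theta >= 1, n_r >= 1, fov > 0)
  alpha <- fov / n_t
  if (alpha <= 0) stop("stage_spec: alpha must be positive")
  structure(list(n_t = as.integer(n_t), n_theta = as.integer(n_theta),
                 n_r = as.integer(n_r), fov = as.numeric(fov),
                 angle_range = as.numeric(angle_range),
                 alpha = alpha, level = as.integer(level)),
            class = "stage_spec")
}

#' Depth-bin centers and view angles of a stage
#'
#' Depth bins tile `[-fov/2, fov/2)`; angles are uniform over
#' `[0, angle_range)` starting at zero, the same convention as
#' [projection_geometry()].
#'
#' @param stage A `stage_spec`.
#' @return Numeric vector of depth-bin centers (`stage_depths`), view angles
#'   in radians (`stage_angles`), or radial bin centers (`stage_offsets`).
#' @export
stage_depths <- function(stage) {
  -stage$fov / 2 + (seq_len(stage$n_t) - 0.5) * stage$alpha
}

#' @rdname stage_depths
#' @export
stage_angles <- function(stage) {
  (seq_len(stage$n_theta) - 1) / stage$n_theta * stage$angle_range * pi / 180
}

#' @rdname stage_depths
#' @export
stage_offsets <- function(stage) {
  d <- stage$fov / stage$n_r
  (seq_len(stage$n_r) - (stage$n_r + 1) / 2) * d
}

#' @rawNamespace S3method(print, stage_spec)
print.stage_spec <- function(x, ...) {
  cat(sprintf("<stage_spec> L=%s: %d depths x %d angles x %d radial, alpha=%g\n",
              ifelse(is.na(x$level), "?", x$level),
              x$n_t, x$n_theta, x$n_r, x$alpha))
  invisible(x)
}

#' Plan a hierarchical stage schedule
#'
#' Builds the sequence of intermediate grids from the sinogram layout
#' (`N_t = 1`, all input angles) to the image layout (`N_theta = 1`,
#' `N_t = image_size`). The default ratio rule increases the depth-bin count
#' by a factor of 4 per step, with the first step adjusted so the ratios
#' multiply out to `image_size`; the angle count shrinks to keep the total
#' data size `N_t * N_theta * N_r` constant whenever the ratios are integer.
#' For the 512-channel / 512-angle / 512-pixel configuration with 5 stages
#' this yields depth counts 1, 2, 8, 32, 128, 512 and angle counts 512, 256,
#' 64, 16, 4, 1. When integer ratios are impossible the depth counts are
#' rounded and the angle counts follow by data-size conservation, giving
#' non-integer resampling ratios (the sparse layers absorb the resampling).
#'
#' @param n_radial Number of radial bins, held constant across stages.
#' @param n_angles Number of view angles in the input sinogram.
#' @param image_size Output image side length in pixels.
#' @param n_stages Number of sparse stage transitions, or `"auto"` for the
#'   smallest count whose ratio-4 steps reach `image_size`
#'   (`ceiling(log4(image_size))`).
#' @param fov Field-of-view side length (default `image_size`: unit pixels).
#' @param angle_range Angular span in degrees.
#' @return An object of class `stage_schedule`: a list of `n_stages + 1`
#'   [stage_spec()] objects (levels 0..N) plus planning metadata.
#' @examples
#' s <- plan_schedule(64, 64, 64, 3)
#' print(s)
#' @export
plan_schedule <- function(n_radial, n_angles, image_size, n_stages = "auto",
                          fov = image_size, angle_range = 360) {
  stopifnot(image_size >= 2, n_angles >= 2, n_radial >= 1)
  if (identical(n_stages, "auto")) {
    n_stages <- max(1L, as.integer(ceiling(log(image_size) / log(4) - 1e-9)))
  }
  n_stages <- as.integer(n_stages)
  stopifnot(n_stages >= 1)

  # depth counts: ratio 4 per step, first step adjusted; round when the
  # first ratio is non-integer, then force strict monotonicity
  n_t <- round(image_size / 4^(n_stages - seq_len(n_stages)))
  n_t[n_stages] <- image_size
  n_t <- pmax(n_t, seq_len(n_stages) + 1L)      # keep above N_t(0) = 1
  n_t <- as.integer(cummax(n_t))
  for (i in seq_len(n_stages - 1L)) {           # strictly increasing
    if (n_t[i + 1L] <= n_t[i]) n_t[i + 1L] <- n_t[i] + 1L
  }
  n_t <- c(1L, n_t)

  # angle counts by data-size conservation; final stage is the image (1 angle)
  n_th <- pmax(1L, as.integer(round(n_angles / n_t)))
  n_th[length(n_th)] <- 1L
  n_th[1] <- as.integer(n_angles)
  for (i in seq_len(n_stages)) {                # strictly decreasing
    if (n_th[i + 1L] >= n_th[i]) n_th[i + 1L] <- max(1L, n_th[i] - 1L)
  }

  stages <- lapply(seq_along(n_t), function(i) {
    stage_spec(n_t[i], n_th[i], n_radial, fov = fov,
               angle_range = angle_range, level = i - 1L)
  })
  structure(list(stages = stages, n_radial = as.integer(n_radial),
                 n_angles = as.integer(n_angles),
                 image_size = as.integer(image_size),
                 n_stages = n_stages, fov = as.numeric(fov),
                 angle_range = as.numeric(angle_range)),
            class = "stage_schedule")
}

#' @rawNamespace S3method(print, stage_schedule)
print.stage_schedule <- function(x, ...) {
  cat(sprintf("<stage_schedule> %d sparse stages, fov = %g\n",
              x$n_stages, x$fov))
  tab <- schedule_table(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stage dimensions as a data frame
#'
#' One row per hierarchy level, mirroring the usual tabular presentation of
#' stage dimensions (level, depth bins, projection angles, radial bins,
#' window width).
#'
#' @param schedule A `stage_schedule`.
#' @return A `data.frame` with columns `level`, `n_t`, `n_theta`, `n_r`,
#'   `alpha`, `data_size`.
#' @export
schedule_table <- function(schedule) {
  st <- schedule$stages
  data.frame(level = vapply(st, `[[`, integer(1), "level"),
             n_t = vapply(st, `[[`, integer(1), "n_t"),
             n_theta = vapply(st, `[[`, integer(1), "n_theta"),
             n_r = vapply(st, `[[`, integer(1), "n_r"),
             alpha = vapply(st, `[[`, numeric(1), "alpha"),
             data_size = vapply(st, function(s) {
               as.numeric(s$n_t) * s$n_theta * s$n_r
             }, numeric(1)))
}

#' Validate a stage schedule
#'
#' Checks the hard invariants (strictly increasing depth counts, strictly
#' decreasing angle counts and window widths, sinogram-shaped first stage,
#' image-shaped last stage) and reports soft diagnostics: per-stage drift of
#' the total data size away from the input size (keeping it constant is
#' preferred but not strict) and non-integer resampling ratios between
#' consecutive stages (allowed; the layers learn the resampling).
#'
#' @param schedule A `stage_schedule`.
#' @param strict If `TRUE` (default), violated hard invariants raise an error
#'   naming the failing stage; otherwise they are returned as diagnostics.
#' @return A list with `ok` (logical), `errors`, `warnings` (character
#'   vectors), and the `drift` per level (fractional deviation of data size).
#' @export
validate_schedule <- function(schedule, strict = TRUE) {
  tab <- schedule_table(schedule)
  n <- nrow(tab)
  errs <- character(0)
  warns <- character(0)

  if (tab$n_t[1] != 1L) {
    errs <- c(errs, "level 0 must have a single depth bin (sinogram layout)")
  }
  if (tab$n_theta[n] != 1L) {
    errs <- c(errs, sprintf("level %d must have a single angle (image layout)",
                            tab$level[n]))
  }
  for (i in seq_len(n - 1L)) {
    if (tab$n_t[i + 1] <= tab$n_t[i]) {
      errs <- c(errs, sprintf("depth bins not increasing at level %d -> %d",
                              tab$level[i], tab$level[i + 1]))
    }
    if (tab$n_theta[i + 1] >= tab$n_theta[i]) {
      errs <- c(errs, sprintf("angle count not decreasing at level %d -> %d",
                              tab$level[i], tab$level[i + 1]))
    }
    if (tab$alpha[i + 1] >= tab$alpha[i]) {
      errs <- c(errs, sprintf("window width not shrinking at level %d -> %d",
                              tab$level[i], tab$level[i + 1]))
    }
    rt <- tab$n_t[i + 1] / tab$n_t[i]
    ra <- tab$n_theta[i] / tab$n_theta[i + 1]
    if (abs(rt - round(rt)) > 1e-9 || abs(ra - round(ra)) > 1e-9) {
      warns <- c(warns, sprintf("non-integer resampling ratio at level %d -> %d",
                                tab$level[i], tab$level[i + 1]))
    }
  }
  drift <- tab$data_size / tab$data_size[1] - 1
  if (any(abs(drift) > 0)) {
    warns <- c(warns, sprintf("total data size drifts by up to %.1f%%",
                              100 * max(abs(drift))))
  }
  if (strict && length(errs) > 0) {
    stop("validate_schedule: ", paste(errs, collapse = "; "))
  }
  list(ok = length(errs) == 0, errors = errs, warnings = warns, drift = drift)
}

#' Read or write a schedule as a plain-text configuration
#'
#' @param schedule A `stage_schedule`.
#' @param path File path of the YAML document.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   the `stage_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  doc <- list(n_radial = schedule$n_radial, n_angles = schedule$n_angles,
              image_size = schedule$image_size, n_stages = schedule$n_stages,
              fov = schedule$fov, angle_range = schedule$angle_range,
              n_t = vapply(schedule$stages, `[[`, integer(1), "n_t"),
              n_theta = vapply(schedule$stages, `[[`, integer(1), "n_theta"))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  doc <- yaml::read_yaml(path)
  stages <- lapply(seq_along(doc$n_t), function(i) {
    stage_spec(doc$n_t[i], doc$n_theta[i], doc$n_radial, fov = doc$fov,
               angle_range = doc$angle_range, level = i - 1L)
  })
  structure(list(stages = stages, n_radial = as.integer(doc$n_radial),
                 n_angles = as.integer(doc$n_angles),
                 image_size = as.integer(doc$image_size),
                 n_stages = as.integer(doc$n_stages),
                 fov = as.numeric(doc$fov),
                 angle_range = as.numeric(doc$angle_range)),
            class = "stage_schedule")
}
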