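# flatten an array to a one-column CSV; dims and attributes live in the
# bundle's YAML metadata, keeping every artifact plain text
.write_array <- function(x, path) {
  utils::write.csv(data.frame(value = as.vector(x)), path, row.names = FALSE)
}

.read_array <- function(path, dims) {
  v <- as.numeric(utils::read.csv(path)$value)
  if (length(dims) > 1) array(v, dims) else v
}

#' Write or read a CT tensor bundle
#'
#' A plain-text container for related CT tensors: a directory holding one
#' CSV per array plus a `meta.yaml` with shapes and acquisition attributes
#' (`fov`, `n_angles`, `angle_range`, per-stage `alpha`). Partial stacks are
#' stored one slice per stage angle under `partial/<level>/<angle>.csv`.
#'
#' @param path Bundle directory (created if needed).
#' @param image Optional [image_grid()].
#' @param sino Optional [sinogram()].
#' @param partial Optional list of [partial_stack()]s.
#' @return `write_ct_bundle` returns `path` invisibly; `read_ct_bundle`
#'   returns a list with any of `image`, `sino`, `partial` present.
#' @export
write_ct_bundle <- function(path, image = NULL, sino = NULL, partial = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  if (!is.null(image)) {
    stopifnot(inherits(image, "image_grid"))
    .write_array(image$values, file.path(path, "image.csv"))
    meta$image <- list(n_x = image$n_x, n_y = image$n_y, fov = image$fov)
  }
  if (!is.null(sino)) {
    stopifnot(inherits(sino, "sinogram"))
    .write_array(sino$values, file.path(path, "sinogram.csv"))
    meta$sinogram <- list(n_channels = sino$geom$n_channels,
                          n_angles = sino$geom$n_angles,
                          fov = sino$geom$fov,
                          angle_range = sino$geom$angle_range)
  }
  if (!is.null(partial)) {
    meta$partial <- list()
    for (ps in partial) {
      stopifnot(inherits(ps, "partial_stack"))
      st <- ps$stage
      lev <- as.character(st$level)
      dir.create(file.path(path, "partial", lev), recursive = TRUE,
                 showWarnings = FALSE)
      for (a in seq_len(st$n_theta)) {
        .write_array(ps$values[, a, ],
                     file.path(path, "partial", lev, paste0(a, ".csv")))
      }
      meta$partial[[lev]] <- list(n_t = st$n_t, n_theta = st$n_theta,
                                  n_r = st$n_r, alpha = st$alpha,
                                  fov = st$fov, angle_range = st$angle_range)
    }
  }
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_ct_bundle
#' @export
read_ct_bundle <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  out <- list()
  if (!is.null(meta$image)) {
    m <- meta$image
    out$image <- image_grid(m$n_x, m$n_y, m$fov,
                            values = .read_array(file.path(path, "image.csv"),
                                                 c(m$n_y, m$n_x)))
  }
  if (!is.null(meta$sinogram)) {
    m <- meta$sinogram
    out$sino <- sinogram(.read_array(file.path(path, "sinogram.csv"),
                                     c(m$n_angles, m$n_channels)),
                         projection_geometry(m$n_channels, m$n_angles,
                                             fov = m$fov,
                                             angle_range = m$angle_range))
  }
  if (!is.null(meta$partial)) {
    out$partial <- lapply(names(meta$partial), function(lev) {
      m <- meta$partial[[lev]]
      st <- stage_spec(m$n_t, m$n_theta, m$n_r, fov = m$fov,
                       angle_range = m$angle_range, level = as.integer(lev))
      q <- array(0, c(m$n_t, m$n_theta, m$n_r))
      for (a in seq_len(m$n_theta)) {
        q[, a, ] <- .read_array(file.path(path, "partial", lev,
                                          paste0(a, ".csv")),
                                c(m$n_t, m$n_r))
      }
      partial_stack(q, st)
    })
  }
  out
}

#' PNG preview of an image
#'
#' Linear window/level display: values are mapped linearly from
#' `[level - window/2, level + window/2]` to gray levels and clipped.
#'
#' @param image An [image_grid()] or numeric matrix.
#' @param path Output PNG path.
#' @param window,level Display window width and center (defaults span the
#'   image range).
#' @return `path`, invisibly.
#' @export
write_png_preview <- function(image, path, window = NULL, level = NULL) {
  v <- .as_values(image)
  if (is.null(window)) window <- diff(range(v))
  if (is.null(level)) level <- mean(range(v))
  if (window <= 0) window <- 1
  g <- (v - (level - window / 2)) / window
  g <- pmin(pmax(g, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}

# a small deterministic content hash (djb2) for manifests, avoiding any
# dependency on external digest packages
.text_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Save or load a network checkpoint
#'
#' Checkpoints are plain-text directories: the schedule as YAML, each weight
#' vector as CSV, and a `meta.yaml` carrying mode, extents, and a content
#' hash of the weights for integrity checks.
#'
#' @param net A `hier_net`.
#' @param path Checkpoint directory.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the reconstructed `hier_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "hier_net"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_schedule(net$schedule, file.path(path, "schedule.yaml"))
  .write_array(net$filter_kernel, file.path(path, "filter.csv"))
  for (i in seq_along(net$layers)) {
    .write_array(net$layers[[i]]$weights,
                 file.path(path, sprintf("sparse%d.csv", i)))
  }
  conv_meta <- NULL
  if (!is.null(net$conv)) {
    conv_meta <- lapply(net$conv$W, dim)
    for (i in seq_along(net$conv$W)) {
      .write_array(net$conv$W[[i]], file.path(path, sprintf("convW%d.csv", i)))
      .write_array(net$conv$b[[i]], file.path(path, sprintf("convb%d.csv", i)))
    }
  }
  allw <- c(net$filter_kernel, unlist(lapply(net$layers, `[[`, "weights")))
  yaml::write_yaml(list(mode = net$mode, extents = net$extents,
                        conv_dims = conv_meta,
                        weight_hash = .text_hash(sprintf("%.8e", allw))),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  schedule <- read_schedule(file.path(path, "schedule.yaml"))
  net <- build_network(schedule, mode = "linear", conv_block = FALSE,
                       extents = as.integer(meta$extents))
  net$filter_kernel <- .read_array(file.path(path, "filter.csv"),
                                   schedule$n_radial)
  for (i in seq_along(net$layers)) {
    w <- .read_array(file.path(path, sprintf("sparse%d.csv", i)),
                     length(net$layers[[i]]$weights))
    net$layers[[i]] <- set_layer_weights(net$layers[[i]], w)
  }
  if (!is.null(meta$conv_dims)) {
    net$conv <- list(W = lapply(seq_along(meta$conv_dims), function(i) {
      d <- as.integer(unlist(meta$conv_dims[[i]]))
      .read_array(file.path(path, sprintf("convW%d.csv", i)), d)
    }), b = lapply(seq_along(meta$conv_dims), function(i) {
      .read_array(file.path(path, sprintf("convb%d.csv", i)), NULL)
    }))
    net$mode <- meta$mode
  }
  net
}
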