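# Toeplitz matrix of the radial filter kernel (zero-padded 'same'
# convolution along r, shared across angles): filtered = values %*% K
.filter_matrix <- function(kernel) {
  n <- length(kernel)
  c0 <- n %/% 2L + 1L
  d <- outer(seq_len(n), seq_len(n), function(m, j) j - m + c0)
  K <- matrix(0, n, n)
  ok <- d >= 1 & d <= n
  K[ok] <- kernel[d[ok]]
  K
}

.glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# -- image-domain 3x3 convolution block ------------------------------------

.shift2 <- function(x, dy, dx) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys - dy, xs - dx] <- x[ys, xs]
  out
}

# cross-correlation with 3x3 kernels, zero padding; x: (h, w, cin),
# W: (3, 3, cin, cout), b: length cout
.conv3_forward <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  out <- array(rep(b, each = h * w), c(h, w, cout))
  for (o in seq_len(cout)) for (ci in seq_len(cin)) {
    for (dy in -1:1) for (dx in -1:1) {
      wk <- W[dy + 2, dx + 2, ci, o]
      if (wk != 0) out[, , o] <- out[, , o] + wk * .shift2(x[, , ci], dy, dx)
    }
  }
  out
}

# gradients of the conv layer; g: (h, w, cout)
.conv3_backward <- function(x, W, g) {
  cin <- dim(W)[3]; cout <- dim(W)[4]
  gW <- array(0, dim(W))
  gb <- numeric(cout)
  gx <- array(0, dim(x))
  for (o in seq_len(cout)) {
    gb[o] <- sum(g[, , o])
    for (ci in seq_len(cin)) for (dy in -1:1) for (dx in -1:1) {
      gW[dy + 2, dx + 2, ci, o] <- sum(.shift2(x[, , ci], dy, dx) * g[, , o])
      gx[, , ci] <- gx[, , ci] +
        W[dy + 2, dx + 2, ci, o] * .shift2(g[, , o], -dy, -dx)
    }
  }
  list(W = gW, b = gb, x = gx)
}

#' Assemble a hierarchical reconstruction network
#'
#' Builds the full pipeline: a sinogram-domain filter layer (a learnable 1D
#' convolution along the radial coordinate with kernel length `N_r`, shared
#' across angles - the learnable analog of the ramp filter), one
#' sparse-connection layer per stage transition of the schedule (linear
#' activation), a fixed reshape of the final stage (`N_t` = image size,
#' `N_theta = 1`) into the image plane at angle zero (depth becomes the image
#' row, radius the column), and optionally an image-domain convolution block
#' (3x3 kernels, ReLU on the hidden layers) used in nonlinear mode. The
#' convolution block is a residual correction head: its output is added to
#' the sparse-chain image, so an untrained block perturbs rather than
#' replaces the linear reconstruction.
#'
#' Sparse-connection weights are initialized to all ones; filter and
#' convolution kernels use Glorot uniform initialization; convolution biases
#' start at zero.
#'
#' @param schedule A [plan_schedule()] result.
#' @param mode `"linear"` (no nonlinear activation anywhere; the network is a
#'   single linear operator) or `"nonlinear"` (enables the convolution
#'   block's ReLU units).
#' @param conv_block Include the image-domain convolution block. Only allowed
#'   in nonlinear mode; default follows the mode.
#' @param extents Sparse neighborhood extents `c(depths, angles, radial)`.
#' @param anchor Neighborhood anchor rule, as in [map_center()].
#' @param conv_channels Hidden channel count of the convolution block.
#' @param conv_layers Number of convolution layers (default 4).
#' @param seed Seed for the random initializations.
#' @return An object of class `hier_net`.
#' @export
build_network <- function(schedule, mode = c("linear", "nonlinear"),
                          conv_block = NULL, extents = c(3L, 5L, 3L),
                          anchor = c("geometric", "proportional"),
                          conv_channels = 8L, conv_layers = 4L, seed = 1L) {
  stopifnot(inherits(schedule, "stage_schedule"))
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  if (is.null(conv_block)) conv_block <- mode == "nonlinear"
  if (conv_block && mode == "linear") {
    stop("build_network: the convolution block carries ReLU units and ",
         "requires nonlinear mode")
  }
  st <- schedule$stages
  layers <- lapply(seq_len(schedule$n_stages), function(i) {
    sparse_layer(build_pattern(st[[i]], st[[i + 1]], extents, anchor = anchor))
  })
  n_r <- schedule$n_radial
  net <- with_seed(seed, {
    filter_kernel <- .glorot(n_r, n_r, n_r)
    conv <- NULL
    if (conv_block) {
      ch <- c(1L, rep(as.integer(conv_channels), conv_layers - 1L), 1L)
      conv <- list(W = lapply(seq_len(conv_layers), function(i) {
        array(.glorot(9 * ch[i] * ch[i + 1], 9 * ch[i], 9 * ch[i + 1]),
              c(3, 3, ch[i], ch[i + 1]))
      }), b = lapply(seq_len(conv_layers), function(i) numeric(ch[i + 1])))
    }
    list(filter_kernel = filter_kernel, conv = conv)
  })
  structure(list(schedule = schedule, mode = mode,
                 extents = as.integer(extents), anchor = anchor,
                 filter_kernel = net$filter_kernel, layers = layers,
                 conv = net$conv),
            class = "hier_net")
}

#' @rawNamespace S3method(print, hier_net)
print.hier_net <- function(x, ...) {
  cat(sprintf("<hier_net> %d sparse stages, mode = %s, conv block = %s\n",
              length(x$layers), x$mode, !is.null(x$conv)))
  cp <- count_params(x)
  cat(sprintf("  trainable parameters: %s (sparse: %s)\n",
              format(cp$total, big.mark = ","),
              format(cp$sparse_total, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Per-layer and total counts of trainable weights. For a schedule, counts
#' the sparse-connection weights of every stage transition (one scalar per
#' stored connection; sparse layers have no bias terms) via the factorized
#' per-dimension neighborhood counts, without materializing the patterns.
#' For a network, filter and convolution parameters are included in the
#' total as well. The report also gives the fully connected equivalent
#' (input size times output size of the whole transform) and the sparse to
#' dense ratio.
#'
#' @param x A `stage_schedule` or `hier_net`.
#' @param extents Neighborhood extents (schedule method only).
#' @param anchor Anchor rule, as in [map_center()] (schedule method only).
#' @param ... Unused.
#' @return A list with `per_layer` (data frame), `sparse_total`, `total`,
#'   `dense_equivalent`, and `ratio`.
#' @export
count_params <- function(x, ...) UseMethod("count_params")

#' @rdname count_params
#' @export
count_params.stage_schedule <- function(x, extents = c(3L, 5L, 3L),
                                        anchor = c("geometric",
                                                   "proportional"), ...) {
  anchor <- match.arg(anchor)
  st <- x$stages
  counts <- vapply(seq_len(x$n_stages), function(i) {
    count_connections(st[[i]], st[[i + 1]], extents, anchor = anchor)
  }, numeric(1))
  per <- data.frame(layer = paste0("L", seq_len(x$n_stages)),
                    parameters = counts)
  n_in <- as.numeric(st[[1]]$n_theta) * st[[1]]$n_r
  n_out <- as.numeric(st[[length(st)]]$n_t) * st[[length(st)]]$n_r
  dense <- n_in * n_out
  list(per_layer = per, sparse_total = sum(counts), total = sum(counts),
       dense_equivalent = dense, ratio = sum(counts) / dense)
}

#' @rdname count_params
#' @export
count_params.hier_net <- function(x, ...) {
  base <- count_params(x$schedule, extents = x$extents, anchor = x$anchor)
  extra <- data.frame(layer = "filter",
                      parameters = length(x$filter_kernel))
  if (!is.null(x$conv)) {
    extra <- rbind(extra, data.frame(
      layer = paste0("conv", seq_along(x$conv$W)),
      parameters = vapply(seq_along(x$conv$W), function(i) {
        length(x$conv$W[[i]]) + length(x$conv$b[[i]])
      }, numeric(1))))
  }
  base$per_layer <- rbind(extra[1, , drop = FALSE], base$per_layer,
                          if (nrow(extra) > 1) extra[-1, , drop = FALSE])
  base$total <- sum(base$per_layer$parameters)
  base
}

# full forward pass; keeps every intermediate needed for backpropagation
.net_forward_full <- function(net, values) {
  sc <- net$schedule
  K <- .filter_matrix(net$filter_kernel)
  filtered <- values %*% K                       # (n_theta, n_r)
  x <- as.vector(filtered)                       # stage-0 vec (t fastest)
  stage_out <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    x <- as.numeric(net$layers[[i]]$W %*% x)
    stage_out[[i]] <- x
  }
  n <- sc$image_size
  img <- matrix(x, n, n)                         # rows = depth = y, cols = r = x
  conv_cache <- NULL
  if (!is.null(net$conv) && net$mode == "nonlinear") {
    nl <- length(net$conv$W)
    acts <- vector("list", nl + 1)
    acts[[1]] <- array(img, c(n, n, 1))
    masks <- vector("list", nl)
    for (i in seq_len(nl)) {
      z <- .conv3_forward(acts[[i]], net$conv$W[[i]], net$conv$b[[i]])
      if (i < nl) {                              # ReLU on hidden layers
        masks[[i]] <- z > 0
        z <- z * masks[[i]]
      }
      acts[[i + 1]] <- z
    }
    conv_cache <- list(acts = acts, masks = masks)
    img <- img + acts[[nl + 1]][, , 1]   # residual correction head
  }
  list(image = img, filtered = filtered, stage_out = stage_out,
       conv_cache = conv_cache)
}

#' Run a network forward
#'
#' @param net A [build_network()] result.
#' @param sino A [sinogram()] or a `(N_theta, N_r)` value matrix matching the
#'   schedule's level-0 layout.
#' @param intermediates Also return each sparse stage's output as a
#'   [partial_stack()] (the per-stage partial images).
#' @return An [image_grid()] (fov from the schedule), or - with
#'   `intermediates = TRUE` - a list with `image` and `stages`.
#' @export
net_forward <- function(net, sino, intermediates = FALSE) {
  stopifnot(inherits(net, "hier_net"))
  values <- if (inherits(sino, "sinogram")) sino$values else as.matrix(sino)
  sc <- net$schedule
  s0 <- sc$stages[[1]]
  if (!all(dim(values) == c(s0$n_theta, s0$n_r))) {
    stop("net_forward: sinogram shape does not match the schedule")
  }
  fw <- .net_forward_full(net, values)
  img <- image_grid(sc$image_size, sc$image_size, sc$fov, values = fw$image)
  if (!intermediates) return(img)
  stages <- lapply(seq_along(fw$stage_out), function(i) {
    st <- sc$stages[[i + 1]]
    partial_stack(array(fw$stage_out[[i]], c(st$n_t, st$n_theta, st$n_r)), st)
  })
  list(image = img, stages = stages)
}

#' Probe a network with intermediate-domain impulses
#'
#' Feeds unit impulses at the given indices of the input of one sparse stage
#' and propagates them through the remaining layers; the image-domain
#' response shows what each partial line integral looks like in the image
#' (a short depth segment; the elementary reconstruction step is
#' local-to-local).
#'
#' @param net A `hier_net`.
#' @param layer Index of the sparse stage to inject into (1-based; the
#'   impulse enters that stage's input).
#' @param points Integer matrix with rows `(t, theta, r)` (1-based indices in
#'   the input stage of `layer`), or a single length-3 vector.
#' @param apply_conv Propagate through the convolution block when present.
#' @return An [image_grid()] with the summed image-domain response.
#' @export
impulse_probe <- function(net, layer, points, apply_conv = FALSE) {
  stopifnot(inherits(net, "hier_net"))
  if (layer < 1 || layer > length(net$layers)) {
    stop("impulse_probe: invalid layer")
  }
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  st <- net$schedule$stages[[layer]]        # input stage of `layer`
  x <- array(0, c(st$n_t, st$n_theta, st$n_r))
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    if (any(p < 1) || p[1] > st$n_t || p[2] > st$n_theta || p[3] > st$n_r) {
      stop("impulse_probe: point index out of range")
    }
    x[p[1], p[2], p[3]] <- 1
  }
  v <- as.vector(x)
  for (i in layer:length(net$layers)) {
    v <- as.numeric(net$layers[[i]]$W %*% v)
  }
  n <- net$schedule$image_size
  img <- matrix(v, n, n)
  if (apply_conv && !is.null(net$conv) && net$mode == "nonlinear") {
    a <- array(img, c(n, n, 1))
    nl <- length(net$conv$W)
    for (i in seq_len(nl)) {
      a <- .conv3_forward(a, net$conv$W[[i]], net$conv$b[[i]])
      if (i < nl) a <- a * (a > 0)
    }
    img <- img + a[, , 1]
  }
  image_grid(n, n, net$schedule$fov, values = img)
}

#' Analytic hierarchical-backprojection parameterization
#'
#' Sets the network weights to the closed-form operator that the sparse
#' architecture is designed to express: the filter kernel becomes the
#' discrete ramp (Ram-Lak) kernel scaled by the backprojection weight
#' `pi / N_theta`, and each sparse layer implements a partition-of-angles
#' backprojection step - every input view angle contributes only to its
#' nearest output frame, with bilinear interpolation weights at the rotated
#' physical position. The composed network then performs filtered
#' backprojection accumulated hierarchically, which is useful as a
#' correctness reference for the architecture, for impulse-response
#' demonstrations, and as a baseline a trained network can be compared
#' against. Requires geometric anchoring.
#'
#' @param net A [build_network()] result with `anchor = "geometric"`.
#' @return The network with analytic weights.
#' @export
init_backprojection <- function(net) {
  stopifnot(inherits(net, "hier_net"))
  if (net$anchor != "geometric") {
    stop("init_backprojection: requires geometric anchoring")
  }
  sc <- net$schedule
  n_r <- sc$n_radial
  dr <- sc$fov / n_r
  rp <- .ramp_profile(n_r, dr)
  spat <- Re(stats::fft(rp$h, inverse = TRUE)) / rp$n_pad
  c0 <- n_r %/% 2L + 1L
  kern <- numeric(n_r)
  for (j in seq_len(n_r)) {
    lag <- j - c0
    kern[j] <- if (lag >= 0) spat[lag + 1] else spat[rp$n_pad + 1 + lag]
  }
  wt0 <- (sc$angle_range * pi / 180) / sc$n_angles *
    min(1, 180 / sc$angle_range)
  net$filter_kernel <- kern * wt0

  tri <- function(d) pmax(0, 1 - abs(d))
  for (L in seq_along(net$layers)) {
    pat <- net$layers[[L]]$pattern
    si <- pat$stage_in
    so <- pat$stage_out
    th_in <- stage_angles(si)
    th_out <- stage_angles(so)
    part <- .nearest_angle(si, so)     # each input angle's parent frame
    nt_i <- si$n_t; na_i <- si$n_theta
    nt_o <- so$n_t; na_o <- so$n_theta
    ii <- pat$in_idx - 1L
    oo <- pat$out_idx - 1L
    it <- ii %% nt_i + 1L
    ia <- (ii %/% nt_i) %% na_i + 1L
    ir <- ii %/% (nt_i * na_i) + 1L
    ot <- oo %% nt_o + 1L
    ob <- (oo %/% nt_o) %% na_o + 1L
    orr <- oo %/% (nt_o * na_o) + 1L
    delta <- th_out[ob] - th_in[ia]
    tpr <- stage_depths(so)[ot]
    rpr <- stage_offsets(so)[orr]
    t_in <- rpr * sin(delta) + tpr * cos(delta)
    r_in <- rpr * cos(delta) - tpr * sin(delta)
    pt <- (t_in + si$fov / 2) / si$alpha + 0.5
    pr <- r_in / (si$fov / si$n_r) + si$n_r / 2 + 0.5
    wt <- if (nt_i == 1L) 1 else tri(pt - it)   # no depth weighting at level 0
    w <- as.numeric(part[ia] == ob) * wt * tri(pr - ir)
    net$layers[[L]] <- set_layer_weights(net$layers[[L]], w)
  }
  net
}
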