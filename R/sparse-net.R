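# anchor of one coordinate under proportional bin-center rescaling,
# rounding halves toward the lower index; 1-based in and out
.dim_anchor <- function(i, n_in, n_out) {
  as.integer(pmin(pmax(ceiling((i - 0.5) * n_out / n_in), 1), n_out))
}

# per-dimension (input index, output index) pairs of the neighborhood:
# a block of `extent` output bins around the anchor, clipped at the
# boundaries, or wrapped periodically and capped at n_out distinct bins
.dim_pairs <- function(n_in, n_out, extent, wrap = FALSE) {
  half <- (extent - 1L) %/% 2L
  anchors <- .dim_anchor(seq_len(n_in), n_in, n_out)
  if (wrap) {
    # symmetric offsets, capped at n_out distinct angles (offsets are then
    # distinct modulo n_out, so no duplicate connections arise)
    off <- if (extent >= n_out) seq.int(0L, n_out - 1L) else seq.int(-half, half)
    ins <- rep(seq_len(n_in), each = length(off))
    outs <- (rep(anchors, each = length(off)) - 1L +
               rep.int(off, n_in)) %% n_out + 1L
    list(ins = ins, outs = as.integer(outs))
  } else {
    lo <- pmax(anchors - half, 1L)
    hi <- pmin(anchors + half, n_out)
    k <- hi - lo + 1L
    ins <- rep.int(seq_len(n_in), k)
    outs <- unlist(lapply(seq_len(n_in), function(i) seq.int(lo[i], hi[i])),
                   use.names = FALSE)
    list(ins = ins, outs = as.integer(outs))
  }
}

# number of connections per dimension without materializing them
.dim_count <- function(n_in, n_out, extent, wrap = FALSE) {
  half <- (extent - 1L) %/% 2L
  if (wrap) return(as.numeric(n_in) * min(extent, n_out))
  anchors <- .dim_anchor(seq_len(n_in), n_in, n_out)
  sum(pmin(anchors + half, n_out) - pmax(anchors - half, 1L) + 1)
}

# circular distance between angles within one period
.circ_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# nearest output angle index (1-based) for every input angle
.nearest_angle <- function(stage_in, stage_out) {
  th_in <- stage_angles(stage_in)
  th_out <- stage_angles(stage_out)
  period <- stage_in$angle_range * pi / 180
  vapply(th_in, function(th) {
    which.min(.circ_dist(th, th_out, period))
  }, integer(1))
}

# depth / radial bin index of a physical coordinate, halves rounded down
.t_index <- function(t, stage) {
  as.integer(pmin(pmax(ceiling((t + stage$fov / 2) / stage$alpha), 1),
                  stage$n_t))
}
.r_index <- function(r, stage) {
  dr <- stage$fov / stage$n_r
  as.integer(pmin(pmax(ceiling(r / dr + stage$n_r / 2), 1), stage$n_r))
}

#' Map an input index to its output-stage anchor
#'
#' The anchor is the center of the sparse-connection neighborhood in the
#' output stage. Two rules are available:
#'
#' * `"geometric"` (default): the input bin's physical center
#'   `u = r e_r(theta) + t e_t(theta)` is re-expressed in the frame of the
#'   nearest output angle, and the output depth/radial bins containing the
#'   rotated coordinates are taken. This realizes localized correspondence
#'   across the rotated `r`-`t` frames of consecutive stages (the elementary
#'   reconstruction step is local in physical space), and is what the
#'   assembled networks use.
#' * `"proportional"`: each coordinate is rescaled independently by
#'   bin-center alignment (input bin `i` of `N_in` goes to the output bin
#'   with the nearest center, halves rounded toward the lower index),
#'   ignoring the frame rotation. The two rules agree whenever the input and
#'   output frames are aligned.
#'
#' @param index Integer vector `c(t, theta, r)`, 1-based, valid in `stage_in`.
#' @param stage_in,stage_out Input and output [stage_spec()]s.
#' @param rule Anchor rule, see above.
#' @return Integer vector `c(t, theta, r)` of the anchor in `stage_out`.
#' @export
map_center <- function(index, stage_in, stage_out,
                       rule = c("geometric", "proportional")) {
  rule <- match.arg(rule)
  stopifnot(length(index) == 3)
  din <- c(stage_in$n_t, stage_in$n_theta, stage_in$n_r)
  dout <- c(stage_out$n_t, stage_out$n_theta, stage_out$n_r)
  if (any(index < 1) || any(index > din)) stop("map_center: index out of range")
  if (rule == "proportional") {
    return(vapply(1:3, function(d) .dim_anchor(index[d], din[d], dout[d]),
                  integer(1)))
  }
  b <- .nearest_angle(stage_in, stage_out)[index[2]]
  delta <- stage_angles(stage_in)[index[2]] - stage_angles(stage_out)[b]
  t_in <- stage_depths(stage_in)[index[1]]
  r_in <- stage_offsets(stage_in)[index[3]]
  tp <- r_in * sin(delta) + t_in * cos(delta)
  rp <- r_in * cos(delta) - t_in * sin(delta)
  c(.t_index(tp, stage_out), b, .r_index(rp, stage_out))
}

# geometric connection enumeration (gather form): every output neuron is
# connected from the d_theta nearest input angles; in each input frame the
# output cell's physical center is rotated into input coordinates and the
# clipped (d_t x d_r) block of input bins around the containing bin is
# connected. This is the tomosynthesis stencil: an output cell draws from
# the rays that pass through it at neighboring view angles, so the
# elementary depth-refinement step is representable with local weights.
# Each input neuron in turn feeds a compact set of output neurons (its
# bin's footprint in the neighboring output frames).
.geom_connections <- function(stage_in, stage_out, extents,
                              count_only = FALSE) {
  ht <- (extents[1] - 1L) %/% 2L
  ha <- (extents[2] - 1L) %/% 2L
  hr <- (extents[3] - 1L) %/% 2L
  th_in <- stage_angles(stage_in)
  th_out <- stage_angles(stage_out)
  near <- .nearest_angle(stage_out, stage_in)   # nearest input angle per output
  offs_a <- if (extents[2] >= stage_in$n_theta) {
    seq.int(0L, stage_in$n_theta - 1L)
  } else seq.int(-ha, ha)
  nt_i <- stage_in$n_t; na_i <- stage_in$n_theta; nr_i <- stage_in$n_r
  nt_o <- stage_out$n_t; na_o <- stage_out$n_theta; nr_o <- stage_out$n_r
  grid_t <- rep(stage_depths(stage_out), times = nr_o)    # t fastest
  grid_r <- rep(stage_offsets(stage_out), each = nt_o)
  gt_idx <- rep(seq_len(nt_o), times = nr_o)
  gr_idx <- rep(seq_len(nr_o), each = nt_o)
  total <- 0
  acc_i <- list(); acc_o <- list(); k <- 0L
  for (b in seq_len(na_o)) {
    base_out <- nt_o * (b - 1L)
    for (oo in offs_a) {
      a <- (near[b] - 1L + oo) %% na_i + 1L
      delta <- th_out[b] - th_in[a]
      at <- .t_index(grid_r * sin(delta) + grid_t * cos(delta), stage_in)
      ar <- .r_index(grid_r * cos(delta) - grid_t * sin(delta), stage_in)
      for (dt in seq.int(-ht, ht)) for (dr in seq.int(-hr, hr)) {
        it <- at + dt
        irr <- ar + dr
        ok <- it >= 1L & it <= nt_i & irr >= 1L & irr <= nr_i
        if (count_only) {
          total <- total + sum(ok)
        } else {
          idx <- which(ok)
          k <- k + 1L
          acc_i[[k]] <- it[idx] + nt_i * (a - 1L) + nt_i * na_i * (irr[idx] - 1L)
          acc_o[[k]] <- gt_idx[idx] + base_out + nt_o * na_o * (gr_idx[idx] - 1L)
        }
      }
    }
  }
  if (count_only) return(total)
  list(in_idx = unlist(acc_i, use.names = FALSE),
       out_idx = unlist(acc_o, use.names = FALSE))
}

#' Build the sparsity pattern of one hierarchical stage transition
#'
#' Builds the local connections of one sparse layer with neighborhood size
#' `extents` (depths x angles x radial bins, default `c(3, 5, 3)`). Under
#' the default geometric rule each output neuron gathers from its `d_theta`
#' nearest input view angles: the output cell's physical center is rotated
#' into each input frame and the clipped `d_t x d_r` block of input bins
#' around the containing bin is connected (the tomosynthesis stencil - an
#' output cell draws from the rays passing through it at neighboring
#' angles; each input neuron correspondingly feeds a compact footprint of
#' output neurons). Under the proportional rule every input neuron is
#' connected to the per-dimension cross product of index blocks centered at
#' its [map_center()] anchor. Blocks are clipped (not wrapped) at the depth
#' and radial boundaries; the angular neighborhood wraps periodically (the
#' projection angle is periodic) and is capped at the number of distinct
#' angles. Expanding the extents to the full grid recovers a fully
#' connected layer.
#'
#' @param stage_in,stage_out Input and output [stage_spec()]s.
#' @param extents Odd positive integers `c(d_t, d_theta, d_r)`.
#' @param anchor Anchor rule, as in [map_center()].
#' @return An object of class `sparsity_pattern` with 1-based linear index
#'   vectors `in_idx`, `out_idx` (column-major `(N_t, N_theta, N_r)` order),
#'   the stage specs, extents, anchor rule, and sizes `n_in`, `n_out`.
#' @export
build_pattern <- function(stage_in, stage_out, extents = c(3L, 5L, 3L),
                          anchor = c("geometric", "proportional")) {
  stopifnot(inherits(stage_in, "stage_spec"), inherits(stage_out, "stage_spec"))
  anchor <- match.arg(anchor)
  extents <- as.integer(extents)
  if (any(extents < 1) || any(extents %% 2L == 0L)) {
    stop("build_pattern: extents must be odd positive integers")
  }
  nin <- c(stage_in$n_t, stage_in$n_theta, stage_in$n_r)
  nout <- c(stage_out$n_t, stage_out$n_theta, stage_out$n_r)
  if (anchor == "geometric") {
    conn <- .geom_connections(stage_in, stage_out, extents)
    in_idx <- conn$in_idx
    out_idx <- conn$out_idx
  } else {
    tp <- .dim_pairs(stage_in$n_t, stage_out$n_t, extents[1], wrap = FALSE)
    ap <- .dim_pairs(stage_in$n_theta, stage_out$n_theta, extents[2],
                     wrap = TRUE)
    rp <- .dim_pairs(stage_in$n_r, stage_out$n_r, extents[3], wrap = FALSE)
    st <- length(tp$ins); sa <- length(ap$ins); sr <- length(rp$ins)
    it <- rep.int(seq_len(st), sa * sr)
    ia <- rep.int(rep(seq_len(sa), each = st), sr)
    ir <- rep(seq_len(sr), each = st * sa)
    in_idx <- tp$ins[it] +
      nin[1] * (ap$ins[ia] - 1L) +
      nin[1] * nin[2] * (rp$ins[ir] - 1L)
    out_idx <- tp$outs[it] +
      nout[1] * (ap$outs[ia] - 1L) +
      nout[1] * nout[2] * (rp$outs[ir] - 1L)
  }
  structure(list(stage_in = stage_in, stage_out = stage_out,
                 extents = extents, anchor = anchor,
                 in_idx = as.integer(in_idx), out_idx = as.integer(out_idx),
                 n_in = prod(nin), n_out = prod(nout)),
            class = "sparsity_pattern")
}

#' @rawNamespace S3method(print, sparsity_pattern)
print.sparsity_pattern <- function(x, ...) {
  cat(sprintf(
    "<sparsity_pattern> %d -> %d neurons, %d connections (%.2f%% dense)\n",
    x$n_in, x$n_out, length(x$in_idx),
    100 * length(x$in_idx) / (as.numeric(x$n_in) * x$n_out)))
  invisible(x)
}

#' Count sparse connections of a stage transition without building it
#'
#' Under the proportional rule the neighborhood factorizes over dimensions
#' and the count is a product of per-dimension counts; under the geometric
#' rule the clipped blocks are enumerated without storing them. Either way
#' the result agrees exactly with the length of the materialized
#' [build_pattern()] connection list.
#'
#' @inheritParams build_pattern
#' @return Connection count as a double (counts exceed integer range for
#'   full-size configurations only in the dense equivalents, but doubles are
#'   used throughout for safety).
#' @export
count_connections <- function(stage_in, stage_out, extents = c(3L, 5L, 3L),
                              anchor = c("geometric", "proportional")) {
  anchor <- match.arg(anchor)
  if (anchor == "geometric") {
    return(.geom_connections(stage_in, stage_out, as.integer(extents),
                             count_only = TRUE))
  }
  .dim_count(stage_in$n_t, stage_out$n_t, extents[1]) *
    .dim_count(stage_in$n_theta, stage_out$n_theta, extents[2], wrap = TRUE) *
    .dim_count(stage_in$n_r, stage_out$n_r, extents[3])
}

# one sparse-connection layer: pattern, per-connection weights, and the
# cached dgCMatrix whose storage order is recorded in `ord`
sparse_layer <- function(pattern, weights = NULL) {
  n <- length(pattern$in_idx)
  if (is.null(weights)) weights <- rep(1, n)   # all-ones initialization
  stopifnot(length(weights) == n)
  W <- Matrix::sparseMatrix(i = pattern$out_idx, j = pattern$in_idx,
                            x = seq_len(n),
                            dims = c(pattern$n_out, pattern$n_in))
  if (length(W@x) != n) stop("sparse_layer: duplicate connections in pattern")
  ord <- as.integer(W@x)
  W@x <- weights[ord]
  structure(list(pattern = pattern, weights = weights, W = W, ord = ord),
            class = "sparse_layer")
}

set_layer_weights <- function(layer, weights) {
  layer$weights <- weights
  layer$W@x <- weights[layer$ord]
  layer
}

#' Apply a sparse-connection layer
#'
#' Forward operator of the sparse layer: the product of the sparse weight
#' matrix and the input data,
#' `output[o] = sum over connected i of w(i, o) * input[i]`.
#' The corresponding backward operator (gradient with respect to the input)
#' is the product with the transposed sparse matrix; see
#' [sparse_apply_transpose()].
#'
#' @param pattern A [build_pattern()] result.
#' @param weights Numeric vector, one trainable scalar per connection (no
#'   bias terms).
#' @param data Numeric array shaped like the input stage
#'   (`N_t x N_theta x N_r`), or a vector of that length.
#' @return Numeric array shaped like the output stage.
#' @export
sparse_apply <- function(pattern, weights, data) {
  stopifnot(inherits(pattern, "sparsity_pattern"))
  x <- as.vector(data)
  if (length(x) != pattern$n_in) stop("sparse_apply: input shape mismatch")
  layer <- sparse_layer(pattern, weights)
  y <- as.numeric(layer$W %*% x)
  so <- pattern$stage_out
  array(y, c(so$n_t, so$n_theta, so$n_r))
}

#' @rdname sparse_apply
#' @param grad Numeric array shaped like the output stage (a backpropagated
#'   gradient).
#' @export
sparse_apply_transpose <- function(pattern, weights, grad) {
  stopifnot(inherits(pattern, "sparsity_pattern"))
  g <- as.vector(grad)
  if (length(g) != pattern$n_out) stop("sparse_apply_transpose: shape mismatch")
  layer <- sparse_layer(pattern, weights)
  x <- as.numeric(Matrix::t(layer$W) %*% g)
  si <- pattern$stage_in
  array(x, c(si$n_t, si$n_theta, si$n_r))
}
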