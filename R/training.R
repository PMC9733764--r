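#' Training configuration
#'
#' Loss is mean squared error and the optimizer is stochastic gradient
#' descent on minibatches; both are fixed by the training protocol. In
#' linear mode each update steps along the stochastic gradient of one layer
#' by the exactly minimizing step size (the loss restricted to a single
#' layer is quadratic), and `lr`/`lr_filter` act as damping factors on that
#' step (1 = full step, 0 = frozen). Convolution layers (nonlinear mode)
#' use a backtracking step size starting from `lr_conv`.
#'
#' @param batch_size Minibatch size (default 20).
#' @param lr Damping factor for sparse-connection weight steps.
#' @param lr_filter Damping factor for sinogram-filter kernel steps.
#' @param lr_conv Initial backtracking rate for convolution layers.
#' @param epochs_pretrain Epochs per stage during stage-wise pretraining.
#' @param epochs Epochs for end-to-end training.
#' @param seed Seed controlling batch sampling and layer selection.
#' @param mode `"linear"` for noise training (no nonlinear activations) or
#'   `"nonlinear"` for refinement with the convolution block.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 20L, lr = 1, lr_filter = 1,
                            lr_conv = 0.05, epochs_pretrain = 150L,
                            epochs = 300L, seed = 1L,
                            mode = c("linear", "nonlinear")) {
  stopifnot(batch_size >= 1, lr >= 0, lr_filter >= 0, lr_conv >= 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_filter = lr_filter, lr_conv = lr_conv,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 mode = match.arg(mode), loss = "mse", optimizer = "sgd"),
            class = "training_config")
}

#' Generate a noise-pattern training set
#'
#' Draws `n` independent white Gaussian noise images (one standard-normal
#' value per pixel) and pairs each with its exact forward projection. Such
#' pairs encode the tomographic transform itself, free of any image prior,
#' and are the training data for learning a linear inverse operator.
#'
#' @param n Number of realizations (default 200).
#' @param grid An [image_grid()] defining the image raster.
#' @param geom A [projection_geometry()] for the projections.
#' @param seed Integer seed; the dataset is a pure function of the seed.
#' @return A list of `n` pairs, each `list(image, sino)` of value matrices,
#'   with the grid and geometry attached as attributes.
#' @export
gen_noise_dataset <- function(n = 200L, grid, geom, seed = 1L) {
  stopifnot(n >= 1, inherits(grid, "image_grid"),
            inherits(geom, "projection_geometry"))
  A <- radon_operator(grid, geom)
  pairs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      img <- matrix(rnorm(grid$n_x * grid$n_y), grid$n_y, grid$n_x)
      sino <- matrix(as.numeric(A %*% as.vector(img)),
                     geom$n_angles, geom$n_channels)
      list(image = img, sino = sino)
    })
  })
  attr(pairs, "grid") <- grid
  attr(pairs, "geom") <- geom
  pairs
}

#' Intermediate training labels for every hierarchical stage
#'
#' For each training pair and each stage `L = 1..N`, computes the target
#' partial-line-integral stack. The default method reconstructs the full
#' sinogram by filtered backprojection onto the stage's anisotropic grid at
#' every stage angle ([fbp_anisotropic()]); the alternative reprojects the
#' image over partial line integrals ([partial_line_integrals()]). Both are
#' stored as mean attenuation, the final-stage label being the FBP image
#' (respectively the image itself).
#'
#' @param pairs A [gen_noise_dataset()] result (or any list of
#'   `list(image, sino)` value-matrix pairs under the schedule's geometry).
#' @param schedule A [plan_schedule()] result.
#' @param method `"fbp"` (analytic labels from the measured data) or
#'   `"reprojection"` (labels from the ground-truth image).
#' @return A list with `stages`: one `(stage size) x n_pairs` matrix per
#'   sparse stage (columns are vectorized `(N_t, N_theta, N_r)` stacks),
#'   plus `schedule` and `method`.
#' @export
make_intermediate_labels <- function(pairs, schedule,
                                     method = c("fbp", "reprojection")) {
  method <- match.arg(method)
  stopifnot(inherits(schedule, "stage_schedule"))
  geom <- projection_geometry(schedule$n_radial, schedule$n_angles,
                              fov = schedule$fov,
                              angle_range = schedule$angle_range)
  grid <- image_grid(schedule$image_size, fov = schedule$fov)
  stages <- vector("list", schedule$n_stages)
  for (L in seq_len(schedule$n_stages)) {
    st <- schedule$stages[[L + 1]]
    lab <- matrix(0, st$n_t * st$n_theta * st$n_r, length(pairs))
    for (p in seq_along(pairs)) {
      if (method == "fbp") {
        sino <- sinogram(pairs[[p]]$sino, geom)
        q <- array(0, c(st$n_t, st$n_theta, st$n_r))
        for (a in seq_len(st$n_theta)) {
          q[, a, ] <- fbp_anisotropic(sino, st, a)
        }
      } else {
        img <- image_grid(grid$n_x, grid$n_y, grid$fov,
                          values = pairs[[p]]$image)
        q <- partial_line_integrals(img, st)$values
      }
      lab[, p] <- as.vector(q)
    }
    stages[[L]] <- lab
  }
  list(stages = stages, schedule = schedule, method = method)
}

# -- internal SGD machinery -------------------------------------------------

# MSE over all elements; `pred` and `target` are (n_out x batch) matrices
.mse <- function(pred, target) mean((pred - target)^2)

# cached index map for the filter-kernel gradient
.filter_grad_index <- function(n) {
  c0 <- n %/% 2L + 1L
  d <- outer(seq_len(n), seq_len(n), function(m, j) j - m + c0)
  ok <- d >= 1 & d <= n
  list(ok = ok, idx = d[ok])
}

# gradient of the filter kernel from input sinograms and gradients w.r.t.
# the filtered sinograms (both lists of (n_theta x n_r) matrices)
.filter_kernel_grad <- function(S_list, G_list, fidx) {
  n <- ncol(S_list[[1]])
  M <- matrix(0, n, n)
  for (b in seq_along(S_list)) M <- M + crossprod(S_list[[b]], G_list[[b]])
  gk <- numeric(n)
  acc <- rowsum(M[fidx$ok], fidx$idx)
  gk[as.integer(rownames(acc))] <- acc
  gk
}

# per-connection gradient of one sparse layer: X (n_in x B), D (n_out x B)
.sparse_weight_grad <- function(pattern, X, D) {
  rowSums(X[pattern$in_idx, , drop = FALSE] * D[pattern$out_idx, , drop = FALSE])
}

# forward a batch of sinogram matrices through the full network, keeping
# every intermediate needed for backpropagation
.batch_forward <- function(net, S_list) {
  B <- length(S_list)
  K <- .filter_matrix(net$filter_kernel)
  Filt <- vapply(S_list, function(S) as.vector(S %*% K),
                 numeric(length(S_list[[1]])))
  Filt <- matrix(Filt, ncol = B)
  stage_mats <- vector("list", length(net$layers))
  X <- Filt
  for (i in seq_along(net$layers)) {
    X <- as.matrix(net$layers[[i]]$W %*% X)
    stage_mats[[i]] <- X
  }
  n <- net$schedule$image_size
  conv_caches <- NULL
  pred <- X
  if (!is.null(net$conv) && net$mode == "nonlinear") {
    nl <- length(net$conv$W)
    conv_caches <- vector("list", B)
    pred <- matrix(0, n * n, B)
    for (b in seq_len(B)) {
      acts <- vector("list", nl + 1)
      masks <- vector("list", nl)
      acts[[1]] <- array(X[, b], c(n, n, 1))
      for (i in seq_len(nl)) {
        z <- .conv3_forward(acts[[i]], net$conv$W[[i]], net$conv$b[[i]])
        if (i < nl) {
          masks[[i]] <- z > 0
          z <- z * masks[[i]]
        }
        acts[[i + 1]] <- z
      }
      conv_caches[[b]] <- list(acts = acts, masks = masks)
      pred[, b] <- X[, b] + acts[[nl + 1]][, , 1]   # residual correction
    }
  }
  list(filtered = Filt, stage_mats = stage_mats, conv_caches = conv_caches,
       pred = pred)
}

# backpropagate D (gradient w.r.t. final image, n^2 x B) through the conv
# block for every sample; returns gradient w.r.t. the sparse-chain image and
# accumulated conv parameter gradients
.conv_backward_batch <- function(net, fw, D) {
  nl <- length(net$conv$W)
  B <- ncol(D)
  n <- net$schedule$image_size
  gW <- lapply(net$conv$W, function(w) array(0, dim(w)))
  gb <- lapply(net$conv$b, function(b) numeric(length(b)))
  Dimg <- matrix(0, n * n, B)
  for (b in seq_len(B)) {
    cc <- fw$conv_caches[[b]]
    g <- array(D[, b], c(n, n, 1))
    for (i in rev(seq_len(nl))) {
      bk <- .conv3_backward(cc$acts[[i]], net$conv$W[[i]], g)
      gW[[i]] <- gW[[i]] + bk$W
      gb[[i]] <- gb[[i]] + bk$b
      g <- bk$x
      if (i > 1) g <- g * cc$masks[[i - 1]]
    }
    Dimg[, b] <- D[, b] + g[, , 1]   # residual path
  }
  list(gW = gW, gb = gb, Dimg = Dimg)
}

# loss, gradient, and forward cache of one named layer under the end-to-end MSE
.layer_loss_grad <- function(net, which_layer, S_list, Ymat, fidx) {
  fw0 <- fw <- .batch_forward(net, S_list)
  B <- ncol(Ymat)
  D <- 2 * (fw$pred - Ymat) / (nrow(Ymat) * B)   # dLoss/dPred
  loss <- .mse(fw$pred, Ymat)
  if (!is.finite(loss)) {
    stop("training diverged: non-finite loss (layer = ", which_layer, ")")
  }
  kind <- sub("[0-9]+$", "", which_layer)
  num <- suppressWarnings(as.integer(sub("^[a-z]+", "", which_layer)))

  if (!is.null(net$conv) && net$mode == "nonlinear") {
    cb <- .conv_backward_batch(net, fw, D)
    if (kind == "conv") {
      return(list(loss = loss, fw = fw0,
                  grad = list(W = cb$gW[[num]], b = cb$gb[[num]])))
    }
    D <- cb$Dimg
  }
  nL <- length(net$layers)
  if (kind == "sparse") {
    if (num < nL) {
      for (i in rev(seq.int(num + 1L, nL))) {
        D <- as.matrix(Matrix::t(net$layers[[i]]$W) %*% D)
      }
    }
    Xin <- if (num == 1L) fw$filtered else fw$stage_mats[[num - 1L]]
    list(loss = loss, fw = fw0,
         grad = .sparse_weight_grad(net$layers[[num]]$pattern, Xin, D))
  } else if (kind == "filter") {
    for (i in rev(seq_len(nL))) {
      D <- as.matrix(Matrix::t(net$layers[[i]]$W) %*% D)
    }
    s0 <- net$schedule$stages[[1]]
    G_list <- lapply(seq_len(ncol(D)), function(b) {
      matrix(D[, b], s0$n_theta, s0$n_r)
    })
    list(loss = loss, fw = fw0,
         grad = .filter_kernel_grad(S_list, G_list, fidx))
  } else {
    stop("unknown layer: ", which_layer)
  }
}

# sensitivity of the batch predictions to a unit step along `grad` in one
# linear-mode layer (predictions are linear in any single layer's weights)
.step_sensitivity <- function(net, kind, num, grad, fw, S_list) {
  nL <- length(net$layers)
  if (kind == "filter") {
    Kd <- .filter_matrix(grad)
    X <- vapply(S_list, function(S) as.vector(S %*% Kd),
                numeric(length(S_list[[1]])))
    X <- matrix(X, ncol = length(S_list))
    for (i in seq_len(nL)) X <- as.matrix(net$layers[[i]]$W %*% X)
  } else {
    ly <- net$layers[[num]]
    Wd <- ly$W
    Wd@x <- grad[ly$ord]
    Xin <- if (num == 1L) fw$filtered else fw$stage_mats[[num - 1L]]
    X <- as.matrix(Wd %*% Xin)
    if (num < nL) {
      for (i in seq.int(num + 1L, nL)) X <- as.matrix(net$layers[[i]]$W %*% X)
    }
  }
  X
}

# apply a gradient step of size lr to one named layer
.apply_step <- function(net, which_layer, grad, lr) {
  kind <- sub("[0-9]+$", "", which_layer)
  num <- suppressWarnings(as.integer(sub("^[a-z]+", "", which_layer)))
  if (kind == "sparse") {
    ly <- net$layers[[num]]
    net$layers[[num]] <- set_layer_weights(ly, ly$weights - lr * grad)
  } else if (kind == "filter") {
    net$filter_kernel <- net$filter_kernel - lr * grad
  } else if (kind == "conv") {
    net$conv$W[[num]] <- net$conv$W[[num]] - lr * grad$W
    net$conv$b[[num]] <- net$conv$b[[num]] - lr * grad$b
  }
  net
}

.batch_loss <- function(net, S_list, Ymat) {
  .mse(.batch_forward(net, S_list)$pred, Ymat)
}

# one stochastic gradient step on a single layer. In linear mode the batch
# loss restricted to one layer is an exact quadratic, so the minimizing step
# size along the gradient has a closed form; the configured rate acts as a
# damping factor on that step. Where ReLU units make the restriction
# non-quadratic (convolution block active), a backtracking step size is used
# instead: halve while the batch loss worsens, grow gently (bounded) after a
# clean acceptance.
.sgd_step <- function(net, which_layer, S_list, Ymat, lr, fidx,
                      max_backtrack = 12L, lr_cap = Inf) {
  lg <- .layer_loss_grad(net, which_layer, S_list, Ymat, fidx)
  if (lr <= 0) return(list(net = net, loss = lg$loss, lr = lr))
  kind <- sub("[0-9]+$", "", which_layer)
  num <- suppressWarnings(as.integer(sub("^[a-z]+", "", which_layer)))
  linear_path <- kind != "conv" &&
    (is.null(net$conv) || net$mode != "nonlinear")
  if (linear_path) {
    X <- .step_sensitivity(net, kind, num, lg$grad, lg$fw, S_list)
    denom <- sum(X^2)
    t_star <- if (denom > 0) lr * sum((lg$fw$pred - Ymat) * X) / denom else 0
    return(list(net = .apply_step(net, which_layer, lg$grad, t_star),
                loss = lg$loss, lr = lr))
  }
  tries <- 0L
  repeat {
    cand <- .apply_step(net, which_layer, lg$grad, lr)
    newloss <- .batch_loss(cand, S_list, Ymat)
    if (is.finite(newloss) && newloss <= lg$loss) break
    lr <- lr / 2
    tries <- tries + 1L
    if (tries >= max_backtrack) return(list(net = net, loss = lg$loss, lr = lr))
  }
  list(net = cand, loss = lg$loss,
       lr = if (tries == 0L) min(lr * 1.2, lr_cap) else lr)
}

# evaluate MSE of the network on a list of (sino, image) pairs
.eval_loss <- function(net, pairs) {
  S_list <- lapply(pairs, `[[`, "sino")
  Y <- vapply(pairs, function(p) as.vector(p$image),
              numeric(length(pairs[[1]]$image)))
  fw <- .batch_forward(net, S_list)
  .mse(fw$pred, matrix(Y, ncol = length(pairs)))
}

#' Stage-wise pretraining of the sparse layers
#'
#' Trains each sparse-connection layer individually with SGD on minibatches
#' of (previous-stage label, stage label) pairs under MSE loss, bringing the
#' all-ones initial weights to a sensible order of magnitude before
#' end-to-end training. The level-0 data are the measured sinograms
#' themselves, so the first sparse stage is pretrained jointly with the
#' sinogram filter layer on (sinogram, stage-1 label) pairs; later stages
#' are trained alone. Pretraining does not alter the end-to-end loss
#' definition.
#'
#' @param net A [build_network()] result.
#' @param pairs A [gen_noise_dataset()] result.
#' @param labels A [make_intermediate_labels()] result for the same pairs
#'   and schedule.
#' @param config A [training_config()].
#' @return The network with pretrained weights; the per-stage epoch-mean
#'   loss curves are attached as `net$pretrain_history` (a data frame with
#'   columns `stage`, `epoch`, `loss`).
#' @export
pretrain_stagewise <- function(net, pairs, labels, config = training_config()) {
  stopifnot(inherits(net, "hier_net"))
  nL <- length(net$layers)
  if (length(labels$stages) != nL) {
    stop("pretrain_stagewise: labels do not cover every stage")
  }
  n <- length(pairs)
  fidx <- .filter_grad_index(net$schedule$n_radial)
  hist <- list()
  with_seed(config$seed, {
    for (L in seq_len(nL)) {
      Y <- labels$stages[[L]]
      X <- if (L == 1L) NULL else labels$stages[[L - 1L]]
      iters_per_epoch <- max(1L, ceiling(n / config$batch_size))
      lr_sparse <- config$lr
      lr_filter <- config$lr_filter
      # a single-stage sub-network turns the stage-1 pretraining pair
      # (sinogram -> stage-1 label) into the standard engine's shape
      sub <- list(schedule = net$schedule, mode = "linear",
                  filter_kernel = net$filter_kernel,
                  layers = net$layers[1L], conv = NULL)
      class(sub) <- "hier_net"
      for (ep in seq_len(config$epochs_pretrain)) {
        losses <- numeric(iters_per_epoch)
        for (it in seq_len(iters_per_epoch)) {
          idx <- sample.int(n, min(config$batch_size, n))
          Yb <- Y[, idx, drop = FALSE]
          if (L == 1L) {
            # joint filter + first-stage update on raw sinograms
            S_list <- lapply(idx, function(p) pairs[[p]]$sino)
            up <- .sgd_step(sub, "sparse1", S_list, Yb, lr_sparse, fidx)
            lr_sparse <- up$lr
            up2 <- .sgd_step(up$net, "filter", S_list, Yb, lr_filter, fidx)
            lr_filter <- up2$lr
            sub <- up2$net
            losses[it] <- up$loss
          } else {
            Xb <- X[, idx, drop = FALSE]
            ly <- net$layers[[L]]
            pred <- as.matrix(ly$W %*% Xb)
            loss <- .mse(pred, Yb)
            if (!is.finite(loss)) {
              stop("pretraining diverged at stage ", L, " epoch ", ep)
            }
            D <- 2 * (pred - Yb) / (nrow(Yb) * ncol(Yb))
            gw <- .sparse_weight_grad(ly$pattern, Xb, D)
            if (lr_sparse > 0) {
              # exact minimizing step along the gradient (quadratic in w)
              Wd <- ly$W
              Wd@x <- gw[ly$ord]
              Xs <- as.matrix(Wd %*% Xb)
              denom <- sum(Xs^2)
              t_star <- if (denom > 0) {
                lr_sparse * sum((pred - Yb) * Xs) / denom
              } else 0
              net$layers[[L]] <- set_layer_weights(ly, ly$weights - t_star * gw)
            }
            losses[it] <- loss
          }
        }
        hist[[length(hist) + 1L]] <- data.frame(stage = L, epoch = ep,
                                                loss = mean(losses))
      }
      if (L == 1L) {
        net$layers[[1L]] <- sub$layers[[1L]]
        net$filter_kernel <- sub$filter_kernel
      }
    }
  })
  net$pretrain_history <- do.call(rbind, hist)
  net
}

#' End-to-end training with single-random-layer updates
#'
#' Trains the assembled network on (sinogram, image) pairs with MSE on the
#' final image only (no intermediate labels). To sidestep vanishing
#' gradients through the deep linear chain, exactly one layer - chosen
#' uniformly at random each iteration - is updated while all others stay
#' frozen. Noise-based training runs in linear mode (no nonlinear
#' activations), constraining the network toward a linear inverse operator.
#'
#' @param net A (typically pretrained) `hier_net`.
#' @param pairs Training pairs as from [gen_noise_dataset()].
#' @param config A [training_config()].
#' @param val_pairs Optional held-out pairs (conventionally structured
#'   images, e.g. phantoms) evaluated with frozen weights once per epoch.
#'   When given, the returned network carries the weights with the best
#'   validation loss (training on a small noise set is underdetermined, so
#'   validation selection is what controls overfitting).
#' @return A list with the trained `net`, per-iteration `history`
#'   (`iteration`, `epoch`, `layer`, `loss`), per-epoch `val_history`, and
#'   `best_epoch`.
#' @export
train_end_to_end <- function(net, pairs, config = training_config(),
                             val_pairs = NULL) {
  stopifnot(inherits(net, "hier_net"))
  n <- length(pairs)
  Y <- vapply(pairs, function(p) as.vector(p$image),
              numeric(length(pairs[[1]]$image)))
  Y <- matrix(Y, ncol = n)
  layer_names <- c("filter", paste0("sparse", seq_along(net$layers)))
  if (!is.null(net$conv) && net$mode == "nonlinear") {
    layer_names <- c(layer_names, paste0("conv", seq_along(net$conv$W)))
  }
  fidx <- .filter_grad_index(net$schedule$n_radial)
  iters_per_epoch <- max(1L, ceiling(n / config$batch_size))
  hist <- vector("list", config$epochs * iters_per_epoch)
  val_hist <- list()
  best_val <- Inf
  best_net <- net
  best_epoch <- NA_integer_
  lr_state <- c(filter = config$lr_filter,
                stats::setNames(rep(config$lr, length(net$layers)),
                                paste0("sparse", seq_along(net$layers))))
  if (!is.null(net$conv) && net$mode == "nonlinear") {
    lr_state <- c(lr_state,
                  stats::setNames(rep(config$lr_conv, length(net$conv$W)),
                                  paste0("conv", seq_along(net$conv$W))))
  }
  with_seed(config$seed, {
    k <- 0L
    for (ep in seq_len(config$epochs)) {
      for (it in seq_len(iters_per_epoch)) {
        idx <- sample.int(n, min(config$batch_size, n))
        pick <- sample(layer_names, 1L)
        up <- .sgd_step(net, pick,
                        lapply(idx, function(p) pairs[[p]]$sino),
                        Y[, idx, drop = FALSE], lr_state[[pick]], fidx)
        net <- up$net
        lr_state[[pick]] <- up$lr
        k <- k + 1L
        hist[[k]] <- data.frame(iteration = k, epoch = ep, layer = pick,
                                loss = up$loss)
      }
      if (!is.null(val_pairs)) {
        vl <- .eval_loss(net, val_pairs)
        val_hist[[ep]] <- data.frame(epoch = ep, val_loss = vl)
        if (vl < best_val) {
          best_val <- vl
          best_net <- net
          best_epoch <- ep
        }
      }
    }
  })
  if (!is.null(val_pairs)) net <- best_net
  list(net = net, history = do.call(rbind, hist),
       val_history = if (length(val_hist)) do.call(rbind, val_hist) else NULL,
       best_epoch = if (is.null(val_pairs)) NA_integer_ else best_epoch)
}

#' Nonlinear refinement on structured images
#'
#' Follows noise-based linear training: enables the image-domain convolution
#' block (ReLU activations) and continues end-to-end training on pairs built
#' by reprojecting structured images (here synthetic ellipse phantoms
#' standing in for clinical images) and inserting Gaussian measurement noise
#' into the sinograms. The returned network carries the weights with the
#' best validation loss seen during refinement.
#'
#' @param net A `hier_net` trained in linear mode.
#' @param images List of image value matrices (or [image_grid()]s) on the
#'   schedule's grid.
#' @param noise_level Sinogram noise standard deviation as a fraction of the
#'   maximum absolute sinogram value (default 0.01); 0 disables noise so the
#'   refinement target equals the linear-mode target.
#' @param config A [training_config()]; its mode is forced to `"nonlinear"`.
#' @param val_images Optional held-out images for validation (same format).
#' @param conv_channels,conv_layers Convolution block shape if the network
#'   does not have one yet.
#' @return As [train_end_to_end()]: `net`, `history`, `val_history`.
#' @export
refine_nonlinear <- function(net, images, noise_level = 0.01,
                             config = training_config(mode = "nonlinear"),
                             val_images = NULL, conv_channels = 8L,
                             conv_layers = 4L) {
  stopifnot(inherits(net, "hier_net"), noise_level >= 0)
  config$mode <- "nonlinear"
  if (is.null(net$conv)) {
    fresh <- build_network(net$schedule, mode = "nonlinear",
                           conv_block = TRUE, extents = net$extents,
                           conv_channels = conv_channels,
                           conv_layers = conv_layers, seed = config$seed)
    net$conv <- fresh$conv
  }
  net$mode <- "nonlinear"

  sc <- net$schedule
  geom <- projection_geometry(sc$n_radial, sc$n_angles, fov = sc$fov,
                              angle_range = sc$angle_range)
  grid <- image_grid(sc$image_size, fov = sc$fov)
  make_pairs <- function(imgs, seed0) {
    lapply(seq_along(imgs), function(i) {
      v <- if (inherits(imgs[[i]], "image_grid")) imgs[[i]]$values else imgs[[i]]
      img <- image_grid(grid$n_x, grid$n_y, grid$fov, values = v)
      sino <- radon_forward(img, geom)
      sino <- insert_noise(sino, level = noise_level, seed = seed0 + i)
      list(image = v, sino = sino$values)
    })
  }
  pairs <- make_pairs(images, config$seed * 1000L)
  val_pairs <- if (!is.null(val_images)) {
    make_pairs(val_images, config$seed * 1000L + length(images))
  }

  best <- list(loss = Inf, net = net)
  res <- NULL
  epochs_total <- config$epochs
  cfg1 <- config
  cfg1$epochs <- 1L
  hist <- list()
  vals <- list()
  for (ep in seq_len(epochs_total)) {
    cfg1$seed <- config$seed + ep
    res <- train_end_to_end(net, pairs, cfg1, val_pairs = val_pairs)
    net <- res$net
    res$history$epoch <- ep
    hist[[ep]] <- res$history
    vl <- if (!is.null(res$val_history)) res$val_history$val_loss[1] else
      mean(res$history$loss)
    vals[[ep]] <- data.frame(epoch = ep, val_loss = vl)
    if (vl < best$loss) best <- list(loss = vl, net = net)
  }
  list(net = best$net, history = do.call(rbind, hist),
       val_history = do.call(rbind, vals))
}
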