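# shared small-scale fixtures (32 x 32, 3 stages) built once per run
tr_env <- new.env()
tr_fixture <- function() {
  if (is.null(tr_env$pairs)) {
    tr_env$sc <- plan_schedule(32, 32, 32)
    tr_env$grid <- image_grid(32, fov = 32)
    tr_env$geom <- projection_geometry(32, 32, fov = 32)
    tr_env$pairs <- gen_noise_dataset(30, tr_env$grid, tr_env$geom, seed = 3)
    tr_env$labels <- make_intermediate_labels(tr_env$pairs, tr_env$sc)
    tr_env$val <- lapply(1:4, function(i) {
      img <- random_ellipses(tr_env$grid, seed = 900 + i)$image
      list(image = img$values,
           sino = radon_forward(img, tr_env$geom)$values)
    })
  }
  tr_env
}

test_that("noise datasets are reproducible and self-consistent", {
  e <- tr_fixture()
  expect_length(e$pairs, 30)
  expect_identical(formals(gen_noise_dataset)$n, 200L)
  again <- gen_noise_dataset(30, e$grid, e$geom, seed = 3)
  expect_identical(e$pairs[[17]], again[[17]])
  other <- gen_noise_dataset(2, e$grid, e$geom, seed = 4)
  expect_false(identical(e$pairs[[1]]$image, other[[1]]$image))
  # each sinogram is the exact projection of its image
  for (i in c(1, 30)) {
    p <- radon_forward(image_grid(32, values = e$pairs[[i]]$image,
                                  fov = 32), e$geom)
    expect_equal(e$pairs[[i]]$sino, p$values, tolerance = 1e-12)
  }
})

test_that("intermediate labels have stage shapes and sane marginal cases", {
  e <- tr_fixture()
  tab <- schedule_table(e$sc)
  for (L in 1:e$sc$n_stages) {
    expect_equal(nrow(e$labels$stages[[L]]),
                 tab$n_t[L + 1] * tab$n_theta[L + 1] * tab$n_r[L + 1])
  }
  # final-stage label is the FBP image
  sino <- sinogram(e$pairs[[1]]$sino, e$geom)
  fbp <- fbp_reconstruct(sino, e$grid)
  expect_equal(matrix(e$labels$stages[[e$sc$n_stages]][, 1], 32, 32),
               fbp$values)
  # the two label constructions agree closely on a structured image
  disk <- disk_image(32, 10, fov = 32)
  pr <- list(list(image = disk$values,
                  sino = radon_forward(disk, e$geom)$values))
  lf <- make_intermediate_labels(pr, e$sc, method = "fbp")
  lr <- make_intermediate_labels(pr, e$sc, method = "reprojection")
  for (L in 1:e$sc$n_stages) {
    expect_gt(cor(lf$stages[[L]][, 1], lr$stages[[L]][, 1]), 0.9)
  }
})

test_that("stage-wise pretraining reduces each stage's loss", {
  e <- tr_fixture()
  net <- build_network(e$sc, mode = "linear", seed = 3)
  tc <- training_config(epochs_pretrain = 30, seed = 3)
  net2 <- pretrain_stagewise(net, e$pairs, e$labels, tc)
  h <- net2$pretrain_history
  for (L in unique(h$stage)) {
    hl <- h[h$stage == L, ]
    expect_lt(hl$loss[nrow(hl)], hl$loss[1])
  }
  # a pretrained stage beats the all-ones initialization on held-out labels
  held <- gen_noise_dataset(5, e$grid, e$geom, seed = 99)
  lab_h <- make_intermediate_labels(held, e$sc)
  X <- lab_h$stages[[1]]
  Y <- lab_h$stages[[2]]
  mse_of <- function(layer) {
    mean((as.matrix(layer$W %*% X) - Y)^2)
  }
  expect_lt(mse_of(net2$layers[[2]]), mse_of(net$layers[[2]]))
  # zero learning rate leaves all weights untouched
  tc0 <- training_config(lr = 0, lr_filter = 0, epochs_pretrain = 3, seed = 3)
  net0 <- pretrain_stagewise(net, e$pairs, e$labels, tc0)
  expect_identical(net0$layers[[1]]$weights, net$layers[[1]]$weights)
  expect_identical(net0$filter_kernel, net$filter_kernel)
  # incomplete labels are rejected
  bad <- e$labels
  bad$stages <- bad$stages[1:2]
  expect_error(pretrain_stagewise(net, e$pairs, bad, tc), "every stage")
  tr_env$pretrained <- net2
})

test_that("end-to-end training converges with one layer updated at a time", {
  e <- tr_fixture()
  tc <- training_config(epochs = 60, seed = 3)
  res <- train_end_to_end(tr_env$pretrained, e$pairs, tc, val_pairs = e$val)
  em <- tapply(res$history$loss, res$history$epoch, mean)
  expect_lt(em[length(em)], em[1])
  expect_lt(min(res$val_history$val_loss), res$val_history$val_loss[1] + 1e-9)
  expect_equal(nrow(res$val_history), 60)
  # the returned network carries the best-validation weights
  vl <- hierct:::.eval_loss(res$net, e$val)
  expect_equal(vl, min(res$val_history$val_loss), tolerance = 1e-10)
  tr_env$trained <- res$net

  # exactly one layer changes per iteration
  one <- train_end_to_end(tr_env$pretrained,
                          e$pairs[1:10],
                          training_config(epochs = 1, batch_size = 10,
                                          seed = 5))
  expect_equal(nrow(one$history), 1)
  changed <- c(
    filter = !identical(one$net$filter_kernel,
                        tr_env$pretrained$filter_kernel),
    vapply(1:3, function(i) {
      !identical(one$net$layers[[i]]$weights,
                 tr_env$pretrained$layers[[i]]$weights)
    }, logical(1)))
  expect_equal(sum(changed), 1L)
  expect_equal(unname(which(changed)),
               match(one$history$layer, c("filter", "sparse1", "sparse2",
                                          "sparse3")))
})

test_that("training runs are reproducible under a fixed seed", {
  e <- tr_fixture()
  tc <- training_config(epochs = 10, seed = 8)
  r1 <- train_end_to_end(tr_env$pretrained, e$pairs, tc)
  r2 <- train_end_to_end(tr_env$pretrained, e$pairs, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$filter_kernel, r2$net$filter_kernel)
})

test_that("a noise-trained linear network is a linear operator", {
  s1 <- matrix(rnorm(32 * 32), 32, 32)
  s2 <- matrix(rnorm(32 * 32), 32, 32)
  f1 <- net_forward(tr_env$trained, s1)$values
  f2 <- net_forward(tr_env$trained, s2)$values
  f12 <- net_forward(tr_env$trained, 2 * s1 + 3 * s2)$values
  expect_equal(f12, 2 * f1 + 3 * f2, tolerance = 1e-9)
})

test_that("nonlinear refinement denoises without losing accuracy", {
  e <- tr_fixture()
  # refine on top of the analytic linear operator to isolate the
  # convolution head's contribution
  base <- init_backprojection(build_network(e$sc, mode = "linear", seed = 3))
  imgs <- lapply(1:30, function(i) {
    random_ellipses(e$grid, seed = 500 + i)$image$values
  })
  tcr <- training_config(epochs = 25, lr_conv = 0.05, seed = 4,
                         mode = "nonlinear")
  ref <- refine_nonlinear(base, imgs, noise_level = 0.02, config = tcr,
                          val_images = lapply(e$val, `[[`, "image"),
                          conv_channels = 4L)
  expect_true(!is.null(ref$net$conv))
  expect_equal(ref$net$mode, "nonlinear")

  # held-out phantoms, measured with the refinement's noisy-input protocol
  heldout <- lapply(1:5, function(i) {
    random_ellipses(e$grid, seed = 700 + i)$image
  })
  eval_net <- function(nn) {
    mean(vapply(seq_along(heldout), function(i) {
      s <- insert_noise(radon_forward(heldout[[i]], e$geom), 0.02,
                        seed = 40 + i)
      rmse(heldout[[i]], net_forward(nn, s))
    }, numeric(1)))
  }
  expect_lte(eval_net(ref$net), eval_net(base) + 1e-9)

  # flat-region noise after refinement sits below the FBP reference
  disk <- disk_image(32, 13, fov = 32)
  s <- insert_noise(radon_forward(disk, e$geom), 0.02, seed = 99)
  ctr <- grid_centers(e$grid)
  roi <- outer(ctr$y, ctr$x, function(y, x) x^2 + y^2 < 7^2)
  sd_net <- sd(net_forward(ref$net, s)$values[roi])
  sd_fbp <- sd(fbp_reconstruct(s, e$grid)$values[roi])
  expect_lt(sd_net, sd_fbp)
})

test_that("zero noise makes the refinement target the clean projections", {
  e <- tr_fixture()
  img <- random_ellipses(e$grid, seed = 1)$image
  clean <- radon_forward(img, e$geom)
  expect_identical(insert_noise(clean, level = 0, seed = 1)$values,
                   clean$values)
})
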