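tiny_in <- stage_spec(1, 8, 8, fov = 8, level = 0L)
tiny_out <- stage_spec(2, 4, 8, fov = 8, level = 1L)

test_that("map_center handles identity, rescaling and rotation", {
  st <- stage_spec(4, 8, 16, fov = 16)
  for (idx in list(c(1, 1, 1), c(2, 5, 9), c(4, 8, 16))) {
    expect_equal(map_center(idx, st, st, rule = "proportional"), idx)
    expect_equal(map_center(idx, st, st, rule = "geometric"), idx)
  }

  # proportional rescaling, bin centers aligned, halves rounded down
  # (0-based (t=0, theta=255, r=100): theta anchor 63, r unchanged)
  si <- stage_spec(2, 256, 512, fov = 512)
  so <- stage_spec(8, 64, 512, fov = 512)
  a <- map_center(c(1, 256, 101), si, so, rule = "proportional") - 1L
  expect_equal(a[2], 63)
  expect_equal(a[3], 100)

  # the geometric anchor of an on-axis point moves with the frame rotation
  st_in <- stage_spec(16, 4, 64, fov = 64)
  st_out <- stage_spec(64, 1, 64, fov = 64)
  # angle-index 2 is the 90-degree frame: its (t, r) swap roles in the image
  g <- map_center(c(8, 2, 48), st_in, st_out, rule = "geometric")
  t_in <- stage_depths(st_in)[8]
  r_in <- stage_offsets(st_in)[48]
  expect_lt(abs(stage_depths(st_out)[g[1]] - r_in), 0.75)
  expect_lt(abs(stage_offsets(st_out)[g[3]] - (-t_in)), 0.75)

  expect_error(map_center(c(0, 1, 1), st, st), "out of range")
})

test_that("anchors stay in range across the full-size stage pairs", {
  s <- plan_schedule(512, 512, 512, 5)
  for (i in seq_len(s$n_stages)) {
    si <- s$stages[[i]]
    so <- s$stages[[i + 1]]
    din <- c(si$n_t, si$n_theta, si$n_r)
    dout <- c(so$n_t, so$n_theta, so$n_r)
    for (d in 1:3) {
      anchors <- hierct:::.dim_anchor(seq_len(din[d]), din[d], dout[d])
      expect_true(all(anchors >= 1 & anchors <= dout[d]))
    }
  }
})

test_that("pattern construction matches exhaustive enumeration", {
  pat <- build_pattern(tiny_in, tiny_out)
  expect_equal(length(pat$in_idx), oracle_pattern_count(tiny_in, tiny_out))
  expect_equal(count_connections(tiny_in, tiny_out), length(pat$in_idx))
  # duplicate-free connection list
  expect_false(any(duplicated(paste(pat$in_idx, pat$out_idx))))

  # a second, less regular pair
  si <- stage_spec(3, 10, 12, fov = 12)
  so <- stage_spec(9, 5, 12, fov = 12)
  pat2 <- build_pattern(si, so)
  expect_equal(length(pat2$in_idx), oracle_pattern_count(si, so))
  expect_equal(count_connections(si, so), length(pat2$in_idx))
})

test_that("full extents recover a dense layer", {
  si <- stage_spec(2, 4, 3, fov = 6)
  so <- stage_spec(3, 2, 3, fov = 6)
  pat <- build_pattern(si, so, extents = c(5, 5, 5))
  expect_equal(length(pat$in_idx), pat$n_in * pat$n_out)
})

test_that("no output neuron is left unconnected", {
  # every stage pair of the scaled schedule, plus the widest and narrowest
  # transitions of the full-size schedule
  s64 <- plan_schedule(64, 64, 64, 3)
  pairs <- lapply(seq_len(3), function(i) {
    list(s64$stages[[i]], s64$stages[[i + 1]])
  })
  s512 <- plan_schedule(512, 512, 512, 5)
  pairs <- c(pairs, list(list(s512$stages[[1]], s512$stages[[2]]),
                         list(s512$stages[[6 - 1]], s512$stages[[6]])))
  for (pr in pairs) {
    pat <- build_pattern(pr[[1]], pr[[2]])
    expect_equal(length(unique(pat$out_idx)), pat$n_out)
  }
})

test_that("sparse application equals a dense masked product", {
  set.seed(7)
  pat <- build_pattern(tiny_in, tiny_out)
  w <- runif(length(pat$in_idx))
  x <- array(rnorm(pat$n_in), c(1, 8, 8))
  dense <- matrix(0, pat$n_out, pat$n_in)
  dense[cbind(pat$out_idx, pat$in_idx)] <- w
  expect_equal(as.vector(sparse_apply(pat, w, x)),
               as.vector(dense %*% as.vector(x)))
  # all-ones weights as the layer initialization uses them
  expect_equal(as.vector(sparse_apply(pat, rep(1, length(w)), x)),
               as.vector((dense > 0) %*% as.vector(x)))
  # zero input -> zero output
  expect_equal(sum(abs(sparse_apply(pat, w, array(0, c(1, 8, 8))))), 0)
  # transpose product is the adjoint
  g <- array(rnorm(pat$n_out), c(2, 4, 8))
  expect_equal(as.vector(sparse_apply_transpose(pat, w, g)),
               as.vector(t(dense) %*% as.vector(g)))
  expect_error(sparse_apply(pat, w, array(0, c(2, 8, 8))), "mismatch")
})

test_that("sparse application matches dense products on a 16x16 chain", {
  s <- plan_schedule(16, 16, 16)
  set.seed(11)
  for (i in seq_len(s$n_stages)) {
    pat <- build_pattern(s$stages[[i]], s$stages[[i + 1]])
    w <- rnorm(length(pat$in_idx))
    x <- rnorm(pat$n_in)
    dense <- matrix(0, pat$n_out, pat$n_in)
    dense[cbind(pat$out_idx, pat$in_idx)] <- w
    expect_equal(as.vector(sparse_apply(pat, w, x)),
                 as.vector(dense %*% x))
  }
})

test_that("analytic gradients agree with central finite differences", {
  s <- plan_schedule(16, 16, 16)
  net <- build_network(s, mode = "linear", seed = 3)
  set.seed(5)
  S <- list(matrix(rnorm(16 * 16), 16, 16))
  Yb <- matrix(rnorm(256), 256, 1)
  fidx <- hierct:::.filter_grad_index(16)
  for (layer in c("sparse1", "sparse2", "filter")) {
    lg <- hierct:::.layer_loss_grad(net, layer, S, Yb, fidx)
    n_par <- if (layer == "filter") length(net$filter_kernel) else {
      length(net$layers[[as.integer(sub("sparse", "", layer))]]$weights)
    }
    for (k in sample.int(n_par, 10)) {
      h <- 1e-5
      bump <- function(delta) {
        n2 <- net
        if (layer == "filter") {
          n2$filter_kernel[k] <- n2$filter_kernel[k] + delta
        } else {
          i <- as.integer(sub("sparse", "", layer))
          w <- n2$layers[[i]]$weights
          w[k] <- w[k] + delta
          n2$layers[[i]] <- hierct:::set_layer_weights(n2$layers[[i]], w)
        }
        hierct:::.batch_loss(n2, S, Yb)
      }
      fd <- (bump(h) - bump(-h)) / (2 * h)
      gk <- if (layer == "filter") lg$grad[k] else lg$grad[k]
      expect_lt(abs(gk - fd) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("parameter accounting matches enumeration and reports ratios", {
  s <- plan_schedule(64, 64, 64, 3)
  cp <- count_params(s)
  for (i in 1:3) {
    pat <- build_pattern(s$stages[[i]], s$stages[[i + 1]])
    expect_equal(cp$per_layer$parameters[i], length(pat$in_idx))
  }
  expect_equal(cp$dense_equivalent, (64 * 64)^2)
  expect_equal(cp$ratio, cp$sparse_total / (64 * 64)^2)

  net <- build_network(s, mode = "linear", seed = 1)
  cpn <- count_params(net)
  expect_equal(cpn$total, cpn$sparse_total + 64)  # + filter kernel
})
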