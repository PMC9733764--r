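test_that("network assembly follows the schedule", {
  s <- plan_schedule(512, 512, 512, 5)
  expect_equal(s$n_stages, 5L)

  s64 <- plan_schedule(64, 64, 64, 3)
  net <- build_network(s64, mode = "linear", seed = 1)
  expect_length(net$layers, 3)
  expect_true(all(vapply(net$layers, function(l) all(l$weights == 1),
                         logical(1))))
  # the conv block requires nonlinear mode
  expect_error(build_network(s64, mode = "linear", conv_block = TRUE),
               "nonlinear")
})

test_that("forward pass produces stage shapes and image layout", {
  s <- plan_schedule(64, 64, 64, 3)
  net <- build_network(s, mode = "linear", seed = 1)
  sino <- matrix(rnorm(64 * 64), 64, 64)
  out <- net_forward(net, sino, intermediates = TRUE)
  expect_s3_class(out$image, "image_grid")
  expect_equal(dim(out$image$values), c(64, 64))
  tab <- schedule_table(s)
  for (i in seq_along(out$stages)) {
    expect_equal(dim(out$stages[[i]]$values),
                 c(tab$n_t[i + 1], tab$n_theta[i + 1], tab$n_r[i + 1]))
  }
  expect_error(net_forward(net, matrix(0, 32, 64)), "shape")
})

test_that("a linear-mode network satisfies superposition", {
  s <- plan_schedule(32, 32, 32)
  net <- build_network(s, mode = "linear", seed = 2)
  s1 <- matrix(rnorm(32 * 32), 32, 32)
  s2 <- matrix(rnorm(32 * 32), 32, 32)
  f1 <- net_forward(net, s1)$values
  f2 <- net_forward(net, s2)$values
  f12 <- net_forward(net, 1.5 * s1 - 2 * s2)$values
  expect_equal(f12, 1.5 * f1 - 2 * f2, tolerance = 1e-10)
})

test_that("the linear network is one matrix, recoverable from impulses", {
  s <- plan_schedule(16, 16, 16)
  net <- build_network(s, mode = "linear", seed = 4)
  n_in <- 16 * 16
  M <- matrix(0, 16 * 16, n_in)
  for (j in seq_len(n_in)) {
    e <- matrix(0, 16, 16)
    e[j] <- 1
    M[, j] <- as.vector(net_forward(net, e)$values)
  }
  set.seed(9)
  x <- matrix(rnorm(n_in), 16, 16)
  expect_equal(as.vector(net_forward(net, x)$values),
               as.vector(M %*% as.vector(x)), tolerance = 1e-10)
})

test_that("the analytic parameterization reconstructs like FBP", {
  s <- plan_schedule(64, 64, 64, 3)
  net <- init_backprojection(build_network(s, mode = "linear", seed = 1))
  grid <- image_grid(64, fov = 64)
  geom <- projection_geometry(64, 64, fov = 64)
  ratios <- vapply(1:5, function(i) {
    truth <- random_ellipses(grid, seed = 7000 + i)$image
    sino <- radon_forward(truth, geom)
    rmse(truth, net_forward(net, sino)) /
      rmse(truth, fbp_reconstruct(sino, grid))
  }, numeric(1))
  expect_lt(mean(ratios), 1.2)
})

test_that("impulse responses stay inside the pattern footprint", {
  s <- plan_schedule(64, 64, 64, 3)
  net <- build_network(s, mode = "linear", seed = 1)  # all-ones final stage
  pt <- c(8L, 1L, 40L)
  resp <- impulse_probe(net, 3, pt)$values
  # support bound: outputs connected to the impulse's input neuron
  pat <- net$layers[[3]]$pattern
  st <- pat$stage_in
  lin <- pt[1] + st$n_t * (pt[2] - 1L) + st$n_t * st$n_theta * (pt[3] - 1L)
  allowed <- rep(FALSE, pat$n_out)
  allowed[pat$out_idx[pat$in_idx == lin]] <- TRUE
  expect_true(all(resp[!matrix(allowed, 64, 64)] == 0))
  expect_gt(sum(abs(resp)), 0)
  expect_error(impulse_probe(net, 9, pt), "invalid layer")
  expect_error(impulse_probe(net, 3, c(99L, 1L, 1L)), "out of range")
})

test_that("analytic impulse responses are oriented depth segments", {
  s <- plan_schedule(64, 64, 64, 3)
  net <- init_backprojection(build_network(s, mode = "linear", seed = 1))
  st_in <- s$stages[[3]]   # (16, 4, 64): angles 0, 90, 180, 270 degrees
  # an impulse in the angle-0 partial image lands at (y = t, x = r) and its
  # energy concentrates in a depth segment of the input stage's window
  frac_in_box <- function(angle_idx, long_axis) {
    pt <- c(10L, angle_idx, 44L)
    resp <- impulse_probe(net, 3, pt)$values
    tc <- stage_depths(st_in)[pt[1]]
    rc <- stage_offsets(st_in)[pt[3]]
    th <- stage_angles(st_in)[angle_idx]
    ctr <- c(rc * cos(th) - tc * sin(th),       # x
             rc * sin(th) + tc * cos(th))       # y
    ys <- abs(stage_depths(s$stages[[4]]) - ctr[2])
    xs <- abs(stage_offsets(s$stages[[4]]) - ctr[1])
    half <- if (long_axis == "y") c(1.5, st_in$alpha / 2 + 0.5) else
      c(st_in$alpha / 2 + 0.5, 1.5)
    box <- outer(ys <= half[2], xs <= half[1], `&`)
    sum(resp[box]^2) / sum(resp^2)
  }
  # angle 0: segment along y; angle 90 (index 2): segment along x
  expect_gt(frac_in_box(1L, "y"), 0.8)
  expect_gt(frac_in_box(2L, "x"), 0.8)
})

test_that("parameter counts scale as n log n, far below the dense square", {
  cs <- vapply(c(32, 64, 128), function(sz) {
    cp <- count_params(plan_schedule(sz, sz, sz))
    n <- sz^2
    cp$sparse_total / (n * log(n))
  }, numeric(1))
  expect_lt((max(cs) - min(cs)) / mean(cs), 0.25)
  cp <- count_params(plan_schedule(128, 128, 128))
  expect_lt(cp$sparse_total / cp$dense_equivalent, 0.01)
})
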