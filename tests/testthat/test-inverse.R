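# small helper: a toy in-memory dataset of clean (delta-scattering,
# noise-free) bead stacks for training tests
toy_dataset <- function(n_stacks, hw = 32L, t_count = 4L, seed = 1L) {
  expsf <- fixture_expsf(); empsf <- fixture_empsf()
  spsf <- delta_spsf_stack(0:4, c(1L, 1L))
  pats <- make_random_patterns(t_count, c(hw, hw), 0.5, seed = seed)
  objs <- lapply(seq_len(n_stacks), function(i)
    generate_beads_volume(bead_spec(count_small = 3, count_large = 1),
                          c(hw, hw, 5L), seed = seed * 1000 + i))
  build_dataset(objs, pats, expsf, empsf, spsf, seed = seed, n_test = 0L)
}

test_that("the network maps stacks to single non-negative images of the same grid", {
  cfg <- network_config(in_channels = 8, base_width = 8, depth_levels = 3)
  net <- build_network(cfg, seed = 2)
  H <- W <- 32L
  F0 <- matrix(abs(rnorm(H * W * 8)), H * W, 8)
  fwd <- descatter:::net_forward(net, F0, H, W, 1L, training = FALSE)
  expect_length(fwd$pred, H * W)
  expect_gte(min(fwd$pred), 0)

  # all-zero input: finite, non-negative output
  fwd0 <- descatter:::net_forward(net, F0 * 0, H, W, 1L, training = FALSE)
  expect_true(all(is.finite(fwd0$pred)))
  expect_gte(min(fwd0$pred), 0)

  # 9 convolution blocks at the default depth; parameter count is stable
  cfg9 <- network_config(in_channels = 4, base_width = 4, depth_levels = 4)
  n1 <- build_network(cfg9, seed = 5)$n_parameters
  n2 <- build_network(cfg9, seed = 6)$n_parameters
  expect_identical(n1, n2)

  # indivisible input sizes are rejected with guidance
  expect_error(descatter:::net_forward(net, matrix(0, 30 * 30, 8), 30L, 30L, 1L),
               "divisible")
})

test_that("loss functions vanish at identity and match hand-derived values", {
  x <- matrix(runif(64, 0.1, 1), 8, 8)
  for (kind in c("mse", "rmsle", "smooth_l1", "kl"))
    expect_equal(loss_value(x, x, kind), 0, tolerance = 1e-12)

  # constant offset of 0.5 on the quadratic branch of the elementwise Huber
  expect_equal(loss_value(x + 0.5, x, "smooth_l1"), 0.125)
  # and on the linear branch
  expect_equal(loss_value(x + 2, x, "smooth_l1"), 1.5)
  expect_equal(loss_value(x + 0.5, x, "mse"), 0.25)

  # KL positivity between different normalized images
  y <- matrix(runif(64, 0.1, 1), 8, 8)
  expect_gt(loss_value(y, x, "kl"), 0)
  expect_error(loss_value(x, matrix(0, 4, 4), "mse"), "identical shape")
})

test_that("analytic gradients agree with finite differences through the whole net", {
  set.seed(41)
  cfg <- network_config(in_channels = 2, base_width = 4, depth_levels = 2,
                        loss = "kl")
  net <- build_network(cfg, seed = 3)
  H <- W <- 8L; N <- 2L
  F0 <- matrix(abs(rnorm(H * W * N * 2)), H * W * N, 2)
  Y <- abs(rnorm(H * W * N))
  sid <- rep(seq_len(N), each = H * W)
  for (kind in c("kl", "mse")) {
    lossfun <- function(nn) {
      fw <- descatter:::net_forward(nn, F0, H, W, N, training = TRUE)
      descatter:::loss_grad(as.numeric(fw$pred), Y, kind, sid,
                            want_grad = FALSE)$value
    }
    fwd <- descatter:::net_forward(net, F0, H, W, N, training = TRUE)
    lg <- descatter:::loss_grad(as.numeric(fwd$pred), Y, kind, sid)
    grads <- descatter:::net_backward(net, fwd, matrix(lg$grad, ncol = 1))
    gflat <- descatter:::flatten_params(grads)
    pflat <- descatter:::flatten_params(net$params)
    set.seed(kind == "kl")
    for (nm in names(pflat)) {
      i <- sample(length(pflat[[nm]]), 1L)
      eps <- 1e-5
      p <- pflat
      n2 <- net
      p[[nm]][i] <- p[[nm]][i] + eps
      n2$params <- descatter:::assign_flat(n2$params, p)
      up <- lossfun(n2)
      p[[nm]][i] <- p[[nm]][i] - 2 * eps
      n2$params <- descatter:::assign_flat(n2$params, p)
      dn <- lossfun(n2)
      num <- (up - dn) / (2 * eps)
      ana <- gflat[[nm]][i]
      expect_lt(abs(num - ana),
                1e-3 * max(abs(num) + abs(ana), 1e-4))
    }
  }
})

test_that("every parameter receives gradient on a random batch", {
  set.seed(43)
  cfg <- network_config(in_channels = 2, base_width = 4, depth_levels = 2,
                        loss = "mse")
  net <- build_network(cfg, seed = 5)
  H <- W <- 16L; N <- 3L
  F0 <- matrix(abs(rnorm(H * W * N * 2)), H * W * N, 2)
  Y <- abs(rnorm(H * W * N))
  fwd <- descatter:::net_forward(net, F0, H, W, N, training = TRUE)
  lg <- descatter:::loss_grad(as.numeric(fwd$pred), Y, "mse",
                              rep(seq_len(N), each = H * W))
  gflat <- descatter:::flatten_params(
    descatter:::net_backward(net, fwd, matrix(lg$grad, ncol = 1)))
  for (nm in names(gflat))
    expect_gt(max(abs(gflat[[nm]])), 0)
})

test_that("forcing the attention gates to one recovers the plain UNet", {
  set.seed(47)
  cfg <- network_config(in_channels = 2, base_width = 4, depth_levels = 2,
                        scse_identity = TRUE)
  net <- build_network(cfg, seed = 9)
  H <- W <- 16L
  F0 <- matrix(abs(rnorm(H * W * 2)), H * W, 2)
  fwd_id <- descatter:::net_forward(net, F0, H, W, 1L, training = FALSE)

  # with the gates forced open the attention parameters are inert: the pass
  # is the plain UNet regardless of their values
  scrambled <- net
  for (i in 1:2) {
    nm <- paste0("scse", i)
    scrambled$params[[nm]] <- lapply(scrambled$params[[nm]],
                                     function(p) p + 10)
  }
  fwd2 <- descatter:::net_forward(scrambled, F0, H, W, 1L, training = FALSE)
  expect_identical(fwd_id$pred, fwd2$pred)

  # with gates active the attention reshapes the output
  active <- net
  active$cfg$scse_identity <- FALSE
  fwd3 <- descatter:::net_forward(active, F0, H, W, 1L, training = FALSE)
  expect_false(identical(fwd_id$pred, fwd3$pred))
})

test_that("training reduces the loss and is bit-reproducible", {
  ds <- toy_dataset(6, hw = 32L, t_count = 4L, seed = 5)
  cfg <- network_config(in_channels = 4, base_width = 8, depth_levels = 2,
                        loss = "kl")
  tc <- train_config(batch_size = 5, epochs = 8, seed = 7, val_every = 4)
  model <- train_network(ds, cfg, tc)
  h <- model$history
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])

  # deterministic re-run: identical loss curves
  model2 <- train_network(ds, cfg, tc)
  expect_identical(model$history, model2$history)

  # reconstruction API: correct shape, non-negative, channel check
  st <- ds$stacks[[ds$splits$val[1]]]
  rec <- reconstruct(model, st)
  expect_identical(dim(rec$image), c(32L, 32L))
  expect_gte(min(rec$image), 0)
  bad <- st; bad$measurements <- st$measurements[, , 1:2]
  expect_error(reconstruct(model, bad), "expects")
})

test_that("the network memorizes a four-stack training set", {
  ds <- toy_dataset(5, hw = 32L, t_count = 4L, seed = 5)  # 4 train / 1 val
  cfg <- network_config(in_channels = 4, base_width = 16, depth_levels = 2,
                        loss = "mse")
  tc <- train_config(lr = 3e-3, batch_size = 1, epochs = 200, seed = 7,
                     val_every = 100)
  model <- train_network(ds, cfg, tc)
  # RMSE under 1.6% of the image dynamic range: the training pairs are
  # reproduced essentially exactly
  expect_lt(min(model$history$train_loss), 2.5e-4)
})
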