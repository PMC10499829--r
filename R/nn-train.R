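## Loss functions, the Adam training loop, and inference.

#' Reconstruction loss between a prediction and its ground truth
#'
#' Four selectable losses: mean squared error; root mean squared logarithmic
#' error (computed on `log(1 + x)` of zero-clipped images, the standard RMSLE
#' convention); smooth L1 (element-wise Huber with threshold 1: quadratic
#' where the absolute error is below 1, linear above); and KL divergence,
#' for which both images are shifted by `1e-8` and normalized to sum to 1
#' over each image so they are comparable as distributions.
#'
#' @param pred,target numeric arrays of identical shape.
#' @param kind `"mse"`, `"rmsle"`, `"smooth_l1"`, or `"kl"`.
#' @return scalar loss (0 when `pred == target` for every kind).
#' @export
loss_value <- function(pred, target, kind = c("mse", "rmsle", "smooth_l1", "kl")) {
  kind <- match.arg(kind)
  assert_that(identical(dim(pred), dim(target)) &&
                length(pred) == length(target),
              "`pred` and `target` must have identical shape")
  loss_grad(as.numeric(pred), as.numeric(target), kind,
            sample_id = rep(1L, length(pred)), want_grad = FALSE)$value
}

# loss + gradient wrt pred; `sample_id` groups pixels into images for the
# per-image KL normalization
loss_grad <- function(pred, target, kind, sample_id, want_grad = TRUE) {
  n <- length(pred)
  if (kind == "mse") {
    e <- pred - target
    return(list(value = mean(e^2),
                grad = if (want_grad) 2 * e / n))
  }
  if (kind == "smooth_l1") {
    e <- pred - target
    ae <- abs(e)
    v <- mean(ifelse(ae < 1, 0.5 * e^2, ae - 0.5))
    g <- if (want_grad) ifelse(ae < 1, e, sign(e)) / n
    return(list(value = v, grad = g))
  }
  if (kind == "rmsle") {
    lp <- log1p(pmax(pred, 0)); lt <- log1p(pmax(target, 0))
    e <- lp - lt
    m <- mean(e^2)
    v <- sqrt(m)
    g <- if (want_grad) {
      if (m == 0) numeric(n)
      else (e / (n * v)) * (pred > 0) / (1 + pmax(pred, 0))
    }
    return(list(value = v, grad = g))
  }
  # kl: per-image distributions
  eps <- 1e-8
  ns <- max(sample_id)
  tp <- pmax(target, 0) + eps
  pp <- pmax(pred, 0) + eps
  St <- as.numeric(rowsum(tp, sample_id))
  Sp <- as.numeric(rowsum(pp, sample_id))
  P <- tp / St[sample_id]
  Q <- pp / Sp[sample_id]
  v <- sum(P * log(P / Q)) / ns
  g <- if (want_grad)
    ((1 - P / Q) / Sp[sample_id]) * (pred > 0) / ns
  list(value = v, grad = g)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param batch_size images per gradient step (default 10).
#' @param epochs training epochs (default 100).
#' @param seed integer seed controlling initialization, shuffling and
#'   batch-norm statistics order.
#' @param val_every compute validation metrics every this many epochs.
#' @param lr_final learning rate at the last epoch (geometric decay from
#'   `lr`); defaults to `lr`, i.e. a constant rate.
#' @return a `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 10L, epochs = 100L, seed = 1L,
                         val_every = 1L, lr_final = lr) {
  assert_scalar_num(lr, "lr", 0, strict_lower = TRUE)
  assert_scalar_num(lr_final, "lr_final", 0, strict_lower = TRUE)
  assert_that(batch_size >= 1L, "`batch_size` must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = seed,
                 val_every = as.integer(val_every), lr_final = lr_final),
            class = "train_config")
}

# flatten nested grads/params to aligned lists for the optimizer
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

assign_flat <- function(x, flat, prefix = "") {
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) x[[nm]] <- assign_flat(x[[nm]], flat, key)
    else x[[nm]] <- flat[[key]]
  }
  x
}

# stack measurement images into the (H*W*N) x C input matrix and the
# prediction-target column used by the network
assemble_batch <- function(stacks, cfg, patterns = NULL) {
  N <- length(stacks)
  d <- dim(stacks[[1]]$measurements)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  Cin <- T_ * (1L + cfg$include_pattern_channels)
  F0 <- matrix(0, H * W * N, Cin)
  Y <- numeric(H * W * N)
  for (i in seq_len(N)) {
    st <- stacks[[i]]
    rows <- (i - 1L) * H * W + seq_len(H * W)
    m <- st$measurements / st$norm$measurement_scale
    F0[rows, seq_len(T_)] <- matrix(m, H * W, T_)
    if (cfg$include_pattern_channels)
      F0[rows, T_ + seq_len(T_)] <- matrix(patterns$patterns, H * W, T_)
    Y[rows] <- as.numeric(st$ground_truth / st$norm$ground_truth_scale)
  }
  list(F0 = F0, Y = Y, H = H, W = W, N = N,
       sample_id = rep(seq_len(N), each = H * W))
}

#' Train the inverse network
#'
#' Adam optimization of the configured loss over the training split, with
#' per-epoch training loss and periodic validation loss / SSIM / PSNR. The
#' parameters with the best validation loss are kept. Fully deterministic
#' given the seeds. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param dataset a dataset from [build_dataset()] (or a list with `stacks`
#'   and `splits`).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param patterns the `pattern_set` (only needed when
#'   `net_cfg$include_pattern_channels`).
#' @param verbose print per-epoch progress.
#' @return a trained `descatter_net` with elements `history` (data.frame of
#'   epoch, train_loss, val_loss, val_ssim, val_psnr) and `best_epoch`.
#' @export
train_network <- function(dataset, net_cfg, train_cfg = train_config(),
                          patterns = NULL, verbose = FALSE) {
  train_stacks <- dataset_split(dataset, "train")
  val_stacks <- dataset_split(dataset, "val")
  assert_that(length(train_stacks) >= 1L, "training split is empty")
  assert_that(length(val_stacks) >= 1L, "validation split is empty")
  net <- build_network(net_cfg, seed = substream_seed(train_cfg$seed, "init"))
  flat <- flatten_params(net$params)
  opt <- list(m = lapply(flat, function(p) p * 0),
              v = lapply(flat, function(p) p * 0), t = 0L)
  n_train <- length(train_stacks)
  bs <- min(train_cfg$batch_size, n_train)
  history <- NULL
  best <- list(loss = Inf, params = net$params, state = net$state, epoch = 0L)
  val_batch <- assemble_batch(val_stacks, net_cfg, patterns)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr_now <- if (train_cfg$epochs == 1L) train_cfg$lr
      else train_cfg$lr * (train_cfg$lr_final / train_cfg$lr)^
        ((epoch - 1) / (train_cfg$epochs - 1))
    ord <- with_seed(substream_seed(train_cfg$seed, "shuffle", epoch),
                     sample.int(n_train))
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n_train, by = bs)) {
      ids <- ord[b0:min(b0 + bs - 1L, n_train)]
      batch <- assemble_batch(train_stacks[ids], net_cfg, patterns)
      fwd <- net_forward(net, batch$F0, batch$H, batch$W, batch$N,
                         training = TRUE)
      net$state <- fwd$state
      lg <- loss_grad(as.numeric(fwd$pred), batch$Y, net_cfg$loss,
                      batch$sample_id)
      if (!is.finite(lg$value))
        stopf("training diverged (non-finite %s loss) at epoch %d; lower the learning rate",
              net_cfg$loss, epoch)
      grads <- net_backward(net, fwd, matrix(lg$grad, ncol = 1L))
      gflat <- flatten_params(grads)
      flat <- flatten_params(net$params)
      opt$t <- opt$t + 1L
      corr1 <- 1 - train_cfg$beta1^opt$t
      corr2 <- 1 - train_cfg$beta2^opt$t
      for (nm in names(flat)) {
        g <- gflat[[nm]]
        opt$m[[nm]] <- train_cfg$beta1 * opt$m[[nm]] + (1 - train_cfg$beta1) * g
        opt$v[[nm]] <- train_cfg$beta2 * opt$v[[nm]] + (1 - train_cfg$beta2) * g^2
        flat[[nm]] <- flat[[nm]] - lr_now * (opt$m[[nm]] / corr1) /
          (sqrt(opt$v[[nm]] / corr2) + 1e-8)
      }
      net$params <- assign_flat(net$params, flat)
      ep_loss <- ep_loss + lg$value
      n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / n_batches
    row <- data.frame(epoch = epoch, train_loss = ep_loss,
                      val_loss = NA_real_, val_ssim = NA_real_,
                      val_psnr = NA_real_)
    if (epoch %% train_cfg$val_every == 0L || epoch == train_cfg$epochs) {
      vfwd <- net_forward(net, val_batch$F0, val_batch$H, val_batch$W,
                          val_batch$N, training = FALSE)
      vl <- loss_grad(as.numeric(vfwd$pred), val_batch$Y, net_cfg$loss,
                      val_batch$sample_id, want_grad = FALSE)$value
      ss <- ps <- numeric(val_batch$N)
      for (i in seq_len(val_batch$N)) {
        rows <- (i - 1L) * val_batch$H * val_batch$W + seq_len(val_batch$H * val_batch$W)
        pr <- matrix(vfwd$pred[rows], val_batch$H, val_batch$W)
        gt <- matrix(val_batch$Y[rows], val_batch$H, val_batch$W)
        mcfg <- metric_config(window_size = min(11L, val_batch$H - val_batch$H %% 2L - 1L))
        ss[i] <- ssim_metric(gt, pmin(pr, 1), mcfg)
        ps[i] <- psnr_metric(gt, pr, R = max(gt))
      }
      row$val_loss <- vl
      row$val_ssim <- mean(ss)
      row$val_psnr <- mean(ps[is.finite(ps)])
      if (vl < best$loss)
        best <- list(loss = vl, params = net$params, state = net$state,
                     epoch = epoch)
    }
    history <- rbind(history, row)
    if (verbose)
      message(sprintf("epoch %3d  train %s %.5g  val %s %s", epoch,
                      net_cfg$loss, ep_loss, net_cfg$loss,
                      ifelse(is.na(row$val_loss), "-", sprintf("%.5g", row$val_loss))))
  }
  net$params <- best$params
  net$state <- best$state
  net$history <- history
  net$best_epoch <- best$epoch
  net
}

#' Reconstruct a de-scattered image from a measurement stack
#'
#' Applies the per-stack normalization used in training, runs the network in
#' evaluation mode (batch-norm running statistics), and returns the
#' non-negative reconstruction on the input grid together with the
#' normalization factor that maps it back towards physical units.
#'
#' @param model a trained `descatter_net`.
#' @param stack a `measurement_stack`.
#' @param patterns the `pattern_set` when the model was trained with pattern
#'   channels.
#' @return list with `image` (H x W, >= 0) and `norm_factor` (the
#'   measurement scale divided out of the inputs).
#' @export
reconstruct <- function(model, stack, patterns = NULL) {
  assert_that(inherits(model, "descatter_net"), "`model` must be a descatter_net")
  assert_that(inherits(stack, "measurement_stack"),
              "`stack` must be a measurement_stack")
  T_ <- dim(stack$measurements)[3]
  want <- model$cfg$in_channels
  if (T_ != want)
    stopf("stack has %d channels but the model expects %d", T_, want)
  batch <- assemble_batch(list(stack), model$cfg, patterns)
  fwd <- net_forward(model, batch$F0, batch$H, batch$W, 1L, training = FALSE)
  list(image = matrix(fwd$pred, batch$H, batch$W),
       norm_factor = stack$norm$measurement_scale)
}
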