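## The de-scattering inverse network: a UNet-style encoder-decoder with
## concurrent spatial/channel squeeze-and-excitation attention on the
## decoder path and a terminal reconstruction block (conv + ReLU to one
## channel), built from the primitives in nn-layers.R.

#' Inverse-network configuration
#'
#' With `depth_levels` encoder blocks the network has
#' `2 * depth_levels + 1` convolution blocks in total (encoder blocks, a
#' bottleneck, and decoder blocks); the default 4 gives the 9-block
#' architecture. Each block is `[conv 3x3 -> batchnorm -> ReLU] x 2`;
#' downsampling is 2x2 max pooling; upsampling is nearest-neighbour followed
#' by a 1x1 conv; skip connections concatenate encoder features; an scSE
#' attention block follows every decoder block; the terminal reconstruction
#' block is a 3x3 conv to one channel followed by ReLU, so outputs are
#' non-negative.
#'
#' @param in_channels number of input channels (= number of patterns T).
#' @param base_width channels of the first encoder block (doubling per level).
#' @param depth_levels number of encoder levels (input H, W must be divisible
#'   by `2^depth_levels`).
#' @param scse_reduction channel-reduction ratio of the attention bottleneck.
#' @param loss one of `"mse"`, `"rmsle"`, `"smooth_l1"`, `"kl"` (default
#'   `"kl"`).
#' @param include_pattern_channels also feed the T binary patterns as extra
#'   input channels (doubles `in_channels`).
#' @param scse_identity force all attention gates to 1 (ablation hook: the
#'   network reduces to the plain UNet forward pass).
#' @return a `network_config`.
#' @export
network_config <- function(in_channels = 32L, base_width = 64L,
                           depth_levels = 4L, scse_reduction = 2L,
                           loss = c("kl", "mse", "rmsle", "smooth_l1"),
                           include_pattern_channels = FALSE,
                           scse_identity = FALSE) {
  loss <- match.arg(loss)
  in_channels <- as.integer(in_channels)
  assert_that(in_channels >= 1L, "`in_channels` must be >= 1")
  structure(list(in_channels = in_channels,
                 base_width = as.integer(base_width),
                 depth_levels = as.integer(depth_levels),
                 scse_reduction = as.integer(scse_reduction),
                 loss = loss,
                 include_pattern_channels = isTRUE(include_pattern_channels),
                 scse_identity = isTRUE(scse_identity)),
            class = "network_config")
}

he_init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

dc_params <- function(cin, cout) {
  list(W1 = he_init(9L * cin, cout), b1 = numeric(cout),
       g1 = rep(1, cout), be1 = numeric(cout),
       W2 = he_init(9L * cout, cout), b2 = numeric(cout),
       g2 = rep(1, cout), be2 = numeric(cout))
}

dc_state <- function(cout)
  list(bn1 = list(rm = numeric(cout), rv = rep(1, cout)),
       bn2 = list(rm = numeric(cout), rv = rep(1, cout)))

scse_params <- function(c, r) {
  cr <- max(1L, c %/% r)
  list(W1 = he_init(c, cr), b1 = numeric(cr),
       W2 = he_init(cr, c), b2 = numeric(c),
       Wsp = he_init(c, 1L), bsp = 0)
}

#' Build the inverse network
#'
#' Initializes all parameters (He initialization for convolutions, unit
#' gamma / zero beta for batch norm) under `seed`, so two constructions with
#' the same configuration and seed are identical.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the parameter initialization.
#' @return a `descatter_net`: list with `cfg`, `params` (named nested list),
#'   `state` (batch-norm running statistics), `n_parameters`.
#' @export
build_network <- function(cfg, seed = 1L) {
  assert_that(inherits(cfg, "network_config"), "`cfg` must be a network_config")
  L <- cfg$depth_levels
  B <- cfg$base_width
  cin0 <- cfg$in_channels * (1L + cfg$include_pattern_channels)
  with_seed(seed, {
    params <- list()
    state <- list()
    widths <- B * 2L^(seq_len(L) - 1L)
    cin <- cin0
    for (i in seq_len(L)) {
      params[[paste0("enc", i)]] <- dc_params(cin, widths[i])
      state[[paste0("enc", i)]] <- dc_state(widths[i])
      cin <- widths[i]
    }
    params$bottleneck <- dc_params(widths[L], B * 2L^L)
    state$bottleneck <- dc_state(B * 2L^L)
    cup <- B * 2L^L
    for (i in rev(seq_len(L))) {
      w <- widths[i]
      params[[paste0("up", i)]] <- list(W = he_init(cup, w), b = numeric(w))
      params[[paste0("dec", i)]] <- dc_params(2L * w, w)
      state[[paste0("dec", i)]] <- dc_state(w)
      params[[paste0("scse", i)]] <- scse_params(w, cfg$scse_reduction)
      cup <- w
    }
    params$recon <- list(W = he_init(9L * B, 1L), b = 0.01)
    net <- structure(list(cfg = cfg, params = params, state = state),
                     class = "descatter_net")
    net$n_parameters <- n_parameters(net)
    net
  })
}

#' Count trainable parameters
#' @param net a `descatter_net`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(rapply(net$params, length, how = "unlist"))
}

#' @export
print.descatter_net <- function(x, ...) {
  cat(sprintf("<descatter_net> %d conv blocks, in_channels %d, base width %d, %s loss, %d parameters\n",
              2L * x$cfg$depth_levels + 1L, x$cfg$in_channels,
              x$cfg$base_width, x$cfg$loss, x$n_parameters))
  invisible(x)
}

check_input_shape <- function(cfg, H, W) {
  div <- 2L^cfg$depth_levels
  if (H %% div != 0L || W %% div != 0L)
    stopf("input %dx%d not divisible by 2^%d = %d; pad or crop the images (e.g. to %dx%d)",
          H, W, cfg$depth_levels, div,
          div * ceiling(H / div), div * ceiling(W / div))
}

# double conv block forward: returns out, cache, updated state
dc_forward <- function(F, p, st, tb, training) {
  a1 <- conv3_forward(F, p$W1, p$b1, tb)
  b1 <- bn_forward(a1, p$g1, p$be1, st$bn1, training)
  r1 <- pmax(b1$out, 0)
  a2 <- conv3_forward(r1, p$W2, p$b2, tb)
  b2 <- bn_forward(a2, p$g2, p$be2, st$bn2, training)
  r2 <- pmax(b2$out, 0)
  list(out = r2,
       cache = list(F = F, a1 = a1, bn1 = b1$cache, r1 = r1,
                    a2 = a2, bn2 = b2$cache, preact2 = b2$out),
       st = list(bn1 = b1$st, bn2 = b2$st))
}

dc_backward <- function(dOut, cache, p, tb) {
  d2 <- dOut * (cache$preact2 > 0)
  bb2 <- bn_backward(d2, cache$bn2, p$g2)
  cv2 <- conv3_backward(bb2$dF, cache$r1, p$W2, tb)
  d1 <- cv2$dF * (cache$r1 > 0)
  bb1 <- bn_backward(d1, cache$bn1, p$g1)
  cv1 <- conv3_backward(bb1$dF, cache$F, p$W1, tb)
  list(dF = cv1$dF,
       grads = list(W1 = cv1$dW, b1 = cv1$db, g1 = bb1$dgamma, be1 = bb1$dbeta,
                    W2 = cv2$dW, b2 = cv2$db, g2 = bb2$dgamma, be2 = bb2$dbeta))
}

# Full network forward. `F0`: (H*W*N) x C input matrix; returns prediction
# column (H*W*N x 1) plus caches needed for the backward pass.
net_forward <- function(net, F0, H, W, N, training = FALSE) {
  cfg <- net$cfg
  check_input_shape(cfg, H, W)
  L <- cfg$depth_levels
  p <- net$params; st <- net$state
  caches <- list()
  skips <- list()
  shapes <- list()
  FF <- F0
  h <- H; w <- W
  for (i in seq_len(L)) {
    tb <- shape_tables(h, w, N)
    dc <- dc_forward(FF, p[[paste0("enc", i)]], st[[paste0("enc", i)]], tb, training)
    st[[paste0("enc", i)]] <- dc$st
    caches[[paste0("enc", i)]] <- dc$cache
    skips[[i]] <- dc$out
    shapes[[i]] <- tb
    caches[[paste0("pool_in", i)]] <- dc$out
    FF <- maxpool_forward(dc$out, tb$pool)
    caches[[paste0("pool_out", i)]] <- FF
    h <- h %/% 2L; w <- w %/% 2L
  }
  tb <- shape_tables(h, w, N)
  dc <- dc_forward(FF, p$bottleneck, st$bottleneck, tb, training)
  st$bottleneck <- dc$st
  caches$bottleneck <- dc$cache
  FF <- dc$out
  for (i in rev(seq_len(L))) {
    tb_lo <- shape_tables(h, w, N)
    FFup <- upsample_forward(FF, tb_lo$up)
    h <- h * 2L; w <- w * 2L
    tb_hi <- shapes[[i]]
    caches[[paste0("upin", i)]] <- FFup
    FFup <- conv1_forward(FFup, p[[paste0("up", i)]]$W, p[[paste0("up", i)]]$b)
    cat_in <- cbind(skips[[i]], FFup)
    dcd <- dc_forward(cat_in, p[[paste0("dec", i)]], st[[paste0("dec", i)]],
                      tb_hi, training)
    st[[paste0("dec", i)]] <- dcd$st
    caches[[paste0("dec", i)]] <- dcd$cache
    sc <- scse_forward(dcd$out, p[[paste0("scse", i)]], tb_hi$sample_id,
                       tb_hi$H * tb_hi$W, identity = cfg$scse_identity)
    caches[[paste0("scse", i)]] <- sc$cache
    caches[[paste0("scse_in", i)]] <- dcd$out
    FF <- sc$out
  }
  tb1 <- shape_tables(H, W, N)
  pre <- conv3_forward(FF, p$recon$W, p$recon$b, tb1)
  pred <- pmax(pre, 0)
  list(pred = pred, pre = pre, final_in = FF, caches = caches, state = st,
       H = H, W = W, N = N)
}

# Full network backward. `dPred`: gradient of the loss wrt the prediction
# column. Returns gradients named congruently with net$params.
net_backward <- function(net, fwd, dPred) {
  cfg <- net$cfg
  L <- cfg$depth_levels
  p <- net$params
  caches <- fwd$caches
  H <- fwd$H; W <- fwd$W; N <- fwd$N
  grads <- list()
  tb1 <- shape_tables(H, W, N)
  dPre <- dPred * (fwd$pre > 0)
  cvr <- conv3_backward(dPre, fwd$final_in, p$recon$W, tb1)
  grads$recon <- list(W = cvr$dW, b = cvr$db)
  dFF <- cvr$dF
  h <- H; w <- W
  for (i in seq_len(L)) {
    tb_hi <- shape_tables(h, w, N)
    sb <- scse_backward(dFF, caches[[paste0("scse_in", i)]],
                        caches[[paste0("scse", i)]], p[[paste0("scse", i)]],
                        tb_hi$sample_id, tb_hi$H * tb_hi$W)
    grads[[paste0("scse", i)]] <- sb$grads
    db <- dc_backward(sb$dF, caches[[paste0("dec", i)]],
                      p[[paste0("dec", i)]], tb_hi)
    grads[[paste0("dec", i)]] <- db$grads
    wch <- ncol(caches[[paste0("dec", i)]]$F) %/% 2L
    dSkip <- db$dF[, seq_len(wch), drop = FALSE]
    dUp <- db$dF[, wch + seq_len(wch), drop = FALSE]
    cu <- conv1_backward(dUp, caches[[paste0("upin", i)]], p[[paste0("up", i)]]$W)
    grads[[paste0("up", i)]] <- list(W = cu$dW, b = cu$db)
    h <- h %/% 2L; w <- w %/% 2L
    tb_lo <- shape_tables(h, w, N)
    dFF <- upsample_backward(cu$dF, tb_lo$up)
    # stash the skip gradient for the encoder sweep
    grads[[paste0(".skip", i)]] <- dSkip
  }
  tb <- shape_tables(h, w, N)
  dbott <- dc_backward(dFF, caches$bottleneck, p$bottleneck, tb)
  grads$bottleneck <- dbott$grads
  dFF <- dbott$dF
  for (i in rev(seq_len(L))) {
    tb_hi <- shape_tables(h * 2L, w * 2L, N)
    dPoolIn <- maxpool_backward(dFF, caches[[paste0("pool_in", i)]],
                                caches[[paste0("pool_out", i)]], tb_hi$pool)
    dEnc <- dPoolIn + grads[[paste0(".skip", i)]]
    grads[[paste0(".skip", i)]] <- NULL
    de <- dc_backward(dEnc, caches[[paste0("enc", i)]],
                      p[[paste0("enc", i)]], tb_hi)
    grads[[paste0("enc", i)]] <- de$grads
    dFF <- de$dF
    h <- h * 2L; w <- w * 2L
  }
  grads
}
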