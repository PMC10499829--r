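## Minimal neural-network primitives on BLAS: feature maps are dense
## matrices with rows indexing (h, w, sample) — h fastest — and columns
## indexing channels. Convolutions are im2col gathers followed by GEMM;
## every layer has an explicit hand-derived backward pass (verified against
## numerical gradients in the test suite).

# ---- shape-indexed gather tables -------------------------------------------

# Build and cache the index tables for a given (H, W, N) feature shape:
#  pool: (R/4 x 4) corner table for 2x2 max pooling
#  up:   (4R) nearest-neighbour source rows for 2x upsampling
#  sample_id: (R) sample index per row
shape_tables <- local({
  cache <- new.env(parent = emptyenv())
  function(H, W, N) {
    key <- paste(H, W, N, sep = "x")
    tb <- cache[[key]]
    if (!is.null(tb)) return(tb)
    R <- H * W * N
    r0 <- seq_len(R) - 1L
    n <- r0 %/% (H * W) + 1L
    tb <- list(sample_id = n, H = H, W = W, N = N)
    if (H %% 2L == 0L && W %% 2L == 0L) {
      Ho <- H %/% 2L; Wo <- W %/% 2L
      Ro <- Ho * Wo * N
      q0 <- seq_len(Ro) - 1L
      ho <- q0 %% Ho + 1L
      wo <- (q0 %/% Ho) %% Wo + 1L
      no <- q0 %/% (Ho * Wo) + 1L
      src <- function(dh, dw)
        (no - 1L) * H * W + (2L * wo - 2L + dw - 1L) * H + (2L * ho - 2L + dh)
      tb$pool <- cbind(src(1L, 1L), src(2L, 1L), src(1L, 2L), src(2L, 2L))
    }
    # upsample table: output shape (2H, 2W)
    Hu <- 2L * H; Wu <- 2L * W
    u0 <- seq_len(Hu * Wu * N) - 1L
    hu <- u0 %% Hu + 1L
    wu <- (u0 %/% Hu) %% Wu + 1L
    nu <- u0 %/% (Hu * Wu) + 1L
    tb$up <- (nu - 1L) * H * W + ((wu + 1L) %/% 2L - 1L) * H + (hu + 1L) %/% 2L
    cache[[key]] <- tb
    tb
  }
})

# ---- convolution ------------------------------------------------------------

conv3_forward <- function(F, Wt, b, tb) {
  out <- im2col3x3(F, tb$H, tb$W, tb$N) %*% Wt
  sweep(out, 2L, b, "+")
}

conv3_backward <- function(dOut, F, Wt, tb) {
  Xc <- im2col3x3(F, tb$H, tb$W, tb$N)
  dW <- crossprod(Xc, dOut)
  db <- colSums(dOut)
  dXc <- tcrossprod(dOut, Wt)
  list(dF = col2im3x3(dXc, tb$H, tb$W, tb$N), dW = dW, db = db)
}

conv1_forward <- function(F, Wt, b) sweep(F %*% Wt, 2L, b, "+")

conv1_backward <- function(dOut, F, Wt)
  list(dF = tcrossprod(dOut, Wt), dW = crossprod(F, dOut), db = colSums(dOut))

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(F, gamma, beta, st, training, eps = 1e-5, momentum = 0.9) {
  R <- nrow(F)
  if (training) {
    mu <- colMeans(F)
    xc <- F - rep(mu, each = R)
    v <- colMeans(xc * xc)
    st$rm <- momentum * st$rm + (1 - momentum) * mu
    st$rv <- momentum * st$rv + (1 - momentum) * v
  } else {
    mu <- st$rm; v <- st$rv
    xc <- F - rep(mu, each = R)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = R)
  out <- xhat * rep(gamma, each = R) + rep(beta, each = R)
  list(out = out, cache = list(xhat = xhat, inv = inv, xc = xc), st = st)
}

bn_backward <- function(dOut, cache, gamma) {
  R <- nrow(dOut)
  dxhat <- dOut * rep(gamma, each = R)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  # dF = inv/R * (R*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dF <- (dxhat - rep(s1 / R, each = R) -
           cache$xhat * rep(s2 / R, each = R)) * rep(cache$inv, each = R)
  list(dF = dF, dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling / upsampling ---------------------------------------------------

maxpool_forward <- function(F, pool_idx) {
  A <- F[pool_idx[, 1], , drop = FALSE]
  B <- F[pool_idx[, 2], , drop = FALSE]
  C <- F[pool_idx[, 3], , drop = FALSE]
  D <- F[pool_idx[, 4], , drop = FALSE]
  pmax(pmax(A, B), pmax(C, D))
}

maxpool_backward <- function(dOut, F, out, pool_idx) {
  dF <- matrix(0, nrow(F), ncol(F))
  taken <- matrix(FALSE, nrow(dOut), ncol(dOut))
  for (k in seq_len(4L)) {
    idx <- pool_idx[, k]
    mk <- (F[idx, , drop = FALSE] == out) & !taken  # first corner wins ties
    dF[idx, ] <- dF[idx, ] + dOut * mk
    taken <- taken | mk
  }
  dF
}

upsample_forward <- function(F, up_idx) F[up_idx, , drop = FALSE]

upsample_backward <- function(dOut, up_idx) {
  out <- rowsum(dOut, up_idx)  # groups 1..R each present; sorted order
  dimnames(out) <- NULL
  out
}

# ---- concurrent spatial & channel squeeze-and-excitation -------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

scse_forward <- function(F, p, sample_id, hw, identity = FALSE) {
  if (identity) return(list(out = F, cache = list(identity = TRUE)))
  N <- max(sample_id)
  z <- rowsum(F, sample_id) / hw                       # N x C channel squeeze
  h1 <- pmax(sweep(z %*% p$W1, 2L, p$b1, "+"), 0)
  a <- sigmoid(sweep(h1 %*% p$W2, 2L, p$b2, "+"))      # channel gates
  Ae <- a[sample_id, , drop = FALSE]
  oc <- F * Ae
  s <- sigmoid(as.vector(F %*% p$Wsp) + p$bsp)         # spatial gate, length R
  os <- F * s
  mask <- oc >= os                                     # element-wise max
  out <- pmax(oc, os)
  list(out = out,
       cache = list(z = z, h1 = h1, a = a, Ae = Ae, s = s, mask = mask))
}

scse_backward <- function(dOut, F, cache, p, sample_id, hw) {
  if (isTRUE(cache$identity))
    return(list(dF = dOut, grads = list()))
  d_oc <- dOut * cache$mask
  d_os <- dOut * !cache$mask
  # spatial branch
  dF <- d_os * cache$s
  dpre_s <- rowSums(d_os * F) * cache$s * (1 - cache$s)
  dWsp <- crossprod(F, dpre_s)
  dbsp <- sum(dpre_s)
  dF <- dF + dpre_s %*% t(p$Wsp)
  # channel branch
  dF <- dF + d_oc * cache$Ae
  dA <- rowsum(d_oc * F, sample_id)
  dpre2 <- dA * cache$a * (1 - cache$a)
  dW2 <- crossprod(cache$h1, dpre2)
  db2 <- colSums(dpre2)
  dh1 <- tcrossprod(dpre2, p$W2) * (cache$h1 > 0)
  dW1 <- crossprod(cache$z, dh1)
  db1 <- colSums(dh1)
  dz <- tcrossprod(dh1, p$W1)
  dF <- dF + dz[sample_id, , drop = FALSE] / hw
  list(dF = dF,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wsp = dWsp, bsp = dbsp))
}
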