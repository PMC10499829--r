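#' @keywords internal
"_PACKAGE"

## ---- validation helpers ----------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              "`%s` must be a finite numeric scalar", name)
  if (strict_lower) assert_that(x > lower, "`%s` must be > %g", name, lower)
  else assert_that(x >= lower, "`%s` must be >= %g", name, lower)
  if (strict_upper) assert_that(x < upper, "`%s` must be < %g", name, upper)
  else assert_that(x <= upper, "`%s` must be <= %g", name, upper)
  invisible(x)
}

## ---- seeded RNG management -------------------------------------------------

#' Derive a reproducible sub-stream seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' seed, the stage name and an item index, so that stages are statistically
#' independent yet fully reproducible. The derivation is a stable string hash
#' (polynomial rolling hash mod 2^31 - 1) and does not depend on R's RNG.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"spsf"`.
#' @param index integer item index within the stage (default 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  assert_that(is.character(stage) && length(stage) == 1L,
              "`stage` must be a single string")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  s <- (abs(as.numeric(seed)) %% m)
  v <- (s * 48271 + h * 69621 + as.numeric(index) * 16807) %% m
  as.integer(v %% (m - 2L) + 1L)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- FFT convolution helpers ----------------------------------------------

# Centre index of a kernel axis: for odd sizes the middle sample, for even
# sizes the left-of-middle sample (size %/% 2 + 1).
kernel_centre <- function(n) n %/% 2L + 1L

fft_good_size <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# Zero-padded "same" 2-D convolution. `kern` is centred at kernel_centre().
conv2d_same <- function(img, kern) {
  di <- dim(img); dk <- dim(kern)
  P1 <- fft_good_size(di[1] + dk[1] - 1L)
  P2 <- fft_good_size(di[2] + dk[2] - 1L)
  A <- matrix(0, P1, P2); A[seq_len(di[1]), seq_len(di[2])] <- img
  B <- matrix(0, P1, P2); B[seq_len(dk[1]), seq_len(dk[2])] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
  c1 <- kernel_centre(dk[1]); c2 <- kernel_centre(dk[2])
  full[c1:(c1 + di[1] - 1L), c2:(c2 + di[2] - 1L), drop = FALSE]
}

# Zero-padded "same" 3-D convolution.
conv3d_same <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  P <- mapply(function(a, b) fft_good_size(a + b - 1L), dv, dk)
  A <- array(0, P); A[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  B <- array(0, P); B[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / prod(P)
  cc <- vapply(dk, kernel_centre, integer(1))
  full[cc[1]:(cc[1] + dv[1] - 1L),
       cc[2]:(cc[2] + dv[2] - 1L),
       cc[3]:(cc[3] + dv[3] - 1L), drop = FALSE]
}

# Direct (spatial-domain) "same" 2-D convolution; O(n^2 k^2) reference used
# by small kernels and as an independent cross-check of the FFT path.
conv2d_direct <- function(img, kern) {
  di <- dim(img); dk <- dim(kern)
  c1 <- kernel_centre(dk[1]); c2 <- kernel_centre(dk[2])
  out <- matrix(0, di[1], di[2])
  for (i in seq_len(dk[1])) for (j in seq_len(dk[2])) {
    w <- kern[i, j]
    if (w == 0) next
    si <- i - c1; sj <- j - c2  # shift applied to the image
    r_dst <- max(1L, 1L + si):min(di[1], di[1] + si)
    c_dst <- max(1L, 1L + sj):min(di[2], di[2] + sj)
    out[r_dst, c_dst] <- out[r_dst, c_dst] + w * img[r_dst - si, c_dst - sj]
  }
  out
}

## ---- misc ------------------------------------------------------------------

# Trilinear resampling of a 3-D array by a scale factor (used for the vessel
# phantom rescale step). Output grid spans the same physical extent.
resample_trilinear <- function(vol, factor) {
  assert_scalar_num(factor, "factor", lower = 0, strict_lower = TRUE)
  d <- dim(vol)
  nd <- pmax(1L, as.integer(round(d * factor)))
  # source coordinates of the new grid (align centres)
  coord <- function(n_new, n_old) {
    if (n_new == 1L) return(rep((n_old + 1) / 2, 1L))
    (seq_len(n_new) - 0.5) * (n_old / n_new) + 0.5
  }
  cx <- coord(nd[1], d[1]); cy <- coord(nd[2], d[2]); cz <- coord(nd[3], d[3])
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  ix0 <- clamp(floor(cx), 1, d[1]); ix1 <- clamp(ix0 + 1, 1, d[1]); fx <- clamp(cx - ix0, 0, 1)
  iy0 <- clamp(floor(cy), 1, d[2]); iy1 <- clamp(iy0 + 1, 1, d[2]); fy <- clamp(cy - iy0, 0, 1)
  iz0 <- clamp(floor(cz), 1, d[3]); iz1 <- clamp(iz0 + 1, 1, d[3]); fz <- clamp(cz - iz0, 0, 1)
  out <- array(0, nd)
  for (k in seq_len(nd[3])) {
    z0 <- iz0[k]; z1 <- iz1[k]; wz <- fz[k]
    interp2 <- function(z) {
      a <- vol[, , z]
      m <- a[ix0, iy0] * outer(1 - fx, 1 - fy) +
        a[ix1, iy0] * outer(fx, 1 - fy) +
        a[ix0, iy1] * outer(1 - fx, fy) +
        a[ix1, iy1] * outer(fx, fy)
      m
    }
    out[, , k] <- (1 - wz) * interp2(z0) + wz * interp2(z1)
  }
  out
}

# radial second moment (variance of radius, in pixel^2) of a non-negative 2-D
# map about a given centre (defaults to the geometric centre pixel)
radial_second_moment <- function(img, centre = NULL) {
  d <- dim(img)
  if (is.null(centre)) centre <- c(kernel_centre(d[1]), kernel_centre(d[2]))
  w <- img / sum(img)
  r2 <- outer((seq_len(d[1]) - centre[1])^2, rep(1, d[2])) +
    outer(rep(1, d[1]), (seq_len(d[2]) - centre[2])^2)
  sum(w * r2)
}

#' @useDynLib descatter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
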