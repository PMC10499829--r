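# Shared fixtures and independent oracles, built in code at test time.

# small PSFs on a coarse grid (kept tiny so convolutions stay cheap)
fixture_expsf <- function(zplanes = 5L)
  make_gaussian_psf(1.0, 1.036, 1.33, c(17L, 17L, zplanes), c(1 / 3, 1 / 3, 1),
                    "excitation")

fixture_empsf <- function(zplanes = 5L)
  make_gaussian_psf(1.0, 0.58, 1.33, c(17L, 17L, zplanes), c(1 / 3, 1 / 3, 1),
                    "emission")

# a small camera + LUT shared across tests (built once per test run)
fixture_camera <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cam <- camera_model(g_em = 300, n_stages = 512L, dark_mean = 0.01,
                          read_sigma = 20, lut_max_input = 60L)
      lut <- build_em_lut(cam, n_draws = 5000L, seed = 42L, n_pool = 5e4)
      val <<- list(camera = cam, lut = lut)
    }
    val
  }
})

# Independent brute-force SSIM: literal sliding-window evaluation of the
# similarity statistic, no shared code with ssim_metric's filtered path.
ssim_bruteforce <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1,
                            win = 11L, sigma = 1.5, uniform = FALSE) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  h <- nrow(x); w <- ncol(x); r <- (win - 1L) %/% 2L
  wv <- if (uniform) rep(1 / win, win)
        else { g <- exp(-((seq_len(win) - r - 1L)^2) / (2 * sigma^2)); g / sum(g) }
  Wm <- outer(wv, wv)
  vals <- c()
  for (i in (r + 1):(h - r)) for (j in (r + 1):(w - r)) {
    px <- x[(i - r):(i + r), (j - r):(j + r)]
    py <- y[(i - r):(i + r), (j - r):(j + r)]
    mx <- sum(Wm * px); my <- sum(Wm * py)
    vx <- sum(Wm * px^2) - mx^2; vy <- sum(Wm * py^2) - my^2
    cxy <- sum(Wm * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# Independent brute-force "same" 3-D convolution (quadruple loop over the
# kernel), used as the oracle for the FFT-based forward model.
conv3d_bruteforce <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  cc <- dk %/% 2L + 1L
  out <- array(0, dv)
  for (x in seq_len(dv[1])) for (y in seq_len(dv[2])) for (z in seq_len(dv[3])) {
    acc <- 0
    for (i in seq_len(dk[1])) for (j in seq_len(dk[2])) for (k in seq_len(dk[3])) {
      sx <- x - (i - cc[1]); sy <- y - (j - cc[2]); sz <- z - (k - cc[3])
      if (sx >= 1 && sx <= dv[1] && sy >= 1 && sy <= dv[2] &&
          sz >= 1 && sz <= dv[3])
        acc <- acc + vol[sx, sy, sz] * kern[i, j, k]
    }
    out[x, y, z] <- acc
  }
  out
}

# exhaustive axial-window scan: the oracle for sub-volume extraction counts
subvolume_oracle <- function(vol, depth, stride, clip_at, gate = NULL) {
  v <- pmin(vol, clip_at)
  if (is.null(gate)) gate <- mean(v)
  starts <- seq(1L, dim(v)[3] - depth + 1L, by = stride)
  starts[vapply(starts, function(s)
    mean(v[, , s:(s + depth - 1L)]) > gate, logical(1))]
}
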