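## Stochastic EMCCD detection: Poisson shot noise and dark current, the
## N-stage Bernoulli electron-multiplication cascade with its excess-noise
## statistics, Gaussian read noise, and a precomputed output-distribution
## lookup table that makes per-pixel cascading affordable.

#' EMCCD camera parameters
#'
#' The multiplication register is parameterized by the mean EM gain and the
#' number of stages; the per-stage success probability is derived as
#' `alpha = g_em^(1/n_stages) - 1`, so that `(1 + alpha)^n_stages = g_em`.
#'
#' @param g_em mean EM gain (>= 1).
#' @param n_stages number of multiplication stages (default 512, the register
#'   length of common EMCCDs).
#' @param dark_mean expected dark electrons per pixel per exposure.
#' @param read_sigma read-noise standard deviation in electrons.
#' @param lut_max_input largest electron count precomputed in the gain lookup
#'   table; larger inputs fall back to direct cascading.
#' @return a `camera_model` with derived `alpha`.
#' @export
camera_model <- function(g_em = 300, n_stages = 512L, dark_mean = 0.01,
                         read_sigma = 20, lut_max_input = 200L) {
  assert_scalar_num(g_em, "g_em", 1)
  n_stages <- as.integer(n_stages)
  assert_that(n_stages >= 1L, "`n_stages` must be >= 1")
  assert_scalar_num(dark_mean, "dark_mean", 0)
  assert_scalar_num(read_sigma, "read_sigma", 0)
  alpha <- g_em^(1 / n_stages) - 1
  assert_that(alpha < 1, "derived alpha >= 1; increase n_stages")
  structure(list(g_em = g_em, n_stages = n_stages, alpha = alpha,
                 dark_mean = dark_mean, read_sigma = read_sigma,
                 lut_max_input = as.integer(lut_max_input)),
            class = "camera_model")
}

#' Excess noise factor of the EM register
#'
#' `F^2 = 2 * (g_em - 1) * g_em^(-(N+1)/N) + 1 / g_em`: the variance
#' inflation the stochastic multiplication cascade adds on top of the input
#' noise. Equals 1 at unit gain and tends to 2 at high gain.
#'
#' @param g_em mean EM gain (>= 1).
#' @param n_stages number of stages.
#' @return `F^2` (dimensionless).
#' @export
excess_noise_factor <- function(g_em, n_stages) {
  assert_scalar_num(g_em, "g_em", 1)
  assert_scalar_num(n_stages, "n_stages", 1)
  2 * (g_em - 1) * g_em^(-(n_stages + 1) / n_stages) + 1 / g_em
}

#' Run the electron-multiplication cascade directly
#'
#' Applies `n_stages` sequential stages; at each stage every electron
#' independently spawns an extra electron with probability `alpha`, so the
#' stage output is `x + Binomial(x, alpha)`. Vectorized over `x_in`.
#'
#' @param x_in integer electron counts (>= 0).
#' @param alpha per-stage multiplication probability.
#' @param n_stages number of stages.
#' @return integer electron counts after the cascade.
#' @export
em_cascade_once <- function(x_in, alpha, n_stages) {
  assert_that(all(x_in >= 0), "`x_in` must be >= 0")
  x <- as.integer(round(x_in))
  for (s in seq_len(n_stages)) x <- x + stats::rbinom(length(x), x, alpha)
  x
}

#' Precompute the EM-gain output lookup table
#'
#' For each input electron count `x` in `0..lut_max_input`, stores `n_draws`
#' samples of the cascade output. `method = "pool"` (default) first simulates
#' a pool of independent single-electron cascades and builds row `x` as row
#' `x-1` plus a fresh single-electron draw — exact in distribution because
#' the binomial cascade acts on each input electron independently.
#' `method = "direct"` cascades every row jointly (slower; used as the
#' independent cross-check).
#'
#' @param camera a [camera_model()].
#' @param n_draws samples stored per row (default 1e4).
#' @param seed integer seed.
#' @param method `"pool"` or `"direct"`.
#' @param n_pool size of the single-electron pool for `method = "pool"`.
#' @return an `em_gain_lut`: list with `samples` (n_draws x (lut_max+1)
#'   integer matrix; column j holds outputs for input j-1), `camera`,
#'   `n_draws`.
#' @export
build_em_lut <- function(camera, n_draws = 1e4, seed = 1L,
                         method = c("pool", "direct"), n_pool = 2e5) {
  method <- match.arg(method)
  assert_that(inherits(camera, "camera_model"), "`camera` must be a camera_model")
  n_draws <- as.integer(n_draws)
  xmax <- camera$lut_max_input
  with_seed(seed, {
    samples <- matrix(0L, n_draws, xmax + 1L)
    if (method == "pool") {
      pool <- em_cascade_once(rep(1L, as.integer(n_pool)),
                              camera$alpha, camera$n_stages)
      for (x in seq_len(xmax))
        samples[, x + 1L] <- samples[, x] +
          pool[sample.int(length(pool), n_draws, replace = TRUE)]
    } else {
      for (x in seq_len(xmax))
        samples[, x + 1L] <- em_cascade_once(rep(x, n_draws),
                                             camera$alpha, camera$n_stages)
    }
    structure(list(samples = samples, camera = camera, n_draws = n_draws),
              class = "em_gain_lut")
  })
}

#' Sample EM-cascade outputs from the lookup table
#'
#' Draws one output per element of `x` from the per-input empirical
#' distributions; inputs above the table limit are cascaded directly (the
#' fallback is logged via `message`).
#'
#' @param lut an `em_gain_lut`.
#' @param x integer electron counts.
#' @return integer cascade outputs, same length as `x`.
#' @export
sample_em_output <- function(lut, x) {
  assert_that(inherits(lut, "em_gain_lut"), "`lut` must be an em_gain_lut")
  x <- as.integer(round(x))
  out <- integer(length(x))
  xmax <- lut$camera$lut_max_input
  small <- x <= xmax
  if (any(small)) {
    rows <- sample.int(lut$n_draws, sum(small), replace = TRUE)
    out[small] <- lut$samples[cbind(rows, x[small] + 1L)]
  }
  if (any(!small)) {
    message(sprintf("sample_em_output: %d value(s) above lut_max_input (%d); direct cascade fallback",
                    sum(!small), xmax))
    out[!small] <- em_cascade_once(x[!small], lut$camera$alpha,
                                   lut$camera$n_stages)
  }
  out
}

#' Detect an expected-photoelectron image on the EMCCD
#'
#' Per pixel: draw the shot count `Poisson(image)`, add a dark count
#' `Poisson(dark_mean)`, push the sum through the EM cascade (sampled from
#' the lookup table), and add `Normal(0, read_sigma)` read noise. Pixels may
#' come out negative because of read noise; they are left as-is (clipping
#' would bias the mean law). With `noise_free = TRUE` the cascade is replaced
#' by its mean and no noise is drawn: the output is exactly `g_em * image`.
#'
#' @param photon_image matrix of expected signal electrons per pixel (>= 0).
#' @param camera a [camera_model()].
#' @param lut an `em_gain_lut` built for `camera` (ignored when
#'   `noise_free = TRUE`).
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param noise_free logical; deterministic mean-gain mode.
#' @return detected image in electrons, same shape as `photon_image`.
#' @export
detect <- function(photon_image, camera, lut = NULL, seed = NULL,
                   noise_free = FALSE) {
  assert_that(all(photon_image >= 0), "`photon_image` must be non-negative")
  if (noise_free) return(camera$g_em * photon_image)
  assert_that(inherits(lut, "em_gain_lut"),
              "`lut` is required unless noise_free = TRUE")
  run <- function() {
    n <- length(photon_image)
    shot <- stats::rpois(n, as.numeric(photon_image))
    dark <- stats::rpois(n, camera$dark_mean)
    amplified <- sample_em_output(lut, shot + dark)
    out <- amplified + stats::rnorm(n, 0, camera$read_sigma)
    dim(out) <- dim(photon_image)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
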