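## Evaluation metrics: MSE, PSNR, and windowed SSIM, plus cohort summaries.

#' SSIM / PSNR configuration
#'
#' @param k1,k2 SSIM stabilization constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the images (default 1.0); the SSIM constants are
#'   `C1 = (k1*L)^2`, `C2 = (k2*L)^2`.
#' @param window `"gaussian"` (11x11, sigma 1.5; the field-standard choice),
#'   `"uniform"` (flat window), or `"global"` (one window spanning the whole
#'   image; admits closed-form checks).
#' @param window_size odd window width for the sliding variants.
#' @param sigma Gaussian window standard deviation in pixels.
#' @return a `metric_config`.
#' @export
metric_config <- function(k1 = 0.01, k2 = 0.03, L = 1.0,
                          window = c("gaussian", "uniform", "global"),
                          window_size = 11L, sigma = 1.5) {
  window <- match.arg(window)
  assert_scalar_num(k1, "k1", 0, strict_lower = TRUE)
  assert_scalar_num(k2, "k2", 0, strict_lower = TRUE)
  assert_scalar_num(L, "L", 0, strict_lower = TRUE)
  window_size <- as.integer(window_size)
  assert_that(window_size %% 2L == 1L, "`window_size` must be odd")
  structure(list(k1 = k1, k2 = k2, L = L, window = window,
                 window_size = window_size, sigma = sigma),
            class = "metric_config")
}

#' Mean squared error
#' @param x,y numeric arrays of identical shape.
#' @return mean of squared differences.
#' @export
mse_metric <- function(x, y) {
  assert_that(identical(dim(x), dim(y)) && length(x) == length(y),
              "`x` and `y` must have identical shape")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(R^2 / MSE)`; identical images give `Inf`.
#'
#' @param x,y numeric arrays of identical shape.
#' @param R peak intensity (default: maximum of `x`).
#' @return PSNR in dB.
#' @export
psnr_metric <- function(x, y, R = max(x)) {
  m <- mse_metric(x, y)
  if (m == 0) return(Inf)
  10 * log10(R^2 / m)
}

# weighted local means/variances via separable window filtering; windows are
# "valid" (fully inside the image), matching the usual cropped evaluation
ssim_filter <- function(img, w) {
  # w: window weight vector (1-D, separable)
  k <- length(w)
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- apply(img, 2, function(col) stats::convolve(col, rev(w), type = "filter"))
  out <- matrix(out, H - k + 1L, W)
  out <- t(apply(out, 1, function(row) stats::convolve(row, rev(w), type = "filter")))
  matrix(out, H - k + 1L, W - k + 1L)
}

#' Structural similarity index
#'
#' Mean over sliding windows of
#' `(2*mu_x*mu_y + C1) * (2*sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`
#' with population (not sample) moments, Gaussian or uniform windows, or a
#' single global window.
#'
#' @param x,y matrices on `[0, L]` of identical shape.
#' @param cfg a [metric_config()].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_metric <- function(x, y, cfg = metric_config()) {
  assert_that(identical(dim(x), dim(y)), "`x` and `y` must have identical shape")
  C1 <- (cfg$k1 * cfg$L)^2
  C2 <- (cfg$k2 * cfg$L)^2
  if (cfg$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
    cxy <- mean(x * y) - mx * my
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  k <- cfg$window_size
  assert_that(all(dim(x) >= k), "window (%d) larger than image", k)
  w <- if (cfg$window == "gaussian") {
    g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * cfg$sigma^2))
    g / sum(g)
  } else rep(1 / k, k)
  mx <- ssim_filter(x, w);  my <- ssim_filter(y, w)
  sxx <- ssim_filter(x * x, w) - mx^2
  syy <- ssim_filter(y * y, w) - my^2
  sxy <- ssim_filter(x * y, w) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Evaluate a trained model over a dataset split
#'
#' Reconstructs every measurement stack in the split, scores it against its
#' ground truth (both on the common `[0, 1]` normalization used in training),
#' and aggregates mean and standard deviation per metric. The summary follows
#' the conventional reporting scales: MSE in units of 1e-4 and SSIM in units
#' of 1e-2.
#'
#' @param model a trained `descatter_net` (or `NULL` to score injected
#'   predictions, see `predictions`).
#' @param dataset a dataset list as produced by [build_dataset()] /
#'   [simulate_measurement_stack()].
#' @param split which split to evaluate (`"val"`, `"train"`, `"test"`), when
#'   the dataset carries split tags; otherwise all stacks are used.
#' @param cfg a [metric_config()].
#' @param predictions optional list of precomputed reconstruction matrices
#'   (bypasses the model; used for baselines and tests).
#' @return a data.frame with one row per stack (`stack_id`, `mse`, `psnr`,
#'   `ssim`) plus attribute `"summary"`: a data.frame of mean and sd for
#'   `mse_1e4`, `psnr_db`, `ssim_1e2`.
#' @export
evaluate_cohort <- function(model, dataset, split = "val",
                            cfg = metric_config(), predictions = NULL) {
  stacks <- dataset_split(dataset, split)
  assert_that(length(stacks) > 0, "split `%s` is empty", split)
  rows <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    gt <- st$ground_truth / max(st$ground_truth)
    pred <- if (!is.null(predictions)) predictions[[i]]
            else reconstruct(model, st)$image
    pm <- max(pred)
    if (pm > 0) pred <- pred / max(pm, 1)  # keep on [0,1] without stretching
    data.frame(stack_id = if (!is.null(st$id)) st$id else i,
               mse = mse_metric(gt, pred),
               psnr = psnr_metric(gt, pred, R = max(gt)),
               ssim = ssim_metric(gt, pred, cfg))
  })
  out <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("mse_1e4", "psnr_db", "ssim_1e2"),
    mean = c(mean(out$mse) * 1e4, mean(out$psnr), mean(out$ssim) * 1e2),
    sd = c(stats::sd(out$mse) * 1e4, stats::sd(out$psnr), stats::sd(out$ssim) * 1e2))
  summ$sd[is.na(summ$sd)] <- 0
  attr(out, "summary") <- summ
  out
}

# pull a split out of a dataset object; tolerate plain lists of stacks
dataset_split <- function(dataset, split) {
  if (!is.null(dataset$splits)) {
    ids <- dataset$splits[[split]]
    return(dataset$stacks[ids])
  }
  if (!is.null(dataset$stacks)) return(dataset$stacks)
  dataset
}
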