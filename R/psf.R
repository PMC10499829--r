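## Excitation / emission point-spread functions and binary DMD pattern sets.

#' Construct a PSF volume
#'
#' A non-negative 3-D field normalized to unit total mass, with its peak at
#' the geometric centre voxel.
#'
#' @param amplitude 3-D non-negative array.
#' @param voxel_size `(dx, dy, dz)` in micrometres.
#' @param kind `"excitation"` or `"emission"`.
#' @return a `psf_volume`.
#' @export
psf_volume <- function(amplitude, voxel_size, kind = c("excitation", "emission")) {
  kind <- match.arg(kind)
  assert_that(is.numeric(amplitude) && length(dim(amplitude)) == 3L,
              "`amplitude` must be a 3-D array")
  assert_that(min(amplitude) >= 0, "`amplitude` must be non-negative")
  s <- sum(amplitude)
  assert_that(is.finite(s) && s > 0, "`amplitude` must have positive finite mass")
  structure(list(amplitude = amplitude / s,
                 voxel_size = as.numeric(voxel_size),
                 kind = kind),
            class = "psf_volume")
}

#' Gaussian approximation of a diffraction-limited PSF
#'
#' Builds a separable Gaussian PSF with lateral and axial widths given by the
#' standard Gaussian approximation of a diffraction-limited focus:
#' `sigma_xy = 0.325 * lambda / (sqrt(2) * NA^0.91)` and
#' `sigma_z = (0.532 * lambda / sqrt(2)) / (n - sqrt(n^2 - NA^2))`.
#' For `kind = "excitation"` the field is squared before normalization
#' (two-photon excitation is proportional to intensity squared), which
#' narrows the PSF by `sqrt(2)` in each axis.
#'
#' @param na numerical aperture (must be < `refractive_index`).
#' @param wavelength wavelength in micrometres.
#' @param refractive_index immersion/tissue refractive index.
#' @param shape integer length-3 grid size (odd sizes keep the peak centred).
#' @param voxel_size `(dx, dy, dz)` in micrometres.
#' @param kind `"excitation"` or `"emission"`.
#' @return a unit-mass `psf_volume`.
#' @export
make_gaussian_psf <- function(na, wavelength, refractive_index = 1.33,
                              shape = c(33L, 33L, 9L),
                              voxel_size = c(1 / 3, 1 / 3, 1),
                              kind = c("excitation", "emission")) {
  kind <- match.arg(kind)
  assert_scalar_num(na, "na", 0, strict_lower = TRUE)
  assert_scalar_num(wavelength, "wavelength", 0, strict_lower = TRUE)
  assert_that(na < refractive_index, "NA (%g) must be < refractive index (%g)",
              na, refractive_index)
  shape <- as.integer(shape)
  n <- refractive_index
  sigma_xy <- 0.325 * wavelength / (sqrt(2) * na^0.91)
  sigma_z <- (0.532 * wavelength / sqrt(2)) / (n - sqrt(n^2 - na^2))
  cc <- vapply(shape, kernel_centre, integer(1))
  gx <- exp(-((seq_len(shape[1]) - cc[1]) * voxel_size[1])^2 / (2 * sigma_xy^2))
  gy <- exp(-((seq_len(shape[2]) - cc[2]) * voxel_size[2])^2 / (2 * sigma_xy^2))
  gz <- exp(-((seq_len(shape[3]) - cc[3]) * voxel_size[3])^2 / (2 * sigma_z^2))
  amp <- outer(outer(gx, gy), gz)
  if (kind == "excitation") amp <- amp^2
  psf_volume(amp, voxel_size, kind)
}

#' Construct a binary pattern set
#'
#' @param patterns 3-D array `(H, W, T)` with values in `{0, 1}`.
#' @param fill_fraction nominal fill fraction in `(0, 1)`.
#' @param seed integer seed or a source-file tag.
#' @return a `pattern_set`.
#' @export
pattern_set <- function(patterns, fill_fraction = NA_real_, seed = NA) {
  assert_that(is.numeric(patterns) && length(dim(patterns)) == 3L,
              "`patterns` must be a 3-D array (H x W x T)")
  assert_that(dim(patterns)[3] >= 1L, "pattern set must contain >= 1 pattern")
  assert_that(all(patterns %in% c(0, 1)), "patterns must be binary (0/1)")
  structure(list(patterns = patterns,
                 fill_fraction = fill_fraction,
                 seed = seed),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("<pattern_set> T = %d patterns of %d x %d, mean fill %.3f\n",
              d[3], d[1], d[2], mean(x$patterns)))
  invisible(x)
}

#' Generate pseudo-random binary excitation patterns
#'
#' Each pixel of each pattern is an independent Bernoulli(`fill_fraction`)
#' draw; patterns are mutually independent. Deterministic given `seed`.
#'
#' @param t_count number of patterns (default 32).
#' @param shape integer length-2 lateral grid `(H, W)`.
#' @param fill_fraction probability a pixel is on (default 0.5).
#' @param seed integer seed.
#' @return a `pattern_set`.
#' @export
make_random_patterns <- function(t_count = 32L, shape, fill_fraction = 0.5,
                                 seed) {
  t_count <- as.integer(t_count)
  assert_that(t_count >= 1L, "`t_count` must be >= 1")
  assert_scalar_num(fill_fraction, "fill_fraction", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  shape <- as.integer(shape)
  with_seed(seed, {
    p <- array(as.numeric(stats::runif(prod(shape) * t_count) < fill_fraction),
               c(shape, t_count))
    pattern_set(p, fill_fraction, seed)
  })
}

# Otsu threshold of a numeric vector (maximizes between-class variance on a
# 256-bin histogram)
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = 257L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Load a measured pattern stack from a multi-page image
#'
#' Reads a multi-page TIFF, binarizes each page (Otsu threshold by default, or
#' a fixed numeric threshold), and validates the pattern-set invariants.
#' Pages that are entirely zero after binarization are rejected: a pattern
#' must excite something.
#'
#' @param path path to a multi-page TIFF stack.
#' @param threshold `"otsu"` (default) or a numeric cut; pixels strictly above
#'   the cut become 1.
#' @return a `pattern_set`.
#' @export
load_patterns <- function(path, threshold = "otsu") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
    if (length(dim(p)) != 2L)
      stopf("page %d is not a single-channel 2-D image", i)
    p
  })
  shp <- dim(mats[[1]])
  ok <- vapply(mats, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stopf("pages have inconsistent shapes (page %d differs)",
                      which(!ok)[1])
  bin <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    cut <- if (identical(threshold, "otsu")) otsu_threshold(as.numeric(m))
           else as.numeric(threshold)
    b <- (m > cut) * 1
    if (sum(b) == 0) stopf("page %d binarizes to all zeros (no excitation)", i)
    b
  })
  arr <- array(unlist(bin), c(shp, length(bin)))
  pattern_set(arr, mean(arr), seed = basename(path))
}

#' Write a pattern set as a multi-page TIFF
#'
#' @param pset a `pattern_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(pset, path) {
  assert_that(inherits(pset, "pattern_set"), "`pset` must be a pattern_set")
  pages <- lapply(seq_len(dim(pset$patterns)[3]),
                  function(t) pset$patterns[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
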