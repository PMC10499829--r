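## Synthetic ground-truth volumes: bead mixtures, vessel-like tube phantoms,
## and training sub-volume extraction from arbitrary stacks.

#' Construct a 3-D fluorophore distribution
#'
#' The ground-truth object of the imaging model: a non-negative scalar field
#' on a voxel grid, with physical voxel size and the axial position of the
#' first plane relative to the tissue surface (negative = below the surface).
#'
#' @param intensity 3-D numeric array, all values >= 0 (arbitrary
#'   fluorescence units).
#' @param voxel_size numeric length-3, `(dx, dy, dz)` in micrometres.
#' @param origin_z axial position of the first plane in micrometres relative
#'   to the tissue surface.
#' @return an `object_volume`.
#' @export
object_volume <- function(intensity, voxel_size = c(1 / 3, 1 / 3, 1),
                          origin_z = 0) {
  assert_that(is.numeric(intensity) && length(dim(intensity)) == 3L,
              "`intensity` must be a 3-D numeric array")
  assert_that(all(is.finite(intensity)), "`intensity` must be finite")
  assert_that(min(intensity) >= 0, "`intensity` must be non-negative")
  assert_that(is.numeric(voxel_size) && length(voxel_size) == 3L &&
                all(voxel_size > 0), "`voxel_size` must be 3 positive numbers")
  assert_scalar_num(origin_z, "origin_z")
  structure(list(intensity = intensity,
                 voxel_size = as.numeric(voxel_size),
                 origin_z = as.numeric(origin_z)),
            class = "object_volume")
}

#' @export
print.object_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<object_volume> %d x %d x %d voxels, voxel %s um, origin_z %.3g um, max %.4g\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "),
              x$origin_z, max(x$intensity)))
  invisible(x)
}

#' Specification of a two-population bead phantom
#'
#' A sparse field of small bright beads and larger dim beads. Radii are given
#' in pixels. Base intensities are drawn from a truncated normal; the small
#' beads are additionally brightened by `small_bead_gain` (default 5x).
#' Bead load is given either as explicit counts per volume
#' (`count_small`/`count_large`) or as an areal density (`density`, beads per
#' 100x100 px^2 of focal area, split equally between the two kinds).
#'
#' @param radius_small_px,radius_large_px bead radii in pixels.
#' @param intensity_mean,intensity_sd normal distribution of base intensity.
#' @param small_bead_gain multiplier applied to small-bead intensities.
#' @param density beads per 100^2 px^2 of lateral field (ignored when counts
#'   are given).
#' @param count_small,count_large explicit per-volume bead counts (optional).
#' @return a `bead_spec`.
#' @export
bead_spec <- function(radius_small_px = 1.5, radius_large_px = 6,
                      intensity_mean = 1, intensity_sd = 0.1,
                      small_bead_gain = 5, density = 3,
                      count_small = NULL, count_large = NULL) {
  assert_scalar_num(radius_small_px, "radius_small_px", 0, strict_lower = TRUE)
  assert_scalar_num(radius_large_px, "radius_large_px", 0, strict_lower = TRUE)
  assert_scalar_num(intensity_sd, "intensity_sd", 0)
  assert_scalar_num(small_bead_gain, "small_bead_gain", 0, strict_lower = TRUE)
  assert_scalar_num(density, "density", 0)
  if (!is.null(count_small)) assert_scalar_num(count_small, "count_small", 0)
  if (!is.null(count_large)) assert_scalar_num(count_large, "count_large", 0)
  structure(list(radius_small_px = radius_small_px,
                 radius_large_px = radius_large_px,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 small_bead_gain = small_bead_gain,
                 density = density,
                 count_small = count_small, count_large = count_large),
            class = "bead_spec")
}

# anti-aliased solid sphere: voxel value = linear edge coverage,
# 1 inside, 0 outside, ramp of width 1 voxel across the boundary
rasterize_sphere <- function(vol, centre, radius, value) {
  d <- dim(vol)
  lo <- pmax(1L, floor(centre - radius - 1))
  hi <- pmin(d, ceiling(centre + radius + 1))
  if (any(lo > hi)) return(vol)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  cov <- pmin(1, pmax(0, radius + 0.5 - r))
  vol[xs, ys, zs] <- pmax(vol[xs, ys, zs], value * cov)
  vol
}

#' Generate a bead-mixture ground-truth volume
#'
#' Places non-overlapping spheres of the two radii at uniform random centres
#' (rejection sampling on pairwise centre distance >= sum of radii), draws a
#' base intensity per bead from Normal(mean, sd) truncated at zero, and
#' multiplies small-bead intensities by `small_bead_gain`. Spheres are
#' rasterized with anti-aliased (linear-coverage) edges. Deterministic given
#' `seed`.
#'
#' @param spec a [bead_spec()].
#' @param shape integer length-3 grid size `(nx, ny, nz)`.
#' @param seed integer seed.
#' @param voxel_size,origin_z passed to [object_volume()].
#' @return an `object_volume` with attribute `beads` (a data.frame of centre,
#'   radius, intensity per bead).
#' @export
generate_beads_volume <- function(spec, shape, seed,
                                  voxel_size = c(1 / 3, 1 / 3, 1),
                                  origin_z = 0) {
  assert_that(inherits(spec, "bead_spec"), "`spec` must be a bead_spec")
  shape <- as.integer(shape)
  assert_that(length(shape) == 3L && all(shape >= 1L),
              "`shape` must be 3 positive integers")
  if (is.null(spec$count_small)) {
    area <- shape[1] * shape[2] / 1e4
    n_small <- round(spec$density * area / 2)
    n_large <- round(spec$density * area / 2)
  } else {
    n_small <- as.integer(spec$count_small)
    n_large <- as.integer(spec$count_large)
  }
  radii <- c(rep(spec$radius_small_px, n_small),
             rep(spec$radius_large_px, n_large))
  kinds <- c(rep("small", n_small), rep("large", n_large))
  vol <- array(0, shape)
  if (length(radii) == 0L)
    return(object_volume(vol, voxel_size, origin_z))
  if (any(2 * radii + 1 > shape[1]) || any(2 * radii + 1 > shape[2]))
    stopf("shape %s too small to place a bead of radius %g",
          paste(shape, collapse = "x"), max(radii))
  with_seed(seed, {
    # place large beads first so small ones can fill the gaps
    ord <- order(radii, decreasing = TRUE)
    radii <- radii[ord]; kinds <- kinds[ord]
    centres <- matrix(NA_real_, length(radii), 3)
    for (i in seq_along(radii)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(stats::runif(1, 1 + radii[i], shape[1] - radii[i]),
                  stats::runif(1, 1 + radii[i], shape[2] - radii[i]),
                  stats::runif(1, 1, shape[3]))
        if (i > 1L) {
          prev <- centres[seq_len(i - 1L), , drop = FALSE]
          dist <- sqrt(rowSums((prev - matrix(cand, i - 1L, 3, byrow = TRUE))^2))
          if (any(dist < radii[i] + radii[seq_len(i - 1L)])) next
        }
        centres[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place bead %d of %d without overlap; shape too small or density too high",
              i, length(radii))
    }
    base <- pmax(0, stats::rnorm(length(radii), spec$intensity_mean, spec$intensity_sd))
    inten <- base * ifelse(kinds == "small", spec$small_bead_gain, 1)
    for (i in seq_along(radii))
      vol <- rasterize_sphere(vol, centres[i, ], radii[i], inten[i])
    out <- object_volume(vol, voxel_size, origin_z)
    attr(out, "beads") <- data.frame(x = centres[, 1], y = centres[, 2],
                                     z = centres[, 3], radius = radii,
                                     kind = kinds, intensity = inten)
    out
  })
}

# Rasterize tubes given as polyline centrelines. Each element of
# `centrelines` is an n x 3 matrix of voxel coordinates; `radii` and
# `intensities` are per-tube. Voxel value = max over tubes of
# intensity * anti-aliased radial coverage.
rasterize_tubes <- function(shape, centrelines, radii, intensities) {
  vol <- array(0, shape)
  for (t in seq_along(centrelines)) {
    pts <- centrelines[[t]]
    # resample the polyline densely so consecutive samples are < 0.5 px apart
    seg <- diff(pts)
    if (nrow(pts) > 1L) {
      len <- sqrt(rowSums(seg^2))
      dense <- list(pts[1, , drop = FALSE])
      for (s in seq_len(nrow(seg))) {
        n <- max(1L, ceiling(len[s] / 0.5))
        f <- seq_len(n) / n
        dense[[s + 1L]] <- pts[rep(s, n), , drop = FALSE] + outer(f, seg[s, ])
      }
      pts <- do.call(rbind, dense)
    }
    for (p in seq_len(nrow(pts)))
      vol <- rasterize_sphere(vol, pts[p, ], radii[t], intensities[t])
  }
  vol
}

#' Generate a vessel-like ground-truth volume
#'
#' Grows seedable random-walk tubes with radii sampled uniformly in
#' `radius_range_px`, rasterizes them with anti-aliased edges, zeroes voxels
#' below `intensity_threshold` (a fraction of the volume maximum), optionally
#' rescales the grid by `rescale` (trilinear), and normalizes the volume so
#' its maximum is 1.
#'
#' @param radius_range_px numeric length-2 `(min, max)` tube radius in pixels.
#' @param intensity_threshold fraction of the maximum intensity below which
#'   voxels are set to zero (default `190/255`, an 8-bit threshold of 190).
#' @param shape integer length-3 grid size.
#' @param seed integer seed.
#' @param n_tubes number of tubes to grow.
#' @param rescale optional isotropic resampling factor applied before
#'   normalization (default 1 = off).
#' @param voxel_size,origin_z passed to [object_volume()].
#' @return an `object_volume` with maximum 1 (all-zero if the threshold
#'   removes everything).
#' @export
generate_vessel_volume <- function(radius_range_px = c(1, 7),
                                   intensity_threshold = 190 / 255,
                                   shape, seed, n_tubes = 6,
                                   rescale = 1,
                                   voxel_size = c(1 / 3, 1 / 3, 1),
                                   origin_z = 0) {
  assert_that(length(radius_range_px) == 2L &&
                radius_range_px[1] >= 1 &&
                radius_range_px[1] <= radius_range_px[2],
              "`radius_range_px` must satisfy 1 <= min <= max")
  assert_scalar_num(intensity_threshold, "intensity_threshold", 0)
  shape <- as.integer(shape)
  with_seed(seed, {
    centrelines <- vector("list", n_tubes)
    radii <- stats::runif(n_tubes, radius_range_px[1], radius_range_px[2])
    # thinner vessels are dimmer, so an intensity threshold removes them
    inten <- stats::runif(n_tubes, 0.4, 1) *
      (radii / radius_range_px[2])^0.5
    for (t in seq_len(n_tubes)) {
      pos <- c(stats::runif(1, 1, shape[1]),
               stats::runif(1, 1, shape[2]),
               stats::runif(1, 1, shape[3]))
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      n_steps <- max(shape)  # long enough to cross the volume
      path <- matrix(NA_real_, n_steps, 3)
      step <- 2
      for (s in seq_len(n_steps)) {
        path[s, ] <- pos
        turn <- stats::rnorm(3, sd = 0.25)
        dir <- dir + turn; dir <- dir / sqrt(sum(dir^2))
        pos <- pos + step * dir
        if (any(pos < -5) || any(pos > shape + 5)) {
          path <- path[seq_len(s), , drop = FALSE]
          break
        }
      }
      centrelines[[t]] <- path[!is.na(path[, 1]), , drop = FALSE]
    }
    vol <- rasterize_tubes(shape, centrelines, radii, inten)
    if (rescale != 1) vol <- resample_trilinear(vol, rescale)
    mx <- max(vol)
    if (intensity_threshold >= 1) vol[] <- 0
    else if (mx > 0) vol[vol < intensity_threshold * mx] <- 0
    mx <- max(vol)
    if (mx > 0) vol <- vol / mx
    object_volume(vol, voxel_size, origin_z)
  })
}

#' Extract training sub-volumes from a stack
#'
#' Clips intensities above `clip_at` to `clip_at`, slides an axial window of
#' `subvol_depth` planes with step `z_stride`, and keeps only windows whose
#' mean intensity strictly exceeds `mean_gate` (default: the mean of the
#' whole clipped stack). Windows are returned in axial order.
#'
#' @param stack an `object_volume`.
#' @param subvol_depth window depth in planes.
#' @param z_stride axial step between window starts (planes, default 5).
#' @param clip_at intensity ceiling (default 20).
#' @param mean_gate keep windows with mean > `mean_gate`; `NULL` (default)
#'   uses the global mean of the clipped stack.
#' @return a list of `object_volume` windows (possibly empty).
#' @export
extract_training_subvolumes <- function(stack, subvol_depth, z_stride = 5L,
                                        clip_at = 20, mean_gate = NULL) {
  assert_that(inherits(stack, "object_volume"), "`stack` must be an object_volume")
  d <- dim(stack$intensity)
  subvol_depth <- as.integer(subvol_depth)
  z_stride <- as.integer(z_stride)
  assert_that(z_stride >= 1L, "`z_stride` must be >= 1")
  assert_that(d[3] >= subvol_depth, "stack depth (%d) < subvol_depth (%d)",
              d[3], subvol_depth)
  vol <- pmin(stack$intensity, clip_at)
  if (is.null(mean_gate)) mean_gate <- mean(vol)
  starts <- seq(1L, d[3] - subvol_depth + 1L, by = z_stride)
  kept <- list()
  for (s in starts) {
    w <- vol[, , s:(s + subvol_depth - 1L), drop = FALSE]
    if (mean(w) > mean_gate) {
      ov <- object_volume(w, stack$voxel_size,
                          stack$origin_z + (s - 1L) * stack$voxel_size[3])
      kept[[length(kept) + 1L]] <- ov
    }
  }
  if (length(kept) == 0L)
    message("extract_training_subvolumes: no window exceeded the mean gate")
  kept
}
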