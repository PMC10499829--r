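## The full forward imaging model: patterned 3-D excitation, object
## interaction, per-depth scattering blur, emission blur, focal-plane
## extraction, EMCCD detection; plus the paired-dataset builder.

#' Patterned 3-D excitation field
#'
#' Convolves the binary focal-plane pattern (a 2-D sheet at the focal plane)
#' in 3-D with the excitation PSF: slice `k` of the result is the pattern
#' convolved in 2-D with slice `k` of the PSF, so the slice index measures
#' axial defocus from the focal plane and the axial confinement of the
#' excitation is carried entirely by the PSF's axial extent.
#'
#' @param expsf an excitation `psf_volume`.
#' @param pattern binary matrix on the object's lateral grid.
#' @return a 3-D array `(H, W, Zpsf)` of excitation intensity; the focal
#'   plane corresponds to the PSF's centre slice.
#' @export
patterned_excitation <- function(expsf, pattern) {
  assert_that(inherits(expsf, "psf_volume"), "`expsf` must be a psf_volume")
  assert_that(is.matrix(pattern), "`pattern` must be a matrix")
  d <- dim(expsf$amplitude)
  out <- array(0, c(dim(pattern), d[3]))
  for (z in seq_len(d[3])) {
    sl <- expsf$amplitude[, , z, drop = FALSE]
    dim(sl) <- d[1:2]
    out[, , z] <- if (all(d[1:2] == 1L)) pattern * sl[1L, 1L]
                  else conv2d_same(pattern, sl)
  }
  pmax(out, 0)  # clip FFT round-off
}

# index of the sPSF image whose depth is closest to `depth`
spsf_plane_index <- function(spsf_stack, depth) {
  which.min(abs(spsf_stack$depths - depth))
}

# depth below the surface of object plane z (1-based); origin_z is the axial
# position of plane 1 relative to the surface (negative = below)
object_plane_depths <- function(object) {
  d <- dim(object$intensity)[3]
  -(object$origin_z + (seq_len(d) - 1L) * object$voxel_size[3])
}

#' Noise-free point-scanning reference image of the focal plane
#'
#' The object convolved in 3-D with the excitation PSF, evaluated at the
#' focal plane: the ground truth the inverse model is trained against.
#'
#' @param object an `object_volume`.
#' @param expsf excitation `psf_volume`.
#' @param focal_plane 1-based z index (default: centre plane).
#' @return a matrix `(H, W)`.
#' @export
pstpm_image <- function(object, expsf,
                        focal_plane = kernel_centre(dim(object$intensity)[3])) {
  X <- object$intensity
  d <- dim(X); dk <- dim(expsf$amplitude)
  cz <- kernel_centre(dk[3])
  out <- matrix(0, d[1], d[2])
  for (zp in seq_len(d[3])) {
    kz <- cz + (focal_plane - zp)
    if (kz < 1L || kz > dk[3]) next
    sl <- expsf$amplitude[, , kz, drop = FALSE]
    dim(sl) <- dk[1:2]
    if (sum(sl) == 0) next
    out <- out + if (all(dk[1:2] == 1L)) X[, , zp] * sl[1L, 1L]
                 else conv2d_same(X[, , zp], sl)
  }
  pmax(out, 0)
}

#' Simulate one patterned wide-field frame
#'
#' Implements the forward imaging chain: the patterned excitation field is
#' multiplied element-wise with the object; each excited plane is blurred in
#' 2-D by the scattering PSF at its own depth; the result is convolved in
#' 3-D with the emission PSF and the focal plane is extracted. With a camera
#' the frame is scaled to expected photoelectrons (`photons_per_unit`) and
#' detected; otherwise the noise-free focal-plane image is returned.
#'
#' @param object an `object_volume`.
#' @param pattern binary matrix on the object's lateral grid.
#' @param expsf,empsf excitation and emission `psf_volume`s.
#' @param spsf_stack an `spsf_stack` whose depths cover the object planes.
#' @param focal_plane 1-based z index of the focal plane (default: centre).
#' @param camera optional [camera_model()]; `NULL` returns the noise-free
#'   frame in object-intensity units.
#' @param lut `em_gain_lut` (required with a camera).
#' @param photons_per_unit expected photoelectrons per object intensity unit.
#' @param seed integer seed for the detection noise.
#' @param excitation optional precomputed [patterned_excitation()] field
#'   (reused across objects that share a pattern).
#' @return detected (or noise-free) frame, a matrix `(H, W)`.
#' @export
simulate_deep_frame <- function(object, pattern, expsf, empsf, spsf_stack,
                                focal_plane = kernel_centre(dim(object$intensity)[3]),
                                camera = NULL, lut = NULL,
                                photons_per_unit = 1, seed = NULL,
                                excitation = NULL) {
  X <- object$intensity
  d <- dim(X)
  assert_that(focal_plane >= 1L && focal_plane <= d[3],
              "`focal_plane` outside the volume")
  if (is.null(excitation)) excitation <- patterned_excitation(expsf, pattern)
  assert_that(identical(dim(excitation)[1:2], d[1:2]),
              "pattern/object lateral grids differ")
  dk <- dim(empsf$amplitude)
  cz <- kernel_centre(dk[3])
  ez_n <- dim(excitation)[3]
  ez_c <- kernel_centre(ez_n)
  depths <- object_plane_depths(object)
  out <- matrix(0, d[1], d[2])
  for (zp in seq_len(d[3])) {
    kz <- cz + (focal_plane - zp)
    if (kz < 1L || kz > dk[3]) next
    em_sl <- empsf$amplitude[, , kz]
    if (sum(em_sl) == 0) next
    ez <- ez_c + (zp - focal_plane)  # excitation slice at this defocus
    if (ez < 1L || ez > ez_n) next   # beyond the excitation PSF: dark plane
    excited <- excitation[, , ez] * X[, , zp]
    if (all(excited == 0)) next
    sp <- spsf_stack$images[, , spsf_plane_index(spsf_stack, depths[zp]),
                            drop = FALSE]
    dim(sp) <- dim(spsf_stack$images)[1:2]
    scattered <- if (all(dim(sp) == 1L)) excited * sp[1L, 1L]
                 else conv2d_same(excited, sp)
    out <- out + conv2d_same(scattered, em_sl)
  }
  out <- pmax(out, 0)
  if (is.null(camera)) return(out)
  detect(out * photons_per_unit, camera, lut, seed = seed)
}

#' Simulate a full patterned measurement stack
#'
#' Runs [simulate_deep_frame()] once per pattern with independent noise
#' draws, and pairs the T detected frames with the noise-free point-scanning
#' ground-truth image of the focal plane. Full provenance (all parameters
#' and seeds) is recorded.
#'
#' @param object an `object_volume`.
#' @param patterns a `pattern_set`.
#' @param expsf,empsf excitation and emission `psf_volume`s.
#' @param spsf_stack an `spsf_stack`.
#' @param camera optional [camera_model()] (`NULL` = noise-free frames).
#' @param lut `em_gain_lut` (required with a camera).
#' @param photons_per_unit expected photoelectrons per intensity unit;
#'   the default 5 puts isolated bright features near a handful of photons.
#' @param focal_plane 1-based z index (default: centre plane).
#' @param seed integer seed; frame t uses `substream_seed(seed, "frame", t)`.
#' @param id optional stack identifier carried into datasets.
#' @return a `measurement_stack`: list with `measurements` (H x W x T),
#'   `ground_truth` (H x W), `pattern_seed`, `focal_plane`, `norm` (the
#'   per-stack normalization factors used for learning), `provenance`.
#' @export
simulate_measurement_stack <- function(object, patterns, expsf, empsf,
                                       spsf_stack, camera = NULL, lut = NULL,
                                       photons_per_unit = 5,
                                       focal_plane = kernel_centre(dim(object$intensity)[3]),
                                       seed = 1L, id = NULL) {
  assert_that(inherits(patterns, "pattern_set"), "`patterns` must be a pattern_set")
  d <- dim(object$intensity)
  tp <- dim(patterns$patterns)
  assert_that(identical(tp[1:2], d[1:2]),
              "pattern grid (%dx%d) must match object lateral grid (%dx%d)",
              tp[1], tp[2], d[1], d[2])
  T_ <- tp[3]
  meas <- array(0, c(d[1], d[2], T_))
  for (t in seq_len(T_)) {
    meas[, , t] <- simulate_deep_frame(
      object, patterns$patterns[, , t], expsf, empsf, spsf_stack,
      focal_plane = focal_plane, camera = camera, lut = lut,
      photons_per_unit = photons_per_unit,
      seed = if (is.null(camera)) NULL else substream_seed(seed, "frame", t))
  }
  gt <- pstpm_image(object, expsf, focal_plane)
  # per-stack normalization for the learning stage: measurements by their
  # 99.9th percentile, ground truth by its max; factors stored
  meas_scale <- as.numeric(stats::quantile(meas, 0.999))
  if (meas_scale <= 0) meas_scale <- max(meas, 1e-12)
  gt_scale <- max(gt)
  if (gt_scale <= 0) gt_scale <- 1
  structure(list(measurements = meas, ground_truth = gt,
                 focal_plane = focal_plane, id = id,
                 norm = list(measurement_scale = meas_scale,
                             ground_truth_scale = gt_scale),
                 provenance = list(seed = seed,
                                   photons_per_unit = photons_per_unit,
                                   t_count = T_,
                                   pattern_seed = patterns$seed,
                                   camera = camera,
                                   spsf_depths = spsf_stack$depths)),
            class = "measurement_stack")
}

#' @export
print.measurement_stack <- function(x, ...) {
  d <- dim(x$measurements)
  cat(sprintf("<measurement_stack> T = %d frames of %d x %d, focal plane %d\n",
              d[3], d[1], d[2], x$focal_plane))
  invisible(x)
}

#' Simulate and split a paired training dataset
#'
#' Simulates one measurement stack per object, splits the stacks into
#' train/validation at the given ratio (default 4:1) after reserving
#' `n_test` held-out test stacks, and (optionally) writes the dataset and a
#' manifest to disk.
#'
#' @param objects list of `object_volume`s.
#' @param patterns a `pattern_set` shared by all stacks.
#' @param expsf,empsf PSFs.
#' @param spsf_stack an `spsf_stack`.
#' @param camera,lut detection model (optional).
#' @param photons_per_unit photoelectrons per intensity unit.
#' @param split train:val ratio as length-2 numeric (default `c(4, 1)`).
#' @param n_test stacks reserved for the held-out test split (default 0).
#' @param seed integer seed; stack i uses `substream_seed(seed, "stack", i)`.
#' @param out_dir optional directory; when given, stacks are written as RDS
#'   shards plus a YAML manifest recording parameters, seeds and splits.
#' @return a dataset: list with `stacks`, `splits` (list of index vectors
#'   `train`, `val`, `test`), `seed`, and `manifest` (when written).
#' @export
build_dataset <- function(objects, patterns, expsf, empsf, spsf_stack,
                          camera = NULL, lut = NULL, photons_per_unit = 5,
                          split = c(4, 1), n_test = 0L, seed = 1L,
                          out_dir = NULL) {
  assert_that(length(objects) >= 1L, "need at least one object")
  n <- length(objects)
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    stacks[[i]] <- simulate_measurement_stack(
      objects[[i]], patterns, expsf, empsf, spsf_stack,
      camera = camera, lut = lut, photons_per_unit = photons_per_unit,
      seed = substream_seed(seed, "stack", i), id = i)
  }
  n_test <- min(as.integer(n_test), n - 1L)
  idx <- seq_len(n)
  test <- if (n_test > 0L) utils::tail(idx, n_test) else integer(0)
  rest <- setdiff(idx, test)
  n_train <- round(length(rest) * split[1] / sum(split))
  n_train <- max(1L, min(n_train, length(rest) - 1L))
  splits <- list(train = rest[seq_len(n_train)],
                 val = rest[-seq_len(n_train)],
                 test = test)
  ds <- list(stacks = stacks, splits = splits, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    shard_files <- sprintf("stack_%04d.rds", seq_len(n))
    for (i in seq_len(n))
      saveRDS(stacks[[i]], file.path(out_dir, shard_files[i]))
    manifest <- list(n_stacks = n, shards = shard_files, splits = splits,
                     seed = seed, photons_per_unit = photons_per_unit,
                     t_count = dim(patterns$patterns)[3],
                     pattern_seed = patterns$seed,
                     spsf_depths = spsf_stack$depths,
                     depth_sls = if (!is.null(spsf_stack$medium))
                       spsf_stack$depths[spsf_plane_index(
                         spsf_stack, -objects[[1]]$origin_z)] *
                       spsf_stack$medium$mu_s else NA)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    ds$manifest <- file.path(out_dir, "manifest.yaml")
  }
  ds
}

#' Load a dataset written by [build_dataset()]
#' @param dir dataset directory containing `manifest.yaml` and RDS shards.
#' @return the dataset list.
#' @export
load_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  stacks <- lapply(manifest$shards, function(f) readRDS(file.path(dir, f)))
  splits <- lapply(manifest$splits, as.integer)
  list(stacks = stacks, splits = splits, seed = manifest$seed,
       manifest = file.path(dir, "manifest.yaml"))
}
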