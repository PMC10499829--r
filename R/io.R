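## Shared I/O: multi-page float TIFF stacks with YAML metadata in the
## description tag, RDS bundles for composite objects, YAML configuration.

#' Write an image stack as a multi-page float TIFF
#'
#' Data are stored as 32-bit floats scaled to `[0, 1]` (the TIFF writer's
#' float range); the scale factor and any metadata (voxel size, depth tag,
#' seeds) are recorded in a YAML sidecar (`<path>.yaml`) and restored on
#' read, so float32 round trips are lossless up to float32 precision.
#'
#' @param data a matrix or 3-D array (pages along the third dimension).
#' @param path output path.
#' @param metadata named list stored alongside the scale factor.
#' @return `path`, invisibly.
#' @export
write_stack <- function(data, path, metadata = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  assert_that(length(dim(data)) == 3L, "`data` must be a matrix or 3-D array")
  mx <- max(data, 0)
  scale <- if (mx > 0) mx else 1
  meta <- c(list(scale = scale), metadata)
  pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15L)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Integer-sampled TIFFs from other sources are promoted to float (the TIFF
#' reader returns them on `[0, 1]`) with the promotion recorded; missing
#' metadata (no sidecar) loads with a warning and a unit scale.
#'
#' @param path TIFF path.
#' @return a 3-D array with attribute `metadata` (named list incl. `scale`).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar))
    tryCatch(yaml::read_yaml(sidecar), error = function(e) NULL)
  if (is.null(meta) || is.null(meta$scale)) {
    warning("no stack metadata found in ", basename(path),
            "; assuming unit scale", call. = FALSE)
    meta <- c(list(scale = 1), meta)
  }
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  arr <- array(unlist(mats), c(dim(mats[[1]]), length(mats))) * meta$scale
  attr(arr, "metadata") <- meta
  arr
}

#' Default run configuration
#'
#' The nested configuration driving [run_pipeline()]: optics, medium, camera,
#' patterns, phantom, dataset, network and training sections plus a global
#' seed from which every stage derives its own sub-stream
#' ([substream_seed()]). Serializes losslessly to YAML.
#'
#' @param seed global seed.
#' @param preset `"smoke"` (minutes on one CPU: small grids, few stacks, few
#'   epochs), `"desk"` (the scaled-down learning setup: 64x64, 8 patterns,
#'   ~100 stacks, 20 epochs), or `"full"` (the full-scale configuration:
#'   256x256, 32 patterns, 3455 stacks, 100 epochs; hours, intended for
#'   capable hardware).
#' @return a `run_config` (a named nested list).
#' @export
default_config <- function(seed = 1L, preset = c("desk", "smoke", "full")) {
  preset <- match.arg(preset)
  base <- list(
    seed = as.integer(seed),
    optics = list(na = 1.0, n_immersion = 1.33, lambda_ex = 1.036,
                  lambda_em = 0.58, psf_shape = c(33L, 33L, 9L),
                  voxel_size = c(1 / 3, 1 / 3, 1)),
    medium = list(mu_s = 0.02, g = 0.9, n_tissue = 1.33),
    camera = list(g_em = 300, n_stages = 512L, dark_mean = 0.01,
                  read_sigma = 20, lut_max_input = 200L),
    patterns = list(t_count = 32L, fill_fraction = 0.5),
    phantoms = list(kind = "beads", count_small = 6L, count_large = 3L,
                    intensity_mean = 1, intensity_sd = 0.1,
                    small_bead_gain = 5),
    dataset = list(n_objects = 100L, shape = c(256L, 256L, 9L),
                   depth_sls = 4, photons_per_unit = 5,
                   split = c(4, 1), n_test = 8L,
                   spsf_photons = 1e6, spsf_shape = c(63L, 63L)),
    network = list(base_width = 64L, depth_levels = 4L,
                   scse_reduction = 2L, loss = "kl"),
    training = list(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                    batch_size = 10L, epochs = 100L))
  if (preset == "full") {
    base$dataset$n_objects <- 3455L
    base$dataset$n_test <- 128L
  } else if (preset == "desk") {
    base$patterns$t_count <- 8L
    base$dataset$shape <- c(64L, 64L, 9L)
    base$dataset$n_objects <- 100L
    base$dataset$n_test <- 10L
    base$network$base_width <- 16L
    base$training$epochs <- 20L
  } else {
    base$patterns$t_count <- 4L
    base$dataset$shape <- c(32L, 32L, 5L)
    base$dataset$n_objects <- 8L
    base$dataset$n_test <- 1L
    base$dataset$spsf_photons <- 2e4
    base$phantoms$count_small <- 3L
    base$phantoms$count_large <- 1L
    base$network$base_width <- 8L
    base$network$depth_levels <- 2L
    base$training$epochs <- 3L
    base$training$batch_size <- 4L
  }
  structure(base, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

# Stable content hash of a configuration-like object (used for stage
# skip-if-unchanged). Hashes the canonical YAML text so that a value is
# invariant to YAML round trips (R storage type of whole numbers may change).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x, precision = 15L), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline from a configuration
#'
#' Executes phantoms -> scattering PSFs -> paired dataset -> training ->
#' evaluation, writing every artifact under `out_dir` together with a
#' manifest that ties artifacts to the configuration and seeds. Re-running
#' with an unchanged configuration skips completed stages (matched by a
#' content hash of the stage inputs).
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return list with `model`, `dataset`, `metrics` (the cohort table),
#'   `manifest` (path).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage_file <- function(name) file.path(out_dir, paste0(name, ".rds"))
  run_stage <- function(name, inputs, fn) {
    f <- stage_file(name)
    h <- config_hash(inputs)
    if (file.exists(f)) {
      cached <- readRDS(f)
      if (identical(cached$hash, h)) {
        say("stage %-10s cached", name)
        return(cached$value)
      }
    }
    say("stage %-10s running", name)
    value <- fn()
    saveRDS(list(hash = h, value = value), f)
    value
  }

  oc <- config$optics
  expsf <- make_gaussian_psf(oc$na, oc$lambda_ex, oc$n_immersion,
                             oc$psf_shape, oc$voxel_size, "excitation")
  empsf <- make_gaussian_psf(oc$na, oc$lambda_em, oc$n_immersion,
                             oc$psf_shape, oc$voxel_size, "emission")
  medium <- scattering_medium(config$medium$mu_s, config$medium$g,
                              config$medium$n_tissue)
  dz <- oc$voxel_size[3]
  shape <- as.integer(config$dataset$shape)
  focal_depth <- config$dataset$depth_sls * medium$scattering_length
  origin_z <- -(focal_depth - (kernel_centre(shape[3]) - 1L) * dz)
  depths <- -(origin_z + (seq_len(shape[3]) - 1L) * dz)

  objects <- run_stage("phantoms", list(config$phantoms, shape, seed), function() {
    ph <- config$phantoms
    lapply(seq_len(config$dataset$n_objects), function(i) {
      s <- substream_seed(seed, "phantom", i)
      if (identical(ph$kind, "vessels"))
        generate_vessel_volume(shape = shape, seed = s,
                               voxel_size = oc$voxel_size, origin_z = origin_z)
      else
        generate_beads_volume(
          bead_spec(intensity_mean = ph$intensity_mean,
                    intensity_sd = ph$intensity_sd,
                    small_bead_gain = ph$small_bead_gain,
                    count_small = ph$count_small,
                    count_large = ph$count_large),
          shape, seed = s, voxel_size = oc$voxel_size, origin_z = origin_z)
    })
  })

  spsf <- run_stage("spsf", list(config$medium, depths, oc$na,
                                 config$dataset$spsf_photons,
                                 config$dataset$spsf_shape, seed), function() {
    build_spsf_stack(medium, sort(depths), oc$na,
                     n_photons = config$dataset$spsf_photons,
                     shape = config$dataset$spsf_shape,
                     pixel_size = oc$voxel_size[1],
                     seed = substream_seed(seed, "spsf-stack"))
  })

  camera <- do.call(camera_model, config$camera)
  lut <- run_stage("emlut", list(config$camera, seed), function()
    build_em_lut(camera, seed = substream_seed(seed, "emlut")))

  patterns <- make_random_patterns(config$patterns$t_count, shape[1:2],
                                   config$patterns$fill_fraction,
                                   seed = substream_seed(seed, "patterns"))

  dataset <- run_stage("dataset", list(config$dataset, config$patterns,
                                       config$phantoms, config$medium,
                                       config$camera, seed), function()
    build_dataset(objects, patterns, expsf, empsf, spsf,
                  camera = camera, lut = lut,
                  photons_per_unit = config$dataset$photons_per_unit,
                  split = config$dataset$split,
                  n_test = config$dataset$n_test,
                  seed = substream_seed(seed, "dataset"),
                  out_dir = file.path(out_dir, "dataset")))

  net_cfg <- network_config(in_channels = config$patterns$t_count,
                            base_width = config$network$base_width,
                            depth_levels = config$network$depth_levels,
                            scse_reduction = config$network$scse_reduction,
                            loss = config$network$loss)
  tr_cfg <- train_config(lr = config$training$lr,
                         beta1 = config$training$beta1,
                         beta2 = config$training$beta2,
                         batch_size = config$training$batch_size,
                         epochs = config$training$epochs,
                         seed = substream_seed(seed, "training"))
  model <- run_stage("model", list(config$network, config$training,
                                   config$dataset, seed), function()
    train_network(dataset, net_cfg, tr_cfg, verbose = verbose))

  metrics <- evaluate_cohort(model, dataset, split = "val")
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  manifest <- list(config = unclass(config),
                   artifacts = c("phantoms.rds", "spsf.rds", "emlut.rds",
                                 "dataset.rds", "model.rds", "metrics.csv",
                                 file.path("dataset", "manifest.yaml")),
                   summary = attr(metrics, "summary"))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  list(model = model, dataset = dataset, metrics = metrics,
       manifest = manifest_path)
}
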