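test_that("patterned excitation reduces correctly for degenerate patterns", {
  expsf <- fixture_expsf()
  H <- 24L; W <- 24L

  # all-zeros pattern -> zero field
  zero <- patterned_excitation(expsf, matrix(0, H, W))
  expect_true(all(zero == 0))

  # single-pixel pattern -> the excitation PSF centred at that pixel
  pat <- matrix(0, H, W); pat[12, 12] <- 1
  field <- patterned_excitation(expsf, pat)
  sl <- expsf$amplitude[, , 3]
  expect_equal(field[12, 12, 3], sl[9, 9], tolerance = 1e-10)
  expect_equal(field[12 + 3, 12 - 2, 3], sl[9 + 3, 9 - 2], tolerance = 1e-10)

  # all-ones pattern -> each z-plane is laterally uniform (= the z-marginal)
  # away from the boundary
  ones <- patterned_excitation(expsf, matrix(1, H, W))
  core <- ones[9:16, 9:16, 3]
  expect_equal(max(core) - min(core), 0, tolerance = 1e-9)
  expect_equal(core[1, 1], sum(expsf$amplitude[, , 3]), tolerance = 1e-9)

  # a pattern grid that disagrees with the object grid is rejected
  obj <- object_volume(array(1, c(H, W, 3L)))
  spsf <- delta_spsf_stack(0:2, c(1L, 1L))
  expect_error(simulate_deep_frame(obj, matrix(1, H, 2 * W), expsf,
                                   fixture_empsf(3L), spsf),
               "lateral grids differ")
})

test_that("the frame simulator matches a brute-force convolution oracle", {
  # delta scattering and a delta (unit) excitation under a uniform pattern
  # reduce the imaging chain to a single 3-D convolution of the object with
  # the remaining PSF kernel; the FFT-based frame must match a direct
  # spatial-domain quadruple-loop convolution at the focal plane
  set.seed(5)
  shape <- c(8L, 8L, 8L)
  X <- array(stats::runif(prod(shape)), shape)
  obj <- object_volume(X, c(1 / 3, 1 / 3, 1), origin_z = 0)
  ker <- array(stats::runif(3 * 3 * 5), c(3L, 3L, 5L))
  kpsf_em <- psf_volume(ker, c(1 / 3, 1 / 3, 1), "emission")
  kpsf_ex <- psf_volume(ker, c(1 / 3, 1 / 3, 1), "excitation")
  # laterally-delta, axially-uniform excitation: every object plane is
  # excited equally (by 1/15), leaving the emission convolution as the only
  # spatial operator
  ex_flat <- psf_volume(array(1, c(1L, 1L, 15L)), c(1 / 3, 1 / 3, 1),
                        "excitation")
  spsf <- delta_spsf_stack(depths = 0:7, shape = c(1L, 1L))

  for (focal in c(3L, 5L)) {
    oracle <- conv3d_bruteforce(X, ker / sum(ker))[, , focal]
    frame <- simulate_deep_frame(obj, matrix(1, 8, 8), ex_flat, kpsf_em,
                                 spsf, focal_plane = focal) * 15
    expect_lt(max(abs(frame - oracle)) / max(oracle), 1e-6)
    # the point-scanning reference image computes the same convolution with
    # the kernel in the excitation slot
    expect_lt(max(abs(pstpm_image(obj, kpsf_ex, focal) - oracle)) / max(oracle),
              1e-6)
  }
})

test_that("the noise-free forward model is linear and conserves energy", {
  set.seed(6)
  obj <- generate_beads_volume(bead_spec(count_small = 2, count_large = 1),
                               c(32L, 32L, 5L), seed = 3)
  expsf <- fixture_expsf(); empsf <- fixture_empsf()
  spsf <- delta_spsf_stack(0:4, c(1L, 1L))
  pat <- matrix(stats::rbinom(32 * 32, 1, 0.5), 32, 32)
  f1 <- simulate_deep_frame(obj, pat, expsf, empsf, spsf)
  obj3 <- object_volume(3 * obj$intensity, obj$voxel_size, obj$origin_z)
  f3 <- simulate_deep_frame(obj3, pat, expsf, empsf, spsf)
  expect_equal(f3, 3 * f1, tolerance = 1e-10)

  zero_obj <- object_volume(array(0, c(32, 32, 5)))
  expect_true(all(simulate_deep_frame(zero_obj, pat, expsf, empsf, spsf) == 0))

  # unit-sum scattering kernels conserve flux (object padded well inside)
  inner <- array(0, c(48, 48, 5))
  inner[20:28, 20:28, 3] <- 1
  obj_c <- object_volume(inner)
  gauss <- exp(-(outer((1:15 - 8)^2, (1:15 - 8)^2, "+")) / (2 * 2^2))
  spsf_g <- delta_spsf_stack(0:4, c(15L, 15L))
  for (k in 1:5) spsf_g$images[, , k] <- gauss / sum(gauss)
  uni <- matrix(1, 48, 48)
  unblurred <- simulate_deep_frame(obj_c, uni, expsf, empsf,
                                   delta_spsf_stack(0:4, c(1L, 1L)))
  blurred <- simulate_deep_frame(obj_c, uni, expsf, empsf, spsf_g)
  expect_equal(sum(blurred), sum(unblurred), tolerance = 0.01)
})

test_that("measurement stacks average to the fill-fraction scaling and are reproducible", {
  obj <- generate_beads_volume(bead_spec(count_small = 2, count_large = 1),
                               c(32L, 32L, 5L), seed = 9)
  expsf <- fixture_expsf(); empsf <- fixture_empsf()
  spsf <- delta_spsf_stack(0:4, c(1L, 1L))
  pats <- make_random_patterns(24L, c(32L, 32L), 0.5, seed = 17)
  ms <- simulate_measurement_stack(obj, pats, expsf, empsf, spsf, seed = 2)
  expect_identical(dim(ms$measurements), c(32L, 32L, 24L))

  uniform <- simulate_deep_frame(obj, matrix(1, 32, 32), expsf, empsf, spsf)
  avg <- apply(ms$measurements, c(1, 2), mean)
  # E[H_t] = 0.5 pointwise; compare where the frame carries signal
  sel <- uniform > 0.1 * max(uniform)
  ratio <- mean(avg[sel]) / mean(uniform[sel])
  expect_equal(ratio, 0.5, tolerance = 0.05)

  ms2 <- simulate_measurement_stack(obj, pats, expsf, empsf, spsf, seed = 2)
  expect_identical(ms$measurements, ms2$measurements)
  expect_gte(min(ms$ground_truth), 0)
})

test_that("scattering degrades structural similarity monotonically with depth", {
  med <- scattering_medium(0.02, 0.9, 1.33)
  obj <- generate_beads_volume(bead_spec(count_small = 4, count_large = 2),
                               c(48L, 48L, 5L), seed = 23,
                               voxel_size = c(1 / 3, 1 / 3, 1))
  expsf <- fixture_expsf(); empsf <- fixture_empsf()
  pats <- make_random_patterns(1L, c(48L, 48L), 0.5, seed = 3)
  gt <- pstpm_image(obj, expsf, 3L)
  gt <- gt / max(gt)
  mc <- metric_config()
  ssims <- vapply(c(2, 4, 6), function(sls) {
    z <- sls * med$scattering_length
    depths <- z + (-2:2)  # plane spacing 1 um around the focal depth
    spsf <- build_spsf_stack(med, depths, 1.0, n_photons = 1e5,
                             shape = c(47L, 47L), pixel_size = 1 / 3,
                             seed = 31 + sls)
    obj_d <- object_volume(obj$intensity, obj$voxel_size,
                           origin_z = -(z - 2))
    fr <- simulate_deep_frame(obj_d, pats$patterns[, , 1], expsf, empsf, spsf,
                              focal_plane = 3L)
    fr <- fr / max(fr)
    ssim_metric(gt, fr, mc)
  }, numeric(1))
  expect_true(all(diff(ssims) < 0))
})

test_that("datasets split 4:1, record provenance and rebuild identically", {
  objs <- lapply(1:10, function(i)
    generate_beads_volume(bead_spec(count_small = 2, count_large = 1),
                          c(32L, 32L, 5L), seed = 100 + i))
  expsf <- fixture_expsf(); empsf <- fixture_empsf()
  spsf <- delta_spsf_stack(0:4, c(1L, 1L))
  pats <- make_random_patterns(4L, c(32L, 32L), 0.5, seed = 8)
  dir1 <- file.path(tempdir(), "ds1")
  ds <- build_dataset(objs, pats, expsf, empsf, spsf, seed = 77,
                      out_dir = dir1)
  expect_length(ds$splits$train, 8)
  expect_length(ds$splits$val, 2)
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))

  # rebuilding from the same seed reproduces identical shards
  ds2 <- build_dataset(objs, pats, expsf, empsf, spsf, seed = 77)
  for (i in seq_along(ds$stacks))
    expect_identical(ds$stacks[[i]]$measurements, ds2$stacks[[i]]$measurements)

  # reloading from disk round-trips
  back <- load_dataset(dir1)
  expect_equal(back$splits$train, ds$splits$train)
  expect_identical(back$stacks[[3]]$ground_truth, ds$stacks[[3]]$ground_truth)
})
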