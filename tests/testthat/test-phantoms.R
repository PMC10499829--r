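test_that("bead volumes respect intensity rules, determinism and the empty case", {
  shape <- c(48L, 48L, 12L)
  # empty case: zero counts give an all-zero volume of the requested shape
  empty <- generate_beads_volume(bead_spec(count_small = 0, count_large = 0),
                                 shape, seed = 1)
  expect_identical(dim(empty$intensity), shape)
  expect_true(all(empty$intensity == 0))

  # with sd = 0 the small/large peak ratio is exactly the small-bead gain
  sp <- bead_spec(intensity_sd = 0, small_bead_gain = 5,
                  count_small = 1, count_large = 1)
  v <- generate_beads_volume(sp, shape, seed = 7)
  beads <- attr(v, "beads")
  expect_equal(max(beads$intensity[beads$kind == "small"]) /
                 max(beads$intensity[beads$kind == "large"]), 5)
  # peak voxel values realize the same ratio (bead interiors reach the full
  # intensity at these radii)
  expect_equal(max(v$intensity), 5 * beads$intensity[beads$kind == "large"])

  # determinism: same spec + seed -> voxel-identical volumes
  v2 <- generate_beads_volume(sp, shape, seed = 7)
  expect_identical(v$intensity, v2$intensity)
  v3 <- generate_beads_volume(sp, shape, seed = 8)
  expect_false(identical(v$intensity, v3$intensity))
})

test_that("bead placement is collision-free and volumes are non-negative", {
  for (seed in 1:5) {
    v <- generate_beads_volume(bead_spec(count_small = 6, count_large = 3),
                               c(64L, 64L, 10L), seed = seed)
    expect_gte(min(v$intensity), 0)
    b <- attr(v, "beads")
    # brute-force pairwise check: centre distances >= sum of radii
    for (i in seq_len(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
      d <- sqrt(sum((unlist(b[i, c("x", "y", "z")]) -
                       unlist(b[j, c("x", "y", "z")]))^2))
      expect_gte(d, b$radius[i] + b$radius[j])
    }
  }
})

test_that("bead generation fails loudly on impossible geometry", {
  expect_error(generate_beads_volume(bead_spec(count_small = 1, count_large = 1),
                                     c(8L, 8L, 4L), seed = 1),
               "too small")
  expect_error(bead_spec(radius_small_px = -1), "must be >")
  expect_error(bead_spec(intensity_sd = -0.1), "must be >=")
})

test_that("a straight tube rasterizes as a disc in cross-section", {
  shape <- c(21L, 40L, 21L)
  centre <- c(11, 1, 11)
  line <- rbind(c(11, 1, 11), c(11, 40, 11))
  vol <- descatter:::rasterize_tubes(shape, list(line), radii = 3, intensities = 1)
  for (y in c(5L, 20L, 35L)) {
    cs <- vol[, y, ]
    d <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"))
    expect_true(all(cs[d <= 2.5] == 1))   # solid interior
    expect_true(all(cs[d >= 3.6] == 0))   # empty exterior
  }
})

test_that("vessel volumes are thresholded, normalized and deterministic", {
  # threshold at >= max kills everything
  dead <- generate_vessel_volume(shape = c(32L, 32L, 16L), seed = 3,
                                 intensity_threshold = 1.0)
  expect_true(all(dead$intensity == 0))

  # default spec over several seeds: per-volume max is exactly 1
  for (seed in 1:6) {
    v <- generate_vessel_volume(shape = c(40L, 40L, 20L), seed = seed,
                                intensity_threshold = 0.3)
    expect_equal(max(v$intensity), 1)
    expect_gte(min(v$intensity), 0)
    v2 <- generate_vessel_volume(shape = c(40L, 40L, 20L), seed = seed,
                                 intensity_threshold = 0.3)
    expect_identical(v$intensity, v2$intensity)
  }
  expect_error(generate_vessel_volume(radius_range_px = c(5, 2),
                                      shape = c(32, 32, 8), seed = 1),
               "min <= max")
})

test_that("sub-volume extraction matches the exhaustive window-scan oracle", {
  # toy stack: 20 planes, dark lower half (0), bright upper half (10)
  vol <- array(rep(c(0, 10), each = 16 * 16 * 10), c(16, 16, 20))
  ov <- object_volume(vol)
  kept <- extract_training_subvolumes(ov, subvol_depth = 6, z_stride = 5,
                                      clip_at = 20)
  oracle <- subvolume_oracle(vol, 6L, 5L, 20)
  expect_length(kept, length(oracle))
  # windows start at planes {1, 6, 11} (1-based); only the all-bright window
  # at 11 exceeds the global mean of 5 under the strict ">" gate
  expect_identical(oracle, 11L)
  expect_equal(kept[[1]]$origin_z, ov$origin_z + 10 * ov$voxel_size[3])

  # randomized stacks against the oracle
  for (seed in 1:4) {
    set.seed(seed)
    v <- array(stats::rexp(12 * 12 * 23, 1 / 8), c(12, 12, 23))
    kept <- extract_training_subvolumes(object_volume(v), 5, 3, clip_at = 20)
    expect_length(kept, length(subvolume_oracle(v, 5L, 3L, 20)))
  }
})

test_that("sub-volume extraction clips intensities and handles uniform stacks", {
  # a single hot voxel is clipped to clip_at
  v <- array(1, c(8, 8, 10)); v[4, 4, 5] <- 100
  kept <- extract_training_subvolumes(object_volume(v), 4, 2, clip_at = 20,
                                      mean_gate = 0)
  expect_equal(max(vapply(kept, function(k) max(k$intensity), numeric(1))), 20)

  # uniform stack: window mean equals the global mean -> nothing kept
  u <- object_volume(array(5, c(8, 8, 12)))
  expect_message(kept <- extract_training_subvolumes(u, 4, 2, clip_at = 20),
                 "no window")
  expect_length(kept, 0)
})

test_that("object_volume validates its invariants", {
  expect_error(object_volume(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(object_volume(array(1, c(2, 2))), "3-D")
  expect_error(object_volume(array(1, c(2, 2, 2)), voxel_size = c(1, 0, 1)),
               "positive")
})
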