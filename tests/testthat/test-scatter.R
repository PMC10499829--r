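test_that("hop lengths follow the exponential free-path law", {
  expect_equal(sample_hop(0, 0.02), 0)
  # one mean free path: rnd1 = 1 - exp(-1) maps to s = 1/mu_s
  expect_equal(sample_hop(1 - exp(-1), 0.02), 50)
  expect_error(sample_hop(1, 0.02), "in \\[0, 1\\)")

  set.seed(101)
  s <- sample_hop(runif(1e6), 0.02)
  # CLT bound on the mean (sd of exponential = mean)
  expect_lt(abs(mean(s) - 50), 3 * 50 / sqrt(1e6))
  # Kolmogorov-Smirnov against the analytic CDF
  ks <- suppressWarnings(stats::ks.test(s[1:1e5], stats::pexp, rate = 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("deflection cosines follow the Henyey-Greenstein phase function", {
  # boundary substitutions
  expect_equal(sample_deflection(0, 0.9), -1)
  expect_equal(sample_deflection(1, 0.9), 1)
  expect_equal(sample_deflection(0.5, 0), 0)

  set.seed(202)
  ct <- sample_deflection(runif(1e5), 0.9)
  # anisotropy g is by definition the mean cosine
  sd_mc <- stats::sd(ct) / sqrt(1e5)
  expect_lt(abs(mean(ct) - 0.9) , 3 * sd_mc)

  # chi-square goodness of fit against the analytic distribution, using
  # equal-probability bins from the closed-form CDF (independent derivation:
  # integrating the phase-function density in cos(theta))
  hg_cdf <- function(cth, g)
    ((1 - g^2) / (2 * g)) * (1 / sqrt(1 + g^2 - 2 * g * cth) - 1 / (1 + g))
  nb <- 20L
  edges <- vapply(seq_len(nb - 1) / nb, function(p)
    stats::uniroot(function(cth) hg_cdf(cth, 0.9) - p, c(-1, 1),
                   tol = 1e-12)$root, numeric(1))
  obs <- as.numeric(table(cut(ct, c(-1, edges, 1), include.lowest = TRUE)))
  chi <- stats::chisq.test(obs, p = rep(1 / nb, nb))
  expect_gt(chi$p.value, 0.01)
})

test_that("spins preserve unit length and zero deflection is the identity", {
  u <- matrix(c(0, 0, 1), 1)
  expect_equal(spin_direction(u, 1, 2.1), u, tolerance = 1e-12)
  v <- spin_direction(u, 0, 0)
  expect_equal(abs(v[3]), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)

  set.seed(303)
  n <- 1e5
  uz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - uz^2)
  U <- cbind(r * cos(phi), r * sin(phi), uz)
  V <- spin_direction(U, sample_deflection(runif(n), 0.9), runif(n, 0, 2 * pi))
  expect_lt(max(abs(sqrt(rowSums(V^2)) - 1)), 1e-12)
  # the realized deflection cosine has mean g
  expect_lt(abs(mean(rowSums(U * V)) - 0.9), 3 * 0.13 / sqrt(n))
})

test_that("the scattering PSF degenerates to a delta at zero depth", {
  med <- scattering_medium(0.02, 0.9, 1.33)
  s0 <- simulate_spsf(med, 0, 1.0, 2e4, c(31, 31), 1 / 3, seed = 1)
  expect_equal(s0$image[16, 16], 1)
  expect_equal(sum(s0$image), 1)
})

test_that("near-ballistic media give an unscattered delta (analytic oracle)", {
  # mu_s * z0 = 0.01: optical depth so small that almost nothing scatters
  med <- scattering_medium(mu_s = 0.001, g = 0.9, n_tissue = 1.33)
  z0 <- 10
  s <- simulate_spsf(med, z0, 1.0, 1e5, c(31, 31), 1 / 3, seed = 4)
  # analytic unscattered fraction among accepted photons: within the
  # acceptance cone exp(-mu_s * z0 / uz) ~ 1 for all uz in the cone
  expect_gt(s$unscattered_fraction, 0.98)
  # virtually all accepted mass in the source pixel
  expect_gt(s$image[16, 16], 0.98)
  expect_lt(descatter:::radial_second_moment(s$image), 0.5)
})

test_that("halo width grows and acceptance falls with depth", {
  med <- scattering_medium(0.02, 0.9, 1.33)
  n_ph <- 3e5
  s2 <- simulate_spsf(med, 100, 1.0, n_ph, c(63, 63), 1 / 3, seed = 11)
  s7 <- simulate_spsf(med, 350, 1.0, n_ph, c(63, 63), 1 / 3, seed = 12)
  r2_2 <- descatter:::radial_second_moment(s2$image)
  r2_7 <- descatter:::radial_second_moment(s7$image)
  expect_gt(r2_7, r2_2)
  s0 <- simulate_spsf(med, 0, 1.0, 1e5, c(63, 63), 1 / 3, seed = 13)
  expect_lt(s2$acceptance, s0$acceptance)
  expect_lt(s7$acceptance, s2$acceptance)

  # statistical centro-symmetry: centroid within 3 sigma of the source
  w <- s2$image
  cx <- sum(row(w) * w); cy <- sum(col(w) * w)
  sig <- sqrt(r2_2 / s2$n_accepted)
  expect_lt(abs(cx - 32), 3 * sig)
  expect_lt(abs(cy - 32), 3 * sig)
})

test_that("PSF stacks are unit-sum, monotone in depth and reproducible", {
  med <- scattering_medium(0.02, 0.9, 1.33)
  st <- build_spsf_stack(med, depths = c(0, 100, 200, 300), na = 1.0,
                         n_photons = 5e4, shape = c(63, 63),
                         pixel_size = 1 / 3, seed = 21)
  expect_equal(apply(st$images, 3, sum), rep(1, 4), tolerance = 1e-12)
  r2 <- apply(st$images, 3, descatter:::radial_second_moment)
  expect_true(all(diff(r2) > 0))

  # duplicated depth reuses the sub-seed: identical images
  st2 <- build_spsf_stack(med, depths = c(100, 100), na = 1.0,
                          n_photons = 2e4, shape = c(31, 31),
                          pixel_size = 1 / 3, seed = 21)
  expect_identical(st2$images[, , 1], st2$images[, , 2])

  # depths = 0 gives a stack of one delta image
  st0 <- build_spsf_stack(med, 0, 1.0, 1e4, c(31, 31), 1 / 3, seed = 5)
  expect_equal(st0$images[16, 16, 1], 1)
})
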