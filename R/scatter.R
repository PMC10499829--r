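## Monte Carlo simulation of the scattering point spread function: the
## apparent lateral photon distribution at the launch plane z = -z0 for a
## point emitter at depth z0, as seen through the tissue surface within the
## objective's acceptance cone.

#' Tissue optical parameters
#'
#' @param mu_s scattering coefficient in 1/um.
#' @param g Henyey-Greenstein anisotropy (mean cosine of the deflection
#'   angle), in (-1, 1).
#' @param n_tissue tissue refractive index.
#' @return a `scattering_medium` with derived `scattering_length = 1/mu_s`.
#' @export
scattering_medium <- function(mu_s = 0.02, g = 0.9, n_tissue = 1.33) {
  assert_scalar_num(mu_s, "mu_s", 0, strict_lower = TRUE)
  assert_scalar_num(g, "g", -1, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_num(n_tissue, "n_tissue", 1)
  structure(list(mu_s = mu_s, g = g, n_tissue = n_tissue,
                 scattering_length = 1 / mu_s),
            class = "scattering_medium")
}

#' Sample a free-path ("hop") length
#'
#' Inverse-CDF sampling of the exponential free-path distribution implied by
#' the scattering coefficient: `s = -log(1 - rnd1) / mu_s`.
#'
#' @param rnd1 uniform(0,1) draws (vectorized); values equal to 1 are
#'   rejected (they map to an infinite hop).
#' @param mu_s scattering coefficient in 1/um.
#' @return path lengths in micrometres.
#' @export
sample_hop <- function(rnd1, mu_s) {
  assert_scalar_num(mu_s, "mu_s", 0, strict_lower = TRUE)
  assert_that(all(rnd1 >= 0 & rnd1 < 1), "`rnd1` must be in [0, 1)")
  -log(1 - rnd1) / mu_s
}

#' Sample a scattering deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function. For
#' `g != 0`: `cos(theta) = (1 + g^2 - ((1-g^2)/(1-g+2*g*rnd2))^2) / (2*g)`;
#' for `g = 0` the isotropic limit `cos(theta) = 2*rnd2 - 1`. The result is
#' clamped to `[-1, 1]`.
#'
#' @param rnd2 uniform(0,1) draws (vectorized).
#' @param g anisotropy in (-1, 1).
#' @return deflection cosines.
#' @export
sample_deflection <- function(rnd2, g) {
  assert_that(all(rnd2 >= 0 & rnd2 <= 1), "`rnd2` must be in [0, 1]")
  if (g == 0) return(2 * rnd2 - 1)
  frac <- (1 - g^2) / (1 - g + 2 * g * rnd2)
  ct <- (1 + g^2 - frac^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

# Henyey-Greenstein density of cos(theta) (used by tests as the analytic
# reference for goodness-of-fit checks)
hg_density <- function(cos_theta, g) {
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

#' Rotate photon directions by a deflection and azimuth ("spin")
#'
#' Applies the standard photon-transport direction update: deflect by
#' `acos(cos_theta)` away from the current direction and rotate by azimuth
#' `psi` in the orthogonal plane, with the numerically stable special case
#' when the direction is nearly parallel to the z axis. Inputs are
#' vectorized over rows.
#'
#' @param u n x 3 matrix of unit direction vectors.
#' @param cos_theta deflection cosines (length n).
#' @param psi azimuth angles in `[0, 2*pi)` (length n).
#' @return n x 3 matrix of unit directions.
#' @export
spin_direction <- function(u, cos_theta, psi) {
  if (is.null(dim(u))) u <- matrix(u, 1L)
  st <- sqrt(pmax(0, 1 - cos_theta^2))
  cp <- cos(psi); sp <- sin(psi)
  ux <- u[, 1]; uy <- u[, 2]; uz <- u[, 3]
  near_pole <- abs(uz) > 0.99999
  den <- sqrt(pmax(1e-300, 1 - uz^2))
  nx <- st * (ux * uz * cp - uy * sp) / den + ux * cos_theta
  ny <- st * (uy * uz * cp + ux * sp) / den + uy * cos_theta
  nz <- -st * cp * den + uz * cos_theta
  if (any(near_pole)) {
    sgn <- sign(uz[near_pole])
    nx[near_pole] <- st[near_pole] * cp[near_pole]
    ny[near_pole] <- st[near_pole] * sp[near_pole]
    nz[near_pole] <- sgn * cos_theta[near_pole]
  }
  out <- cbind(nx, ny, nz, deparse.level = 0)
  out / sqrt(rowSums(out^2))
}

#' Simulate the scattering PSF at one depth
#'
#' Launches photons from `(0, 0, -z0)` with isotropic directions (by default
#' restricted to the upper hemisphere, towards the surface), alternates
#' exponential hops and Henyey-Greenstein spins until each photon crosses the
#' surface `z = 0` (the final hop is truncated exactly at the surface), and
#' records the exit direction. A photon is accepted when its exit polar angle
#' lies inside the objective's acceptance cone in tissue,
#' `sin(theta_exit) <= NA / n_tissue`. Accepted photons are traced straight
#' back along their final direction to the launch plane and binned at the
#' lateral position where they appear to originate. Photons still inside the
#' medium after `max_hops` scattering events are terminated and counted in
#' the acceptance denominator, as are accepted photons that land outside the
#' grid.
#'
#' @param medium a [scattering_medium()].
#' @param z0 source depth below the surface in micrometres (>= 0).
#' @param na objective numerical aperture.
#' @param n_photons photons to launch (default 1e6).
#' @param shape integer length-2 lateral grid `(H, W)`; odd sizes centre the
#'   source on a pixel.
#' @param pixel_size lateral pixel size in micrometres.
#' @param seed integer seed.
#' @param launch `"hemisphere"` (default; isotropic over the upward
#'   hemisphere) or `"full"` (isotropic over 4*pi; downward photons never
#'   return in this absorption-free model and count as lost).
#' @param max_hops termination cap on scattering events per photon.
#' @return a list with `image` (H x W, unit sum), `acceptance` (accepted /
#'   launched; halved under hemisphere launch so it refers to full-sphere
#'   emission), `n_launched`, `n_accepted`, `unscattered_fraction` (fraction
#'   of accepted photons that exited without scattering), `z0`, `pixel_size`.
#' @export
simulate_spsf <- function(medium, z0, na, n_photons = 1e6,
                          shape = c(63L, 63L), pixel_size = 1 / 3,
                          seed = 1L, launch = c("hemisphere", "full"),
                          max_hops = 300L) {
  launch <- match.arg(launch)
  assert_that(inherits(medium, "scattering_medium"),
              "`medium` must be a scattering_medium")
  assert_scalar_num(z0, "z0", 0)
  assert_scalar_num(na, "na", 0, strict_lower = TRUE)
  n_photons <- as.integer(n_photons)
  assert_that(n_photons >= 1L, "`n_photons` must be >= 1")
  shape <- as.integer(shape)
  sin_max <- na / medium$n_tissue
  with_seed(seed, {
    n <- n_photons
    # isotropic directions: uz uniform, azimuth uniform
    uz <- if (launch == "hemisphere") stats::runif(n) else stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    rr <- sqrt(pmax(0, 1 - uz^2))
    ux <- rr * cos(phi); uy <- rr * sin(phi)
    px <- numeric(n); py <- numeric(n); pz <- rep(-z0, n)
    hops <- integer(n)
    photon_id <- seq_len(n)
    # preallocated accumulators for exited photons
    ex_x <- ex_y <- ex_ux <- ex_uy <- ex_uz <- numeric(n)
    ex_hops <- integer(n)
    n_exit <- 0L
    it <- 0L
    mu_s <- medium$mu_s
    g <- medium$g
    while (length(photon_id) > 0L && it < max_hops) {
      it <- it + 1L
      m <- length(photon_id)
      s <- -log1p(-stats::runif(m)) / mu_s
      t_surf <- -pz / uz
      crossing <- uz > 0 & s >= t_surf
      if (any(crossing)) {
        tt <- t_surf[crossing]
        k <- sum(crossing)
        at <- n_exit + seq_len(k)
        ex_x[at] <- px[crossing] + tt * ux[crossing]
        ex_y[at] <- py[crossing] + tt * uy[crossing]
        ex_ux[at] <- ux[crossing]
        ex_uy[at] <- uy[crossing]
        ex_uz[at] <- uz[crossing]
        ex_hops[at] <- hops[crossing]
        n_exit <- n_exit + k
      }
      stay <- !crossing
      m2 <- sum(stay)
      if (m2 == 0L) { photon_id <- integer(0); break }
      s <- s[stay]
      px <- px[stay] + s * ux[stay]
      py <- py[stay] + s * uy[stay]
      pz <- pz[stay] + s * uz[stay]
      ux <- ux[stay]; uy <- uy[stay]; uz <- uz[stay]
      hops <- hops[stay] + 1L
      photon_id <- photon_id[stay]
      # spin: Henyey-Greenstein deflection + uniform azimuth (inlined,
      # validation-free version of sample_deflection for the hot loop)
      rnd2 <- stats::runif(m2)
      ct <- if (g == 0) 2 * rnd2 - 1 else {
        frac <- (1 - g * g) / (1 - g + 2 * g * rnd2)
        pmin(1, pmax(-1, (1 + g * g - frac * frac) / (2 * g)))
      }
      st <- sqrt(pmax(0, 1 - ct * ct))
      psi <- stats::runif(m2, 0, 2 * pi)
      cp <- cos(psi); sp <- sin(psi)
      near_pole <- abs(uz) > 0.99999
      den <- sqrt(pmax(1e-300, 1 - uz * uz))
      nx <- st * (ux * uz * cp - uy * sp) / den + ux * ct
      ny <- st * (uy * uz * cp + ux * sp) / den + uy * ct
      nz <- -st * cp * den + uz * ct
      if (any(near_pole)) {
        sgn <- sign(uz[near_pole])
        nx[near_pole] <- st[near_pole] * cp[near_pole]
        ny[near_pole] <- st[near_pole] * sp[near_pole]
        nz[near_pole] <- sgn * ct[near_pole]
      }
      nrm <- sqrt(nx * nx + ny * ny + nz * nz)
      ux <- nx / nrm; uy <- ny / nrm; uz <- nz / nrm
    }
    keep <- seq_len(n_exit)
    ex_x <- ex_x[keep]; ex_y <- ex_y[keep]
    ex_ux <- ex_ux[keep]; ex_uy <- ex_uy[keep]; ex_uz <- ex_uz[keep]
    ex_hops <- ex_hops[keep]
    ok <- ex_uz > 0 & sqrt(ex_ux^2 + ex_uy^2) <= sin_max
    if (!any(ok))
      stopf("no photon was accepted at z0 = %g um; increase n_photons or NA",
            z0)
    acc_idx <- which(ok)
    # straight-line backpropagation along the final direction to z = -z0
    t_back <- z0 / ex_uz[acc_idx]
    bx <- ex_x[acc_idx] - t_back * ex_ux[acc_idx]
    by <- ex_y[acc_idx] - t_back * ex_uy[acc_idx]
    cx <- kernel_centre(shape[1]); cy <- kernel_centre(shape[2])
    ix <- round(bx / pixel_size) + cx
    iy <- round(by / pixel_size) + cy
    inside <- ix >= 1 & ix <= shape[1] & iy >= 1 & iy <= shape[2]
    img <- matrix(0, shape[1], shape[2])
    if (any(inside)) {
      tab <- tabulate((iy[inside] - 1L) * shape[1] + ix[inside],
                      nbins = prod(shape))
      img <- matrix(tab, shape[1], shape[2])
    }
    n_acc <- sum(inside)
    if (n_acc == 0L)
      stopf("all accepted photons landed outside the %dx%d grid", shape[1], shape[2])
    acceptance <- n_acc / n_photons
    if (launch == "hemisphere") acceptance <- acceptance / 2
    list(image = img / sum(img),
         acceptance = acceptance,
         n_launched = n_photons,
         n_accepted = n_acc,
         unscattered_fraction = mean(ex_hops[acc_idx][inside] == 0L),
         z0 = z0, pixel_size = pixel_size)
  })
}

#' Simulate a per-depth stack of scattering PSFs
#'
#' One [simulate_spsf()] call per depth with independent sub-seeds derived
#' from `seed`, so equal depths with the same sub-seed give identical images.
#'
#' @param medium a [scattering_medium()].
#' @param depths ascending depths z0 in micrometres.
#' @param na objective numerical aperture.
#' @param n_photons photons per depth.
#' @param shape lateral grid `(H, W)`.
#' @param pixel_size micrometres per pixel.
#' @param seed integer global seed; depth `i` uses
#'   `substream_seed(seed, "spsf", i)`.
#' @param ... passed to [simulate_spsf()].
#' @return an `spsf_stack`: list with `images` (H x W x D array, each plane
#'   unit-sum), `depths`, `acceptance`, `pixel_size`, `medium`, `na`.
#' @export
build_spsf_stack <- function(medium, depths, na, n_photons = 1e6,
                             shape = c(63L, 63L), pixel_size = 1 / 3,
                             seed = 1L, ...) {
  assert_that(!is.unsorted(depths), "`depths` must be sorted ascending")
  shape <- as.integer(shape)
  imgs <- array(0, c(shape, length(depths)))
  acc <- numeric(length(depths))
  seen <- new.env()
  for (i in seq_along(depths)) {
    # duplicate depths share a sub-seed, keyed by depth value
    key <- paste0("d", format(depths[i], digits = 12))
    if (is.null(seen[[key]])) seen[[key]] <- substream_seed(seed, "spsf", i)
    one <- simulate_spsf(medium, depths[i], na, n_photons, shape,
                         pixel_size, seed = seen[[key]], ...)
    imgs[, , i] <- one$image
    acc[i] <- one$acceptance
  }
  structure(list(images = imgs, depths = as.numeric(depths),
                 acceptance = acc, pixel_size = pixel_size,
                 medium = medium, na = na),
            class = "spsf_stack")
}

#' A delta (no-scattering) PSF stack
#'
#' Utility for noise-free reduction tests and shallow imaging: every depth
#' maps to a single-pixel delta kernel.
#'
#' @param depths depths in micrometres.
#' @param shape lateral grid `(H, W)`.
#' @param pixel_size micrometres per pixel.
#' @return an `spsf_stack` of delta images.
#' @export
delta_spsf_stack <- function(depths, shape = c(1L, 1L), pixel_size = 1 / 3) {
  shape <- as.integer(shape)
  img <- matrix(0, shape[1], shape[2])
  img[kernel_centre(shape[1]), kernel_centre(shape[2])] <- 1
  imgs <- array(rep(img, length(depths)), c(shape, length(depths)))
  structure(list(images = imgs, depths = as.numeric(depths),
                 acceptance = rep(1, length(depths)),
                 pixel_size = pixel_size, medium = NULL, na = NA_real_),
            class = "spsf_stack")
}
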