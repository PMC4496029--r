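# Synthetic per-species reflectance model.
#
# Species mean spectra are smooth random modulations of a canonical green-
# vegetation curve (chlorophyll trough near 670 nm, NIR plateau, shortwave
# shoulders around the water features). Crown- and pixel-level variability is
# lognormal and spectrally structured: a brightness scalar (illumination),
# a smooth shape component and a small white sensor-noise component. Smooth
# components are natural-spline interpolations of iid normal knot values, so
# within- and between-class variation is low-dimensional and correlated
# across bands, as in real imaging-spectrometer data.

# Canonical green-vegetation reflectance (fraction) at wavelengths wl (nm).
canonical_vegetation_spectrum <- function(wl) {
  pts_nm <- c(380, 450, 500, 550, 600, 650, 670, 700, 730, 760, 850, 1000,
              1100, 1250, 1350, 1450, 1550, 1650, 1750, 1900, 2050, 2200,
              2350, 2512)
  pts_rf <- c(0.030, 0.035, 0.045, 0.095, 0.070, 0.045, 0.040, 0.090, 0.280,
              0.430, 0.460, 0.450, 0.430, 0.400, 0.250, 0.120, 0.250, 0.280,
              0.230, 0.050, 0.140, 0.200, 0.130, 0.070)
  y <- stats::spline(pts_nm, pts_rf, xout = wl, method = "natural")$y
  pmin(pmax(y, 0.005), 0.95)
}

# Liana/epiphyte-like contaminant: flatter, brighter in the red, dimmer in
# the NIR, so NDVI falls below typical vegetation thresholds.
liana_spectrum <- function(wl) {
  0.45 * canonical_vegetation_spectrum(wl) + 0.13
}

# B x K natural-spline basis mapping knot values (every knot_nm nanometers)
# to band values; smooth random curves are then Z %*% t(basis).
smooth_basis <- function(wl, knot_nm = 160) {
  knots <- seq(min(wl) - knot_nm, max(wl) + knot_nm, by = knot_nm)
  vapply(seq_along(knots), function(j) {
    v <- numeric(length(knots)); v[j] <- 1
    stats::spline(knots, v, xout = wl, method = "natural")$y
  }, numeric(length(wl)))
}

# n smooth random curves with per-knot sd `sd` (rows) over the basis bands.
smooth_noise <- function(n, basis, sd) {
  matrix(stats::rnorm(n * ncol(basis), 0, sd), n) %*% t(basis)
}

# One smooth random modulation curve at wavelengths wl.
smooth_modulation <- function(wl, sd, knot_nm = 160) {
  as.vector(smooth_noise(1, smooth_basis(wl, knot_nm), sd))
}

# n x B matrix of pixel-level log-deviations: brightness scalar (sd w_sd) +
# smooth shape (sd 0.7 w_sd, combined with any extra smooth sd, e.g. the
# between-crown scale when pixels carry their own crown offset) + white
# sensor noise (sd 0.3 w_sd).
pixel_log_noise <- function(n, basis, n_band, w_sd, extra_smooth_sd = 0) {
  sm_sd <- sqrt((0.7 * w_sd)^2 + extra_smooth_sd^2)
  smooth_noise(n, basis, sm_sd) +
    stats::rnorm(n, 0, w_sd) +
    matrix(stats::rnorm(n * n_band, 0, 0.3 * w_sd), n)
}

# RMS standardized distance between two mean spectra under the pooled
# between+within noise scales -- the "noise metric" separability is defined in.
spectral_separation <- function(mean_a, mean_b, sd_a, sd_b) {
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  sqrt(mean(((mean_a - mean_b) / pooled)^2))
}

#' Generate a synthetic per-species spectral library
#'
#' Draws one smooth mean reflectance spectrum per species (focal species
#' first), together with per-band between-crown and within-crown standard
#' deviations. Background means are random smooth modulations of the
#' canonical vegetation curve; focal means are redrawn with growing
#' modulation amplitude until each is at least `config$separability` away
#' (in the pooled-noise RMS metric, see Details) from every background mean.
#' All means are vegetation-like by construction: the NIR plateau exceeds the
#' red reflectance and the NDVI of every mean passes the default vegetation
#' filter.
#'
#' @details The separation between two species is the root-mean-square over
#' retained bands of the mean difference divided by the pooled (between +
#' within crown) standard deviation, i.e. a Mahalanobis-like distance under a
#' diagonal noise model. If the requested separability cannot be reached
#' within the modulation-amplitude budget the function fails explicitly
#' rather than clipping spectra.
#'
#' @param config a [scene_config()].
#' @param grid a `wavelength_grid` with at least 10 retained bands.
#' @return object of class `spectral_library`: species ids (`1..n_focal`
#'   focal, then background), `is_focal`, and `means`, `between_sd`,
#'   `within_sd` matrices (species x retained band).
#' @export
make_spectral_library <- function(config, grid) {
  stopifnot(inherits(config, "scene_config"), inherits(grid, "wavelength_grid"))
  if (n_bands(grid) < 10)
    stop("spectral library requires a grid with at least 10 retained bands",
         call. = FALSE)
  wl <- retained_wavelengths(grid)
  base <- canonical_vegetation_spectrum(wl)
  nf <- config$n_focal_species
  nb <- config$n_background_species
  b_sd <- config$between_crown_sd
  w_sd <- config$within_crown_sd
  amp0 <- config$modulation_sd
  i_red <- nearest_band(grid, 650, "red")
  i_nir <- nearest_band(grid, 860, "NIR")

  veg_like <- function(m) {
    ndvi <- (m[i_nir] - m[i_red]) / (m[i_nir] + m[i_red])
    ndvi >= 0.7 && m[i_nir] > m[i_red] && all(m > 0) && all(m < 1)
  }

  with_seed(derive_seed(config$seed, "library"), {
    bg <- matrix(NA_real_, nb, length(wl))
    for (j in seq_len(nb)) {
      repeat {
        m <- base * exp(smooth_modulation(wl, amp0))
        if (veg_like(m)) break
      }
      bg[j, ] <- m
    }
    sep_to_bg <- function(m) {
      min(vapply(seq_len(nb), function(j)
        spectral_separation(m, bg[j, ], sqrt(b_sd^2 + w_sd^2) * m,
                            sqrt(b_sd^2 + w_sd^2) * bg[j, ]), numeric(1)))
    }
    fc <- matrix(NA_real_, max(nf, 0), length(wl))
    for (i in seq_len(nf)) {
      amp <- amp0
      ok <- FALSE
      for (try in seq_len(60)) {
        m <- base * exp(smooth_modulation(wl, amp))
        if (veg_like(m) && sep_to_bg(m) >= config$separability) {
          fc[i, ] <- m; ok <- TRUE; break
        }
        amp <- amp * 1.12
      }
      if (!ok)
        stop(sprintf(paste0("could not achieve separability %.2f for focal ",
                            "species %d within the smooth-modulation budget; ",
                            "reduce separability or the noise scales"),
                     config$separability, i), call. = FALSE)
    }
    means <- rbind(fc, bg)
    structure(list(
      species_id = seq_len(nf + nb),
      is_focal = c(rep(TRUE, nf), rep(FALSE, nb)),
      means = means,
      between_sd = b_sd * means,
      within_sd = w_sd * means,
      grid = grid,
      config = config), class = "spectral_library")
  })
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d species (%d focal) x %d bands\n",
              length(x$species_id), sum(x$is_focal), ncol(x$means)))
  invisible(x)
}

#' Nearest-mean focal/background pixel separability
#'
#' Simulates pixels from every library species under the crown + pixel noise
#' model (smooth crown offset, brightness, smooth shape and white pixel
#' components) and classifies them by the nearest library mean (Euclidean).
#' Returns the accuracy of the induced focal-vs-background decision, a
#' Bayes-style summary of how separable the generated classes are; `1 -`
#' accuracy is the pixel overlap between the focal species and the
#' background cloud.
#'
#' @param library a `spectral_library`.
#' @param n_per_species pixels simulated per species.
#' @param seed RNG seed.
#' @return accuracy in `[0, 1]`.
#' @export
nearest_mean_separability <- function(library, n_per_species = 40, seed = 1) {
  S <- length(library$species_id)
  B <- ncol(library$means)
  wl <- retained_wavelengths(library$grid)
  basis <- smooth_basis(wl)
  b_sd <- library$config$between_crown_sd
  w_sd <- library$config$within_crown_sd
  with_seed(derive_seed(seed, "separability"), {
    truth <- rep(seq_len(S), each = n_per_species)
    dev <- pixel_log_noise(length(truth), basis, B, w_sd,
                           extra_smooth_sd = b_sd)
    x <- library$means[truth, ] * exp(dev)
    d2 <- outer(rowSums(x^2), rowSums(library$means^2), "+") -
      2 * x %*% t(library$means)
    pred <- apply(d2, 1, which.min)
    mean(library$is_focal[pred] == library$is_focal[truth])
  })
}
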