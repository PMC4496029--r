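# Synthetic hyperspectral forest scenes with known crown-level ground truth.

#' Scene generator configuration
#'
#' Collects every knob of the synthetic forest-scene generator. The defaults
#' define the package's standard study conditions: three focal species with
#' 44 training crowns each amongst a diverse background of 80 species (4
#' crowns each), elliptical crowns of 2-4 pixel radius placed without overlap
#' in a 260 x 260 pixel scene, moderate between- and within-crown spectral
#' variability, and a 5% + 5% sprinkling of shadow and liana contaminants
#' that fail the vegetation filter.
#'
#' @param height,width scene size in pixels.
#' @param n_focal_species number of focal (target) species.
#' @param crowns_per_focal training crowns per focal species (may be 0).
#' @param n_background_species number of background species.
#' @param crowns_per_background crowns per background species (may be 0).
#' @param crown_radius_range length-2 numeric, ellipse semi-axis range (px).
#' @param separability required pooled-noise RMS distance of every focal mean
#'   from every background mean (see [make_spectral_library()]).
#' @param between_crown_sd,within_crown_sd relative (fraction-of-mean)
#'   standard deviations of the crown-level and pixel-level perturbations.
#' @param modulation_sd amplitude of the smooth between-species modulation.
#' @param shadow_fraction,liana_fraction fractions of scene pixels
#'   overwritten with shadow / liana contaminant spectra, in `[0, 1)`.
#' @param seed integer; fully determines generator output.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height = 260, width = 260,
                         n_focal_species = 3, crowns_per_focal = 44,
                         n_background_species = 80, crowns_per_background = 4,
                         crown_radius_range = c(2, 4),
                         separability = 1.5,
                         between_crown_sd = 0.06, within_crown_sd = 0.05,
                         modulation_sd = 0.10,
                         shadow_fraction = 0.05, liana_fraction = 0.05,
                         seed = 1) {
  stop_if_not_scalar_number(height, "height", 8)
  stop_if_not_scalar_number(width, "width", 8)
  stop_if_not_scalar_number(n_focal_species, "n_focal_species", 1)
  stop_if_not_scalar_number(crowns_per_focal, "crowns_per_focal", 0)
  stop_if_not_scalar_number(n_background_species, "n_background_species", 1)
  stop_if_not_scalar_number(crowns_per_background, "crowns_per_background", 0)
  stopifnot(length(crown_radius_range) == 2L,
            crown_radius_range[1] >= 1, diff(crown_radius_range) >= 0)
  stop_if_not_scalar_number(separability, "separability", 0)
  stop_if_not_scalar_number(between_crown_sd, "between_crown_sd", 0)
  stop_if_not_scalar_number(within_crown_sd, "within_crown_sd", 0)
  stop_if_not_scalar_number(modulation_sd, "modulation_sd", 1e-6)
  stop_if_not_scalar_number(shadow_fraction, "shadow_fraction", 0, 1 - 1e-9)
  stop_if_not_scalar_number(liana_fraction, "liana_fraction", 0, 1 - 1e-9)
  stop_if_not_scalar_number(seed, "seed")
  structure(as.list(environment()), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config> %dx%d px, %d focal x %d crowns, ",
                     "%d background x %d crowns, separability %.1f, seed %d\n"),
              x$height, x$width, x$n_focal_species, x$crowns_per_focal,
              x$n_background_species, x$crowns_per_background,
              x$separability, as.integer(x$seed)))
  invisible(x)
}

# Pixel set of an ellipse (center-in-ellipse rasterization), as an index
# matrix (row, col) clipped to the raster.
ellipse_pixels <- function(r0, c0, a, b, theta, H, W) {
  rr <- max(1L, floor(r0 - a - b)):min(H, ceiling(r0 + a + b))
  cc <- max(1L, floor(c0 - a - b)):min(W, ceiling(c0 + a + b))
  g <- expand.grid(row = rr, col = cc)
  dx <- g$row - r0; dy <- g$col - c0
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  as.matrix(g[u^2 + v^2 <= 1, , drop = FALSE])
}

# Place all configured crowns as disjoint ellipses by rejection sampling.
# Returns crown raster + table; errors if a crown cannot be placed.
place_crowns <- function(config) {
  H <- config$height; W <- config$width
  species <- c(rep(seq_len(config$n_focal_species),
                   each = config$crowns_per_focal),
               rep(config$n_focal_species + seq_len(config$n_background_species),
                   each = config$crowns_per_background))
  raster <- matrix(0L, H, W)
  tab <- data.frame(crown_id = integer(0), species_id = integer(0),
                    n_pixels = integer(0))
  rmin <- config$crown_radius_range[1]; rmax <- config$crown_radius_range[2]
  if (2 * rmax + 2 >= min(H, W))
    stop("crowns do not fit in the scene: increase scene size", call. = FALSE)
  for (k in seq_along(species)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      r0 <- stats::runif(1, 1 + rmax, H - rmax)
      c0 <- stats::runif(1, 1 + rmax, W - rmax)
      a <- stats::runif(1, rmin, rmax)
      b <- stats::runif(1, rmin, rmax)
      px <- ellipse_pixels(r0, c0, a, b, stats::runif(1, 0, pi), H, W)
      if (nrow(px) < 4) next
      idx <- px[, 1] + (px[, 2] - 1L) * H
      if (any(raster[idx] != 0L)) next
      raster[idx] <- k
      tab <- rbind(tab, data.frame(crown_id = k, species_id = species[k],
                                   n_pixels = nrow(px)))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place crown %d of %d without overlap; enlarge the scene",
                   k, length(species)), call. = FALSE)
  }
  crown_map(raster, tab)
}

# Row-wise vegetation-filter check used to make pure crown pixels pass the
# mask by construction (the training-crown protocol: well-lit leafy pixels).
veg_pass_fun <- function(grid) {
  i_red <- nearest_band(grid, 650, "red")
  i_nir <- nearest_band(grid, 860, "NIR")
  nir_win <- bands_in_window(grid, 850, 1050)
  function(x) {
    s <- x[, i_nir] + x[, i_red]
    ndvi <- ifelse(s == 0, 0, (x[, i_nir] - x[, i_red]) / s)
    ndvi >= 0.7 & rowMeans(x[, nir_win, drop = FALSE]) >= 0.21
  }
}

# Render n pixels of one crown: shared smooth offset (between-crown scale)
# plus per-pixel brightness/smooth/white noise; rows failing the vegetation
# filter are redrawn, falling back to the (filter-passing) crown or species
# mean, so pure crown pixels pass the mask by construction.
render_crown_pixels <- function(mean_spec, n, basis, w_sd, offset, veg_pass) {
  B <- length(mean_spec)
  crown_mean <- mean_spec * exp(offset)
  mk <- function(k) {
    crown_mean_m <- matrix(crown_mean, k, B, byrow = TRUE)
    pmin(pmax(crown_mean_m * exp(pixel_log_noise(k, basis, B, w_sd)), 0), 1)
  }
  x <- mk(n)
  for (i in seq_len(50)) {
    bad <- which(!veg_pass(x))
    if (!length(bad)) break
    x[bad, ] <- mk(length(bad))
  }
  bad <- which(!veg_pass(x))
  if (length(bad)) {
    fb <- if (veg_pass(rbind(crown_mean))) crown_mean else mean_spec
    x[bad, ] <- matrix(fb, length(bad), B, byrow = TRUE)
  }
  x
}

#' Generate a synthetic hyperspectral scene
#'
#' Renders a reflectance cube plus ground-truth crown map under the
#' generative model: each crown's pixels are the species mean times a
#' crown-level smooth lognormal offset (scale `between_crown_sd`) times
#' per-pixel noise (brightness, smooth shape and white components on scale
#' `within_crown_sd`); crown pixels are guaranteed to pass the vegetation
#' filter. The canopy matrix between crowns is filled with per-pixel draws
#' from random background species. Finally `shadow_fraction` and
#' `liana_fraction` of all pixels are overwritten with contaminant spectra
#' that fail the vegetation filter (shadow: dark, low NIR; liana: low NDVI).
#' Reflectance is truncated to `[0, 1]`.
#'
#' @param config a [scene_config()].
#' @param library matching [make_spectral_library()] output.
#' @return list with elements `cube` (a `reflectance_cube`), `map` (a
#'   `crown_map` recording species truth), and `contaminated` (logical
#'   matrix marking shadow/liana pixels).
#' @export
generate_scene <- function(config, library) {
  stopifnot(inherits(config, "scene_config"),
            inherits(library, "spectral_library"))
  grid <- library$grid
  wl <- retained_wavelengths(grid)
  B <- length(wl)
  H <- config$height; W <- config$width
  b_sd <- config$between_crown_sd; w_sd <- config$within_crown_sd
  basis <- smooth_basis(wl)
  veg_pass <- veg_pass_fun(grid)
  with_seed(derive_seed(config$seed, "scene"), {
    map <- place_crowns(config)
    vals <- matrix(NA_real_, H * W, B)
    ras <- map$crown_id_raster

    # canopy matrix: random background species, combined crown+pixel noise
    bg_ids <- library$species_id[!library$is_focal]
    mat_idx <- which(ras == 0L)
    sp <- sample(bg_ids, length(mat_idx), replace = TRUE)
    dev <- pixel_log_noise(length(mat_idx), basis, B, w_sd,
                           extra_smooth_sd = b_sd)
    vals[mat_idx, ] <- library$means[sp, , drop = FALSE] * exp(dev)

    # crowns: shared smooth offset per crown + pixel noise, mask-safe
    for (i in seq_len(nrow(map$crown_table))) {
      id <- map$crown_table$crown_id[i]
      spi <- map$crown_table$species_id[i]
      idx <- which(ras == id)
      vals[idx, ] <- render_crown_pixels(
        library$means[spi, ], length(idx), basis, w_sd,
        as.vector(smooth_noise(1, basis, b_sd)), veg_pass)
    }

    # contaminants overwrite a stated fraction of all pixels
    n_sh <- round(config$shadow_fraction * H * W)
    n_li <- round(config$liana_fraction * H * W)
    cont <- sample(H * W, n_sh + n_li)
    base <- canonical_vegetation_spectrum(wl)
    if (n_sh > 0) {
      sh <- cont[seq_len(n_sh)]
      vals[sh, ] <- matrix(0.06 * base, n_sh, B, byrow = TRUE) *
        exp(matrix(stats::rnorm(n_sh * B, 0, 0.1), ncol = B))
    }
    if (n_li > 0) {
      li <- cont[n_sh + seq_len(n_li)]
      vals[li, ] <- matrix(liana_spectrum(wl), n_li, B, byrow = TRUE) *
        exp(matrix(stats::rnorm(n_li * B, 0, 0.05), ncol = B))
    }

    vals <- pmin(pmax(vals, 0), 1)
    contaminated <- matrix(FALSE, H, W)
    contaminated[cont] <- TRUE
    list(cube = reflectance_cube(array(vals, c(H, W, B)), grid),
         map = map, contaminated = contaminated)
  })
}

#' Reference crown inventory
#'
#' The crown/pixel inventory the generator can mirror exactly: three focal
#' species with (50, 44, 44) delineated crowns and (10726, 3325, 2091)
#' vegetation pixels, plus 322 field-collected crowns of other species with
#' 9350 pixels -- 460 crowns and 25492 pixels in total, the shape of a
#' field + satellite crown-collection campaign on Barro Colorado Island.
#'
#' @return data.frame with columns `label`, `focal`, `n_crowns`, `n_pixels`.
#' @export
reference_inventory <- function() {
  data.frame(
    label = c("focal_1", "focal_2", "focal_3", "other"),
    focal = c(TRUE, TRUE, TRUE, FALSE),
    n_crowns = c(50L, 44L, 44L, 322L),
    n_pixels = c(10726L, 3325L, 2091L, 9350L))
}

# Split `total` into `k` integer parts differing by at most 1.
split_count <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  rem <- total - base * k
  if (rem > 0) out[seq_len(rem)] <- out[seq_len(rem)] + 1L
  as.integer(out)
}

#' Generate a crown training dataset
#'
#' Draws labeled crown pixels directly (without rasterizing a scene), under
#' the same crown + pixel noise model as [generate_scene()] including the
#' vegetation-filter guarantee. By default crown counts follow `config` and
#' per-crown pixel counts follow random ellipse areas; passing
#' `inventory = reference_inventory()` instead mirrors the reference
#' campaign exactly: its per-class crown counts are used and its per-class
#' pixel totals are split evenly (±1) across crowns, so the dataset's totals
#' match the inventory to the pixel. Inventory crowns of the "other" class
#' are dealt round-robin across the background species.
#'
#' @param config a [scene_config()].
#' @param library matching `spectral_library`.
#' @param inventory optional data.frame as from [reference_inventory()];
#'   its `focal` rows are matched to the focal species in order.
#' @return a `pixel_dataset` with crown ids and species labels.
#' @export
generate_crown_dataset <- function(config, library, inventory = NULL) {
  stopifnot(inherits(config, "scene_config"),
            inherits(library, "spectral_library"))
  grid <- library$grid
  wl <- retained_wavelengths(grid)
  B <- length(wl)
  nf <- config$n_focal_species
  bg_ids <- library$species_id[!library$is_focal]
  w_sd <- config$within_crown_sd; b_sd <- config$between_crown_sd
  basis <- smooth_basis(wl)
  veg_pass <- veg_pass_fun(grid)

  with_seed(derive_seed(config$seed, "dataset"), {
    if (is.null(inventory)) {
      species <- c(rep(seq_len(nf), each = config$crowns_per_focal),
                   rep(bg_ids, each = config$crowns_per_background))
      a <- stats::runif(length(species), config$crown_radius_range[1],
                        config$crown_radius_range[2])
      b <- stats::runif(length(species), config$crown_radius_range[1],
                        config$crown_radius_range[2])
      sizes <- pmax(4L, round(pi * a * b))
    } else {
      stopifnot(all(c("focal", "n_crowns", "n_pixels") %in% names(inventory)))
      if (sum(inventory$focal) != nf)
        stop("inventory focal rows must match config n_focal_species",
             call. = FALSE)
      species <- integer(0); sizes <- integer(0)
      fi <- 0L
      for (i in seq_len(nrow(inventory))) {
        k <- inventory$n_crowns[i]
        if (inventory$focal[i]) {
          fi <- fi + 1L
          species <- c(species, rep(fi, k))
        } else {
          species <- c(species, rep(bg_ids, length.out = k))
        }
        sizes <- c(sizes, split_count(inventory$n_pixels[i], k))
      }
    }
    n_tot <- sum(sizes)
    x <- matrix(NA_real_, n_tot, B)
    crown_id <- rep(seq_along(species), times = sizes)
    sp_row <- rep(species, times = sizes)
    pos <- 1L
    for (k in seq_along(species)) {
      n <- sizes[k]
      x[pos:(pos + n - 1L), ] <- render_crown_pixels(
        library$means[species[k], ], n, basis, w_sd,
        as.vector(smooth_noise(1, basis, b_sd)), veg_pass)
      pos <- pos + n
    }
    pixel_dataset(x, crown_id, sp_row, grid)
  })
}
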