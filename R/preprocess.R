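# Vegetation masking and crown-pixel extraction.

#' Vegetation-filter configuration
#'
#' Thresholds of the well-lit leafy-vegetation pixel filter: NDVI at least
#' `ndvi_min` and mean near-infrared (`nir_window_nm`) reflectance at least
#' `nir_mean_min`; both comparisons inclusive. The NDVI reference bands are
#' the nearest retained bands to `red_band_nm` and `nir_band_nm` (the filter
#' convention leaves the exact sensor bands open, so they are configurable).
#'
#' @param ndvi_min NDVI threshold (default 0.7).
#' @param nir_window_nm window for the mean-NIR test, nm (default 850-1050).
#' @param nir_mean_min mean NIR reflectance threshold as a fraction
#'   (default 0.21, i.e. 21%).
#' @param red_band_nm,nir_band_nm NDVI reference wavelengths, nm.
#' @return object of class `mask_config`.
#' @export
mask_config <- function(ndvi_min = 0.7, nir_window_nm = c(850, 1050),
                        nir_mean_min = 0.21, red_band_nm = 650,
                        nir_band_nm = 860) {
  stop_if_not_scalar_number(ndvi_min, "ndvi_min", 0, 1)
  stop_if_not_scalar_number(nir_mean_min, "nir_mean_min", 0, 1)
  stopifnot(length(nir_window_nm) == 2L, nir_window_nm[2] > nir_window_nm[1])
  structure(list(ndvi_min = ndvi_min, nir_window_nm = nir_window_nm,
                 nir_mean_min = nir_mean_min, red_band_nm = red_band_nm,
                 nir_band_nm = nir_band_nm), class = "mask_config")
}

#' Normalized difference vegetation index raster
#'
#' NDVI = (NIR - red) / (NIR + red) using the nearest retained bands to the
#' configured red and NIR reference wavelengths; defined as 0 where
#' NIR + red = 0.
#'
#' @param cube a `reflectance_cube`.
#' @param cfg a [mask_config()].
#' @return numeric H x W matrix.
#' @export
compute_ndvi <- function(cube, cfg = mask_config()) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$values)
  red <- matrix(cube$values[, , nearest_band(cube$grid, cfg$red_band_nm, "red")],
                d[1], d[2])
  nir <- matrix(cube$values[, , nearest_band(cube$grid, cfg$nir_band_nm, "NIR")],
                d[1], d[2])
  s <- nir + red
  out <- (nir - red) / s
  out[s == 0] <- 0
  out
}

# NDVI of spectra given as rows of a matrix on a grid (library means, pixels).
spectrum_ndvi <- function(x, grid, cfg = mask_config()) {
  x <- rbind(x)
  red <- x[, nearest_band(grid, cfg$red_band_nm, "red")]
  nir <- x[, nearest_band(grid, cfg$nir_band_nm, "NIR")]
  s <- nir + red
  ifelse(s == 0, 0, (nir - red) / s)
}

#' Well-lit leafy-vegetation pixel mask
#'
#' A pixel is included iff its NDVI is at least `cfg$ndvi_min` and its mean
#' reflectance over retained bands within `cfg$nir_window_nm` is at least
#' `cfg$nir_mean_min` (both inclusive).
#'
#' @inheritParams compute_ndvi
#' @return logical H x W matrix.
#' @export
vegetation_mask <- function(cube, cfg = mask_config()) {
  stopifnot(inherits(cube, "reflectance_cube"))
  ndvi <- compute_ndvi(cube, cfg)
  nir_idx <- bands_in_window(cube$grid, cfg$nir_window_nm[1], cfg$nir_window_nm[2])
  d <- dim(cube$values)
  nir_mean <- matrix(rowMeans(matrix(cube$values[, , nir_idx, drop = FALSE],
                                     nrow = d[1] * d[2])), d[1], d[2])
  ndvi >= cfg$ndvi_min & nir_mean >= cfg$nir_mean_min
}

#' Extract labeled crown pixels from a scene
#'
#' One dataset row per pixel that passes the mask and lies under a nonzero
#' crown id; spectra are the cube's retained-band values and rows carry the
#' crown id and its species from the crown table. An empty crown map yields
#' an empty dataset.
#'
#' @param cube a `reflectance_cube`.
#' @param map a `crown_map` co-registered with the cube.
#' @param mask logical matrix of the same dimensions (e.g. from
#'   [vegetation_mask()]); pass a matrix of `TRUE` to keep all crown pixels.
#' @return a `pixel_dataset`.
#' @export
extract_crown_pixels <- function(cube, map, mask) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(map, "crown_map"),
            is.logical(mask))
  d <- dim(cube$values)
  if (!all(dim(map$crown_id_raster) == d[1:2]) || !all(dim(mask) == d[1:2]))
    stop("cube, crown map and mask dimensions differ", call. = FALSE)
  keep <- which(map$crown_id_raster > 0L & mask)
  x <- cube_matrix(cube)[keep, , drop = FALSE]
  ids <- map$crown_id_raster[keep]
  lookup <- integer(max(map$crown_table$crown_id, 0L))
  lookup[map$crown_table$crown_id] <- map$crown_table$species_id
  pixel_dataset(x, ids, if (length(keep)) lookup[ids] else integer(0), cube$grid)
}
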