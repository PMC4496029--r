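# Core data containers: reflectance cube, pixel dataset, crown map.
# Spectra are stored over the *retained* bands of a wavelength_grid only;
# reflectance is a fraction in [0, 1] (the field convention "21%" is 0.21).

#' Construct a reflectance cube
#'
#' An H x W x B array of reflectance fractions tied to a [build_band_grid()]
#' spectral axis; `B` must equal the number of retained bands of the grid.
#' Negative values (possible in atmospherically corrected data) are clipped
#' to zero; the clipped count is reported via a message when nonzero.
#'
#' @param values numeric array, H x W x B.
#' @param grid a `wavelength_grid`.
#' @return object of class `reflectance_cube` with elements `values`, `grid`.
#' @export
reflectance_cube <- function(values, grid) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            inherits(grid, "wavelength_grid"))
  if (dim(values)[3] != n_bands(grid))
    stop(sprintf("cube has %d bands but grid retains %d",
                 dim(values)[3], n_bands(grid)), call. = FALSE)
  if (any(!is.finite(values)))
    stop("cube contains non-finite reflectance values", call. = FALSE)
  n_neg <- sum(values < 0)
  if (n_neg > 0) {
    message(sprintf("clipped %d negative reflectance values to 0", n_neg))
    values[values < 0] <- 0
  }
  structure(list(values = values, grid = grid), class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d retained bands\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.reflectance_cube <- function(x) dim(x$values)

# Flatten a cube to a (H*W) x B matrix of spectra, pixels in column-major
# raster order (the order used by matrix indexing throughout).
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
}

#' Construct a pixel dataset
#'
#' The classifier currency: one spectrum per row plus a crown id and species
#' label. Species code 0 means unknown identity (pseudo-outliers); crown id
#' `NA` marks pixels not belonging to a delineated crown.
#'
#' @param x numeric matrix, one spectrum per row over the retained bands.
#' @param crown_id integer vector (or `NA`), one per row.
#' @param species integer species codes, one per row; 0 = unknown.
#' @param grid the `wavelength_grid` the spectra live on.
#' @return object of class `pixel_dataset`.
#' @export
pixel_dataset <- function(x, crown_id, species, grid) {
  x <- as.matrix(x)
  stopifnot(inherits(grid, "wavelength_grid"),
            ncol(x) == n_bands(grid),
            length(crown_id) == nrow(x), length(species) == nrow(x))
  structure(list(x = x, crown_id = as.integer(crown_id),
                 species = as.integer(species), grid = grid),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("<pixel_dataset> %d pixels x %d bands, %d crowns, species codes: %s\n",
              nrow(x$x), ncol(x$x),
              length(unique(x$crown_id[!is.na(x$crown_id)])),
              paste(sort(unique(x$species)), collapse = " ")))
  invisible(x)
}

#' Number of pixel rows in a dataset
#' @param ds a `pixel_dataset`.
#' @export
n_pixels <- function(ds) nrow(ds$x)

# Row subset preserving class and metadata.
subset_pixels <- function(ds, idx) {
  pixel_dataset(ds$x[idx, , drop = FALSE], ds$crown_id[idx], ds$species[idx],
                ds$grid)
}

# Stack datasets sharing a grid.
bind_pixels <- function(...) {
  dss <- list(...)
  pixel_dataset(do.call(rbind, lapply(dss, `[[`, "x")),
                unlist(lapply(dss, `[[`, "crown_id")),
                unlist(lapply(dss, `[[`, "species")),
                dss[[1]]$grid)
}

# Crown-level summary table of a pixel dataset: crown_id, species_id, n_pixels.
crown_summary <- function(ds) {
  keep <- !is.na(ds$crown_id)
  id <- ds$crown_id[keep]
  sp <- ds$species[keep]
  first <- !duplicated(id)
  if (anyDuplicated(unique(cbind(id, sp))[, 1]))
    stop("a crown id maps to more than one species", call. = FALSE)
  data.frame(crown_id = id[first], species_id = sp[first],
             n_pixels = as.integer(table(factor(id, levels = id[first]))))
}

#' Construct a crown map
#'
#' Ground-truth (or manually delineated) crown geometry: an integer raster of
#' crown ids (0 = no crown) plus a crown table with one row per crown.
#'
#' @param crown_id_raster integer matrix; 0 marks pixels outside any crown.
#' @param crown_table data.frame with columns `crown_id`, `species_id`,
#'   `n_pixels`.
#' @return object of class `crown_map`.
#' @export
crown_map <- function(crown_id_raster, crown_table) {
  stopifnot(is.matrix(crown_id_raster),
            all(c("crown_id", "species_id", "n_pixels") %in% names(crown_table)))
  ids <- crown_id_raster[crown_id_raster > 0]
  tab <- table(ids)
  in_raster <- as.integer(names(tab))
  if (anyDuplicated(crown_table$crown_id))
    stop("duplicated crown_id in crown_table", call. = FALSE)
  if (!setequal(in_raster, crown_table$crown_id))
    stop("crown ids in raster and crown_table disagree", call. = FALSE)
  counts <- as.integer(tab[as.character(crown_table$crown_id)])
  if (!all(counts == crown_table$n_pixels))
    stop("crown_table n_pixels does not match raster pixel counts", call. = FALSE)
  structure(list(crown_id_raster = crown_id_raster,
                 crown_table = crown_table), class = "crown_map")
}

#' @export
print.crown_map <- function(x, ...) {
  cat(sprintf("<crown_map> %d x %d raster, %d crowns, %d crown pixels\n",
              nrow(x$crown_id_raster), ncol(x$crown_id_raster),
              nrow(x$crown_table), sum(x$crown_table$n_pixels)))
  invisible(x)
}

# Species raster implied by a crown map (0 where no crown).
crown_species_raster <- function(map) {
  out <- matrix(0L, nrow(map$crown_id_raster), ncol(map$crown_id_raster))
  pos <- map$crown_id_raster > 0
  lookup <- integer(max(map$crown_table$crown_id))
  lookup[map$crown_table$crown_id] <- map$crown_table$species_id
  out[pos] <- lookup[map$crown_id_raster[pos]]
  out
}
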