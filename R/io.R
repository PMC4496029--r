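# File interchange: ENVI-style flat-binary rasters with text headers, plus
# CSV sidecars for wavelengths, crown tables and pixel datasets.

write_envi_header <- function(path, dims, bands, dtype = 4L, interleave = "bsq",
                              extra = character(0)) {
  lines <- c("ENVI",
             sprintf("samples = %d", dims[2]),
             sprintf("lines = %d", dims[1]),
             sprintf("bands = %d", bands),
             "header offset = 0",
             "file type = ENVI Standard",
             sprintf("data type = %d", dtype),
             sprintf("interleave = %s", interleave),
             "byte order = 0",
             extra)
  writeLines(lines, path)
}

parse_envi_header <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([a-z ]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

#' Write a reflectance cube as an ENVI raster + wavelength sidecar
#'
#' Band-sequential (BSQ) 32-bit float binary with a text `.hdr`, plus a
#' `*_wavelengths.csv` sidecar listing every grid band with its retained
#' flag. `path` is the data-file path; the header and sidecar derive from it.
#'
#' @param cube a `reflectance_cube`.
#' @param path output data-file path (e.g. `"scene.dat"`).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path) {
  d <- dim(cube$values)
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, within band row-major lines (samples fastest)
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 4)
  write_envi_header(paste0(path, ".hdr"), d[1:2], d[3])
  g <- cube$grid
  utils::write.csv(
    data.frame(band_index = seq_along(g$centers_nm),
               center_nm = g$centers_nm,
               retained_flag = as.integer(g$retained)),
    sidecar_path(path, "_wavelengths.csv"), row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path, suffix) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), suffix)
}

#' Read an ENVI reflectance cube written by [write_envi_cube()]
#'
#' Rebuilds the wavelength grid from the sidecar CSV; negative reflectance is
#' clipped to zero by the cube constructor.
#'
#' @param path data-file path.
#' @return a `reflectance_cube`.
#' @export
read_envi_cube <- function(path) {
  hdr <- parse_envi_header(paste0(path, ".hdr"))
  H <- as.integer(hdr$lines); W <- as.integer(hdr$samples)
  B <- as.integer(hdr$bands)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = H * W * B, size = 4)
  vals <- array(NA_real_, c(H, W, B))
  for (b in seq_len(B))
    vals[, , b] <- t(matrix(raw[((b - 1) * H * W + 1):(b * H * W)], W, H))
  wl <- utils::read.csv(sidecar_path(path, "_wavelengths.csv"))
  grid <- grid_from_table(wl)
  reflectance_cube(vals, grid)
}

# Rebuild a wavelength_grid object from a sidecar table (centers + flags).
grid_from_table <- function(tab) {
  stopifnot(all(c("center_nm", "retained_flag") %in% names(tab)))
  centers <- tab$center_nm
  structure(list(centers_nm = centers,
                 retained = tab$retained_flag > 0,
                 spacing_nm = if (length(centers) > 1) stats::median(diff(centers)) else 1,
                 span_nm = range(centers),
                 exclusions = list(), keep_nm = range(centers)),
            class = "wavelength_grid")
}

#' Write / read an integer label or crown-id raster (ENVI, int32)
#' @param raster integer matrix.
#' @param path data-file path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_envi_raster <- function(raster, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(raster)), con, size = 4)
  write_envi_header(paste0(path, ".hdr"), dim(raster), 1L, dtype = 3L)
  invisible(path)
}

#' @rdname write_envi_raster
#' @export
read_envi_raster <- function(path) {
  hdr <- parse_envi_header(paste0(path, ".hdr"))
  H <- as.integer(hdr$lines); W <- as.integer(hdr$samples)
  con <- file(path, "rb")
  on.exit(close(con))
  t(matrix(readBin(con, integer(), n = H * W, size = 4), W, H))
}

#' Write / read a pixel dataset as CSV
#'
#' Columns `crown_id`, `species`, then `b1..bB` over the retained bands.
#' Writing is deterministic (fixed significant digits), so identical datasets
#' produce byte-identical files.
#'
#' @param ds a `pixel_dataset`.
#' @param path CSV path.
#' @param grid grid for reading (a `wavelength_grid` whose retained-band
#'   count matches the file's spectral columns).
#' @return `path` (write) or a `pixel_dataset` (read).
#' @export
write_pixel_dataset <- function(ds, path) {
  df <- data.frame(crown_id = ds$crown_id, species = ds$species,
                   signif(ds$x, 7))
  names(df)[-(1:2)] <- paste0("b", seq_len(ncol(ds$x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_dataset
#' @export
read_pixel_dataset <- function(path, grid) {
  df <- utils::read.csv(path)
  pixel_dataset(as.matrix(df[, -(1:2), drop = FALSE]),
                df$crown_id, df$species, grid)
}

#' Write a crown map (id raster + crown table CSV)
#' @param map a `crown_map`.
#' @param path data-file path for the raster; the table goes to a
#'   `*_crowns.csv` sidecar.
#' @export
write_crown_map <- function(map, path) {
  write_envi_raster(map$crown_id_raster, path)
  utils::write.csv(map$crown_table, sidecar_path(path, "_crowns.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_crown_map
#' @export
read_crown_map <- function(path) {
  crown_map(read_envi_raster(path),
            utils::read.csv(sidecar_path(path, "_crowns.csv")))
}
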