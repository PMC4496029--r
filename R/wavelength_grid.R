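#' Build a spectrometer band grid with exclusion windows
#'
#' Constructs the spectral axis used throughout the package: a uniform grid of
#' band centers spanning `span_nm`, with a retained/excluded flag per band.
#' Bands are excluded when their center lies below `keep_nm[1]`, above
#' `keep_nm[2]`, or inside any exclusion window. Exclusion windows are closed
#' intervals: a band center equal to a window endpoint is excluded. The
#' defaults reproduce a visible-to-shortwave-infrared imaging spectrometer
#' resampled to 10.4 nm resolution with the two major atmospheric
#' water-absorption windows removed and the noisy spectrum ends trimmed.
#'
#' @param span_nm length-2 numeric, first and nominal last band center (nm).
#' @param spacing_nm band spacing (nm), > 0.
#' @param exclusions list of length-2 numeric windows (nm) to exclude, closed
#'   at both ends.
#' @param keep_nm length-2 numeric; centers strictly below `keep_nm[1]` or
#'   strictly above `keep_nm[2]` are excluded.
#' @return An object of class `wavelength_grid`: a list with `centers_nm`
#'   (all band centers), `retained` (logical per band), and the call
#'   parameters.
#' @examples
#' g <- build_band_grid()
#' sum(g$retained)           # 159 retained of 206 bands
#' @export
build_band_grid <- function(span_nm = c(380, 2512),
                            spacing_nm = 10.4,
                            exclusions = list(c(1330, 1460), c(1770, 2022)),
                            keep_nm = c(400, 2422)) {
  stopifnot(length(span_nm) == 2L, span_nm[2] > span_nm[1])
  stop_if_not_scalar_number(spacing_nm, "spacing_nm", lower = 1e-9)
  centers <- span_nm[1] + spacing_nm * seq(0L, floor((span_nm[2] - span_nm[1]) / spacing_nm))
  retained <- centers >= keep_nm[1] & centers <= keep_nm[2]
  for (w in exclusions) {
    stopifnot(length(w) == 2L, w[2] >= w[1])
    retained <- retained & !(centers >= w[1] & centers <= w[2])
  }
  if (!any(retained))
    stop("band grid has no retained bands: exclusions cover the full span",
         call. = FALSE)
  structure(
    list(centers_nm = centers, retained = retained,
         spacing_nm = spacing_nm, span_nm = span_nm,
         exclusions = exclusions, keep_nm = keep_nm),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands (%.1f-%.1f nm @ %.2f nm), %d retained\n",
              length(x$centers_nm), min(x$centers_nm), max(x$centers_nm),
              x$spacing_nm, sum(x$retained)))
  invisible(x)
}

#' Band centers of the retained bands
#' @param grid a `wavelength_grid`.
#' @return numeric vector of retained band centers (nm).
#' @export
retained_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$centers_nm[grid$retained]
}

#' Number of retained bands
#' @param grid a `wavelength_grid`.
#' @export
n_bands <- function(grid) sum(grid$retained)

# Index (into the retained bands) of the band nearest to a target wavelength.
# Errors when the grid retains no band within half the grid span of `nm`,
# naming the requested wavelength.
nearest_band <- function(grid, nm, what = "band") {
  wl <- retained_wavelengths(grid)
  if (length(wl) == 0L) stop("grid has no retained bands", call. = FALSE)
  i <- which.min(abs(wl - nm))
  if (abs(wl[i] - nm) > max(2 * grid$spacing_nm, 25))
    stop(sprintf("no retained band near %s reference wavelength %.0f nm (closest: %.1f nm)",
                 what, nm, wl[i]), call. = FALSE)
  i
}

# Indices (into retained bands) whose centers fall in [lo, hi].
bands_in_window <- function(grid, lo, hi) {
  wl <- retained_wavelengths(grid)
  idx <- which(wl >= lo & wl <= hi)
  if (length(idx) == 0L)
    stop(sprintf("no retained bands in window %.0f-%.0f nm", lo, hi), call. = FALSE)
  idx
}
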