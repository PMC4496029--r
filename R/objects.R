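# Crown-object extraction: side-adjacent connected components per species
# with a minimum-size rule.

#' Extract crown objects from a label raster
#'
#' Computes connected components per species with 4-connectivity (contiguity
#' = side-adjacent pixels; diagonal contact does not connect), removes
#' components smaller than `min_size` pixels from both the raster and the
#' table, and enumerates the survivors as crown objects. Note a crown object
#' may merge adjacent conspecific crowns or cover a fragment of one crown;
#' it is a map unit, not an individual tree.
#'
#' @param labels integer label matrix (0 = background), typically the output
#'   of [apply_contextual_filter()].
#' @param min_size minimum object size in pixels at the raster's resolution
#'   (default 10; objects with fewer than `min_size` pixels are eliminated).
#' @return list with `object_raster` (integer matrix of object ids, 0 =
#'   none) and `table`, a `data.frame` of class `crown_object_table` with
#'   one row per object: `object_id`, `species_id`, `pixel_count`,
#'   `centroid_row`, `centroid_col`, `bbox_*`.
#' @export
extract_objects <- function(labels, min_size = 10) {
  stopifnot(is.matrix(labels))
  species <- sort(unique(labels[labels > 0]))
  obj_raster <- matrix(0L, nrow(labels), ncol(labels))
  rows <- list()
  next_id <- 1L
  for (s in species) {
    comp <- EBImage::bwlabel(labels == s)
    if (max(comp) == 0) next
    counts <- tabulate(comp[comp > 0], nbins = max(comp))
    for (ci in seq_along(counts)) {
      if (counts[ci] < min_size) next
      px <- which(comp == ci)
      r <- (px - 1L) %% nrow(labels) + 1L
      c <- (px - 1L) %/% nrow(labels) + 1L
      obj_raster[px] <- next_id
      rows[[next_id]] <- data.frame(
        object_id = next_id, species_id = s, pixel_count = counts[ci],
        centroid_row = mean(r), centroid_col = mean(c),
        bbox_rmin = min(r), bbox_rmax = max(r),
        bbox_cmin = min(c), bbox_cmax = max(c))
      next_id <- next_id + 1L
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = integer(0), species_id = integer(0),
               pixel_count = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), bbox_rmin = integer(0),
               bbox_rmax = integer(0), bbox_cmin = integer(0),
               bbox_cmax = integer(0))
  class(tab) <- c("crown_object_table", "data.frame")
  list(object_raster = obj_raster, table = tab)
}

#' @export
print.crown_object_table <- function(x, ...) {
  cat(sprintf("<crown_object_table> %d objects, %d pixels\n",
              nrow(x), sum(x$pixel_count)))
  if (nrow(x)) print(as.data.frame(table(species = x$species_id)), ...)
  invisible(x)
}

# Count connected components (side-adjacent) per species without a size
# filter; used for the pre/post filtering bookkeeping.
count_components <- function(labels) {
  species <- sort(unique(labels[labels > 0]))
  stats::setNames(vapply(species, function(s)
    max(EBImage::bwlabel(labels == s)), numeric(1)), species)
}
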