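# Contextual filtering of label rasters by mathematical morphology.
#
# The filter chain per species: binarize, cut each pixel into quarters
# (2x upsample), opening then closing with a full 3x3 structuring element
# (removing objects and filling holes up to one original pixel in width),
# then downsample back to the original resolution. Out-of-bounds is always
# treated as background, so morphology cannot create spurious edge objects.

#' Cut each pixel into quarters
#'
#' Replicates each pixel into a 2 x 2 block, doubling both raster
#' dimensions; values are preserved.
#'
#' @param raster integer, logical or numeric matrix.
#' @return matrix of dimensions `2H x 2W`.
#' @export
upsample_quarters <- function(raster) {
  stopifnot(is.matrix(raster))
  raster[rep(seq_len(nrow(raster)), each = 2),
         rep(seq_len(ncol(raster)), each = 2)]
}

# Zero-pad a binary matrix on all sides.
pad_zero <- function(m, k) {
  out <- matrix(0, nrow(m) + 2 * k, ncol(m) + 2 * k)
  out[k + seq_len(nrow(m)), k + seq_len(ncol(m))] <- m
  out
}

#' Morphological opening-closing with a 3 x 3 kernel
#'
#' Binary opening (erosion then dilation) followed by closing (dilation then
#' erosion), both with the full 3 x 3 structuring element. Every primitive
#' treats out-of-bounds as background: each erosion/dilation is evaluated on
#' the raster's finite domain with a zero border. On a quartered raster the
#' opening removes objects up to two fine pixels (one original pixel) in
#' width and the closing fills holes of the same size.
#'
#' @param raster logical (or 0/1) matrix.
#' @return logical matrix of the same dimensions.
#' @export
open_close_3x3 <- function(raster) {
  stopifnot(is.matrix(raster))
  brush <- EBImage::makeBrush(3, "box")
  H <- nrow(raster); W <- ncol(raster)
  op <- function(x, f) f(pad_zero(x, 1), brush)[1 + seq_len(H), 1 + seq_len(W)]
  m <- (raster != 0) * 1
  m <- op(op(m, EBImage::erode), EBImage::dilate)   # opening
  m <- op(op(m, EBImage::dilate), EBImage::erode)   # closing
  m > 0
}

#' Aggregate a quartered raster back to the original resolution
#'
#' Each coarse pixel summarizes its 2 x 2 fine block. Under the default
#' `"majority"` rule the coarse pixel is focal iff at least 2 of the 4 fine
#' pixels are focal (approximately area-conserving); `"unanimous"` requires
#' all 4 and `"any"` requires 1.
#'
#' @param fine logical (or 0/1) matrix with even dimensions.
#' @param rule aggregation rule.
#' @return logical matrix of dimensions `H/2 x W/2`.
#' @export
downsample_majority <- function(fine, rule = c("majority", "unanimous", "any")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(fine))
  if (nrow(fine) %% 2L != 0L || ncol(fine) %% 2L != 0L)
    stop("fine raster dimensions must be even", call. = FALSE)
  b <- (fine != 0) * 1
  counts <- b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE] +
    b[seq(2, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE] +
    b[seq(1, nrow(b), 2), seq(2, ncol(b), 2), drop = FALSE] +
    b[seq(2, nrow(b), 2), seq(2, ncol(b), 2), drop = FALSE]
  counts >= switch(rule, majority = 2L, unanimous = 4L, any = 1L)
}

#' Contextual filter of a species label raster
#'
#' Applies the quarter / open-close / aggregate chain independently per
#' species and recombines the layers. Pixels claimed by two or more species
#' after recombination (possible in principle because closing can grow each
#' layer) are resolved by the larger count of same-species neighbors in the
#' 8-neighborhood of the filtered layers; remaining ties go to the lower
#' species code. The number of such conflicts is returned as an attribute.
#'
#' @param labels integer H x W matrix (0 = background, `1..S` species).
#' @param rule downsampling rule, see [downsample_majority()].
#' @return filtered integer label matrix with attribute `n_conflicts`.
#' @export
apply_contextual_filter <- function(labels, rule = "majority") {
  stopifnot(is.matrix(labels))
  species <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(species) == 0L) {
    attr(out, "n_conflicts") <- 0L
    return(out)
  }
  layers <- lapply(species, function(s)
    downsample_majority(open_close_3x3(upsample_quarters(labels == s)),
                        rule = rule))
  claim <- Reduce(`+`, lapply(layers, function(l) l * 1L))
  single <- claim == 1L
  for (i in seq_along(species))
    out[single & layers[[i]]] <- species[i]
  conflicts <- which(claim >= 2L)
  for (px in conflicts) {
    r <- (px - 1L) %% nrow(labels) + 1L
    c <- (px - 1L) %/% nrow(labels) + 1L
    rr <- max(1, r - 1):min(nrow(labels), r + 1)
    cc <- max(1, c - 1):min(ncol(labels), c + 1)
    claimants <- which(vapply(layers, function(l) l[r, c], logical(1)))
    support <- vapply(claimants, function(i)
      sum(layers[[i]][rr, cc]) - 1L, integer(1))
    out[r, c] <- species[claimants[which.max(support)]]
  }
  attr(out, "n_conflicts") <- length(conflicts)
  out
}
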