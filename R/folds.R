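#' Crown-level cross-validation fold assignment
#'
#' Assigns whole crowns (never pixels) to `k` folds, stratified: within each
#' stratum the crowns are shuffled by `seed` and dealt round-robin, so fold
#' crown-counts differ by at most one per stratum. Pixels inherit the fold of
#' their crown, which prevents within-crown leakage between training and
#' held-out data.
#'
#' @param crown_table data.frame with a `crown_id` column (e.g. a crown map's
#'   table or [crown_summary] output).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @param strata stratification vector parallel to `crown_table` rows
#'   (defaults to `species_id`); every stratum needs at least `k` crowns.
#' @return object of class `fold_assignment`: an integer vector of folds in
#'   `1..k` named by crown id.
#' @export
crown_folds <- function(crown_table, k = 5, seed = 1, strata = NULL) {
  stopifnot(is.data.frame(crown_table), "crown_id" %in% names(crown_table),
            k >= 2)
  if (is.null(strata)) {
    if (!"species_id" %in% names(crown_table))
      stop("supply 'strata' or a 'species_id' column", call. = FALSE)
    strata <- crown_table$species_id
  }
  strata <- as.character(strata)
  out <- integer(nrow(crown_table))
  with_seed(derive_seed(seed, "folds"), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k)
        stop(sprintf("class '%s' has %d crowns, fewer than k = %d folds",
                     s, length(idx), k), call. = FALSE)
      out[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(stats::setNames(out, crown_table$crown_id),
            k = as.integer(k), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d crowns in %d folds\n",
              length(x), attr(x, "k")))
  invisible(x)
}

# Fold of each pixel row of a dataset (NA for rows without a crown).
pixel_folds <- function(ds, folds) {
  unname(folds[as.character(ds$crown_id)])
}

# Hard guard used by every tuner: training and held-out crown sets of a fold
# must be disjoint.
assert_no_leak <- function(train_crowns, test_crowns) {
  leak <- intersect(train_crowns, test_crowns)
  if (length(leak))
    stop(sprintf("crown-level CV leak: crowns %s in both training and test",
                 paste(utils::head(leak, 5), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
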