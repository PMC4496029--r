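# Multi-species fusion: one biased detector per focal species combined with
# a balanced tie-breaking multiclass SVM via three exhaustive, exclusive
# rules: (i) no detector fires -> background/outlier (code 0); (ii) exactly
# one fires -> that species; (iii) two or more fire -> the tie-breaker
# decides.

#' Balance focal-species pixel sets to the smallest class
#'
#' Randomly subsets each species' pixel rows to the minimum class size, the
#' balancing step used before fitting the tie-breaking SVM (e.g. classes of
#' 10726, 3325 and 2091 pixels are each subset to 2091).
#'
#' @param dataset `pixel_dataset` with focal species labels (> 0).
#' @param seed RNG seed; the subset is deterministic under it.
#' @return a `pixel_dataset` with equal class sizes.
#' @export
balance_classes <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  cls <- sort(unique(dataset$species))
  if (any(cls <= 0)) stop("balance_classes expects focal labels > 0", call. = FALSE)
  n_min <- min(table(dataset$species))
  keep <- with_seed(derive_seed(seed, "balance"), {
    unlist(lapply(cls, function(s) {
      idx <- which(dataset$species == s)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  subset_pixels(dataset, keep)
}

#' Fit the tie-breaking multiclass SVM
#'
#' Balances the focal-species pixels with [balance_classes()] and fits an
#' ordinary multiclass RBF-kernel SVM over the focal species. Used to decide
#' the species of pixels claimed by more than one single-species detector.
#'
#' @param dataset `pixel_dataset` of focal-species pixels (at least two
#'   species, each with at least one pixel).
#' @param params a [detector_params()] (`weight` ignored).
#' @param seed seed for the balancing subsample.
#' @return object of class `tiebreaker_svm`.
#' @export
train_tiebreaker <- function(dataset, params = detector_params(), seed = 1) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  cls <- sort(unique(dataset$species))
  if (length(cls) < 2)
    stop("tie-breaker needs at least two focal species with pixels",
         call. = FALSE)
  bal <- balance_classes(dataset, seed)
  fit <- e1071::svm(bal$x, factor(bal$species, levels = cls),
                    type = "C-classification", kernel = "radial",
                    gamma = params$gamma, cost = params$cost, scale = FALSE)
  structure(list(svm = fit, classes = cls, params = params,
                 n_per_class = min(table(dataset$species))),
            class = "tiebreaker_svm")
}

#' @export
print.tiebreaker_svm <- function(x, ...) {
  cat(sprintf("<tiebreaker_svm> %d classes balanced to %d pixels each\n",
              length(x$classes), x$n_per_class))
  invisible(x)
}

#' @export
#' @param object a `tiebreaker_svm`.
#' @param newdata matrix of spectra.
#' @param ... unused.
#' @rdname train_tiebreaker
predict.tiebreaker_svm <- function(object, newdata, ...) {
  as.integer(as.character(stats::predict(object$svm, as.matrix(newdata))))
}

# Restricted tie-break: majority vote over the pairwise decision values
# among the flagged classes only; ties go to the lower species code.
tiebreak_restricted <- function(tb, x, flagged) {
  pred <- stats::predict(tb$svm, as.matrix(x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pairs <- strsplit(colnames(dv), "/")
  out <- integer(nrow(as.matrix(x)))
  for (i in seq_along(out)) {
    votes <- stats::setNames(integer(length(tb$classes)),
                             as.character(tb$classes))
    for (j in seq_along(pairs)) {
      a <- pairs[[j]][1]; b <- pairs[[j]][2]
      w <- if (dv[i, j] > 0) a else b
      votes[w] <- votes[w] + 1L
    }
    cand <- as.character(flagged[[i]])
    out[i] <- as.integer(cand[which.max(votes[cand])])
  }
  out
}

#' Combine per-species detector flags into species labels
#'
#' Applies the fusion rules: (i) a pixel flagged by no detector gets the
#' outlier code 0; (ii) a pixel flagged by exactly one detector gets that
#' species; (iii) a pixel flagged by two or more detectors is passed to the
#' tie-breaking SVM. By default the tie-breaker predicts over all focal
#' classes; with `restrict = TRUE` its pairwise votes are restricted to the
#' flagged classes.
#'
#' @param flags logical matrix, pixels x focal species; column `s` is
#'   detector `s`'s focal assignment.
#' @param tiebreaker a `tiebreaker_svm` (may be `NULL` when fewer than two
#'   detectors exist, in which case rule (iii) is unreachable).
#' @param x spectra matrix aligned with `flags` rows (needed for rule iii).
#' @param restrict restrict tie-breaking to the flagged classes.
#' @return integer vector of species labels (0 = outlier).
#' @export
combine_flags <- function(flags, tiebreaker = NULL, x = NULL,
                          restrict = FALSE) {
  flags <- as.matrix(flags)
  n_hit <- rowSums(flags)
  out <- integer(nrow(flags))
  one <- which(n_hit == 1L)
  if (length(one))
    out[one] <- max.col(flags[one, , drop = FALSE])
  multi <- which(n_hit >= 2L)
  if (length(multi)) {
    if (is.null(tiebreaker) || is.null(x))
      stop("pixels flagged by several detectors need a tiebreaker and spectra",
           call. = FALSE)
    xm <- as.matrix(x)[multi, , drop = FALSE]
    if (restrict) {
      flagged <- lapply(multi, function(i) which(flags[i, ]))
      out[multi] <- tiebreak_restricted(tiebreaker, xm, flagged)
    } else {
      out[multi] <- predict(tiebreaker, xm)
    }
  }
  out
}

#' Assemble a multi-species classification model
#'
#' Bundles one fitted biased detector per focal species with the
#' tie-breaking SVM. Species codes are `1..S` in detector order; 0 is
#' reserved for the background/outlier class.
#'
#' @param detectors list of `species_detector` objects, one per focal
#'   species, in species-code order.
#' @param tiebreaker a `tiebreaker_svm` over the same species (or `NULL`
#'   with a single detector).
#' @param restrict passed on to [combine_flags()].
#' @return object of class `multispecies_svm`.
#' @export
multispecies_svm <- function(detectors, tiebreaker = NULL, restrict = FALSE) {
  stopifnot(length(detectors) >= 1,
            all(vapply(detectors, inherits, logical(1), "species_detector")))
  if (length(detectors) >= 2) {
    if (is.null(tiebreaker)) stop("two or more detectors need a tiebreaker",
                                  call. = FALSE)
    if (length(tiebreaker$classes) != length(detectors))
      stop("tiebreaker class count must equal detector count", call. = FALSE)
  }
  structure(list(detectors = detectors, tiebreaker = tiebreaker,
                 restrict = restrict, n_species = length(detectors)),
            class = "multispecies_svm")
}

#' @export
print.multispecies_svm <- function(x, ...) {
  cat(sprintf("<multispecies_svm> %d biased detectors + %s tiebreaker\n",
              x$n_species,
              if (is.null(x$tiebreaker)) "no" else "multiclass"))
  invisible(x)
}

#' Predict species labels for a matrix of spectra
#'
#' Runs every detector, then [combine_flags()].
#'
#' @param object a `multispecies_svm`.
#' @param newdata spectra matrix.
#' @param ... unused.
#' @return integer labels (0 = outlier) with attribute `flags` (the logical
#'   detector-assignment matrix).
#' @export
predict.multispecies_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  flags <- vapply(object$detectors, function(d) predict(d, newdata),
                  logical(nrow(newdata)))
  flags <- matrix(flags, nrow = nrow(newdata))
  out <- combine_flags(flags, object$tiebreaker, newdata,
                       restrict = object$restrict)
  attr(out, "flags") <- flags
  out
}

#' Classify every vegetation pixel of a scene
#'
#' Applies the multi-species model to the masked-in pixels of a cube;
#' masked-out pixels receive the background code 0 (the mask is returned so
#' the two meanings of 0 stay distinguishable). Run metadata records the
#' fraction of vegetation pixels flagged by at least one detector, the share
#' of those flagged by more than one, and their product — the fraction of
#' vegetation pixels whose label came from the tie-breaker.
#'
#' @param cube a `reflectance_cube`.
#' @param mask logical vegetation mask from [vegetation_mask()].
#' @param model a `multispecies_svm`.
#' @return object of class `species_map`: `labels` (integer H x W matrix),
#'   `mask`, and `meta` (assignment bookkeeping).
#' @export
classify_image <- function(cube, mask, model) {
  stopifnot(inherits(cube, "reflectance_cube"), is.logical(mask),
            inherits(model, "multispecies_svm"))
  d <- dim(cube$values)
  if (!all(dim(mask) == d[1:2]))
    stop("cube and mask dimensions differ", call. = FALSE)
  if (ncol(cube_matrix(cube)) != ncol(model$detectors[[1]]$svm$SV))
    stop("cube band count does not match the model's training grid",
         call. = FALSE)
  labels <- matrix(0L, d[1], d[2])
  idx <- which(mask)
  meta <- list(n_vegetation = length(idx), frac_any_flag = 0,
               frac_multi_given_any = 0, frac_tiebreak = 0)
  if (length(idx)) {
    pred <- predict(model, cube_matrix(cube)[idx, , drop = FALSE])
    labels[idx] <- pred
    n_hit <- rowSums(attr(pred, "flags"))
    meta$frac_any_flag <- mean(n_hit >= 1)
    meta$frac_multi_given_any <- if (any(n_hit >= 1))
      mean(n_hit[n_hit >= 1] >= 2) else 0
    meta$frac_tiebreak <- meta$frac_any_flag * meta$frac_multi_given_any
  }
  structure(list(labels = labels, mask = mask, meta = meta),
            class = "species_map")
}

#' @export
print.species_map <- function(x, ...) {
  cat(sprintf(paste0("<species_map> %d x %d, %d vegetation px, ",
                     "%.2f%% flagged, %.2f%% tie-broken\n"),
              nrow(x$labels), ncol(x$labels), x$meta$n_vegetation,
              100 * x$meta$frac_any_flag, 100 * x$meta$frac_tiebreak))
  invisible(x)
}

#' Fit the final multi-species model on all data
#'
#' Refits one biased detector per focal species on all of that species'
#' crown pixels against the full pseudo-outlier pool (the final-model
#' protocol: no data held out), plus the balanced tie-breaker on all focal
#' pixels.
#'
#' @param dataset `pixel_dataset` of focal crown pixels (species `1..S`).
#' @param pseudo `pixel_dataset` of pseudo-outliers.
#' @param params_list list of [detector_params()] per species (recycled if
#'   length 1).
#' @param tiebreaker_params [detector_params()] for the tie-breaker.
#' @param restrict passed to [multispecies_svm()].
#' @param seed seed for the tie-breaker balancing.
#' @return a `multispecies_svm`.
#' @export
fit_multispecies <- function(dataset, pseudo, params_list,
                             tiebreaker_params = detector_params(),
                             restrict = FALSE, seed = 1) {
  species <- sort(unique(dataset$species[dataset$species > 0]))
  if (length(params_list) == 1L)
    params_list <- rep(params_list, length(species))
  dets <- lapply(seq_along(species), function(i)
    species_detector(dataset$x[dataset$species == species[i], , drop = FALSE],
                     pseudo$x, params_list[[i]], mode = "biased"))
  tb <- if (length(species) >= 2)
    train_tiebreaker(subset_pixels(dataset, dataset$species > 0),
                     tiebreaker_params, seed) else NULL
  multispecies_svm(dets, tb, restrict)
}
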