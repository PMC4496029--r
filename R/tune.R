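# Grid-search tuning with crown-level cross-validation.
#
# Criteria are computed on predictions pooled across the held-out folds (not
# averaged per fold): per-fold averaging is unstable for the small focal
# classes this method targets. Ties on the criterion are broken towards the
# simpler model: smallest C, then smallest gamma, then smallest w_c.

# Precompute per-fold train/test splits for crown-labeled datasets.
# Returns list of folds, each with train/test row indices per dataset.
crown_fold_splits <- function(ds, folds) {
  k <- attr(folds, "k")
  pf <- pixel_folds(ds, folds)
  lapply(seq_len(k), function(i) {
    train_crowns <- as.integer(names(folds)[folds != i])
    test_crowns <- as.integer(names(folds)[folds == i])
    assert_no_leak(train_crowns, test_crowns)
    list(train = which(pf != i), test = which(pf == i))
  })
}

# Random by-pixel split of an (unlabeled) dataset into k groups.
pixel_fold_splits <- function(n, k, seed) {
  g <- with_seed(derive_seed(seed, "pseudo_groups"),
                 sample(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(i)
    list(train = which(g != i), test = which(g == i)))
}

order_best <- function(results, criterion) {
  o <- order(-results[[criterion]], results$cost, results$gamma,
             if ("weight" %in% names(results)) results$weight else
               rep(0, nrow(results)))
  o[1]
}

#' Tune a one-against-all binary detector
#'
#' Exhaustive grid search over `(gamma, cost)` with crown-level k-fold
#' cross-validation; the criterion is the pixel-level F-score on the focal
#' class computed from held-out predictions pooled over folds. The default
#' grid is `gamma = e^-12..e^-6` by `cost = e^5..e^15` (77 combinations).
#'
#' @param focal `pixel_dataset` of focal-species crown pixels.
#' @param outliers `pixel_dataset` of labeled outlier-species crown pixels.
#' @param folds a [crown_folds()] assignment covering the crowns of both
#'   datasets.
#' @param gamma,cost numeric grids.
#' @return object of class `svm_tuning`: `results` (one row per grid point
#'   with pooled precision/recall/F) and `best_params`.
#' @export
tune_binary <- function(focal, outliers, folds,
                        gamma = exp(-12:-6), cost = exp(5:15)) {
  sp_f <- crown_fold_splits(focal, folds)
  sp_o <- crown_fold_splits(outliers, folds)
  k <- attr(folds, "k")
  grid <- expand.grid(gamma = gamma, cost = cost)
  res <- cbind(grid, precision = NA_real_, recall = NA_real_,
               f_score = NA_real_)
  for (g in seq_len(nrow(grid))) {
    pr <- detector_params(grid$gamma[g], grid$cost[g])
    truth <- logical(0); pred <- logical(0)
    for (i in seq_len(k)) {
      det <- species_detector(focal$x[sp_f[[i]]$train, , drop = FALSE],
                              outliers$x[sp_o[[i]]$train, , drop = FALSE],
                              pr, mode = "binary")
      xt <- rbind(focal$x[sp_f[[i]]$test, , drop = FALSE],
                  outliers$x[sp_o[[i]]$test, , drop = FALSE])
      truth <- c(truth, rep(c(TRUE, FALSE), c(length(sp_f[[i]]$test),
                                              length(sp_o[[i]]$test))))
      pred <- c(pred, predict(det, xt))
    }
    m <- binary_metrics(truth, pred)
    res$precision[g] <- m$precision
    res$recall[g] <- m$recall
    res$f_score[g] <- m$f_score
  }
  b <- order_best(res, "f_score")
  structure(list(results = res,
                 best_params = detector_params(res$gamma[b], res$cost[b]),
                 criterion = "f_score", mode = "binary", folds = folds),
            class = "svm_tuning")
}

#' @export
print.svm_tuning <- function(x, ...) {
  b <- order_best(x$results, x$criterion)
  cat(sprintf("<svm_tuning> %s SVM, %d grid points, best %s = %.4f\n",
              x$mode, nrow(x$results), x$criterion, x$results[[x$criterion]][b]))
  print(x$best_params)
  invisible(x)
}

# Evaluate the biased criterion for one parameter combination, pooling
# held-out focal and pseudo-outlier predictions across folds.
eval_biased_point <- function(params, focal, pseudo, sp_f, sp_p, k) {
  n_test <- 0L; n_assigned <- 0L; n_focal_test <- 0L; n_focal_hit <- 0L
  for (i in seq_len(k)) {
    det <- species_detector(focal$x[sp_f[[i]]$train, , drop = FALSE],
                            pseudo$x[sp_p[[i]]$train, , drop = FALSE],
                            params, mode = "biased")
    pf <- predict(det, focal$x[sp_f[[i]]$test, , drop = FALSE])
    pp <- predict(det, pseudo$x[sp_p[[i]]$test, , drop = FALSE])
    n_focal_test <- n_focal_test + length(pf)
    n_focal_hit <- n_focal_hit + sum(pf)
    n_test <- n_test + length(pf) + length(pp)
    n_assigned <- n_assigned + sum(pf) + sum(pp)
  }
  r <- if (n_focal_test > 0) n_focal_hit / n_focal_test else 0
  p1 <- if (n_test > 0) n_assigned / n_test else 0
  c(recall = r, assign_fraction = p1, criterion = biased_criterion(r, p1))
}

#' Tune a biased (positive-unlabeled) detector
#'
#' Grid search over `(gamma, cost, w_c)` using the `r^2 / P[f(x) = 1]`
#' criterion ([biased_criterion()]): recall is measured on held-out focal
#' crown pixels and the assignment fraction on all held-out focal plus
#' pseudo-outlier pixels, pooled over folds. Focal crowns follow the
#' crown-level fold assignment; the pseudo-outliers are split into k groups
#' randomly by pixel. To save computation a coarse pass visits every other
#' grid value of each parameter (4 x 4 x 4 = 64 points on the default grids),
#' then a fine pass evaluates the full-resolution neighborhood (one grid
#' step) around the coarse optimum.
#'
#' @param focal `pixel_dataset` of focal-species crown pixels.
#' @param pseudo `pixel_dataset` of pseudo-outlier pixels (species 0).
#' @param folds [crown_folds()] assignment for the focal crowns.
#' @param gamma,cost,weight numeric grids (defaults `e^-8..e^-2`,
#'   `e^5..e^11`, `0.1..0.7`).
#' @param seed seed for the by-pixel split of the pseudo-outliers.
#' @param coarse_fine set `FALSE` to search the full grid exhaustively.
#' @return an `svm_tuning` object; `results` has a `pass` column
#'   (`"coarse"`/`"fine"`) when the two-stage search is used.
#' @export
tune_biased <- function(focal, pseudo, folds,
                        gamma = exp(-8:-2), cost = exp(5:11),
                        weight = seq(0.1, 0.7, by = 0.1),
                        seed = 1, coarse_fine = TRUE) {
  sp_f <- crown_fold_splits(focal, folds)
  k <- attr(folds, "k")
  sp_p <- pixel_fold_splits(n_pixels(pseudo), k, seed)
  eval_ids <- function(ids, pass) {
    out <- data.frame(gamma = gamma[ids[, 1]], cost = cost[ids[, 2]],
                      weight = weight[ids[, 3]], recall = NA_real_,
                      assign_fraction = NA_real_, criterion = NA_real_,
                      pass = pass)
    for (g in seq_len(nrow(ids))) {
      m <- eval_biased_point(
        detector_params(out$gamma[g], out$cost[g], out$weight[g]),
        focal, pseudo, sp_f, sp_p, k)
      out$recall[g] <- m["recall"]
      out$assign_fraction[g] <- m["assign_fraction"]
      out$criterion[g] <- m["criterion"]
    }
    out
  }
  idx_grid <- function(gi, ci, wi)
    as.matrix(expand.grid(gi, ci, wi, KEEP.OUT.ATTRS = FALSE))
  if (coarse_fine) {
    coarse_ids <- idx_grid(seq(1, length(gamma), by = 2),
                           seq(1, length(cost), by = 2),
                           seq(1, length(weight), by = 2))
    res <- eval_ids(coarse_ids, "coarse")
    b <- order_best(res, "criterion")
    bi <- c(match(res$gamma[b], gamma), match(res$cost[b], cost),
            match(res$weight[b], weight))
    nb <- function(i, n) unique(pmin(pmax(i + (-1:1), 1), n))
    fine_ids <- idx_grid(nb(bi[1], length(gamma)), nb(bi[2], length(cost)),
                         nb(bi[3], length(weight)))
    seen <- paste(coarse_ids[, 1], coarse_ids[, 2], coarse_ids[, 3])
    fine_ids <- fine_ids[!(paste(fine_ids[, 1], fine_ids[, 2], fine_ids[, 3])
                           %in% seen), , drop = FALSE]
    if (nrow(fine_ids) > 0) res <- rbind(res, eval_ids(fine_ids, "fine"))
  } else {
    res <- eval_ids(idx_grid(seq_along(gamma), seq_along(cost),
                             seq_along(weight)), "full")
  }
  b <- order_best(res, "criterion")
  structure(list(results = res,
                 best_params = detector_params(res$gamma[b], res$cost[b],
                                               res$weight[b]),
                 criterion = "criterion", mode = "biased", folds = folds),
            class = "svm_tuning")
}

#' Tune the multiclass tie-breaking SVM
#'
#' Same grid/CV machinery as [tune_binary()] but for the multiclass RBF SVM
#' over the focal species, with pooled overall accuracy as the criterion.
#' Training data are balanced (each class subset to the smallest class size
#' within the fold's training portion) before fitting.
#'
#' @param dataset `pixel_dataset` of focal-species pixels (species > 0).
#' @param folds [crown_folds()] assignment for the focal crowns.
#' @param gamma,cost numeric grids.
#' @param seed seed for the per-fold balancing subsample.
#' @return an `svm_tuning` object with pooled `accuracy` per grid point.
#' @export
tune_tiebreaker <- function(dataset, folds, gamma = exp(-6:-3),
                            cost = exp(5:9), seed = 1) {
  sp <- crown_fold_splits(dataset, folds)
  k <- attr(folds, "k")
  grid <- expand.grid(gamma = gamma, cost = cost)
  res <- cbind(grid, accuracy = NA_real_)
  for (g in seq_len(nrow(grid))) {
    truth <- integer(0); pred <- integer(0)
    for (i in seq_len(k)) {
      tb <- train_tiebreaker(subset_pixels(dataset, sp[[i]]$train),
                             params = detector_params(grid$gamma[g],
                                                      grid$cost[g]),
                             seed = derive_seed(seed, paste0("tb", i)))
      truth <- c(truth, dataset$species[sp[[i]]$test])
      pred <- c(pred, predict(tb, dataset$x[sp[[i]]$test, , drop = FALSE]))
    }
    res$accuracy[g] <- mean(pred == truth)
  }
  b <- order_best(res, "accuracy")
  structure(list(results = res,
                 best_params = detector_params(res$gamma[b], res$cost[b]),
                 criterion = "accuracy", mode = "tiebreaker", folds = folds),
            class = "svm_tuning")
}
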