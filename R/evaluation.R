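# Evaluation protocols: detector comparison, producer's accuracy by
# crown-level CV, map bookkeeping, object validation against ground truth,
# and the training-amount/balance sweep.

# Pooled crown-level CV of a binary detector at fixed params.
pooled_binary_cv <- function(focal, outliers, folds, params) {
  sp_f <- crown_fold_splits(focal, folds)
  sp_o <- crown_fold_splits(outliers, folds)
  truth <- logical(0); pred <- logical(0)
  for (i in seq_len(attr(folds, "k"))) {
    det <- species_detector(focal$x[sp_f[[i]]$train, , drop = FALSE],
                            outliers$x[sp_o[[i]]$train, , drop = FALSE],
                            params, mode = "binary")
    xt <- rbind(focal$x[sp_f[[i]]$test, , drop = FALSE],
                outliers$x[sp_o[[i]]$test, , drop = FALSE])
    truth <- c(truth, rep(c(TRUE, FALSE), c(length(sp_f[[i]]$test),
                                            length(sp_o[[i]]$test))))
    pred <- c(pred, predict(det, xt))
  }
  binary_metrics(truth, pred)
}

#' Compare binary and biased detectors by repeated crown holdout
#'
#' Per repetition, one fifth of both the focal and the outlier crowns are
#' removed to form the test set (the same crown assignments are used for
#' both methods). The binary detector trains on the remaining focal +
#' outlier crowns; the biased detector trains on the remaining focal crowns
#' plus a 4/5 subsample of the pseudo-outlier pool (32,000 of the default
#' 40,000). Sensitivity is measured on the held-out focal pixels and
#' specificity on the held-out outlier-crown pixels — for the biased model
#' too, even though outlier crowns play no part in its training.
#'
#' @param focal `pixel_dataset` of focal-species crown pixels (one species).
#' @param outliers `pixel_dataset` of labeled outlier crown pixels.
#' @param pseudo `pixel_dataset` pseudo-outlier pool.
#' @param params_binary,params_biased tuned [detector_params()] per method.
#' @param reps repetitions (default 100).
#' @param seed RNG seed.
#' @return object of class `comparison_report`: `per_rep` data.frame
#'   (rep, method, sensitivity, specificity) and `summary` of means/sds.
#' @export
compare_binary_biased <- function(focal, outliers, pseudo,
                                  params_binary, params_biased,
                                  reps = 100, seed = 1) {
  cf <- crown_summary(focal); co <- crown_summary(outliers)
  n_pseudo_train <- floor(0.8 * n_pixels(pseudo))
  rows <- vector("list", 2 * reps)
  with_seed(derive_seed(seed, "compare"), {
    for (rep in seq_len(reps)) {
      test_f <- sample(cf$crown_id, max(1, round(nrow(cf) / 5)))
      test_o <- sample(co$crown_id, max(1, round(nrow(co) / 5)))
      tr_f <- !(focal$crown_id %in% test_f); te_f <- !tr_f
      tr_o <- !(outliers$crown_id %in% test_o); te_o <- !tr_o
      assert_no_leak(setdiff(cf$crown_id, test_f), test_f)
      ps <- sample(n_pixels(pseudo), n_pseudo_train)

      bin <- species_detector(focal$x[tr_f, , drop = FALSE],
                              outliers$x[tr_o, , drop = FALSE],
                              params_binary, mode = "binary")
      bia <- species_detector(focal$x[tr_f, , drop = FALSE],
                              pseudo$x[ps, , drop = FALSE],
                              params_biased, mode = "biased")
      for (m in c("binary", "biased")) {
        det <- if (m == "binary") bin else bia
        rows[[2 * (rep - 1) + (m == "biased") + 1]] <- data.frame(
          rep = rep, method = m,
          sensitivity = mean(predict(det, focal$x[te_f, , drop = FALSE])),
          specificity = mean(!predict(det, outliers$x[te_o, , drop = FALSE])))
      }
    }
  })
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$method), function(d)
    data.frame(method = d$method[1],
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = stats::sd(d$sensitivity),
               mean_specificity = mean(d$specificity),
               sd_specificity = stats::sd(d$specificity))))
  structure(list(per_rep = per_rep, summary = summ, reps = reps),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d repetitions\n", x$reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Producer's accuracy of the multi-species model by crown-level CV
#'
#' Five-fold crown-level cross-validation of the full fusion pipeline: per
#' fold, one biased detector per focal species plus the balanced tie-breaker
#' are trained on the in-fold focal crowns (against the full pseudo-outlier
#' pool) and the held-out focal pixels are labeled through the combination
#' rules. Producer's accuracy per species is the fraction of its held-out
#' pixels that receive the correct species label, pooled over folds.
#'
#' @param dataset `pixel_dataset` containing the focal crown pixels (other
#'   species, if present, are ignored).
#' @param pseudo pseudo-outlier `pixel_dataset`.
#' @param focal_species integer codes of the focal species (default: all
#'   positive species in `dataset`).
#' @param params_list biased [detector_params()] per species (recycled).
#' @param tiebreaker_params params for the tie-breaking SVM.
#' @param k folds; each focal species needs at least `k` crowns.
#' @param seed RNG seed (folds and balancing).
#' @param restrict restrict tie-breaking to flagged classes.
#' @return object of class `cv_report`: `producer_accuracy` (named, per
#'   species), pooled `confusion` matrix (truth x assigned label), and the
#'   fold assignment.
#' @export
multi_species_cv <- function(dataset, pseudo, focal_species = NULL,
                             params_list = list(detector_params(weight = 0.4)),
                             tiebreaker_params = detector_params(),
                             k = 5, seed = 1, restrict = FALSE) {
  if (is.null(focal_species))
    focal_species <- sort(unique(dataset$species[dataset$species > 0]))
  ds <- subset_pixels(dataset, dataset$species %in% focal_species)
  cs <- crown_summary(ds)
  folds <- crown_folds(cs, k = k, seed = seed, strata = cs$species_id)
  sp <- crown_fold_splits(ds, folds)
  if (length(params_list) == 1L)
    params_list <- rep(params_list, length(focal_species))
  truth <- integer(0); assigned <- integer(0)
  for (i in seq_len(k)) {
    train <- subset_pixels(ds, sp[[i]]$train)
    model <- fit_multispecies(train, pseudo, params_list, tiebreaker_params,
                              restrict = restrict,
                              seed = derive_seed(seed, paste0("cvfit", i)))
    pred <- predict(model, ds$x[sp[[i]]$test, , drop = FALSE])
    truth <- c(truth, ds$species[sp[[i]]$test])
    assigned <- c(assigned, as.integer(pred))
  }
  confusion <- table(truth = factor(truth, levels = focal_species),
                     assigned = factor(assigned, levels = c(0, focal_species)))
  acc <- vapply(focal_species, function(s)
    mean(assigned[truth == s] == s), numeric(1))
  structure(list(producer_accuracy = stats::setNames(acc, focal_species),
                 confusion = confusion, k = k, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold crown-level CV\n", x$k))
  cat("producer's accuracy (%):",
      paste(sprintf("%s: %.1f", names(x$producer_accuracy),
                    100 * x$producer_accuracy), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize the effect of contextual filtering on a species map
#'
#' Per species: fraction of vegetation pixels assigned before filtering, the
#' percent reduction in assigned pixels and in connected components
#' (side-adjacent, pre-filter components vs retained crown objects), and the
#' final object count.
#'
#' @param before,after integer label matrices pre/post
#'   [apply_contextual_filter()].
#' @param objects `crown_object_table` from [extract_objects()] on `after`.
#' @param mask logical vegetation mask (denominator for assigned fractions).
#' @return data.frame, one row per species.
#' @export
map_summary <- function(before, after, objects, mask) {
  stopifnot(all(dim(before) == dim(after)))
  species <- sort(unique(before[before > 0]))
  n_veg <- sum(mask)
  comp_before <- count_components(before)
  out <- lapply(species, function(s) {
    nb <- sum(before == s); na <- sum(after == s)
    ob <- unname(comp_before[as.character(s)])
    oa <- sum(objects$species_id == s)
    data.frame(species_id = s,
               assigned_fraction_pct = 100 * nb / max(n_veg, 1),
               pixels_before = nb, pixels_after = na,
               pixel_reduction_pct = if (nb > 0) 100 * (1 - na / nb) else 0,
               objects_before = ob, objects_final = oa,
               object_reduction_pct = if (ob > 0) 100 * (1 - oa / ob) else 0)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(species_id = integer(0), assigned_fraction_pct = numeric(0),
               pixels_before = integer(0), pixels_after = integer(0),
               pixel_reduction_pct = numeric(0), objects_before = numeric(0),
               objects_final = integer(0), object_reduction_pct = numeric(0))
}

#' Validate predicted crown objects against ground truth
#'
#' An object is correct iff the plurality truth species over its pixels
#' matches its predicted species, where each truth crown is first dilated by
#' `dilate` pixels (3 x 3 kernel per step) to absorb the one-pixel growth
#' the closing step can add; an object overlapping no (dilated) truth crown
#' is a false positive over background. The false-positive rate per species
#' counts every incorrect object, mirroring a field check of mapped crowns.
#' As a supplementary truth-only statistic the report also gives the
#' fraction of truth focal crowns covered by at least one correct object
#' (object-level detection rate, unmeasurable in a field campaign).
#'
#' @param objects output of [extract_objects()] (the full list: raster +
#'   table).
#' @param truth a `crown_map` with species ground truth.
#' @param dilate dilation steps applied to the truth crowns (default 1).
#' @return object of class `validation_report`: a data.frame per focal
#'   species with `n_objects`, `n_false_positive`, `false_positive_pct`,
#'   `crown_detection_pct`.
#' @export
validate_objects <- function(objects, truth, dilate = 1) {
  stopifnot(inherits(truth, "crown_map"))
  tab <- objects$table
  obj_raster <- objects$object_raster
  truth_sp <- crown_species_raster(truth)
  sp_all <- sort(unique(truth_sp[truth_sp > 0]))
  brush <- EBImage::makeBrush(3, "box")
  dil <- lapply(sp_all, function(s) {
    m <- (truth_sp == s) * 1
    for (i in seq_len(dilate)) m <- EBImage::dilate(m, brush)
    m > 0
  })
  names(dil) <- sp_all
  correct <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    px <- which(obj_raster == tab$object_id[i])
    counts <- vapply(dil, function(m) sum(m[px]), numeric(1))
    correct[i] <- any(counts > 0) &&
      sp_all[which.max(counts)] == tab$species_id[i]
  }
  species <- sort(unique(tab$species_id))
  per_sp <- lapply(species, function(s) {
    sel <- tab$species_id == s
    n <- sum(sel); nfp <- sum(sel & !correct)
    # truth crowns of s covered by a correct object of s
    crowns_s <- truth$crown_table$crown_id[truth$crown_table$species_id == s]
    ok_obj <- tab$object_id[sel & correct]
    detected <- vapply(crowns_s, function(id)
      any(obj_raster[truth$crown_id_raster == id] %in% ok_obj), logical(1))
    data.frame(species_id = s, n_objects = n, n_false_positive = nfp,
               false_positive_pct = if (n > 0) 100 * nfp / n else 0,
               crown_detection_pct = if (length(crowns_s))
                 100 * mean(detected) else NA_real_)
  })
  rep <- if (length(per_sp)) do.call(rbind, per_sp) else
    data.frame(species_id = integer(0), n_objects = integer(0),
               n_false_positive = integer(0), false_positive_pct = numeric(0),
               crown_detection_pct = numeric(0))
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Training-amount and class-balance sweep for the binary detector
#'
#' For each combination of focal crown count `n_f` and outlier crown count
#' `n_o`, subsamples the crowns, runs crown-level k-fold CV at fixed
#' parameters and records the pooled F-score. With `n_f` and `n_o` equal to
#' the full crown counts the result coincides with a plain CV of the full
#' dataset under the same fold seed.
#'
#' @param focal,outliers `pixel_dataset`s of crown pixels.
#' @param n_f_list,n_o_list crown counts to sweep; must not exceed the
#'   available crowns.
#' @param params a [detector_params()].
#' @param k folds.
#' @param seed RNG seed (subsampling and folds).
#' @return data.frame grid with columns `n_f`, `n_o`, `f_score`,
#'   `precision`, `recall`.
#' @export
balance_sweep <- function(focal, outliers, n_f_list, n_o_list,
                          params = detector_params(), k = 5, seed = 1) {
  cf <- crown_summary(focal); co <- crown_summary(outliers)
  if (max(n_f_list) > nrow(cf) || max(n_o_list) > nrow(co))
    stop(sprintf("requested crown counts exceed available (%d focal, %d outlier)",
                 nrow(cf), nrow(co)), call. = FALSE)
  grid <- expand.grid(n_f = n_f_list, n_o = n_o_list)
  out <- cbind(grid, f_score = NA_real_, precision = NA_real_,
               recall = NA_real_)
  for (g in seq_len(nrow(grid))) {
    sub <- with_seed(derive_seed(seed, paste0("sweep", g)), list(
      f = sample(cf$crown_id, grid$n_f[g]),
      o = sample(co$crown_id, grid$n_o[g])))
    fsub <- subset_pixels(focal, focal$crown_id %in% sub$f)
    osub <- subset_pixels(outliers, outliers$crown_id %in% sub$o)
    cs <- rbind(crown_summary(fsub), crown_summary(osub))
    folds <- crown_folds(cs, k = k, seed = seed,
                         strata = rep(c("focal", "outlier"),
                                      c(grid$n_f[g], grid$n_o[g])))
    m <- pooled_binary_cv(fsub, osub, folds, params)
    out$f_score[g] <- m$f_score
    out$precision[g] <- m$precision
    out$recall[g] <- m$recall
  }
  out
}
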