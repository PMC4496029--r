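# Single-species margin classifiers: one-against-all binary SVM and biased
# (positive-unlabeled) SVM. Both are soft-margin RBF-kernel SVMs; the biased
# variant penalizes errors on the unlabeled pseudo-outlier class by
# weight * cost instead of cost, reflecting that the unlabeled pool contains
# focal-class samples. Spectra are fed as raw reflectance fractions (already
# on a commensurate scale); no standardization is applied.

#' Detector hyper-parameters
#'
#' @param gamma RBF kernel width parameter, > 0.
#' @param cost misclassification penalty C, > 0.
#' @param weight relative penalty `w_c` in `(0, 1]` for errors on the
#'   pseudo-outlier class; required by (and only meaningful for) biased mode.
#' @return object of class `detector_params`.
#' @export
detector_params <- function(gamma = exp(-5), cost = exp(8), weight = NULL) {
  stop_if_not_scalar_number(gamma, "gamma", lower = 1e-300)
  stop_if_not_scalar_number(cost, "cost", lower = 1e-300)
  if (!is.null(weight))
    stop_if_not_scalar_number(weight, "weight", lower = 1e-12, upper = 1)
  structure(list(gamma = gamma, cost = cost, weight = weight),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf("<detector_params> log(gamma) = %.2f, log(C) = %.2f%s\n",
              log(x$gamma), log(x$cost),
              if (is.null(x$weight)) "" else sprintf(", w_c = %.2f", x$weight)))
  invisible(x)
}

#' Fit a single-species detector
#'
#' Fits a soft-margin RBF-kernel SVM contrasting focal-class spectra against
#' a contrast class: in `"binary"` mode the contrast class is labeled
#' outlier-species data and errors in both classes cost `C`; in `"biased"`
#' mode the contrast class is unlabeled pseudo-outlier spectra and its errors
#' cost `weight * C` (with `weight = 1` the two modes coincide). Prediction
#' is the sign of the decision function.
#'
#' @param x_focal numeric matrix of focal-class spectra (rows).
#' @param x_contrast numeric matrix of contrast-class spectra.
#' @param params a [detector_params()]; biased mode requires `weight`.
#' @param mode `"binary"` or `"biased"`.
#' @return object of class `species_detector`.
#' @seealso [tune_binary()], [tune_biased()]
#' @export
species_detector <- function(x_focal, x_contrast,
                             params = detector_params(),
                             mode = c("biased", "binary")) {
  mode <- match.arg(mode)
  x_focal <- as.matrix(x_focal); x_contrast <- as.matrix(x_contrast)
  if (nrow(x_focal) == 0L || nrow(x_contrast) == 0L)
    stop("both the focal and contrast class need at least one sample",
         call. = FALSE)
  if (mode == "biased" && is.null(params$weight))
    stop("biased mode requires 'weight' (w_c) in detector_params",
         call. = FALSE)
  y <- factor(c(rep("focal", nrow(x_focal)), rep("outlier", nrow(x_contrast))),
              levels = c("focal", "outlier"))
  cw <- if (mode == "biased") c(focal = 1, outlier = params$weight) else NULL
  fit <- e1071::svm(rbind(x_focal, x_contrast), y, type = "C-classification",
                    kernel = "radial", gamma = params$gamma,
                    cost = params$cost, class.weights = cw, scale = FALSE)
  structure(list(svm = fit, params = params, mode = mode,
                 n_focal = nrow(x_focal), n_contrast = nrow(x_contrast)),
            class = "species_detector")
}

#' @export
print.species_detector <- function(x, ...) {
  cat(sprintf("<species_detector> %s SVM, %d focal + %d contrast samples, %d SVs\n",
              x$mode, x$n_focal, x$n_contrast, x$svm$tot.nSV))
  print(x$params)
  invisible(x)
}

#' Predict focal-class membership
#'
#' @param object a `species_detector`.
#' @param newdata numeric matrix of spectra.
#' @param ... unused.
#' @return logical vector: `TRUE` where the pixel is assigned to the focal
#'   class.
#' @export
predict.species_detector <- function(object, newdata, ...) {
  unname(stats::predict(object$svm, as.matrix(newdata)) == "focal")
}

#' Sample pseudo-outlier pixels from a scene
#'
#' Uniform sample without replacement of vegetation pixels from a cube; the
#' resulting dataset has species label 0 (unknown identity) and no crown id,
#' matching the positive-unlabeled training protocol in which the contrast
#' class is drawn from the whole image.
#'
#' @param cube a `reflectance_cube`.
#' @param mask logical vegetation mask.
#' @param n sample size (default 40000); must not exceed the number of
#'   masked-in pixels.
#' @param seed RNG seed.
#' @return a `pixel_dataset` with `species = 0`.
#' @export
sample_pseudo_outliers <- function(cube, mask, n = 40000, seed = 1) {
  stopifnot(inherits(cube, "reflectance_cube"), is.logical(mask))
  avail <- which(mask)
  if (n > length(avail))
    stop(sprintf("requested %d pseudo-outliers but only %d vegetation pixels",
                 n, length(avail)), call. = FALSE)
  idx <- if (n == 0) integer(0) else
    with_seed(derive_seed(seed, "pseudo"), sample(avail, n))
  pixel_dataset(cube_matrix(cube)[idx, , drop = FALSE],
                rep(NA_integer_, n), rep(0L, n), cube$grid)
}
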