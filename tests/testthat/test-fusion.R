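# Three well-separated 2-D Gaussian classes for tie-breaker mechanics.
blob_dataset <- function(n = 60, seed = 5) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- do.call(rbind, lapply(1:3, function(s)
    cbind(rnorm(n, centers[s, 1]), rnorm(n, centers[s, 2]))))
  g <- build_band_grid(c(500, 600), 100, exclusions = list(),
                       keep_nm = c(0, Inf))  # 2 retained bands
  pixel_dataset(x, rep(1:9, each = n / 3), rep(1:3, each = n), g)
}

fx_blob_tb <- function() fixture("blob_tb",
  train_tiebreaker(blob_dataset(), detector_params(gamma = 0.5, cost = 10)))

test_that("class balancing subsets every species to the smallest class", {
  g <- build_band_grid(c(500, 600), 100, exclusions = list(), keep_nm = c(0, Inf))
  sizes <- c(10726L, 3325L, 2091L)
  ds <- pixel_dataset(matrix(runif(sum(sizes) * 2), ncol = 2),
                      rep(1:3, sizes), rep(1:3, sizes), g)
  bal <- balance_classes(ds, seed = 1)
  expect_equal(unname(c(table(bal$species))), rep(2091L, 3))
  expect_identical(balance_classes(ds, seed = 1)$x, bal$x)   # deterministic
  expect_false(identical(balance_classes(ds, seed = 2)$x, bal$x))
})

test_that("the tie-breaker separates balanced separable classes", {
  tb <- fx_blob_tb()
  fresh <- blob_dataset(seed = 99)
  expect_gte(mean(predict(tb, fresh$x) == fresh$species), 0.95)
  expect_error(train_tiebreaker(subset_pixels_(blob_dataset(),
                                               blob_dataset()$species == 1)),
               "at least two")
})

test_that("combination rules (i)-(iii) are exhaustive, exclusive and correct", {
  tb <- fx_blob_tb()
  x <- blob_dataset(seed = 100)$x
  # all 8 flag patterns over 3 detectors hit exactly one rule
  patterns <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE),
                                    c(FALSE, TRUE)))
  rule_of <- function(nf) if (nf == 0) "i" else if (nf == 1) "ii" else "iii"
  for (p in seq_len(nrow(patterns))) {
    n_hit <- sum(patterns[p, ])
    rules_hit <- c(n_hit == 0, n_hit == 1, n_hit >= 2)
    expect_equal(sum(rules_hit), 1L)
    out <- combine_flags(patterns[p, , drop = FALSE], tb, x[p, , drop = FALSE])
    if (rule_of(n_hit) == "i") expect_equal(out, 0L)
    if (rule_of(n_hit) == "ii") expect_equal(out, unname(which(patterns[p, ])))
    if (rule_of(n_hit) == "iii") expect_true(out %in% 1:3)
  }
})

test_that("restricted tie-breaking only picks flagged classes", {
  tb <- fx_blob_tb()
  x <- blob_dataset(seed = 42)$x[1:20, , drop = FALSE]  # class-1 points
  flags <- matrix(c(FALSE, TRUE, TRUE), 20, 3, byrow = TRUE)
  out <- combine_flags(flags, tb, x, restrict = TRUE)
  expect_true(all(out %in% 2:3))  # class 1 not flagged, cannot be chosen
})

test_that("a single-detector model degenerates to that detector's flags", {
  set.seed(6)
  a <- matrix(rnorm(40, 0), 20); b <- matrix(rnorm(40, 5), 20)
  det <- species_detector(a, b, detector_params(gamma = 0.5, cost = 10),
                          "binary")
  m <- multispecies_svm(list(det))
  pred <- predict(m, rbind(a, b))
  expect_equal(as.integer(pred), as.integer(predict(det, rbind(a, b))))
})

test_that("image classification respects the mask, the label set and the tie-break identity", {
  sc <- fx_scene()
  ds <- fx_dataset()
  model <- fit_multispecies(
    subset_pixels_(ds, ds$species %in% 1:2), fx_pseudo(),
    list(detector_params(weight = 0.4)), detector_params(), seed = 1)
  # all-masked-out scene -> all-zero raster
  none <- matrix(FALSE, nrow(fx_mask()), ncol(fx_mask()))
  expect_true(all(classify_image(sc$cube, none, model)$labels == 0L))
  # real mask: labels confined to {0..S}; tie-break identity holds
  m <- classify_image(sc$cube, fx_mask(), model)
  expect_true(all(m$labels %in% 0:2))
  expect_true(all(m$labels[!fx_mask()] == 0L))
  expect_equal(m$meta$frac_tiebreak,
               m$meta$frac_any_flag * m$meta$frac_multi_given_any)
  # band mismatch between cube and model training grid fails
  g2 <- build_band_grid(c(500, 600), 100, exclusions = list(), keep_nm = c(0, Inf))
  small <- reflectance_cube(array(0.3, c(4, 4, 2)), g2)
  expect_error(classify_image(small, matrix(TRUE, 4, 4), model),
               "training grid")
})
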