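# Detector-layer fixtures: species 1 of the small scene against the labeled
# background crowns (thinned to keep SVM grids fast) and the pseudo-outlier
# pool. Cached for reuse by the fold-integrity acceptance check.

test_that("f_score is the harmonic mean with the 0/0 convention", {
  expect_equal(f_score(1, 1), 1)
  expect_equal(f_score(0.5, 0.5), 0.5)
  expect_equal(f_score(0.9, 0.6), 0.72)
  expect_equal(f_score(0, 0), 0)
  expect_equal(f_score(0.3, 0.8), f_score(0.8, 0.3))
})

test_that("biased criterion rewards recall and parsimony", {
  expect_equal(biased_criterion(1, 1), 1)
  expect_equal(biased_criterion(0.9, 0.05), 16.2)
  expect_equal(biased_criterion(0, 0.3), 0)
  expect_equal(biased_criterion(0, 0), 0)
})

test_that("crown folds are stratified, deterministic and inherited by pixels", {
  tab <- data.frame(crown_id = 1:10, species_id = rep(1, 10))
  f <- crown_folds(tab, k = 5, seed = 4)
  expect_equal(as.integer(sort(table(f))), rep(2L, 5))
  expect_identical(f, crown_folds(tab, k = 5, seed = 4))
  expect_false(identical(f, crown_folds(tab, k = 5, seed = 5)))
  # stratified: per-class fold counts differ by at most one
  folds <- fx_binary_folds()
  cs <- rbind(crown_summary_(fx_focal1()), crown_summary_(fx_outcrowns()))
  for (s in unique(cs$species_id == 1)) {
    counts <- table(folds[as.character(cs$crown_id[(cs$species_id == 1) == s])])
    expect_lte(diff(range(counts)), 1)
  }
  # pixels inherit their crown's fold regardless of crown size
  ds <- fx_focal1()
  pf <- crowndetect:::pixel_folds(ds, folds)
  expect_true(all(tapply(pf, ds$crown_id, function(x) length(unique(x))) == 1))
  # a class with fewer crowns than folds errs, naming the class
  expect_error(crown_folds(data.frame(crown_id = 1:6, species_id = rep(1:2, 3)),
                           k = 5), "class '1'")
})

test_that("a detector separates distant Gaussian blobs perfectly on its training data", {
  set.seed(1)
  a <- matrix(rnorm(100, 0), 50)
  b <- matrix(rnorm(100, 6), 50)
  det <- species_detector(a, b, detector_params(gamma = 0.5, cost = 10),
                          mode = "binary")
  expect_true(all(predict(det, a)))
  expect_false(any(predict(det, b)))
  expect_identical(predict(det, b), predict(det, b))  # deterministic
})

test_that("biased mode with w_c = 1 reduces to the binary detector", {
  set.seed(2)
  a <- matrix(rnorm(60, 0), 30)
  b <- matrix(rnorm(160, 1.2), 80)
  q <- matrix(rnorm(80, 0.6), 40)
  p_bin <- detector_params(gamma = 0.3, cost = 5)
  p_bia <- detector_params(gamma = 0.3, cost = 5, weight = 1)
  expect_identical(
    predict(species_detector(a, b, p_bin, "binary"), q),
    predict(species_detector(a, b, p_bia, "biased"), q))
})

test_that("degenerate single-class input is refused", {
  x <- matrix(rnorm(10), 5)
  expect_error(species_detector(x, x[0, , drop = FALSE]), "at least one sample")
  expect_error(species_detector(x, x, detector_params(), "biased"), "weight")
})

test_that("pseudo-outlier sampling is exact, deterministic and bounded", {
  sc <- fx_scene()
  mask <- fx_mask()
  ps <- sample_pseudo_outliers(sc$cube, mask, n = 200, seed = 9)
  expect_equal(n_pixels(ps), 200L)
  expect_true(all(ps$species == 0L))
  expect_identical(ps$x, sample_pseudo_outliers(sc$cube, mask, 200, 9)$x)
  expect_equal(n_pixels(sample_pseudo_outliers(sc$cube, mask, 0, 1)), 0L)
  expect_error(sample_pseudo_outliers(sc$cube, mask, sum(mask) + 1, 1),
               "only")
})

test_that("binary tuning searches the full 7 x 11 grid and breaks ties toward simpler models", {
  tb <- fx_tuned_binary()
  expect_equal(nrow(tb$results), 77L)
  expect_gte(max(tb$results$f_score), 0.95)  # separable synthetic data
  # independent re-derivation of the argmax + tie rule
  r <- tb$results
  best <- r[order(-r$f_score, r$cost, r$gamma), ][1, ]
  expect_equal(tb$best_params$gamma, best$gamma)
  expect_equal(tb$best_params$cost, best$cost)
})

test_that("biased tuning runs a 64-point coarse pass, then brackets the optimum", {
  tb <- fx_tuned_biased()
  expect_equal(sum(tb$results$pass == "coarse"), 64L)
  expect_true(all(tb$results$pass %in% c("coarse", "fine")))
  # the fine pass stays within one grid step of the coarse optimum
  r <- tb$results
  cb <- r[r$pass == "coarse", ]
  cb <- cb[order(-cb$criterion, cb$cost, cb$gamma, cb$weight), ][1, ]
  fine <- r[r$pass == "fine", ]
  if (nrow(fine)) {
    expect_true(all(abs(log(fine$gamma) - log(cb$gamma)) <= 1 + 1e-9))
    expect_true(all(abs(log(fine$cost) - log(cb$cost)) <= 1 + 1e-9))
    expect_true(all(abs(fine$weight - cb$weight) <= 0.1 + 1e-9))
  }
  # held-out recall high and assignment parsimonious on separable data
  b <- r[order(-r$criterion, r$cost, r$gamma, r$weight), ][1, ]
  prevalence <- n_pixels(fx_focal1()) /
    (n_pixels(fx_focal1()) + n_pixels(fx_pseudo()))
  expect_gte(b$recall, 0.9)
  expect_lte(b$assign_fraction, prevalence + 0.05)
})

test_that("tuning criteria vary monotonically as the metric identities demand", {
  # biased_criterion strictly increases in r, strictly decreases in P
  r <- seq(0.1, 1, length.out = 20)
  expect_true(all(diff(biased_criterion(r, 0.3)) > 0))
  p <- seq(0.05, 1, length.out = 20)
  expect_true(all(diff(biased_criterion(0.7, p)) < 0))
})
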