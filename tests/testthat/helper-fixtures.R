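# Shared fixtures (built lazily, cached for the whole run) and the
# independent brute-force morphology oracle.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# Full-resolution spectrometer grid (206 bands, 159 retained).
fx_grid <- function() fixture("grid", build_band_grid())

# Small, cleanly separable scene config: 2 focal + 10 background species.
fx_config <- function() fixture("config", scene_config(
  height = 90, width = 90, n_focal_species = 2, crowns_per_focal = 6,
  n_background_species = 10, crowns_per_background = 3,
  separability = 2.5, seed = 7))

fx_library <- function() fixture("library",
  make_spectral_library(fx_config(), fx_grid()))

fx_scene <- function() fixture("scene", generate_scene(fx_config(), fx_library()))

fx_mask <- function() fixture("mask", vegetation_mask(fx_scene()$cube))

fx_dataset <- function() fixture("dataset",
  generate_crown_dataset(fx_config(), fx_library()))

fx_pseudo <- function() fixture("pseudo",
  sample_pseudo_outliers(fx_scene()$cube, fx_mask(), n = 500, seed = 11))

# Internal helpers reached for repeatedly in tests.
crown_summary_ <- crowndetect:::crown_summary
subset_pixels_ <- crowndetect:::subset_pixels

# Thin a dataset to the first n pixels of every crown (keeps SVM grids fast).
first_n_per_crown <- function(ds, n) {
  keep <- unlist(lapply(split(seq_along(ds$crown_id), ds$crown_id),
                        utils::head, n))
  subset_pixels_(ds, sort(keep))
}

# Detector-layer fixtures shared across test files: species 1 of the small
# scene against the labeled background crowns (thinned) and the pseudo pool.
fx_focal1 <- function() fixture("focal1", {
  ds <- fx_dataset()
  first_n_per_crown(subset_pixels_(ds, ds$species == 1), 12)
})

fx_outcrowns <- function() fixture("outcrowns", {
  ds <- fx_dataset()
  first_n_per_crown(subset_pixels_(ds, ds$species > 2), 8)
})

fx_binary_folds <- function() fixture("binary_folds", {
  cs <- rbind(crown_summary_(fx_focal1()), crown_summary_(fx_outcrowns()))
  crown_folds(cs, k = 5, seed = 1,
              strata = ifelse(cs$species_id == 1, "focal", "outlier"))
})

fx_tuned_binary <- function() fixture("tuned_binary",
  tune_binary(fx_focal1(), fx_outcrowns(), fx_binary_folds()))

fx_focal_folds <- function() fixture("focal_folds", {
  cs <- crown_summary_(fx_focal1())
  crown_folds(cs, k = 5, seed = 2, strata = rep("focal", nrow(cs)))
})

fx_tuned_biased <- function() fixture("tuned_biased",
  tune_biased(fx_focal1(), fx_pseudo(), fx_focal_folds(), seed = 3))

# ---- brute-force morphology oracle (independent of the implementation) ----

# Shift with background (FALSE) fill.
bf_shift <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

bf_erode3 <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out & bf_shift(m, dr, dc)
  out
}

bf_dilate3 <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out | bf_shift(m, dr, dc)
  out
}

bf_open_close <- function(m) {
  m <- m != 0
  bf_erode3(bf_dilate3(bf_dilate3(bf_erode3(m))))
}
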