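---
title: "Methods: single-species detection and crown-object mapping"
author: "crowndetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-species detection and crown-object mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mapping individual canopy trees of a few focal species across a diverse,
closed-canopy tropical forest is hard for two reasons. First, a conventional
multi-class classifier needs representative training spectra for *every*
species in the scene — hundreds of tree and liana species — which is
infeasible to collect. Second, individual tree crowns cannot be segmented
reliably from spectral data alone, so classification has to happen at the
pixel level, with crown-scale map units derived afterwards.

`crowndetect` implements an operational answer: single-species margin
classifiers that need training data only from the focal species (plus either
a modest labeled background sample or an unlabeled pixel sample), fused into
a multi-species pixel classifier, followed by morphological cleaning and
connected-component extraction of "crown objects". Because real airborne
imagery of this kind is not redistributable, the package ships a synthetic
hyperspectral forest-scene generator with known ground truth, so the whole
chain is testable end to end.

## Detectors

Both detectors are soft-margin SVMs with an RBF kernel acting on raw
reflectance fractions (spectra are already on a common `[0, 1]` scale; no
standardization is applied, and none is exposed as an option).

**One-against-all binary SVM.** The focal species' crown pixels are
contrasted with the pooled crown pixels of all other labeled species. Tuning
maximizes the pixel-level F-score on the focal class, `F = 2pr/(p + r)`,
over the grid `gamma ∈ {e^-12, …, e^-6} × C ∈ {e^5, …, e^15}` (77 points),
because with strongly imbalanced classes the F-score rewards jointly high
precision and recall where overall accuracy would not.

**Biased SVM.** A positive-unlabeled variant: the focal crown pixels are
contrasted with *pseudo-outliers* — vegetation pixels sampled uniformly from
the whole image (40,000 by default), which inevitably contain some focal
pixels. Errors on the unlabeled side are therefore penalized by `w_c · C`
with `w_c ∈ (0, 1]` instead of `C` (implemented as a class weight on the
cost; at `w_c = 1` the two modes coincide exactly, which the tests assert).
Without labeled negatives, precision is unavailable, so tuning maximizes
`r² / P[f(x) = 1]`: squared recall on held-out focal pixels divided by the
fraction of all held-out (focal + pseudo-outlier) pixels assigned to the
focal class. The criterion is large when recall is high and the assignment
is parsimonious. The grid is `gamma ∈ {e^-8, …, e^-2} × C ∈ {e^5, …, e^11} ×
w_c ∈ {0.1, …, 0.7}`, searched as a coarse pass over every other value
(4 × 4 × 4 = 64 points) followed by a fine pass one grid step around the
coarse optimum.

**Crown-level cross-validation.** All tuning and evaluation assigns whole
crowns — never pixels — to folds (stratified, shuffled under a seed, dealt
round-robin so per-stratum fold sizes differ by at most one). Pixels of one
crown are strongly correlated; splitting them across folds would leak and
inflate every criterion. Pseudo-outliers, which have no crown structure, are
split into five groups randomly by pixel. Fold disjointness is asserted at
run time inside every tuning loop.

Two pooling conventions were genuinely open: the criteria are computed from
held-out predictions *pooled across folds*, not averaged per fold, because
per-fold estimates are unstable for focal classes with few crowns; and ties
in the grid search go to the smallest `C`, then smallest `gamma`, then
smallest `w_c` — the least complex model. Both choices are fixed, documented
behavior.

## Fusion

One biased detector per focal species is refit on all of that species'
crowns against the full pseudo-outlier pool, and combined by three
exhaustive, exclusive rules: (i) no detector fires → background/outlier
(code 0); (ii) exactly one fires → that species; (iii) several fire → an
ordinary multiclass RBF SVM over the focal species decides. That
tie-breaker is trained on focal pixels only, with every class randomly
subset to the smallest class size so no species dominates. By default it
predicts over all focal classes (the protocol passes tied pixels to the
tie-breaker without restriction); `restrict = TRUE` confines its pairwise
votes to the classes actually flagged. Its `(gamma, C)` are tunable by the
same crown-level CV machinery with overall accuracy as the criterion — a
choice the original protocol leaves unstated.

## Preprocessing

The spectral axis is a uniform 10.4 nm grid from 380 to 2512 nm with the
water-absorption windows 1330–1460 and 1770–2022 nm excluded (closed
intervals: a band center on the boundary is excluded) and ends below 400 or
above 2422 nm trimmed, leaving 159 of 206 bands. Analysis is restricted to
well-lit leafy vegetation: NDVI ≥ 0.7 *and* mean reflectance over the
850–1050 nm window ≥ 0.21 (both inclusive). NDVI uses the nearest retained
bands to 650 nm (red) and 860 nm (NIR); the convention does not pin the
sensor bands, so both are configurable in `mask_config()`. Negative
reflectance (possible after atmospheric correction) is clipped to zero at
load with a reported count.

## Contextual filtering and crown objects

The raw pixel map contains salt-and-pepper noise. Per species,
independently: the binary occurrence raster is upsampled by cutting each
pixel into quarters, opened and then closed with a full 3 × 3 structuring
element (removing objects and filling holes up to one original pixel wide),
and aggregated back at the original resolution. Each morphological
primitive treats out-of-bounds as background on the raster's finite domain
— the convention is pinned by an exact brute-force oracle test. The
re-aggregation rule is not dictated by the protocol; the default is
majority-of-four with ties counted focal (approximately area-conserving),
with `unanimous` and `any` available. Pixels claimed by two or more species
after recombination (possible because closing grows each layer) are
resolved by the larger count of same-species 8-neighbors, remaining ties to
the lower species code; occurrences are counted and reported.

Crown objects are then side-adjacent (4-connected) components per species;
diagonal contact does not connect. Components under 10 pixels (at original
resolution) are eliminated. A crown object is a map unit, not a tree: it
may merge adjacent conspecific crowns or represent a liana-split fragment
of one crown, and the package does not attempt to resolve that.

## The synthetic scene generator

The generator emulates the statistical structure the analysis assumes, not
radiative transfer. Species mean spectra are smooth random modulations
(natural-spline interpolation of iid normal knot values every 160 nm,
exponentiated) of a canonical green-vegetation curve with the chlorophyll
trough near 670 nm, the NIR plateau and the shortwave water-feature
shoulders. Crown-level and pixel-level variation are lognormal with
relative scales `between_crown_sd = 0.06` and `within_crown_sd = 0.05`;
pixel noise is split into a brightness scalar, a smooth shape component and
a small white component, so variation is spectrally correlated and
low-dimensional, as in real imaging spectroscopy. White independent
per-band noise was rejected: in 159 dimensions it makes any configuration
trivially separable, and the difficulty dial below would be dead.

Crowns are random ellipses (semi-axes 2–4 px) placed by rejection sampling
without overlap; overlap handling is out of scope because training crowns
are modeled as pure. The canopy matrix between crowns is filled with
per-pixel draws from random background species. Shadow (dark, fails the
NIR test) and liana-like (low NDVI) contaminants overwrite 5% + 5% of
pixels, so the *filter*, not the classifier, removes them — matching the
filtering-first design. Pure crown pixels are guaranteed to pass the
vegetation filter: pixel noise is redrawn for the rare tail draws that
would fail it (truncated noise), mirroring a training protocol that keeps
only well-lit leafy crown pixels.

**Separability** is the generator's difficulty dial: every focal mean must
be at least `separability` away from every background mean, where distance
is the RMS over bands of the mean difference divided by the pooled
between+within standard deviation. Focal means are redrawn with growing
modulation amplitude until the floor is met, and the generator fails
explicitly if it cannot be. The quantitative within/between variance of
real crowns is not published, so the default was chosen once against a
stated difficulty target — detection hard but achievable, with a 5–15%
pixel overlap between focal species and the nearest background class under
nearest-mean classification. With the default noise scales that overlap is
roughly 50% at separability 0.6, 17% at 1.3 and 7% at 1.6; the default is
**1.5** (≈10% overlap). `nearest_mean_separability()` recomputes this
summary, and a test asserts it increases monotonically with the dial.

The default scene — the package's reference study conditions — is 260 × 260
pixels with 3 focal species × 44 crowns and 80 background species × 4
crowns, i.e. a focal class that is well represented by crowns while the
background is broad and shallow, as a field campaign sampling diversity
widely would produce. `reference_inventory()` additionally mirrors a real
campaign's bookkeeping exactly (50/44/44/322 crowns, 25,492 pixels) for
tests of the data plumbing.

What passing on these scenes does **not** show: robustness to BRDF and
illumination gradients, sensor noise structure, mis-registration, mixed
boundary pixels, or spectral phenology — none of which the generator
emulates. Results on synthetic scenes bound the method's behavior under its
own assumptions; they do not certify field performance.

## Problem sizes and numerical choices

The reference analyses run at desk scale, chosen so a full pipeline
(simulate → mask → CV → classify → filter → objects → validate) completes
in well under a minute on one CPU: a 4,000-pixel pseudo-outlier pool in the
pipeline defaults (the `sample_pseudo_outliers()` function default stays at
the protocol's 40,000), 20 repetitions in the script's binary-vs-biased
comparison (the function default stays 100), and fixed detector parameters
`gamma = e^-5`, `C = e^8`, `w_c = 0.4` (near the biased grid's center;
`gamma ≈ 1/d` for `d = 159` bands is the standard RBF scale) rather than a
re-tune on every run — `detector$tune = TRUE` switches the coarse/fine
search on. Other conventions: reflectance is a fraction (the 21% NIR
threshold is 0.21); NDVI is 0 where NIR + red = 0; the separability
rejection loop fails after 60 amplitude escalations; all RNG flows through
per-stage seeds derived from one master seed, so identical configs produce
byte-identical artifacts (asserted via MD5 digests in the tests).

## Known limitations

- Detector training is O(n²)-ish in pixels (kernel SVM); island-scale
  pseudo-outlier pools (40k) are supported but slow on one core.
- The 8-neighbor vote for cross-species filter conflicts and the
  majority-of-four re-aggregation are package conventions where the field
  protocol is silent; both are configurable and logged.
- Object-level *sensitivity* is computed against synthetic truth (reported
  as `crown_detection_pct`) — a quantity a field campaign cannot measure;
  it is supplementary output, not part of the field-style validation.
- No probabilistic outputs; labels only.
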