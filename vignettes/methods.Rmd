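---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Senescent cells arrest stably, remodel their chromatin and enlarge and
deform their nuclei. Because no single molecular marker is universal, a
practical alternative is to classify senescence from interpretable nuclear
shape descriptors measured at scale by high-content microscopy or
whole-slide scanners. `senomorph` implements that programme end to end:
feature extraction, tree/forest classifiers, well- and plate-level screen
analytics, and a per-cell/per-tissue scoring system for histology, with a
synthetic-data module standing in for microscopy data.

# Feature extraction

All geometry is computed on integer label masks. Coordinates are 0-based
pixel indices, centroids sit at pixel centres, and areas are pixel counts
times the squared pixel size (default 0.5 µm/pixel, the slide-analysis
convention).

Numerical choices that matter:

* **Perimeter** is measured on the Moore-traced boundary chain with the
  Vossepoel–Smeulders corrected step weights (0.948 per axial step, 1.340
  per diagonal step). Raw 1/√2 chain weights overestimate a circle's
  circumference by several percent, which would push the form factor of a
  disc visibly below 1; the corrected weights keep the error well under 1%
  for radii above ~10 px.
* **FormFactor / Circularity** is `4πA/P²`, the only standard "roundness"
  that equals 1 for a circle. Values marginally above 1 caused by the
  perimeter underestimate on small shapes are clamped to 1, matching the
  (0, 1] support declared for ratio features.
* **Axis-based features** (Elongation = minor/major, Eccentricity,
  axis lengths) come from the second-moment best-fit ellipse with the 1/12
  pixel-extent correction, so small rasterized ellipses recover their
  generating axes to ~1%.
* **Caliper (Feret) diameters** are measured on the convex hull of pixel
  centres by rotating calipers, plus 0.5 px for the pixel extent. The
  centre hull undercuts the analytic support by 0–1 px depending on
  orientation; +0.5 px is the balanced convention and keeps both max and
  min calipers within 5% of the closed form across axis ratios 1–0.25.
* **ChordRatio** is MinFeret/MaxFeret. The upstream vendor formula is not
  published; the Feret ratio is the standard reading of a "min/max chord"
  descriptor and is declared, not inferred.
* **GyrationRadius** is the RMS distance of member pixels from the
  centroid ("average radius of the shape" made precise: for a disc of
  radius r it is r/√2). **Compactness** is the arithmetic mean distance
  (2r/3 for a disc) — deliberately a different statistic so the two
  features are not duplicates.
* **Displacement** is the distance between the intensity-weighted and
  geometric centroids of the nucleus, normalized by the gyration radius.
  The vendor definition references a whole-cell centre of gravity, but the
  pipeline is nucleus-only; this proxy is computable from the same channel
  and is zero for symmetric shapes. Requesting it without an intensity
  image is an error rather than a silent zero.
* **ConvexArea / Solidity** use the discretized convex area (the number of
  bounding-box pixel centres inside the centre hull), so the solidity of a
  convex rasterized shape is ~1 by construction. A polygon-area hull
  (pixel corners) systematically inflates convex area by ~P/2 pixels and
  biases solidity low on thin shapes; this was measured and rejected.

QC filters mirror acquisition practice: objects whose bounding box touches
the image border are excluded (partially acquired nuclei), an
equivalent-diameter window (default 5–40 µm) drops debris and clumps, and
an optional minimum mean intensity drops under-stained objects. Filters
never fail; every exclusion is logged with a reason
(`edge`/`diameter`/`intensity`).

The segmentation path (global threshold, Otsu by default, plus 8-connected
components) exists to close the loop on synthetic images; it is explicitly
not a production nucleus segmenter (no watershed splitting, no stain
deconvolution).

# Classifiers

Two labelling policies build training sets. *Assumption* labelling takes
every treated cell as senescent and every control cell as normal — the
pragmatic choice when a senescence inducer converts the large majority of
a culture. *Marker* labelling first filters treated cells to
marker-positive and control cells to marker-negative; the default marker
rule for fluorescent SA-β-Gal substrates is "above the 95th percentile of
the pooled control cells", since absolute positivity cutoffs for such
stains are arbitrary and set against controls; an absolute threshold can
be supplied instead. The sampler draws exactly 10,000 cells per class by
default, without replacement, reproducibly under a seed; multi-condition
pools (a "general" classifier) are sampled equally per condition, with the
remainder assigned to the first conditions in order — the original
per-condition proportions are unpublished, so equal allocation is our
declared choice.

No tree package is assumed at run time, so the CART engine is implemented
here: Gini impurity, exhaustive split search with deterministic
tie-breaking (lowest feature index, then lowest threshold; rows with
x ≤ threshold go left), weakest-link cost-complexity pruning producing the
nested alpha sequence, and selection of the alpha maximizing accuracy on a
30% holdout (ties go to the larger alpha, i.e. the simpler tree). One
caveat worth knowing: the holdout accuracy stored in the model metadata is
the *selection* criterion, and on label-noise data the maximum over the
alpha grid is optimistically biased by a few points; the test suite
therefore checks the chance-level contract on fresh data, not on the
selection holdout.

The random forest is bagging over the same CART grower with per-split
feature sampling (mtry = ⌊√p⌋), 100 unpruned trees by default, and a 50%
holdout for performance estimation. The per-cell senescence probability is
the fraction of trees voting senescent, and a cell is called senescent
only when the probability *strictly* exceeds 0.5 — a cell exactly at the
cutoff is called normal. The same conservative convention resolves ties in
the equal-weight voting consensus (an even number of members voting 4–4
yields "normal"); the source procedure is silent on ties and we prefer
under-calling senescence to over-calling it. Forest size, depth and mtry
defaults are ours and are recorded in the model metadata.

# Metrics

Accuracy, precision, recall and F1 follow the standard confusion-matrix
definitions; the published F1 expression is typeset ambiguously and is
implemented as the harmonic mean `2PR/(P+R)`, which matches its limiting
behaviour. Ratios with zero denominators surface as flagged `NA`s, never
as silent zeros. AUC is the Mann–Whitney exceedance probability with half
credit for ties (so an all-tied score vector scores 0.5), making it
invariant under strictly monotone transforms. The two-sample
Kolmogorov–Smirnov D is the sup-norm ECDF distance, implemented directly
and checked against `stats::ks.test` as an independent oracle. Where
well-level metrics are aggregated, we compute metrics per well and then
take the median across wells (pooling order is unspecified upstream; this
choice is recorded here).

# Screen analytics

Toxicity is judged per plate and replicate: a drug well is excluded when
its cell count is strictly below 40% of the mean positive-control count of
its own plate. The reference could alternatively be screen-wide; per-plate
was chosen because viability drifts plate to plate and the positive
controls ride along with that drift.

The B-score is the canonical Tukey construction — the published analysis
delegates it to an external package without printing formulas, so we
implement the standard definition it computes: two-way median polish of
the plate matrix (row and column sweeps iterated to a relative tolerance
of 1e-8 or 20 sweeps by default), then `B = r / (1.4826 × median|r|)`.
Missing and toxicity-excluded wells are ignored by the medians and carry
no B-score (absent, not zero). A constant plate scores 0 everywhere by
convention. Note that the polish's residual row/column medians vanish only
at *convergence*; the 20-sweep default is a throughput compromise, and the
invariant tests run the polish to full convergence before asserting
medians ≈ 0. Control wells participate in the polish (they anchor row and
column effects) but are never hit-eligible.

A drug is a hit when strictly more than the threshold (B > 15) in at least
2 of its 3 replicates; replicates lost to toxicity count toward neither
side. Hits from two cell lines partition the shared library into
A-only / B-only / both / none selectivity classes.

# Tissue scoring

Marker status is called from DAB nuclear mean optical density with a
strict threshold (positive iff OD > 0.2). The ideal normal cell `P^N` is
the per-feature mean of all marker-negative cells; the ideal senescent
cell `P^S` is the mean of the top 100 marker-positive cells ranked by DAB
OD mean, descending, with ties broken by cell id so the derivation is
order-invariant. Ranking uses OD *mean* rather than total DAB (total
conflates intensity with size, which would leak the very features being
scored).

The per-cell score is
`CSS = Σᵢ wᵢ (pᵢ − P^Nᵢ)/(P^Sᵢ − P^Nᵢ)` with
`wᵢ = |P^Nᵢ/P^Sᵢ| / Σⱼ |P^Nⱼ/P^Sⱼ|`. This is the reading of the published
scoring operation that satisfies its own stated contract — CSS exactly 0
at the ideal normal vector and exactly 1 at the ideal senescent vector,
for *any* valid reference (property-tested over 1,000 random references).
The expression as printed composes an additional normalizer (the summed
absolute reference differences) with two divisions by the feature count;
that literal composition cannot meet the 0/1 endpoints and is kept behind
`cell_senescence_score(..., literal = TRUE)` for comparison only. CSS is
affine in each feature and unbounded in both directions: cells more
extreme than the senescent ideal score above 1.

The tissue senescence score is the percentage of cells with CSS inside
the closed window [1, 5] ("between 1 and 5" read inclusively; the window
is configurable because it was originally tuned over candidate ranges).
Two sample-level filters precede scoring: an opt-in hepatocyte filter
dropping cells with circularity ≤ 0.7 (applied to human samples, where
low-circularity nuclei are mostly stromal or immune), and exclusion of
samples with fewer than 10,000 surviving cells. Exclusion is a logged
outcome, not an error. A reference derived on one cohort is reusable
unchanged on any other (scoring is a pure function of the reference), and
references serialize to JSON.

Because roughly the upper half of the senescent CSS distribution falls
inside [1, 5] while normal cells sit near 0, TSS is a *monotone readout*
of senescent burden, not an unbiased estimate of the senescent fraction —
the invariant tests assert strict monotonicity across fractions
{0.02, 0.1, 0.3} and positive correlation with marker positivity, not
equality.

# The synthetic world

Every generator is a pure function of its spec and seed; a single global
seed expands into per-stage child seeds by a fixed affine map
(`(seed·48271 + stage offset) mod 2³¹−1`), so stages are independent of
call order.

*Masks* are rasterized ellipses whose polar radius is modulated by
harmonics 2–5 (`r(θ) = r_ellipse(θ)(1 + Σ c_k cos(kθ+φ_k))`). Normal
nuclei draw semi-major axes of 8–12 px and amplitudes up to 0.04;
senescent nuclei 14–20 px and up to 0.10 — larger and lumpier, which is
what the classifiers exploit. This is boundary plumbing with analytic
ground truth, not a chromatin model.

*Feature tables* draw each feature independently (optionally coupled by a
Gaussian copula) from distributions matched to its support: log-normal
for strictly positive quantities, logit-normal for (0, 1] ratios. The
source data's distributional forms are not published; these forms are our
choice, flagged as such. Default class parameters encode the documented
direction of effect — senescent nuclei roughly double in area (median 140
→ 260 µm² for the culture set; 55 → 110 µm² for the tissue set), gyration
radius and calipers grow ~40%, form factor/circularity and elongation
drop. A single `effect_scale` dial interpolates both location and scale
between the classes on the log/logit scale, so 0 gives literally
identical distributions (classifier AUC 0.5) and the dial supports the
monotone-recovery invariants. Class counts use round-half-even so tests
can assert them exactly.

*Screen plates* default to the published design scale: 676 drugs, 16×24
plates, biological triplicates, one positive- and one negative-control
column per plate. The null percent-senescent is N(5, 1.5²); positive
controls sit at 40%; additive row/column artifacts have sd 2 (what the
median polish exists to remove); spiked actives add +30 percentage points
— an effect size chosen once so that a genuine senescence inducer clears
B = 15 at the null noise level, mirroring a screen designed so real hits
clear its threshold; toxic drugs reduce counts to (1 − 0.7) of the
healthy mean of 1000. Spiked drug identities are drawn by seed so they
scatter across the layout (clustered spikes in one row would be partly
absorbed by the row polish — a real phenomenon, but not the null the
recovery invariant describes).

*Tissue tables* tie the hidden senescence status to DAB OD through two
overlapping log-normals (negatives median 0.07, positives median 0.45,
both sdlog 0.5), so ~2% of negatives exceed the 0.2 calling threshold and
~95% of positives do — the marker is good but imperfect, as in practice.

What a green test therefore establishes: the algorithms recover planted
structure of the stated kind and magnitude under clean, independent,
correctly supported marginals. What it does not establish: performance
under real microscope noise and PSF, segmentation errors, touching
nuclei, batch effects, feature correlations beyond the optional copula,
or biological heterogeneity of senescence programs.

# Known limitations

* The feature formalizations for the proprietary high-content descriptors
  (Compactness, ChordRatio, Displacement) are declared standard readings,
  not reverse-engineered vendor formulas.
* Trees collapsed to the root under the strict >0.5 rule call every cell
  normal on exactly balanced data; the unbiasedness invariant is
  therefore stated for the forest vote.
* The screen module models one readout per well; dose–response and
  within-well heterogeneity are out of scope.
* Reproducing any originally fitted classifier is impossible without the
  original training libraries; the package reproduces the *procedures*
  and verifies them against synthetic ground truth and closed forms.
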