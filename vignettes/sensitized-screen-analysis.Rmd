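---
title: "Analysing a sensitized RNAi spindle screen with spindlescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a sensitized RNAi spindle screen with spindlescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlescreen)
```

## The problem

A sensitized RNAi screen perturbs each library gene twice: once in an
unsensitized background (a non-silencing shRNA, `NS`) and once in a
background already compromised for the process under study — here a ch-TOG
(CKAP5) knockdown that destabilizes bipolar spindle assembly and raises the
baseline rate of multipolar spindles. Genes whose depletion suppresses or
enhances the multipolar phenotype specifically in the sensitized background
reveal genetic interactions with ch-TOG that are invisible in wild-type
cells.

The raw data are multichannel fluorescence fields per well of 384-well
plates: DNA (Hoechst), phospho-histone H3 (PHH3, marking mitotic
chromatin), RFP (co-expressed with the shRNA, filling the cytoplasm) and
α-tubulin (spindles and their poles). `spindlescreen` implements the full
path from these images to gene-level conclusions, plus a synthetic
generator so that every stage can be validated against known ground truth.

## Per-cell image analysis

`analyze_field()` composes the per-field stages:

1. **Nucleus segmentation** (`segment_nuclei()`): Otsu threshold on the DNA
   channel, removal of sub-nuclear specks, and a distance-map watershed to
   split touching nuclei. The number of segmented nuclei is the well's
   total cell number.
2. **Mitotic gating** (`classify_mitotic()`): a nucleus is mitotic iff its
   mean PHH3 exceeds a threshold (strict inequality). The default
   `"auto"` threshold is mean + 3 SD of the lower (interphase) mode of the
   per-nucleus PHH3 means, the two modes split by 2-means; it needs at
   least 10 nuclei and can always be overridden with a fixed value.
3. **Cytoplasm segmentation** (`segment_mitotic_cells()`): geodesic Voronoi
   propagation from each mitotic nucleus over RFP-positive pixels, giving
   disjoint masks; cells meeting the image border are flagged.
4. **Quality control** (`qc_filter()`), in order: edge cells out
   (incomplete segmentation); cells with isoperimetric roundness
   $4\pi A/P^2 < 0.8$ out (poor segmentation); cells with mean tubulin
   below 30 out (poles indistinguishable). The tubulin cut-off is defined
   on an 8-bit 0–255 intensity scale; the simulator's `eight_bit` flag
   produces that scale. All three thresholds use strict inequalities, and
   every mitotic cell carries exactly one exclusion reason.
5. **Spindle-pole detection** (`detect_spindle_poles()`), described below.
   Cells with more than two poles are multipolar; cells with zero detected
   poles are retained (contributing 0 to the mean pole count) because the
   screen excludes cells only on the three QC rules above.
6. **Multinucleate scoring** (`detect_multinucleate()`): mitotic nuclei are
   excluded first; interphase RFP bodies are segmented as connected
   components, bodies containing a mitotic nucleus or touching the border
   are dropped, and a body with two or more interphase nuclei is
   multinucleate. Component-based body segmentation (rather than seeded
   splitting) is deliberate: seeded propagation from the nuclei would cut a
   binucleate body into two mononucleate halves, defining the phenotype
   away.

### The spot detector

Commercial screening software scores "spots" with proprietary definitions;
this package uses an explicit, testable definition with the screen's
published operating point (relative spot intensity 0.095, splitting
coefficient 0.56) as defaults:

* smooth the tubulin channel with a Gaussian (default SD 1 px) inside the
  cell's bounding box;
* find 8-connected local maxima inside the mask; equal-valued plateaus
  collapse to one representative;
* keep maxima with relative spot intensity
  $r = (I_{peak}-bg)/(I_{max}-bg) > 0.095$, where $bg$ is the median
  smoothed intensity over the mask — $r$ is a ratio, so pole counts are
  invariant to any overall intensity gain;
* merge: walking candidates from brightest to dimmest, a candidate is
  absorbed by a brighter kept peak when the minimum smoothed intensity
  along the straight pixel path between them exceeds 0.56 × the
  candidate's own height — i.e. there is no valley deep enough to call
  them two poles. This one rule removes noise maxima on the flanks of real
  poles (the path to the peak never dips) while keeping genuinely separate
  poles (the inter-pole valley dips below the criterion).

The default smoothing of 1 px balances two failure modes: heavier
smoothing suppresses noise maxima but fuses neighbouring poles of
high-order multipolar cells (at 5–6 poles in a ~18 px cell, adjacent poles
sit only ~8–9 px apart); lighter smoothing resolves them while the merge
rule absorbs the extra noise maxima. On synthetic cells at the default
signal-to-noise ratio the detector recovers the exact pole count for ≥99%
of mitotic cells, and a brute-force re-evaluation of the definition above
(direct convolution, exhaustive neighbour checks) reproduces it exactly on
small patches.

## Per-well features and screen statistics

`summarize_well()` produces the five screen features: total cell number,
mitotic index, percentage of multipolar mitotic cells, mean poles per
mitotic cell (averaged over **all** QC-passed mitotic cells, not only
multipolar ones), and percentage of multinucleate interphase cells. Wells
with zero kept mitotic cells record missing mitotic features — missing, not
zero — and are dropped from affected gene scores with a warning.

`compute_zscores()` standardizes each feature per plate (one
background–replicate combination) against that plate's **library sample
wells** — controls are too few for a stable SD, and plate-wise
normalization cancels batch effects; a median/MAD variant is available
(`robust = TRUE`). Replicates are combined by averaging the per-plate Z
values (not by standardizing averaged raw values), and the differential
score is $dZ = Z_{NS} - Z_{chTOG}$: a large $|dZ|$ means the phenotype
changes between backgrounds, the signature of a genetic interaction with
ch-TOG.

`call_hits()` works on the raw percentage of multipolar cells, not Z
scores: a gene whose replicate-averaged value lies strictly beyond
±1.5 control-well SDs of the control-well mean is an enhancer or
suppressor. Two statistical properties are worth keeping in mind:

* comparing single-well-scale control dispersion with replicate-averaged
  gene values is conservative for genes: under pure per-well noise the
  expected null flag rate is $2\Phi(-1.5\sqrt{2}) \approx 3.4\%$ rather
  than the single-well $2\Phi(-1.5) \approx 13.4\%$;
* plate-common batch effects inflate the control SD while cancelling from
  the gene-minus-control difference, lowering the false-positive rate
  further — but with only two plates per background, how much protection
  this buys varies from screen to screen.

`replicate_correlation()` quantifies plate agreement with Spearman's rank
correlation (average ranks for ties; t-approximation p values, with a
permutation option for small plates). `summarize_hits()` and
`proportion()` provide the screen's headline arithmetic (e.g. 8 enhancers
of 240 genes = 3.3%).

### Genetic-interaction score

`interaction_score()` implements the multiplicative epistasis model: each
phenotype is normalized to the reference condition ($w_X = p_X/p_{ref}$,
control = 1), the expected double phenotype is $w_A w_B$, and
$\epsilon = w_{AB} - w_A w_B$. With severity defined as the percentage of
multipolar spindles, a double phenotype less severe than expected
($\epsilon < -\text{threshold}$, default 0.25) is alleviating and a more
severe one aggravating. Published interaction scores from screening
pipelines use undocumented normalizations and sign conventions, so the
convention here is explicit and switchable (`convention = "rescue"` flips
the labels for phenotypes where larger means rescued); numeric agreement
with any particular published score value is not claimed. The score is
invariant to rescaling all four phenotypes by a common factor.

## Clustering dZ profiles

`filter_genes()` keeps genes with $|Z_{chTOG}| > 1$ (strict) for the
multipolar percentage **or** the mean pole count — the two features that
define the spindle phenotype — and assembles their dZ values across all
five features. No rescaling is applied to the dZ matrix.

Source descriptions of the clustering disagree on the metric (city-block
in one place; "uncentred Pearson correlation" with a 0.7 cut in another).
Both are implemented; the default is **uncentred Pearson + complete
linkage** because only a correlation-like similarity makes a 0.7 cut
interpretable (distance = 1 − similarity, cut at distance ≤ 0.3);
city-block remains available, with the cut then a free distance parameter.
The uncentred form (no mean-centring) treats the all-zero profile — a gene
behaving identically in both backgrounds — as the natural origin.

`cluster_complete()` is a deterministic complete-linkage agglomerator:
ties are broken by the lowest original gene index, so the tree is
reproducible across platforms; it matches exhaustive brute-force
agglomeration exactly and `stats::hclust` heights on tie-free data.
`cut_clusters()` forms the maximal subtrees whose merge heights all lie at
or below the cut; raising the similarity cut only ever splits clusters
(monotonicity), and permuting gene order changes labels, never the
partition. `export_tree()` writes Cluster-3.0 CDT/GTR files (round-trip
tested) and a Newick tree via `ape`.

## The synthetic generator

Two levels, both returning exact ground truth.

**Field images** (`simulate_field()`): 2-D fields (the screen analysed
single-plane 20× images; no z-stacks) with four co-registered channels.
Interphase nuclei are Gaussian blobs inside RFP discs; mitotic chromatin is
brighter and more condensed, with PHH3 high only there; spindle poles are
isotropic 2 px Gaussian foci on a faint haze (8% of pole amplitude), the
simplest geometry that exercises merge/split behaviour. Optics are a
Gaussian blur; noise is Poisson on the signal followed by additive Gaussian
read noise, with defaults giving peak-to-background ≈ 10 — a bright,
well-stained screen. Intensities are 16-bit-like; `eight_bit` rescales to
0–255. Cell bodies overlapping beyond a tolerance are rejected because
their segmentation ground truth would be ill-defined. What the simulator
does **not** emulate — real textured chromatin, mitotic-stage morphology,
uneven illumination, debris, out-of-focus fields — bounds what passing
tests mean: they validate the algorithmic contract (segmentation topology,
QC logic, spot definitions, feature arithmetic), not robustness to every
real-world artefact.

**Well tables** (`simulate_screen_tables()`): for desk-scale statistical
experiments the per-well features are drawn directly. Cell counts are
Poisson; mitotic, multipolar and multinucleate cells are Binomial; pole
counts of multipolar cells are 3 + Poisson(mean − 3). Background defaults
mimic the screen's reported scale: ~1200 cells and mitotic index 0.03 in
`NS` wells (~36 mitotic cells), ~900 cells and mitotic index 0.30 in
`chTOG` wells (~270 mitotic cells, reflecting mitotic arrest), baseline
multipolar penetrance 0.05 (`NS`) vs 0.40 (`chTOG`). The per-well
penetrance adds two noise terms chosen once from the variance structure of
real screens: a per-well reagent/handling term (`well_noise_sd = 0.02` on
the fraction scale) and a per-plate staining/imaging batch shift shared by
every well of a plate (`plate_effect_sd = 0.035`) — batch effects of a few
percentage points are routine in fixed-and-stained plate pairs, and the
plate-common term is what makes control-based hit thresholds conservative
(see above). Emitted well features are computed exactly from the drawn
counts, so per-cell truth rows (`per_cell = TRUE`) reproduce them to the
digit.

## Numerical choices and degenerate inputs

* Strict inequalities at every published threshold ("greater than",
  "below").
* 0-based pixel coordinates in all reported positions; images are `[x, y]`
  matrices.
* Blank images segment to zero nuclei (not an error); constant tubulin
  yields zero poles; an empty cytoplasm mask is an error; a mask smaller
  than the smoothing kernel warns and returns zero poles.
* A zero-SD feature on a plate is an error naming the feature; an all-zero
  dZ row is an error under uncentred Pearson (its similarity is
  undefined).
* `proportion()` requires a positive denominator; divide-by-zero states
  are reported as missing, never silently zero.
* Agglomeration ties break on the lowest gene index; the tie rule is part
  of the tested contract.
* The run manifest records every parameter and seed, contains no
  timestamps, and its MD5 stamps every output table, so identical
  configurations produce byte-identical outputs.

## Problem sizes used in the validation suite

The test and acceptance runs use desk-scale versions of the study design,
chosen as the package's own validation conditions: image benchmarks use
two conditions of 200 simulated mitotic cells (40 fields of 14 cells
each); statistical benchmarks use a 240-gene duplicate two-background
screen with 20 planted enhancers and 10 suppressors at ±3 control SDs;
oracle checks run on patches of at most 64×64 px and gene sets of at most
8. Limitations worth restating: recovery rates quoted here are for
synthetic data at the default SNR; the exact Columbus formulas behind the
published 0.095/0.56 spot parameters are not recoverable, so numeric
agreement with the original per-well values is not claimed; and
multi-batch normalization beyond one plate pair per background is out of
scope.

## A worked example

```{r example}
lay <- make_layout(paste0("GENE", 1:24), n_controls = 8)
mod <- gene_effect_model(lay)
mod <- set_gene_effect(mod, c("GENE2", "GENE9"), "chTOG",
                       multipolar_penetrance = 0.70)
mod <- set_gene_effect(mod, "GENE5", "chTOG",
                       multipolar_penetrance = 0.10)
sim <- simulate_screen_tables(lay, mod, seed = 15)
res <- run_screen(lay, wells = sim$wells, seed = 15)
res
subset(res$hits, class != "none" & background == "chTOG")
```

And one simulated field through the image pipeline:

```{r field}
well <- simulate_and_analyze_well(n_fields = 4, n_interphase = 10,
                                  n_mitotic = 4, penetrance = 0.5,
                                  seed = 42)
well$summary[, c("n_cells", "mitotic_index", "pct_multipolar",
                 "mean_poles")]
well$truth_summary[, c("n_cells", "mitotic_index", "pct_multipolar",
                       "mean_poles")]
```
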