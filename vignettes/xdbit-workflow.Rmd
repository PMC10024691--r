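---
title: "Methods: from barcoded reads to registered spatial counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from barcoded reads to registered spatial counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdbitr)
```

This vignette explains the models and procedures behind `xdbitr`, the
choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Deterministic barcoding in tissue encodes position by flowing DNA
barcodes through two orthogonal sets of parallel microchannels. A chip
with $n$ channels per axis at pitch $p$ (centre-to-centre) and width $w$
produces an $n \times n$ array of $w \times w$ spots; with the default
38-channel, 50 µm / 100 µm design that is 1444 intersections per capture
area, of which $36^2 = 1296$ carry barcodes on both axes — the two
outermost channels hold a fluorescent alignment marker instead. Nine
capture areas in a $3\times3$ arrangement give a scan area of
$9\,(36 \cdot 100\,\mu m)^2 = 116.64\ \mathrm{mm}^2$. The spot centre
convention is origin at the top-left of each capture area, x rightward,
y downward, channel $i$ starting at offset $i\,p$, centre at
$i\,p + w/2$; indices are 0-based and all lengths are in micrometres.

One design question the chip geometry cannot answer by itself is which
ligation round maps to which axis. We fix the convention that the
horizontally routed channels of round 1 encode the row index (y) and
expose it as the `round1_axis` field of `chip_layout()`, since both
choices are geometrically equivalent. Similarly, whether the outermost
channels count as "spots" is representation, not fact: we enumerate all
$n^2$ intersections and mark alignment-channel spots `is_barcoded =
FALSE`, so both totals (1444 and 1296) are first-class.

## Demultiplexing

Read 2 is modelled as an ordered list of fixed-position segments (UMI,
x/y/z barcodes, linkers). Exact positions and linker lengths differ
between library designs, so the layout is fully configurable; the
default is UMI(10 nt) – x(8) – linker(20) – y(8) – linker(20) – z(8),
with the 8-nt barcode length anchored by the reverse-transcription
primer design and the rest chosen as representative values.

Barcode correction is exhaustive minimum-Hamming matching: an observed
barcode is assigned to the unique legend entry within `max_hamming`
(default 1) mismatches; a tie at the minimal distance is ambiguous and
discarded. Hamming rather than edit distance keeps the decision
deterministic and position-stable for fixed-length barcodes. Because
generated legends enforce a pairwise distance of at least 3 within each
axis, every single-error barcode corrects uniquely — the property the
error-rate tests exercise. A read is *valid* only if x and y (and z,
when the layout has a z segment) all resolve; the first failing axis
labels the read (`invalid_x`, `invalid_y`, `invalid_z`), short reads are
`short`, and every input read lands in exactly one class.

When samples carry both a well (z) barcode and a library index, a valid
read whose well disagrees with its library is re-flagged `crosstalk`
and dropped from counting — but it is still tallied by
`well_composition()`, which is how the cross-contamination percentage is
measured in the first place.

Gene assignment replaces genome alignment with a deliberately small
contract: the first `min_prefix` (default 30) nucleotides of read 1
must match exactly one transcript of a user-supplied reference; zero or
several matching transcripts leave the read unassigned. Reference
records are named `gene|transcript|region`, and `region = intronic`
records let intron-derived reads be included (the default) or excluded.
Users with real alignments supply a pre-tagged read table instead.

UMI collapsing is single-linkage clustering of the UMIs within each
(spot, gene) group at Hamming distance ≤ 1, implemented as union–find;
the count is the number of clusters. The result is independent of read
order, and the tests compare it against an independent graph-components
oracle on adversarial inputs (4-nt two-letter UMIs, which chain
heavily).

## Registration

All transforms are planar affines stored as $2\times3$ matrices acting
on (x, y) with the raster convention (x = column, y = row, origin
top-left). Estimation from $k \ge 3$ non-collinear point
correspondences is linear least squares via QR; with $k=3$ it is exact.

The alignment-mark frame gives absolute anchoring: the marker channel is
Otsu-thresholded, morphologically closed, the largest connected
component taken as the frame, and the four corners read off its
minimum-area bounding rectangle (rotating calipers over the convex
hull). Corners are labelled TL/TR/BR/BL by angle around the component
centre and paired with their known micrometre positions — the frame
spans $(n-1)p + w$ on each side. Interactive vertex picking is replaced
by this detector plus a manual-points file override, which keeps the
step testable without a GUI.

Between imaging rounds (alignment image at 0.49 µm/px, high-resolution
image at 0.24 µm/px by default) no absolute anchor exists, so
registration is feature-based and specified by contract: blob keypoints
(intensity-weighted centroids of segmented nuclei, with an
equivalent-circle radius), a scale- and rotation-invariant descriptor,
nearest-neighbour matching under Lowe's ratio test (0.75), and a seeded
random-sample consensus affine (3 px inlier tolerance, ≥ 3 inliers,
least-squares refinement on inliers, two rounds). The descriptor is the
local keypoint *constellation*: distances to the 8 nearest keypoints as
ratios to the nearest-neighbour distance, plus angles relative to the
nearest-neighbour direction. For dot-like nuclei this carries far more
information than local intensity patches, and it is invariant under
similarity transforms by construction. The consensus seed is an
argument (default 0) so runs are reproducible.

Spot projection applies a µm→px affine to every spot centre and to the
four corners of its $w \times w$ outline; spots landing outside the
image are flagged, never dropped.

## Quality control

**Tissue calling.** A spot is tissue if its mean nuclear-stain intensity
over the projected polygon reaches a threshold; `"otsu"` (the default)
derives the cut from the spot-mean distribution, because stained tissue
against clean background is strongly bimodal. Whether the original
workflow thresholded manually or automatically is not decidable from
the available description, hence the manual override.

**Ambient gene filter.** Background spots (no tissue) measure ambient
contamination. Assuming Poisson-distributed background counts, gene $g$
with background mean $\mu_b$ gets the threshold
$t_g = \mu_b + 2\sqrt{\mu_b}$ (mean plus two standard deviations), and
is kept in a sample iff its mean over *tissue* spots exceeds $t_g$;
with several samples a gene survives if it is kept in at least one.
Note the direction: the rule compares tissue expression against a
background-derived bound. (A literal reading of one published
formulation — removing genes whose *background* mean is *below* $t_g$ —
is self-contradictory, since $t_g \ge \mu_b$ always; we implement the
comparison the accompanying results text describes.) The one-sided
$2\sigma$ bound caps the false-keep rate of a pure-background gene near
2.5% per sample; the tests verify ≥ 99% correct keep/remove decisions
under the planted-gene simulation (ambient $\lambda = 2$, tissue genes
at 10× enrichment, 20 seeds).

**Stripe normalization.** Unequal flow in individual channels yields
rows/columns of systematically high or low counts. The stripe metric is
the population coefficient of variation of per-row (and per-column)
mean spot totals — exactly $1/3$ for one doubled row in a two-row grid,
0 for a single row. Scaling every spot to a common total (default: the
median spot total), optionally followed by $\log(1+x)$, removes the
artifact; the tests inject row factors 0.5–2.0 and require at least a
5-fold CV drop.

**Saturation.** Sequencing saturation is estimated by subsampling the
retained read-level records *before* UMI collapse and rebuilding the
matrix per fraction. Subsamples are nested — one seeded permutation,
fraction $f$ takes the first $fn$ reads — so a run's curve is
internally consistent, and medians are taken over the full run's spot
set. For a library with $d$ reads per molecule the expected recovery at
fraction $f$ is $1-(1-f)^d$, which the duplicate-heavy test checks.

**Pseudobulk.** Spatial counts summed per gene are compared with bulk
profiles after TPM scaling when gene lengths are available; without
lengths the package falls back to counts-per-million and labels the
output `cpm`, since TPM is undefined without a length.

## Wells and flow

Well composition aggregates resolved z-barcodes by (library, well) into
row percentages; a well's contamination is 100 minus its own-barcode
share. The estimator is a plain proportion, hence unbiased, which the
tests confirm to within 0.2 percentage points over 100 simulations.

Flow measurements (channel length in mm vs volumetric flow in µL/min)
are fit by ordinary least squares — over the narrow 117.7–165.7 mm
design range the Hagen–Poiseuille $1/L$ dependence is effectively
linear. The `flow_model` object carries slope, intercept, Pearson r and
p, and `predict()` provides 95% confidence and prediction bands.
`max_operable_length()` inverts the mean line at a minimal acceptable
flow; the conservative variant uses the prediction-interval lower bound
and can only be shorter. The ideal-flow reference is the standard
first-order rectangular-duct approximation
$Q = \frac{w h^3 \Delta P}{12 \mu L}(1 - 0.63\,h/w)$, an approximation
(stated as such) that is adequate for a square 50 µm channel. The
measured flow table of the original instrument is not available, so the
package ships a clearly labelled *synthetic* measurement fixture
spanning the printed design length range (slope −0.02 µL/min/mm,
intercept 10 µL/min, σ = 0.1, four replicates per channel) and treats
real measurements as user input. The empirical ~26.5% shortest-longest
flow difference is a property of one physical instrument and is not a
target of the ideal model.

## The synthetic-data generator

The generator produces everything the pipeline consumes under a single
master seed (fixed sub-streams for legend, counts, reads, images;
identical config + seed gives byte-identical FASTQ and rasters).

What it emulates: per-gene tissue expression (log-normal means, Poisson
or negative-binomial counts), a uniform ambient background
($\lambda_{bg}$ in every spot), a central tissue disc per capture area,
multiplicative channel stripe factors, barcode legends with enforced
pairwise separation, configurable read-2 assembly, per-base substitution
errors, read duplication per molecule, well-barcode swapping at a set
contamination rate, and two imaging rounds rendered from one micrometre
scene under known similarity transforms (nuclei as Gaussian blobs,
diffuse tissue autofluorescence, the marker frame, additive pixel
noise).

Defaults are fixed once to the study conditions of the assay this
models: 38 channels / 50 µm / 100 µm pitch / 3×3 areas, alignment
channels {0, 37}; 9 wells × 4 z-barcodes at pairwise Hamming ≥ 3; UMI
10 nt, barcodes 8 nt; 0.49 and 0.24 µm/px image resolutions. Where no
value is documented we chose representative ones, once: per-base error
0.005 (typical short-read substitution scale), contamination rate 0.07
(mid-range of reported well cross-contamination), 4 reads per molecule
(deeply sequenced libraries near saturation), 250 nuclei per capture
area, 2° and 5° image rotations.

Two constructions deserve emphasis. First, truth identifiability: real
UMIs can collide, but a generator whose truth matrix should be exactly
recoverable must not emit two molecules of the same (spot, gene) whose
UMIs differ at ≤ 1 position — collapse would merge them, correctly but
unverifiably. UMIs are therefore rejection-sampled to pairwise distance
≥ 2 within each group. Second, the transcript reference is random
sequence (1 kb exonic + 0.5 kb intronic per gene): hermetic, but it
means gene assignment is tested only in its unique-prefix contract, not
against the ambiguity structure of a real transcriptome.

What it does **not** emulate: optics (point-spread functions, uneven
illumination, autofluorescence texture), platform-specific error
profiles (indels, quality-dependent errors), cell-type structure or
spatial expression gradients within the tissue, diffusion halos at
tissue boundaries, and chimeric reads. Passing tests therefore
demonstrate algorithmic correctness under the stated statistical model,
not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Otsu thresholds cut at the upper edge of the variance-maximizing
  histogram bin (256 bins), so the two classes separate cleanly.
* Affine estimation refuses collinear sources (QR rank); `affine2d()`
  refuses singular linear parts; compose ∘ invert returns identity to
  ≤ 1e−9 (tested).
* Keypoint coordinates are continuous: centroid index minus 0.5, so
  both images live in the same frame as the true transforms rather
  than inheriting a half-pixel bias.
* Single-row/column grids report stripe CV 0; zero-total spots are
  dropped with a message before normalization; an all-zero matrix is an
  error; a sample without background spots disables the gene filter
  with a warning rather than silently keeping it.
* Constant flow responses report r = 0 with a warning (the correlation
  is undefined); `max_operable_length()` requires a negative slope
  beyond numerical noise.

## Problem sizes in the tests

The test suite and acceptance script run on reduced layouts chosen as
the package's own test sizes: 8-channel chips (36 barcoded spots per
area) for simulation-heavy checks, a single 38-channel area (~10⁵
reads) for the exact round-trip, 10⁴ reads for the correction oracle,
220-nuclei image pairs (~1600² and ~3400² px) for registration, 20
seeds × 40 genes for the background filter, and 100 replicates × 152
points for flow-fit coverage. The geometry identities are computed at
full design size, where they are exact.

## Known limitations

* Gene assignment is a toy contract, not an aligner; real data should
  arrive as a pre-tagged read table.
* Feature-based registration assumes a shared set of well-separated
  blob-like features; it will fail (explicitly, with an inlier-count
  error) on featureless or non-overlapping image pairs, and is not a
  substitute for deformable registration of warped sections.
* The Poisson background filter models ambient contamination as
  spatially uniform; localized artifacts (e.g. smears) violate that
  assumption.
* Counts export is MatrixMarket + TSV sidecars (plus JSON transforms);
  downstream single-cell containers can be built from those in one
  step.
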