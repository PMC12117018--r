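---
title: "Quantitative clonal tracking of barcoded tumor xenografts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative clonal tracking of barcoded tumor xenografts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrackr)
```

## The measurement problem

Lentiviral cellular barcoding marks single tumor cells with a heritable,
expressed DNA barcode before implantation into immunodeficient mice. Every
clone later detected in a xenograft is then the progeny of one uniquely
barcoded cell, and sequencing the barcode amplicon gives, per clone, a read
count that can be converted into an absolute cell number. From these two
primitives the package derives the quantities that characterize clonal
fitness:

* **Clone-initiating cell (CIC) frequency** — clones detected in a primary
  xenograft divided by the number of barcoded cells implanted
  (`cells implanted x transduction efficiency`), reported as a fraction and
  as "1 in N".
* **In vivo doubling time** — `days in vivo / log2(clone size)`: the average
  number of days per population doubling needed to grow the clone from one
  cell to its observed size. It is deliberately independent of tumor size
  and harvest time, so clones can be compared across xenografts and models.
* **Clone fate** — propagating (detected in primary and a secondary
  xenograft), transient (primary only) or emerging (secondary only), with
  "detected" meaning above the limit of detection.
* **Speed class** — fast / medium / slow, from a Gaussian mixture fitted to
  the doubling-time distribution.

A synthetic-data module generates every input (barcode libraries, clone
populations, spike-in ladders, paired FASTQ, single-cell fixtures) with
ground truth attached, so the whole pipeline is exercised end to end with
no external data.

## From reads to counts

Amplicon reads carry a 31-bp insert — a 27-bp barcode followed by a 4-bp
library ID — between constant flanks. Three staggered primer pairs were
used to increase base diversity on the sequencer, so `extract_barcodes()`
accepts any of the three printed flank pairs. The filters are applied in a
fixed order: flank match, exact 31-bp insert length, alphabet/pattern
check, then a minimum insert base quality of Phred 30. Every read is
accounted for: kept reads plus typed rejections always sum to the input.

Sequencing errors are removed by grouping reads within edit distance 1.
Because the length filter runs first, all inserts have equal length and
edit distance coincides with Hamming distance. The direction of grouping is
not prescribed by the distance itself, so the package uses greedy
descending-count centroid absorption (the directional collapse familiar
from UMI processing): barcodes are visited from most to least reads (ties
broken lexicographically), and each unabsorbed barcode claims all remaining
barcodes within the distance threshold. This makes collapsing
deterministic, read-conserving and idempotent, and it is verified
exhaustively against a brute-force oracle in the test suite. Read-count
thresholds for aberrant barcodes are applied only *after* collapsing, so
that genuine reads absorbed into their centroid are never discarded; the
default threshold is the read count at which the calibrated size estimate
reaches one cell.

Library safety rests on a diversity argument: for barcodes drawn uniformly
from 4^27 sequences, the chance that a draw of 1,000 barcodes contains any
pair within Hamming distance 4 is far below 1%, so distinct observed
barcodes represent distinct clones even after error collapsing.
`simulate_collision_rate()` estimates this fraction by repeated sampling
without replacement from pooled simulated libraries. The published barcode
design is semi-random with an unpublished template; the generator uses
fully random barcodes, whose collision properties are at least as adverse
as any constrained design, making the check conservative.

## Absolute clone sizes

Spike-in controls — barcoded cells of known number spanning 10 to 12,500
cells, with tens to hundreds of technical replicates — are carried through
library preparation and sequencing with each sample. The fractional read
value of a clone,

$$\mathrm{FRV} = \frac{\text{clone reads}}{\sum \text{spike-in reads}},$$

is converted to cells through an ordinary least-squares fit of
`log10(cells)` on `log10(FRV)` over the ladder. The regression is run in
the direction needed for estimation (cells from FRV), not the reverse.
Spike-ins with zero reads cannot enter a log-log fit; they are excluded
and counted, a choice the calibration report makes explicit. Because the
spike-ins sit in the sequenced aliquot, the calibrated estimate measures
cells *in the sample*; `quantify_clones()` multiplies by
`100 / percent of tumor sampled` to report whole-tumor clone sizes, the
scale on which the limit of detection

$$\mathrm{LOD} = 20 \times \frac{100}{\text{percent of tumor sampled}}$$

is defined (20 cells is the size detected with 95% sensitivity when the
entire tumor is sampled).

## The doubling-time mixture

Doubling times across thousands of clones are multimodal. The package fits
univariate Gaussian mixtures with K = 1..`max_K` components by
expectation-maximization and selects K by the Akaike Information
Criterion (BIC is available by flag; AIC is the documented default). Each
K is fitted from a deterministic quantile initialization plus ten seeded
k-means++ initializations; each start runs a short EM (40 iterations) and
the best continues to convergence, so the fit is reproducible under its
seed. The EM log-likelihood trace is exposed and tested for monotonicity.
Degenerate input (all observations equal) returns K = 1 with a floored
standard deviation and a flag rather than an error.

`max_K` defaults to 3, and that default is a considered choice rather than
a convenience. The growth model below implies that realized doubling times
within one subpopulation follow `t / Gamma(t)`, a mildly right-skewed
distribution; at sample sizes in the tens of thousands, unrestricted AIC
prefers to describe one skewed subpopulation with two Gaussians. The
speed-class framework is a three-class analysis — fast, medium, slow — so
the classifier (`classify_speed()`) is defined for at most three
components and the fitter searches K in 1..3 by default. Users studying
finer structure can raise `max_K`, but the speed classes are then no
longer defined.

Class boundaries between mean-ordered components are reported as
posterior-equality points (where the weighted component densities cross,
found by root-finding between adjacent means; equal weights and standard
deviations give the midpoint). Classification defaults to
maximum-posterior assignment; hard cutoff-based assignment is available,
and the two coincide except deep in the tails where a wide component can
overtake a narrow one.

## The stochastic growth model

Each clone starts from one cell. On day $t$ it gains an exponentially
distributed number of doublings $r_t$, so

$$\log_2 N_t = r_1 + \dots + r_t \sim \mathrm{Gamma}(t, \lambda),\qquad
\frac{\log_2 N_t}{t} \xrightarrow{t\to\infty}
\mathcal{N}\!\left(\frac{1}{\lambda}, \frac{1}{t\lambda^2}\right).$$

The rate convention deserves care. A literal reading of "exponential with
rate parameter 1/mu" makes the *increments* average mu doublings per day,
which would make clones with long doubling times grow fastest —
dimensionally inconsistent with the doubling-time statistic
`t / log2(N_t)` the simulation must reproduce. The package therefore
parameterizes the default so increments average `1/mu` doublings per day
(rate `lambda = mu`), making the realized doubling time concentrate on the
configured mu; the literal reading remains available via
`rate_convention = "literal"`. The time step is one day. Trajectories stop
at the first limit reached — a cell capacity of 1e7 (the maximum
permissible tumor size in mice) or a time stop of 1e3 days — and the
increment that crosses the capacity is included. The capacity applies to
the summed population by default, mirroring a shared tumor; a per-clone
cap is available, and the generator uses a truncating variant when a hard
"never exceed the tumor size" invariant is required.

Simulating a population with the observed subpopulation proportions
(19% / 62% / 19% at mean doubling times of 5, 15 and 40 days in the
default configuration) and refitting the mixture closes the loop: AIC
recovers three components and the weights return within ±0.03 at
n = 19,303 clones, which is the package's in-silico replication of the
multimodality argument — distinct peaks arise from subpopulations with
different growth rates, not from stochastic variation alone.

## The detection simulator

The negative association between CIC frequency and implanted cell dose
could be a sampling artifact: more founders share the same read budget.
`simulate_detection()` isolates that artifact by growing all founders
synchronously (equal clone sizes up to rounding — growth-rate variation is
deliberately absent here), sampling reads with replacement (representing
PCR amplification), and counting unique founders detected, over 50
repetitions. Subtracting the simulated log-log slope from the experimental
one (`corrected_dose_slope()`, standard errors propagated in quadrature)
leaves the biological component: zero when only sampling effects exist, and
negative when suppression of clone initiation is planted in the generator —
both behaviors are verified in the acceptance suite.

## The single-cell layer

Cells are linked to clones through the expressed barcode. Cells carrying
two or more barcodes are resolved by a recurrence rule: a multi-barcode
pattern seen in exactly one cell is a droplet doublet and is blacklisted;
the same pattern recurring across cells marks multiple integrations in the
clone of origin, and all carriers are resolved to one representative
barcode (highest aggregate read count, lexicographic tie-break — the rule
must pick *some* representative and this one is deterministic).

Cell states are metacells — groups of transcriptionally similar cells —
taken as input along with their similarity matrix; deriving metacells is
outside the package's scope. The similarity graph connects each metacell
to its three most similar peers (undirected union of directed top-3 lists;
mutuality is not required, and ties break by node id). For a clone, root
states are metacells holding at least three of its primary-xenograft
cells; every metacell is then labeled with its breadth-first distance from
the nearest root, and gene-module enrichment is tracked over that
distance:

$$\mathrm{enrichment}(m, d) = \log_2
\frac{\overline{x}_{m,\,\text{metacells at } d}}{\overline{x}_{m,\,\text{all metacells}}}.$$

The baseline is the arithmetic mean over all metacells (a geometric-mean
option exists); standard errors come from per-metacell log-ratios at each
distance. Modules themselves are k-means partitions of gene-gene
correlation profiles over strong, highly variable genes; the strength and
variability thresholds are exposed because the published per-model values
are not printed.

Clone differentiation breadth is the count and fraction of metacells a
clone contributes cells to, plus the Shannon entropy of its cell
distribution over metacells. Entropy is reported in bits (base 2) by
default with a natural-log option; the log base is a documented choice —
either satisfies the Shannon index, but comparability requires fixing one.

Pseudobulk differential expression between cell groups first excludes
cells below a 500-UMI floor, downsamples every cell to the minimum
remaining per-cell total (the downsampling target is not prescribed
anywhere, so the package uses this most conservative common denominator and
exposes it), pools each group and normalizes the profiles to equal totals.
Genes are tested only if, in the group where they are enriched, they are
expressed in at least 50% of cells and average at least 0.1 UMI per cell.
P-values are Mann-Whitney rank-sum on per-cell downsampled counts —
per-cell counts are the assumed unit — corrected by Benjamini-Hochberg.
Under label permutation the empirical fraction of q < 0.05 genes stays at
or below nominal, which the acceptance suite checks over 200 replicates.

Two projection utilities round out the layer: `signature_ternary()`
expresses a clone's UMIs as proportions over basal / luminal-progenitor /
mature-luminal signature genes (signature lists are inputs; proportions
are over signature genes only and are scale-invariant), and
`bimodal_threshold()` places the boundary between two cell fractions at
the kernel-density minimum between the two largest modes of a per-cell
score distribution, erroring on unimodal input rather than inventing a
threshold. Per-cell signature scores themselves, where needed by the
synthetic fixtures, are computed as the fraction of a cell's UMIs in
signature genes — a simple documented stand-in, since the published
scorer's internals are out of scope.

## What the generator does and does not emulate

The synthetic experiment reproduces the statistical structure the analyses
rely on: uniform barcode libraries with realistic collision geometry;
clones drawn from growth-rate subpopulations (defaults 19% / 62% / 19% at
mu = 5 / 15 / 40 days) with propagating / transient / emerging fates
defined exactly by cross-passage presence; multinomial read sampling
proportional to cell numbers with per-base substitution errors and
quality corruption; spike-in ladders from 10 to 12,500 cells with 24
replicates per level; and single-cell fixtures with a metacell chain, a
planted epithelial-to-mesenchymal expression gradient, doublets and
multi-integration clones. Default scales (two models, 250 primary clones
and 40 emerging clones each, 2e6-cell tumors, 10% of the tumor sampled,
1e5 cells implanted at 25% transduction) keep a full run in seconds while
preserving realistic limit-of-detection behavior; they are the package's
chosen study conditions, stated here so results are interpretable.

It does not emulate mouse physiology, spatial tumor structure, PCR
chimeras, index hopping, GC bias, clone competition or death, or
single-cell chemistry beyond barcode and doublet logic. Passing tests
therefore demonstrate correctness of the computations and recoverability
of planted structure under idealized noise — not robustness to every
artifact of real amplicon or droplet data.

## Numerical choices and degenerate inputs

* Phred qualities are simulated as constant Q37 with a configurable
  corruption rate to Q20; only the threshold at Q30 matters downstream.
* The 4-bp library ID sits at the end of the 31-bp insert by default
  (configurable to the start); its true position is not printed.
* `shannon_entropy()` requires probabilities summing to 1 within 1e-9
  unless `normalize = TRUE`; `0 log 0` is 0.
* Mixture EM floors standard deviations at 1e-4 of the sample standard
  deviation to avoid variance collapse onto single points.
* `collapse_by_edit_distance()` on an empty table returns an empty table;
  `find_roots()` with no qualifying metacell warns and returns an empty
  set (distance analysis is skipped for that clone, not failed).
* Zero-variance inputs to `replicate_state_correlation()` return NA with
  a warning; zero-spike-in-read samples are a hard calibration error.

## Problem sizes used in the checks

The acceptance suite pools two simulated libraries of 1e6 barcodes for the
collision bound (100 draws of 1,000), fits 50 replicate mixtures at
n = 19,303 clones, verifies the Gamma law at t = 500 with 1e4 draws, runs
100 random instances of each oracle equivalence, 200 permutation
replicates of the DE null at 200 genes, and one full two-model experiment
(primary plus two secondaries, 4e4 reads per sample) end to end. These
sizes were chosen to give the statistical assertions comfortable power
while keeping a complete run fast on a single CPU.

## Limitations

Real amplicon data bring artifacts the simulators exclude by design, so
calibration quality on real spike-ins should always be inspected
(`CalibrationModel` reports residual spread and excluded points). The
mixture model describes doubling times as Gaussian within class although
the growth model itself implies mild skew; with very large samples this
shows up as sensitivity of unrestricted model selection, which is why the
speed-class analysis fixes K at three candidates. Transcriptional
distances assume phenotypic change is gradual on the similarity graph;
abrupt state switches make the ordering putative, and the enrichment
curves should be read as trends rather than trajectories.
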