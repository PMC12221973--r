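---
title: "Methods: comparative 3D chromatin architecture with chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative 3D chromatin architecture with chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromarch)
```

# Scope and model

`chromarch` analyses binned chromosome conformation capture (Micro-C /
Hi-C) contact matrices for comparative studies of genome architecture:
chromosomal A/I/B compartmentalization, insulation boundaries, focal
chromatin loops with promoter/enhancer annotation and promoter hubs, and
orthology-anchored tests of loop-synteny conservation. All stages are
validated against a synthetic generator that plants each structure with
known parameters, so every claim the test suite makes is a recovery claim
against ground truth, not against external data.

The package starts from binned matrices; read mapping, pair filtering,
genome assembly, peak calling and orthology inference are upstream of its
scope and are consumed as inputs (dense TSV matrices, bedGraph tracks,
BED/GFF3 intervals, BEDPE loop lists, two-column orthology tables).

# The synthetic contact-map generator

The generator's expected matrix is a closed-form product over planted
features:

$$E_{ij} = (\max(|i-j|,1)\,b)^{-\alpha}\; c_{ij}\, s_{ij}\, \ell_{ij}\, d_{ij},$$

with bin size $b$, decay exponent $\alpha$; $c_{ij} = \sqrt{f_i f_j}$
when bins $i,j$ share an A or B state (homotypic boost $f \ge 1$, the
geometric mean permitting per-interval factors); $s_{ij} = \prod
\beta_k$ over boundaries $k$ the pair straddles (attenuation $\beta \in
(0,1]$); $\ell_{ij} = e$ at a loop-anchor pixel with $(1+e)/2$ on its 8
neighbours (a halo that makes pile-ups realistic while keeping the
centre recoverable); and $d_{ij}$ an optional within-domain boost.
Unmappable bins are zeroed before sampling. Counts are independent
Poisson draws per upper-triangle pixel scaled to a total depth, then
symmetrized; overdispersion is deliberately not modelled because no
downstream statistic here requires it. All randomness flows through one
seed; identical configuration and seed give byte-identical output.

Two modelling choices deserve emphasis:

* **Compartment segmentation is irregular.** A perfectly periodic
  checkerboard is degenerate: the same-state fraction then depends only
  on genomic distance, so the compartment signal is absorbed entirely
  into the distance-decay normalization and no eigenvector can recover
  it. `randomCompartmentSegments()` therefore draws alternating A/B
  intervals with exponentially distributed lengths (default mean 100–200
  kb, floor 30–50 kb), which is also what real compartment maps look
  like.
* **What the generator does not emulate.** Translocation artefacts,
  copy-number variation, restriction/MNase fragment structure,
  overdispersed counts, trans contacts, stripes and fountains. Passing
  recovery tests therefore demonstrates correctness of the estimators
  under the stated generative model, not robustness to every artefact of
  real libraries.

Chromatin tracks are Poisson background (rate 1 per 200-bp track bin)
plus Gaussian peaks (default height 50, sd 400 bp) at the TSSs of active
(GP1/GP2) genes for ATAC/H3K4me3/H3K4me2, and at planted enhancers for
ATAC/H3K4me1/H3K4me2 without H3K4me3. Paired genomes for synteny tests
relocate a stated fraction of genes to uniform random positions in the
gene order, optionally exempting conserved blocks.

# Matrix normalization

**ICE balancing** (`iceBalance`) iterates multiplicative marginal
correction with a square-root damping step until the valid-bin marginal
coefficient of variation falls below `tol` (default 1e-8); weights are
then rescaled so valid marginals equal 1. Bins whose raw marginal is
below 2% of the median valid marginal are dropped beforehand — the
concrete, reproducible counterpart of the coverage filtering balancing
tools apply by default. The test suite checks the fixed point against an
independent Sinkhorn-style oracle run to 10,000 iterations.

**Decay and O/E.** Per-distance means are computed exactly per diagonal
over valid bin pairs (per chromosome, then averaged), and reported on a
log-spaced grid (ratio 1.12 per step, 1 kb–100 Mb clipped to the
chromosome). `observedOverExpected` divides each diagonal by its own
mean, so every retained diagonal of the O/E has mean exactly 1 — this is
asserted to 1e-9 in the tests.

**SCC** (`sccCompare`) smooths both balanced matrices with an NA-aware
3×3 mean filter, computes the Pearson correlation within each distance
stratum, and combines strata with weights $N_d\,\mathrm{sd}(x_d)\,
\mathrm{sd}(y_d)$. The smoothing span and stratum weighting are declared
defaults (the originating description of the statistic leaves them
open); the resulting score is symmetric, scale-invariant, equals 1 on
self-comparison, and separates Poisson replicates (> 0.7 at depth 1e6)
from maps with different compartment configurations.

# Compartments

Eigendecomposition is applied to the Pearson correlation matrix of the
cis O/E map (pairwise-complete over missing pixels) — the field-standard
form whose eigenvector sign structure matches saddle behaviour.
Selection of the compartment eigenvector is automatic: the candidate
with maximal absolute Spearman correlation to a per-bin reference track
(GC fraction, or H3K4me3 where GC is uninformative) is chosen and
oriented so the correlation is positive; the chosen index and a
near-tied-eigenvalue flag are recorded. This replaces a visual
inspection step with a reproducible rule.

Saddle analysis ranks valid bins by the eigenvector into 40 equal-count
groups, drops the extreme 2.5% at both ends, and averages O/E over group
pairs. Compartment strength is (mean AA + mean BB)/(mean AB + mean BA)
over corner blocks covering the extreme 20% of retained groups
(`ceil(0.2 × 38) = 8` groups per corner). The alternative reading of
"top 20% of interaction values" — the top O/E pixels within corners — is
available via the corner means returned alongside; the ranked-group
reading is the default because it is scale-invariant and matches the
saddle construction.

The intermediate (I) state is fitted by a univariate three-component
Gaussian mixture via EM with deterministic initialization (means at the
10th/50th/90th percentiles, shared initial variance, equal weights;
component-specific variances afterwards, which is the more general of
the two conventions). B–I and I–A thresholds are the density
intersections between adjacent components inside the inter-mean
interval; when the intersection falls outside that interval the midpoint
of the means is used and flagged. The fit is affine-equivariant, which
the tests assert directly.

Feature coverage per compartment is reported as
$-\log_2(1 - q)$ of the empirical quantile $q$ (mid-rank ties, maximum
capped at $(n-0.5)/n$): a value of 6 means the upper $2^{-6}$ tail.

# Insulation and boundaries

The diamond insulation score of bin $i$ at window $w$ is the log2 ratio
of the mean balanced signal in $[i-w,i) \times (i,i+w]$ to the
chromosome-wide mean of such diamonds; it is missing where less than
half the diamond is valid. The resolution/window grid (windows ×5, ×10,
×25 of each resolution) is scored by mean topographic prominence of the
profile's local minima — "maximum average insulation" is read as the
strongest partitioning; ties break to the smallest resolution, then the
smallest windows, and the full grid report is returned. The two best
windows are used jointly: a boundary must appear in both profiles within
1 bin.

Boundary strength is the topographic prominence of the inverted score
(against the lower of the two flanking maxima, walks terminated by NA or
the profile edge). Minima within 2 bins of an unmappable interval are
removed. The strong/weak split uses the iterative minimum cross-entropy
(Li) threshold on the strength distribution; an exhaustive search of the
cross-entropy objective serves as the test oracle.

Classification of boundaries follows the strict precedence loop-anchor >
TSS > accessible > compartment-limit > unassigned, with a ±1-bin
matching tolerance and TSSs of loop-participating genes excluded from
the TSS class; interval queries go through IRanges and are verified
against a brute-force scan on random fixtures. Rescaled pile-ups average
the O/E submatrix of each inter-boundary valley ≤ 100 kb (plus
one-domain flanks) after area-weighted resampling onto a fixed raster.

# Loops, anchors, hubs and gene groups

The focal caller is a transparent ring-background detector: a candidate
pixel must exceed `foldThreshold` times the mean of a surrounding square
ring (half-width 5 bins, central 3×3 excluded, NA-aware exact sums) and
carry a minimum raw count; 8-connected candidates merge and the peak
pixel represents each loop. It deliberately does not re-implement any
external caller's scoring; externally called loops can be imported from
BEDPE and flow through APA and annotation unchanged.

APA extracts the O/E submatrix ±10 bins around each loop pixel and
scores the centre against the mean of the lower-left (short-distance)
corner quadrant of 5×5 pixels. The centre defaults to the single centre
pixel: with the generator's halo the centre-pixel ratio equals the
planted enrichment exactly (e.g. 3 for e = 3), whereas a 3×3 centre mean
would conflate peak and halo (yielding ≈ 2.1); the 3×3 variant remains
available via `centerSize = 3`. Outlier filtering removes loops with
|z| > 3 on log-APA in both tails — high-intensity artefacts from
rearrangements as well as implausibly weak calls.

Anchor classification computes CPM coverage of H3K4me3/me2/me1 in a
species-configurable window (1/2/10 kb) around each anchor centre,
quantile-normalizes the marks against genome-wide windows
(mean-of-sorted-values reference, mid-rank ties), and thresholds at the
70th percentile of normalized genome-wide coverage (no cutoff is
prescribed by the underlying protocol; 70% is a declared default). P
requires active and dominant H3K4me3; E requires the enhancer mark
(H3K4me1 or H3K4me2, configurable per species) active and dominant over
H3K4me3. Dominance, rather than a hard "H3K4me3 below threshold" veto,
is used because ~30% of pure-background H3K4me3 windows exceed a 70th
percentile threshold by construction, and a strong enhancer should not
be demoted to U by background noise.

Promoter hubs are connected components (≥ 2 promoters) of the
promoter–promoter loop graph, computed with igraph and checked against a
union-find oracle. GP groups: GP1 = ATAC + H3K4me3 peak at the TSS
(±1 kb) and loop-anchor overlap; GP2 = peaks without a loop (genes with
only one of the two peaks are GP2 with a `partial` flag); GP3 = no
peaks.

# Synteny conservation

Foreground regions (loop anchor pairs) and 3× length-matched,
non-overlapping background regions are mapped to flanking anchor genes
(closest overlapping gene per region end; overlap first, then distance,
ties to the smaller start) and through the orthology table to the second
species. The per-region statistic counts orthogroups present both among
the genes between (and including) the anchors in species A and among the
genes between the ortholog counterparts in species B — the inter-anchor
reading; one-to-many orthology contributes at most one count per
orthogroup per region. Global shared fractions are compared by a
chi-squared goodness-of-fit test against background-derived
probabilities, per-region distributions by a one-sided Wilcoxon rank-sum
test with continuity correction.

Calibration is asserted for the Wilcoxon test: over 1000 null
simulations (uniform 50% shuffle, 40 random foreground regions of 3–10
genes on an 800-gene chromosome, 3× background) the rejection rate at
α = 0.05 falls in [0.03, 0.07] — slightly conservative, as expected with
discrete tied counts and continuity correction. The chi-squared test
aggregates dependent per-region counts and is reported alongside but is
not expected to be exactly calibrated under the null; under planted
contrast (100 conserved 8-gene blocks, 50% shuffle outside them) both
tests reject essentially always.

# Problem sizes, tolerances and degenerate inputs

The validation suite runs at desk scale by design: chromosomes of
400–2000 bins, depths 1e6–1e7, 20 planted boundaries/loops, 1000-rep
null calibrations. These sizes were chosen so each stage's recovery
behaviour is clearly resolved (e.g. per-pixel Poisson means of ~10–100)
while the whole suite completes in minutes. Numerical conventions:
coordinates are 0-based half-open with fixed-width bins (short terminal
bin allowed); ICE converges at marginal CV < 1e-8 with a warning and
residual on non-convergence; all-zero expected matrices, all-identical
mixture inputs, empty saddle corners, windows exceeding half the
chromosome and sub-minimum region sets raise errors rather than
returning silently degenerate results; EM variances are floored at
1e-10 × var(x) to avoid collapse.

# Known limitations

Single-chromosome containers (multi-chromosome analyses pass lists;
averaging across chromosomes is supported for decay, saddle and SCC);
cis contacts only; Poisson noise only; no hic/cool binary formats (dense
TSV, bedGraph, BED/GFF3, BEDPE and JSON cover interchange); the focal
caller is intentionally simple and is not a drop-in replacement for
dedicated callers on real, artefact-laden maps — the BEDPE import path
exists for exactly that case.
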