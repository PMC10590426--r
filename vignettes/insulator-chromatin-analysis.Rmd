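---
title: "Quantifying insulator-driven chromatin folding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying insulator-driven chromatin folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromins)
```

## Scope

`chromins` asks, from two directions, how much insulator-bound chromatin
contributes to 3D genome folding in systems (like *Drosophila* embryos)
where domain boundaries are insulator-defined rather than CTCF/cohesin
loops:

1. **Genome-wide**, from binned balanced contact maps and loop calls:
   chromatin-network assortativity of binding features with a
   distance-preserving randomization null; distance-normalized
   (log2 observed/expected) aggregate peak analysis with quintile
   stratification and anchor bootstraps; insulation-score boundary
   calling; loop/border classification.
2. **At a single locus**, from multiplexed DNA-FISH chromatin traces:
   per-nucleus pairwise-distance matrices, proximity maps at a distance
   cutoff, an imaging insulation score and domainogram, distance-matched
   control sets, and multiway proximity clusters compared against an
   independence expectation.

Everything runs on chromosome *arms* (2L, 2R, 3L, 3R, X); inter-arm pairs
are excluded throughout. All interval handling is 0-based half-open with
bin index `floor(position / bin_size)`; BED/BEDPE conventions are honored
at file boundaries. Matrix balancing, loop detection, read alignment and
peak calling are upstream of this package: balanced maps, BEDPE loop
calls and peak files are consumed, not recomputed.

## The chromatin network and assortativity

Loop calls define an undirected network: 5-kb bins appearing as loop
anchors are nodes, each unique cis loop is an edge carrying its genomic
separation. Chromatin assortativity (ChAs) of a node feature is the
Pearson correlation of feature values across edge endpoints, computed
over the directed edge list that contains both orientations of every
edge; this symmetrized form equals Newman's scalar assortativity
coefficient. Cross-ChAs correlates feature A at one end with feature B at
the other (symmetrized, so it is invariant to argument order), and
AND-ChAs is plain ChAs of the co-occupancy indicator `A & B`. A feature
that is constant on all edge endpoints has an undefined assortativity and
is returned as `NA`, never silently as 0.

Raw assortativity conflates 3D specificity with 1D clustering: a feature
painted in wide genomic blocks is assortative on *any* network whose
edges join nearby bins. The null model therefore preserves genomic
distance exactly: each edge is re-placed uniformly on its arm at its
exact separation, and feature values are looked up genome-wide at the new
positions (annotation tracks cover every bin, not just current nodes,
precisely so that randomized edges can land anywhere). The Z-score
standardizes the observed value against `n_rand = 1000` such
randomizations (sample standard deviation); `z > 2` is the conventional
significance threshold. Randomizations with undefined assortativity are
dropped and the effective count reported; more than 50% undefined is an
error recommending a larger network. An alternative reading of
"distance-preserving" — resampling within separation strata rather than
at exact separation — was considered; exact preservation is the stricter
null and is what the package implements.

## Distance normalization and aggregate peak analysis

The expected profile is the mean balanced contact frequency per bin
separation per arm, computed over valid bins only; `log2(O/E)` is missing
wherever observed or expected is missing or zero (balancing-masked bins
are pervasive at 5 kb, so every mean in the package excludes missing
pixels from numerator and denominator alike). APA extracts the
`(2w+1)²` log2(O/E) submatrix around each anchor pair's pixel and
averages element-wise; the default half-window is `w = 10` bins
(±50 kb at 5 kb resolution, a ~100 kb window around the intersection),
configurable because reasonable window conventions differ by a factor of
two. Anchor pairs default to separations of 20 kb–2 Mb, the detection
bounds of the reference loop caller; the short-range preset (< 250 kb) is
the regime where insulator-insulator preference concentrates and is used
by the anchor bootstrap (see below).

Stratified aggregates sort anchors by a score (ChIP signal or boundary
strength), split them into five contiguous equal-size groups — stable
sort, ties broken by genomic position, remainder assigned to the
highest-score groups — and compare APA centers across groups I–V.

The anchor bootstrap quantifies how many anchors must be aggregated
before the mean interaction preference is reliably positive: for each
subset size N it draws `iters` subsets without replacement and records
the mean center log2(O/E) over qualifying pairs (subsets with no
qualifying pair are redrawn and counted). Two numerical cautions shaped
the defaults: (i) the log of low Poisson counts is biased downward, so
far pairs with single-digit counts drag the mean negative regardless of
planted structure — the bootstrap is therefore run in the < 250 kb regime
where counts are informative; (ii) at N equal to the full anchor set the
distribution collapses to a point, which the tests use as a degeneracy
check.

## Insulation score and boundary calling

The insulation score at bin i is the missing-aware mean of the
`window × window` square of contacts crossing i (bins i−window…i−1
against i+1…i+window; default window 8 bins), log2-normalized to the arm
mean. Boundaries are local minima of the profile whose strength — the
difference between the neighboring extremes of the delta vector (mean
score right of the bin minus mean left) — reaches `delta_span`
(default 0.1). The strength threshold is deliberately configurable: the
upstream literature applies the same statistic with varying spans. A
called boundary bin may legitimately sit on either side of the true
inter-bin edge, so downstream matching uses a 1-bin slop by default
(`slop_bins = 1` in loop classification; exact matching available).

Loop classification assigns each loop to border/border,
border/non-border or non-border/non-border from its two anchors;
percentages sum to 100 and every loop is classified exactly once. Anchor
occupancy counts, per loop, how many anchors overlap at least one of a
list of peak sets (bin-level ≥ 1 bp overlap, optional slop), and border
participation reports the fraction of boundary bins appearing in at
least one loop anchor, split by whether the partner anchor is also a
boundary.

## Chromatin-trace statistics

A trace is the set of 3D barcode positions of one chromosome copy in one
nucleus. Pairwise distances are Euclidean, missing where either barcode
went undetected; the ensemble median map flags entries supported by
fewer than 50 traces (the threshold below which a median distance is not
considered representative). Proximity frequency divides the number of
traces with distance ≤ cutoff by the number of traces with both barcodes
detected; the 200 nm default is the threshold commonly used to make
imaging proximity comparable with ligation-based contact maps, and
sweeps over 100–500 nm are built in. The imaging insulation score slides
an n×n square along the diagonal of the median map and sums
cross-window distances (scaled to the full block when entries are
missing); *high* values mean strong insulation. The domainogram stacks
window sizes 1–6, each smoothed with a centered width-3 moving average.
One caveat found during testing: a width-3 smoother provably ties a
width-1 peak with its neighbors, so junction localization at window size
1 should be read from the unsmoothed profile.

Control sets for the insulator barcodes are drawn from non-insulator
barcodes to match the insulator set's pairwise genomic-separation
multiset (greedy slot matching, deterministic per seed). Matching
positions instead of separations was tried first and discarded: it
produced control sets containing adjacent-barcode pairs absent from the
insulator set, inflating the control proximity level — the matching
quality (mean separation per set) is reported so this remains auditable.

Multiway analysis counts, per anchor barcode and per trace in which the
anchor is detected, the number k of other anchors within the cutoff.
Undetected partners count as non-proximal (a strict mode requiring all
partners detected exists); the denominator choice keeps the multiway
statistics well-defined under per-barcode dropout while pairwise
frequencies condition on co-detection. Cluster-size counts are also
normalized by the anchor's total number of pairwise proximity events.
The independence expectation for a k-partner event is the mean over all
k-subsets S of the anchor's partners of the product of pairwise
frequencies; the observed counterpart averages, over the same subsets,
the fraction of traces in which the whole subset is simultaneously
proximal. Approximate standard errors (binomial for observed,
delta-method for expected) accompany the pooled values.

## The synthetic-data generator

The generator provides ground truth for every stage; its defaults are
the study conditions the analysis is meant to operate under.

**Contact maps.** Intensities follow
λ(i,j) = C·|i−j|^(−α) · T(i,j) · L(i,j): a power-law decay (α = 1 by
default), a compaction factor (default 2) multiplying intra-domain
pairs (planted boundaries partition the arm), and per-loop enrichment
factors (default 3) at planted loop pixels with a 1-bin halo at half
strength. Finite depth draws Poisson counts with the stated total and
returns frequencies; `depth = Inf` returns the raw intensities so that
observed/expected ratios are analytically exact (normalizing the
noiseless map would shift log2(O/E) by the log of a total-mass ratio —
this is why the analytic APA check can hold to 1e−9). The default depth
of 5e6 counts per ~3.5 Mb of simulated genome yields per-pixel counts at
loop separations in the tens-to-hundreds, comparable to a deep 5-kb
dataset. Poisson (not negative-binomial) noise is deliberate: it is the
minimal model sufficient for O/E and APA recovery, and overdispersion is
not part of the modeled analysis.

**Peak tracks.** One single-bin peak per planted loop anchor, signal an
arbitrary monotone function of the anchor's enrichment (identity by
default, so stratified recovery of the gradient is testable), plus
uniformly placed background peaks at baseline signal (resampled off
anchors, bounded retries).

**Traces.** Each trace is a 3D Gaussian random walk over barcodes in
genomic order with per-axis step `backbone_step · sqrt(gap_kb)` nm,
giving the monotone proximity–distance decay of a polymer without
simulating one (this is the only polymer feature the analysis relies
on). Planted pairwise colocalization collapses barcode j into a uniform
ball of radius `cutoff` around barcode i with probability p(i,j),
independently per pair and trace; detection dropout is independent per
(trace, barcode). Two honest limitations: collapses are transitive
(if (a,j) and (j,k) both fire, k ends near a), and a polymer backbone
correlates the proximity events of nearby barcodes — so the
"independent planting ⇒ independence null" calibration is exact only in
a star geometry (all planted pairs sharing one anchor, large mutual
separations), which is how the calibration test is constructed. Real
traces violate independence for the same physical reasons. An optional
`hub_prob` collapses a whole barcode set onto its first member,
planting genuine multiway hubs for sensitivity testing.

**The bundled study scenario** (`simulate_him_study`) fixes 34 barcodes
at 12.2 kb spacing (~400 kb locus), ten insulator barcodes, detection
efficiency 0.8, `backbone_step = 27` nm/√kb and a planted
insulator-pair excess of 0.016. The last two values calibrate the
scenario to its target regime — distance-matched control pairs
colocalizing at ~10–11% and insulator pairs at ~12% at the 200 nm
cutoff — i.e. colocalization that is infrequent and only slightly
insulator-enriched, which is the regime the trace statistics must
resolve. What passing recovery tests on these traces does *not* show:
robustness to segmentation/registration artifacts, chromatid pairing,
or locus-specific polymer structure, none of which the random-walk
backbone emulates.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and is
bit-reproducible given (parameters, seed). The test-suite problem sizes
are chosen to make each check statistically decisive at desk scale:
assortativity oracles on 200 networks of ≤ 50 edges; Z-score calibration
over 100 seeds at 200 randomizations on a 150-edge network; APA recovery
on 60 planted loops (noiseless and at depth 1e6); boundary recovery over
20 seeds on 200-bin arms; trace recovery at 5,000 traces × 34 barcodes;
bootstrap trends at 1,000 iterations. The acceptance script
(`scripts/acceptance.R`) reruns the full synthetic pipeline at these
scales from a single seed and writes its headline quantities as JSON,
alongside the resolved run configuration.

## Worked example

```{r example, eval = FALSE}
bins <- genomic_bins(c(armA = 2e6), bin_size = 5000)
loops <- loop_list(data.frame(arm = "armA",
                              bin1 = c(40, 120, 200),
                              bin2 = c(60, 150, 240)), bins)
sim <- simulate_contact_map(bins, tad_boundaries = list(armA = c(100, 250)),
                            loops = loops, enrichment = 3,
                            depth = 5e6, seed = 1)

oe  <- oe_transform(sim$map)
apa <- apa_aggregate(oe, as.data.frame(loops), w = 10)
apa$center                       # ~ log2(3)

bd <- call_boundaries(insulation_score(sim$map, window = 8))
anchor_bins(bd, bins)            # ~ bins 100 and 250

net <- build_network(loops, bins)
pk  <- simulate_peaks(bins, sim$truth, n_background = 10, seed = 2)
net <- annotate_nodes(net, pk, "factor", mode = "binary")
chas_zscore(net, "factor", n_rand = 1000, seed = 3)
```

## Known limitations

* The cooler HDF5 container is not read directly; contact maps enter via
  the plain-text dense-matrix archive (manifest + one matrix per arm).
* Assortativity uses the endpoint-pair Pearson convention; degree
  preserving rewiring nulls are out of scope (the distance-preserving
  null is the one the analysis is defined against).
* The polynomial fit of proximity versus genomic distance (default
  degree 3) is descriptive; its bootstrap band resamples traces, not
  barcodes.
* Per-embryo stratification is carried through the trace container but
  the statistics pool traces by default.
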