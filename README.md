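# chromins

Insulator-centric analysis of 3D genome folding, combining genome-wide
chromatin-network statistics on Hi-C loop calls with locus-scale
statistics on multiplexed DNA-FISH chromatin traces.

## Who this is for

In *Drosophila* (and other systems without CTCF/cohesin focal loops),
topologically associating domains are demarcated by insulator binding
proteins (IBPs), yet how much insulator-bound chromatin actually drives
preferential 3D contact — and how often insulator regions physically
colocalize in single cells — are quantitative questions. `chromins`
implements the statistical machinery to answer both from standard inputs
(balanced 5-kb contact maps, BEDPE loop calls, ChIP peak files, chromatin
trace tables), plus a synthetic-data generator with known ground truth so
every stage is testable end to end.

## Core statistics

**Chromatin assortativity (ChAs).** Loop calls define a network whose
nodes are 5-kb bins and whose edges are significant cis interactions. For
a node feature *f* (e.g. binding of one IBP), ChAs is the Pearson
correlation of *f* across edge endpoints, taken over both orientations of
every edge (Newman's scalar assortativity). Significance is a Z-score
against a distance-preserving null:

    z = (X − μ) / σ

where X is the observed assortativity and μ, σ are the mean and standard
deviation of assortativities over 1000 randomized networks in which every
edge is re-placed uniformly on its arm at its exact genomic separation
(features looked up genome-wide at the new positions). `z > 2` marks
preferential 3D interaction beyond what linear genomic clustering of the
feature explains. Cross-ChAs (feature A at one end, B at the other) and
AND-ChAs (assortativity of co-occupancy) ask whether pairs of factors
act together.

**Aggregate peak analysis (APA).** Contacts are distance-normalized as
log2(O/E) against the per-arm mean at each separation; the (2w+1)²
submatrices around anchor pairs are averaged element-wise (default
w = 10 bins, ±50 kb). Includes quintile stratification by ChIP signal or
boundary strength, and a bootstrap of the mean log2(O/E) over random
anchor subsets of size N ∈ {2, 5, 10, 25, 50, 100, 250, 300}.

**Insulation-score boundaries.** Crane-style sliding-square insulation
score (window 8 bins at 5 kb), log2-normalized per arm; boundaries are
profile minima with delta-vector strength ≥ 0.1. Loops are classified as
border/border, border/non-border, non-border/non-border, with anchor
occupancy and border-participation statistics.

**Chromatin-trace statistics.** Per-nucleus pairwise-distance matrices;
ensemble median maps; proximity frequency (fraction of traces within
200 nm of each other, conditioned on co-detection); per-barcode detection
efficiency; an imaging insulation score and domainogram; cumulative
proximity-versus-cutoff curves for insulator barcodes against 10
separation-matched control sets; proximity-versus-genomic-distance
polynomial fits with bootstrap bands; and multiway cluster analysis — the
frequency with which an anchor barcode has k partners within the cutoff,
compared with the independence expectation (mean over k-subsets of the
product of pairwise frequencies).

**Synthetic data.** Contact maps with power-law decay, planted domains
(compaction factor) and planted loops (enrichment factors, Poisson
sampling at a stated depth); peak tracks coinciding with planted anchors
with graded signal; polymer-like 3D traces (random-walk backbone, planted
pairwise colocalization, optional multiway hubs, per-barcode dropout).

## Worked example

```r
library(chromins)
bins <- genomic_bins(c(armA = 2e6), bin_size = 5000)

# --- genome-wide: planted loops, APA, boundaries, assortativity --------
set.seed(1)
sep <- sample(8:50, 100, replace = TRUE)
b1  <- floor(runif(100) * (400 - 1 - sep))
loops <- loop_list(data.frame(arm = "armA", bin1 = b1, bin2 = b1 + sep), bins)
sim <- simulate_contact_map(bins, loops = loops, enrichment = 3,
                            depth = 5e6, seed = 1)
oe  <- oe_transform(sim$map)
apa_aggregate(oe, as.data.frame(loops), w = 10)
#> APA: center log2(O/E) = 1.4852 over 100 pairs (0 skipped), window +/-10 bins

simt <- simulate_contact_map(bins, tad_boundaries = list(armA = c(100, 250)),
                             compaction = 2, depth = 5e6, seed = 2)
bd <- call_boundaries(insulation_score(simt$map, window = 8))
anchor_bins(bd, bins)
#>    arm bin
#> 1 armA 100
#> 2 armA 250

sub <- as.data.frame(loops)[sample(100, 60), ]   # factor on 60% of anchors
pk  <- peak_set(data.frame(arm = "armA",
                           start = c(sub$bin1, sub$bin2) * 5000,
                           end   = (c(sub$bin1, sub$bin2) + 1) * 5000))
net <- build_network(loops, bins)
net <- annotate_nodes(net, pk, "factor", mode = "binary")
chas_zscore(net, "factor", n_rand = 1000, seed = 3)
#> ChAs [plain] factor: X = 0.6394, mu = 0.0081, sigma = 0.1006, z = 6.27 (n_rand = 1000 effective)

# --- locus-scale: traces, proximity, insulator colocalization ----------
him <- simulate_him_study(n_traces = 5000, seed = 1)
ens <- pwd_matrices(him$traces)
proximity_map(ens, 200)
#> proximity_map: 34 barcodes, cutoff 200 nm, mean off-diagonal frequency 0.153
cc <- cumulative_proximity_curve(ens, him$truth$insulator_set, cutoffs = 200)
sprintf("insulator pairs within 200 nm: %.2f%%", 100 * cc$mean_freq)
#> "insulator pairs within 200 nm: 11.55%"
```

Reading the numbers: the APA center of ~1.49 recovers the planted
threefold enrichment (log2 3 ≈ 1.58, slightly shrunk because the expected
profile is estimated from the same enriched map); the two planted domain
boundaries are recovered exactly; the planted-anchor factor scores
z ≈ 6.3, far above the z = 2 significance threshold, while the same
machinery leaves random features near zero; and in the imaging scenario
insulator barcode pairs colocalize in only ~12% of traces at 200 nm —
infrequent colocalization despite strong genome-wide assortativity, which
is precisely the regime the package is built to quantify.

## Layout

- `R/` — bins/contact-map containers and readers, loop/peak/trace I/O,
  synthetic generators, network + assortativity, O/E + APA, insulation +
  classification, trace statistics.
- `tests/testthat/` — unit and property tests per module with brute-force
  oracles, plus end-to-end recovery tests (`test-acceptance.R`).
- `vignettes/insulator-chromatin-analysis.Rmd` — models, parameter
  choices, numerical caveats, generator calibration and limitations.
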