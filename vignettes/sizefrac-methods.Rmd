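---
title: "Methods: size-fractionated drinking-water microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-fractionated drinking-water microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drinking-water treatment trains (raw water RW → flocculation–sedimentation
FS → rapid sand filtration RSF → biological activated carbon BAC →
chlorination CW) reshape the bacterial community, and they do so differently
for ordinary **large bacteria (LB**, captured on a 0.22-µm filter**)** and
**ultramicrobacteria (UMB**, passing 0.22 µm and captured on 0.10 µm**)**.
`sizefrac` implements the full analysis chain for paired LB/UMB 16S
amplicon surveys of such trains: cell-density bookkeeping from flow
cytometry, diversity profiling with PERMANOVA variance partitioning,
effect-size based indicator-taxon discovery, fate tracking of those
indicators along the train, and co-occurrence network non-randomness
statistics. A synthetic-data generator with planted, recoverable structure
makes every stage testable without sequence data.

## Cell-density bookkeeping

Flow cytometry counts total cells in the original water
($CD_\mathrm{original}$) and in the 0.22-µm filtrate ($CD_\mathrm{UMB}$).
The package derives

$$CD_\mathrm{LB} = CD_\mathrm{original} - CD_\mathrm{UMB}, \qquad
UMB\% = \frac{CD_\mathrm{UMB}}{CD_\mathrm{original}} \times 100.$$

Replicate FCM counts carry a coefficient of variation of up to about 2%, so
a filtrate count marginally above the original count is treated as
measurement noise: within a 2% tolerance it is clamped
($CD_\mathrm{LB} = 0$, $UMB\% = 100$) with a warning, beyond it it is an
error. Across-unit trends are tested by one-way ANOVA with sampling batches
as replicates, on $\log_{10}$ densities because densities span orders of
magnitude (raw-scale testing is available via `log10 = FALSE`; UMB%, already
bounded, is tested on the raw scale). When every observation is identical
the F statistic is degenerate and the convention is $p = 1$.

## Diversity

Tables are rarefied to a common depth (default 17,000 reads) by a single
seeded subsample without replacement per sample — the mothur subsampling
convention; averaging over repeated draws would shrink variance the
downstream tests assume is there. Samples below depth are dropped, never
scaled. Richness is the number of nonzero OTUs, Shannon diversity is
$H = -\sum_i p_i \ln p_i$ in nats (the vegan default; other bases via the
`base` argument), and Good's coverage is $1 - F_1/N$ with $F_1$ the
per-sample singleton count. Dataset-wide singleton OTUs (total count 1
across all samples) are removed by `drop_singletons()`; "singleton" is
deliberately the dataset-total convention, not per-sample.

Beta diversity is Bray–Curtis on counts (`vegan::vegdist`). Variance
partitioning uses the standard Adonis analysis (`vegan::adonis2`) with
sequential (Type I) sums of squares in the order
`fraction + batch + fraction:batch` — fraction first because the
size-separation is the designed contrast — and free permutation of sample
labels. The model order is a documented choice; no claim is made that any
particular published run used the same order. Factors with a single level
carry no variance; they are dropped with a warning and reported with `NA`
p-values rather than passed to the fitting engine, which would refuse them.

## Indicator discovery

An OTU is an indicator of a fraction when it passes two gates, the
conventional thresholds of effect-size based biomarker discovery:

* Kruskal–Wallis rank test $P < 0.05$ (`stats::kruskal.test`, midrank tie
  correction; all-tied features get $H = 0$, $p = 1$ by convention), and
* a bootstrapped linear-discriminant effect size $> 2$ on the
  $\log_{10}$ scale.

The effect-size scorer follows the published LEfSe recipe, with every
constant exposed as an argument: per-sample relative abundances are
rescaled to a per-million basis; over 30 bootstrap rounds, two thirds of
each class is subsampled and a two-class linear discriminant is fit on the
feature joined with a class-mean pseudo-feature (a relative ridge
regularises the pooled within-class covariance, keeping the fit defined
when a direction is degenerate); the per-round effect size averages the
discriminant-weighted class-mean difference with the raw class-mean
difference, and the score is $\log_{10}(\text{mean effect} + 1)$. The score
therefore scales like $\log_{10}$ of the class-mean gap on the per-million
scale: a feature at $10^5$ in one class and absent in the other scores
about 5, and a tenfold larger gap adds about one unit.

Two implementation choices matter for reproducibility. Subsample index sets
are drawn once per call from the class sizes alone and shared by all OTUs,
so scores are deterministic given the seed and invariant to OTU order; and
subsampling acts on the *sorted* within-class values, so scores are also
invariant to sample order. There is no subclass (within-class Wilcoxon)
stage: the design has exactly two classes, LB and UMB. Discovery pools all
samples of both fractions into one global indicator list; everything that
fails a gate is a "normal" taxon.

Fate tracking sums each category's relative abundance per sample (the three
categories close to 100% by construction), averages over batches within
each (fraction, unit) cell, and reports the ARA — the average over **all**
samples of a category's summed relative abundance. Per-OTU trajectories are
kept for OTUs above a 0.1% display cutoff.

## Co-occurrence network and O/R statistics

Candidate OTUs pass category-specific mean-relative-abundance cutoffs
(indicators $> 0.02\%$, normal $> 0.1\%$). All pairs are scored by Spearman
correlation (midranks) of relative abundances across all pooled samples,
with p-values from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; edges survive when $|\rho| > 0.8$ and
$P < 0.01$. P-values are deliberately not multiplicity-corrected by default
— the strong-and-significant rule is the published convention — but a
Benjamini–Hochberg option exists (`fdr = TRUE`). Negative edges are
retained everywhere; topology uses $|\rho|$ weights. Nodes exist only while
incident to an edge; no isolated nodes are injected.

Topology reports average weighted degree, unweighted diameter and average
path length over connected pairs (whole graph and largest component — the
convention of the original tooling is unknowable, so both are printed),
mean local clustering with degree-<2 nodes contributing 0, and the
modularity of a greedy agglomerative partition on $|\rho|$ weights
(`igraph::cluster_fast_greedy`, which is deterministic — the "seeded
greedy" requirement is met with no seed sensitivity at all).

The non-randomness statistics label each node by indicator category or
phylum. For each unordered label pair the **observed incidence** O% is the
percentage of edges joining that pair; incidences close to 100%. The
**random incidence** R% is the expectation of O% under uniformly random
label assignment to the fixed topology. Sampling the two endpoints of an
edge is sampling two distinct nodes without replacement, giving the closed
form

$$R\%_{AA} = 100\,\frac{n_A (n_A - 1)}{n (n - 1)}, \qquad
R\%_{AB} = 100\,\frac{2\, n_A n_B}{n (n - 1)},$$

with a seeded label-permutation estimator as a cross-check (the two agree
within Monte-Carlo error by construction and by test). The ratio O/R is the
non-randomness benchmark: O/R > 1 means co-occurrence enrichment.
`intra_incidence_test()` condenses this into one number — the combined
same-label incidence against its permutation null, reported with the
97.5th null percentile and a one-sided permutation p-value
$(k+1)/(B+1)$. A degree-preserving (configuration-model) null is *not*
implemented; label shuffling conditions on the observed topology, which is
the appropriate null for the question "are labels arranged non-randomly on
this network".

## The synthetic-data generator

`sim_config()` encodes the study conditions: 3 batches × 5 units × 2
fractions with the (DWTP2, BAC) pair absent — 28 samples — at depth
17,000. Counts arise from a latent log-normal + multinomial model: a
heavy-tailed across-OTU baseline (sd 2 in log units, so a few taxa
dominate, as in real amplicon surveys), per-sample log-normal noise
(sd 0.5) for overdispersion, and a multinomial draw of exactly `depth`
reads, so column sums are exact by construction.

Planted structure, and why it is parameterised the way it is:

* **Indicators** (7.5% LB, 2.5% UMB of OTUs — echoing the roughly 3:1
  LB:UMB imbalance fraction-indicator surveys report) are drawn from the
  detectable 0.02–0.1% expected-abundance band and given a fold change of 8
  split symmetrically, $\pm\log(8)/2$ per fraction. The split keeps the
  planted mass shift between fractions near zero, so "normal" OTUs are not
  dragged into apparent differential abundance by compositional closure.
  Each indicator's per-sample enrichment also carries heterogeneity
  (`effect_sd = 1`): fraction preference is a noisy ecological response. A
  deterministic uniform shift would make every indicator pair correlate at
  about 0.8 — wiring an artifactual near-clique into the co-occurrence
  network exactly at its threshold, which real networks do not show.
* **Correlation blocks** (4 blocks of 5 OTUs, each wholly inside one
  category, cycling LB/UMB/normal/normal) share a latent factor:
  block OTUs' log-noise is
  $\sqrt{\rho}\, s\, f_{\text{block}} + \sqrt{1-\rho}\, s\, z$ with target
  $\rho = 0.95$ and total scale $s = 0.7$. This plants exactly the target
  correlation at a bounded noise scale; the naive alternative (a large
  factor loading on top of ordinary noise) lets one block dominate entire
  samples and wrecks richness comparisons. Block OTUs are boosted into the
  0.15–0.4% band so they clear the network cutoffs.
* **UMB support restriction**: half of the unstructured OTUs expected below
  0.005% are removed from the UMB support entirely, so UMB richness sits
  below LB richness in expectation. The threshold is deliberately far below
  the level at which pure absence could clear the LDA > 2 gate
  (an absent OTU at 0.005% yields a per-million mean gap of ~50, i.e. a
  score of ~1.7), so the richness mechanism cannot masquerade as planted
  indicator signal.
* **Densities** decline multiplicatively along the train (factor 0.45 per
  unit) with a ×3 rebound at BAC, and UMB% interpolates 3% → 15% and is
  kept non-decreasing per batch — the qualitative profile of a treatment
  train in which small cells survive disinfection better. Published
  per-unit density *ranges* exist but per-sample values do not, so
  magnitudes are calibrated to trends only.

All randomness flows from the single `seed` through one sequential stream
(baselines, planted structure, samples in grid order, taxonomy, densities),
so the full output is reproducible bit for bit. Taxonomy is a random phylum
assignment from a Proteobacteria-dominated pool with unresolved lower ranks
— enough to exercise phylum-level incidence, with no pretence of
phylogenetic realism.

### What the generator does and does not establish

Passing recovery tests on this generator shows the pipeline recovers the
planted model: monotone mean shifts between balanced groups, shared-factor
correlations, support-based richness deficits. Real data add features the
generator omits — taxon-specific dispersion, batch effects beyond random
density jitter, phylogenetic correlation of abundances, compositional
correlations among dominant taxa, and detection artifacts near the
rarefaction depth. Recovery rates here are therefore upper bounds on what
identical thresholds achieve in the field, not predictions.

## Numerical conventions and degenerate inputs

* Rarefaction: single draw, seeded; samples at exactly the target depth
  pass through unchanged; `depth <= 0` errors.
* All-zero samples: error in diversity and relative-abundance code paths.
* Zero-variance OTUs: skipped with a warning in the correlation screen.
* $|\rho| = 1$ pairs: $p = 0$ (the t approximation diverges).
* Empty networks (no surviving edge) are an error, not an empty object.
* O/R with $R\% = 0$: `NA`, never `Inf`.
* The effect-size scorer's ridge is relative (`1e-6` of the pooled
  variance plus `1e-12`), preserving the score's scale equivariance.
* Problem sizes in the test and acceptance suites: 600 OTUs × 28 samples at
  depth 17,000 for the default study; 150 OTUs at depth 3,000 for
  replicated property checks; 500–1000 replicates for type-I calibrations;
  2000 permutations for incidence nulls. These sizes give the Monte-Carlo
  tolerances quoted in the tests.

## Known limitations

Indicator discovery is OTU-level only (no per-rank cladogram stage);
correlations are plain Spearman, with no compositional correction such as
SparCC — at these sparsity levels and with an abundance filter the induced
compositional correlation is small, but it is not zero; the analytic R%
conditions on label counts, not on the degree sequence; and the PERMANOVA
factor order is a convention, with no attempt to reproduce any particular
published decomposition beyond its printed component sum.
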