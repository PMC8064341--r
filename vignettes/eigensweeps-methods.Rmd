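---
title: "Methods: labelling selective sweeps in structured diversity panels"
author: "eigenSweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: labelling selective sweeps in structured diversity panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenSweeps)
```

## The problem

Crop diversity panels that mix landraces with modern cultivars carry the
footprint of a century of breeding: genomic regions where allele
frequencies were driven apart between the two germplasm groups.
`eigenSweeps` labels such selective sweeps from a biallelic genotype
matrix (presence/absence and SNP markers, haploid-coded 0/1 with missing
values), a genetic map in centimorgans, and sample metadata (era,
origin, optional subpopulation label and covariates).  The chain is:

1. marker quality control (unmapped, missingness, minor allele
   frequency, duplicate patterns);
2. Nei gene-diversity decomposition and gene flow between
   subpopulations;
3. linkage-disequilibrium (LD) decay on the genetic map;
4. principal coordinates (PCoA) on the simple matching coefficient;
5. a mixed-linear-model association scan that uses the top PCoA
   eigenvectors as phenotypes;
6. clustering of significant associations into QTL hotspots at the LD
   scale; and
7. a dual-allele frequency rule that labels the markers actually swept.

Each stage is an exported function; `runPipeline()` strings them
together and writes every table plus a manifest.

## Statistical models

### Diversity and gene flow

For a biallelic locus with allele frequency $p$, the gene diversity is
$H = 1 - p^2 - q^2$.  Over a partition of the samples into groups the
package reports total diversity $H_T$ (computed from the unweighted mean
of the group allele frequencies per locus), the mean within-group
diversity $H_S$, their difference $D_{ST} = H_T - H_S$, the
differentiation coefficient $G_{ST} = D_{ST} / H_T$, and the gene-flow
estimate $Nm = 0.5\,(1 - G_{ST})/G_{ST}$.  $G_{ST}$ and $Nm$ are always
computed from the unrounded components: rounding $G_{ST}$ to two digits
first can shift $Nm$ by several percent, which is why a table printed at
two decimals will not reproduce $Nm$ from its own rounded entries.
Weighting is a genuinely open choice here; the package uses Nei's
unweighted form (each group counts equally regardless of size) for both
$H_T$ and $H_S$.  Loci fixed in every group contribute zero to every
component but stay in the denominator, so marker panels remain
comparable.  $G_{ST} = 0$ reports $Nm = \infty$ with an explicit flag.

Both PIC and gene diversity are reported per marker.  The two are often
conflated for biallelic markers: gene diversity caps at 0.5 at $p =
0.5$, while the Botstein polymorphic information content
$\mathrm{PIC} = 1 - p^2 - q^2 - 2p^2q^2$ caps at 0.375.  Output labelled
PIC always uses the Botstein formula.

### LD decay

Within each chromosome, all marker pairs at map distance $\le$ 50 cM
(the sliding window) contribute $r^2$, the squared Pearson correlation
of the 0/1 call vectors over jointly non-missing samples, with the
haploid $\chi^2 = n r^2$ (1 df) significance approximation.  Pairs pool
by genome (A/B).  A local-linear LOESS of $r^2$ on distance (span 0.5)
is evaluated on a 0.01 cM grid; the decay distance is where the curve
first falls to the genome's mean $r^2$.  Two numerical guards matter:

* **Binning.** `loess()` cost grows super-linearly; at $3\times10^5$
  raw pairs a single fit takes minutes.  Above 20,000 pairs the package
  therefore bins pairs to 0.1 cM and fits the count-weighted bin means;
  the mean $r^2$ (the critical value) always uses the raw pairs.  An
  exact mode remains available (`bin_threshold = Inf`), and the two
  agree closely on synthetic decays.
* **Resolution.** A span-0.5 smoother over a 50 cM window has an
  effective bandwidth of tens of cM.  When the true decay happens in
  the first 1-2 cM and the pair-distance density is flat (as in the
  package's Markov-chain LD simulator), the smoothed curve smears the
  short-range drop and the intercept overshoots severalfold.  Real
  dense maps concentrate pairs at short distances, which localises the
  LOESS bandwidth; the parameter-recovery tests therefore run the
  estimator with the window near the decay scale (5 cM), where recovery
  is within about 20% of the planted truth.  This is a documented
  limitation of the LOESS-intercept estimator, not of the simulator.
* **Degenerate curves.** A flat curve that starts at or below its own
  mean cannot cross it from above; the decay is reported as 0 with a
  `starts_below_mean` flag.  Downstream, the hotspot half-window is
  `max(decay per genome)` rounded *up* to 0.5 cM, so a degenerate 0
  still yields a usable clustering window; an explicit
  `decay_override_cM` (e.g. the conventional 1 cM) bypasses estimation.

### Ordination

The simple matching distance between samples is
$d_{ij} = 1 - \text{matches}/\text{jointly scored markers}$.  For 0/1
calls this equals the *squared* Euclidean distance divided by the marker
count, so it is a squared-type dissimilarity: Gower double-centering of
$-d^2/2$ (classical PCoA) therefore does **not** reduce to a covariance
PCA of the genotype matrix, and some eigenvalues can be negative.
Negative eigenvalues are reported but excluded from the
variance-explained denominator.  Axis signs are arbitrary in any
eigendecomposition; the package orients every axis so the landrace-era
group mean is non-negative, which makes group splits and downstream
tables reproducible across platforms.  Pairs of samples with zero joint
coverage are a hard error naming the pair.

### The eigenvector association scan

The scan regresses each standardised top-$k$ PCoA eigenvector $y$ on
every marker under the mixed model
$y = X\beta + Zu + e$, $u \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$, with a VanRaden-style centred-crossproduct
kinship $K$ and fixed effects: intercept, six genotype principal
components, optional covariates (e.g. heading date), and the tested
marker.  Variance components are profiled by REML on the spectral
decomposition of $K$, optimising the single ratio
$\delta = \sigma_e^2/\sigma_g^2$; with P3D (the default) they are
estimated once per phenotype on the null model and reused for every
marker, reducing each marker test to one generalised-least-squares fit
in the whitened basis.  The marker coefficient is tested by a Wald
t-test with $n - p - 1$ degrees of freedom, which makes the scan
*exactly* equal to OLS when $K = I$ (a property the tests assert to
1e-8).  Markers collinear with the fixed effects are flagged and
reported at $p = 1$.

**Collinear phenotype guard.**  Eigen-phenotypes are themselves
structure axes, and the PC fixed effects are structure axes of the same
matrix.  On clean simulated panels the top PCoA axes are numerically
inside the PC span ($R^2 > 0.999$): regressing an axis on covariates
that contain it leaves a null model whose residual is machine noise,
and every marker test becomes meaningless — measured sweep-detection
sensitivity collapses to zero.  The package therefore excludes, per
phenotype, any PC whose absolute correlation with that phenotype
reaches `pc_cor_max` (default 0.9), and reports the exclusions in the
scan attributes.  With the guard in place the kinship term still
controls drift-driven inflation (the published eigenvector-scan
approach), and planted sweeps are recovered; with `pc_cor_max = 1` the
guard is off and the degenerate behaviour can be reproduced.  On real
panels, where phenotype axes and PCs come from different marker
treatments, the guard typically triggers only for the leading axes.

Two significance thresholds are derived: the fixed moderate threshold
$-\log_{10} p = 3$, and the Benjamini-Hochberg FDR threshold at
$\alpha = 0.05$ applied to the *pooled* p-values of all markers across
all ten eigenvectors, reported as $-\log_{10}$ of the largest p-value
declared significant ($\infty$, flagged, when nothing is).  Pooling is
used because a single genome-wide threshold is what the hotspot stage
consumes; per-eigenvector BH is available by flag.

### Hotspots and the sweep rule

Significant associations (records are marker-by-eigenvector pairs)
chain into QTL hotspots by single linkage: two records merge when their
map positions lie within $2\times$ the LD-decay distance.  Chains with
at least two records become hotspots with confidence interval
$[\min - \text{decay}, \max + \text{decay}]$ clipped at 0 cM;
single-record chains are set aside as singletons.  The chaining (rather
than fixed-width windows) is what lets hotspot intervals grow far
beyond $2\times$ decay when associations tile a region.  Clustering is
order-independent and equals the brute-force transitive closure of the
pairwise distance relation (asserted on small cases).

Markers with best $-\log_{10} p > 5$ are re-ordinated; samples split by
the sign of the first axis (oriented so the landrace-majority side is
group 2 — era labels orient the axis but never assign samples); and a
marker is labelled swept when each group's major allele reaches a
frequency of **at least** 0.80 and the two major alleles differ.  The
threshold is inclusive because published worked examples pass markers
at exactly 0.80.  Major-allele ties at 0.5 resolve to the 0-coded
allele (they can never pass anyway at thresholds above 0.5).  A marker
with no scored call in a group cannot pass and is flagged.

## The synthetic panel generator

`simulatePanel()` emulates the dimensions of a Mediterranean durum
panel: 387 samples — five subpopulations of 19/119/43/116/39 plus 51
admixed — on 14 chromosomes (1A-7B, 152.1 cM each, about 2129 cM
total).  Neutral subpopulation allele frequencies follow the
Balding-Nichols model around ancestral frequencies uniform on
(0.05, 0.95); the drift parameter defaults to `divergence_F = 0.08`,
chosen once to reproduce a whole-panel $G_{ST}$ near 0.08, the
differentiation typical of such panels.  Admixed samples draw each
marker from one of two sample-specific source subpopulations with equal
probability.  A fifth of the markers receive MCAR missingness at rates
up to 30%; about 1% of markers are duplicated verbatim (opposite marker
type, same map position); 5% are left unmapped; 80% are
presence/absence markers; and a heading-date covariate (days, around
118 with a 7-day marker effect and 3-day noise) tracks one designated
sweep marker, mimicking a photoperiod locus.

Sweeps are planted as **regions**, not isolated loci: each of the 20
sweep regions comprises 3 markers within 1 cM whose frequencies
separate the landrace block (SP1-SP3) from the modern block (SP4-SP5)
by at least `sweep_delta = 0.7`, with the high allele alternating
randomly between blocks.  Selection drags linked hitchhiking loci, and
hotspot detection (which requires at least two member associations) is
defined at the region scale; a generator of isolated single-marker
sweeps would test a different, biologically flat scenario.
`truthReport()` scores a run against the generator truth:
region-level sweep sensitivity, false-hotspot rate, $G_{ST}$ error
against the planted frequencies, and duplicate recovery.

What the generator does *not* emulate: background LD between neutral
loci (a separate Markov-chain emitter, `simulateLDPanel()`, provides
planted exponential LD decay for the decay estimator), demographic
history (bottlenecks, time-varying migration), genotyping error beyond
MCAR missingness, and non-random missingness.  Passing recovery tests
on this generator therefore demonstrates correctness of the statistics
under the stated model, not robustness to every artefact of real
DArTseq data.

## Defaults and problem sizes

All analysis defaults are the standard settings of this kind of study:
MAF 5%, SNP missingness 30% (PAVs are not missingness-filtered,
mirroring the asymmetric bookkeeping of DArTseq panels), duplicate
overlap 0.9, LD window 50 cM at $p < 0.001$, ten eigen-phenotypes, six
PCs, moderate threshold 3, FDR 0.05, top-marker threshold 5, allele
rule 0.80.  The generator default of 5000 markers keeps a full pipeline
run near 15 s on one core, so the test suite's ten-seed sensitivity
study and the twenty-seed decay-recovery study complete in a few
minutes; the panel scales to the full 24,000-marker size when needed.

## Known limitations

* The LOESS-intercept decay estimator is biased upward when the decay
  scale is far below the window span (see above).
* REML uses a single genetic variance component; no compressed-MLM
  clustering of individuals is implemented (a performance device, not a
  statistical requirement, at this scale).
* Duplicate detection requires agreement on at least 90% joint
  coverage; heavily missing duplicate pairs are intentionally not
  collapsed.
* The allele rule evaluates group major alleles only; multi-allelic
  markers are out of scope (the containers are strictly biallelic).
* $H_S$ for pairs is unweighted; size-weighted alternatives would shift
  pair tables by a few hundredths at unequal group sizes.
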