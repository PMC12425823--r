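---
title: "Purity- and copy-number-aware analysis of tumor methylome evolution"
author: "methevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity- and copy-number-aware analysis of tumor methylome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methevolve)
library(dplyr)
```

# The problem

Bulk bisulfite sequencing of a tumor biopsy measures a mixture: the
methylation signal of cancer cells diluted by normal infiltrating cells, and
re-weighted wherever the tumor genome has gained or lost copies. Multi-region
designs add a second axis — the same tumor sampled at several sites — which
lets methylation changes be timed (clonal events present in every region
versus subclonal events in a subset) and compared against copy-number
alterations affecting the same genes. `methevolve` implements the
computational chain for this setting: deconvolution of bulk methylation and
epiallele discordance into cancer-cell-specific estimates, tumor–normal
differential methylation at position, region and promoter level, intratumor
heterogeneity distances, a dN/dS-analogous selection ratio for promoter
hypermethylation, driver ranking from differentially hypermethylated cytosine
ratios, copy-number–methylation interplay and timing, dosage-compensation
scanning, chromatin-transition detection at co-amplified loci, and an
expression-threshold dichotomization transferable to expression-only cohorts.

Because real multi-region methylomes of this kind are controlled-access, the
package ships a synthetic cohort generator that reproduces the statistical
structure every stage assumes. All quantitative claims in this vignette are
properties the test suite and `scripts/acceptance.R` verify on those
synthetic cohorts; none are measurements on patient data.

# The mixture model and its inversion

At a CpG with bulk methylation rate $m_b$, matched-normal rate $m_n$, tumor
total copy number $n_t$, normal copy number $n_n$ (usually 2) and tumor
purity $\rho$,

$$m_b = \frac{m_t\,n_t\,\rho + m_n\,n_n\,(1-\rho)}{n_t\,\rho + n_n\,(1-\rho)},$$

so the cancer-cell-specific rate is recovered as

$$\hat m_t = \frac{m_b\,(n_t\rho + n_n(1-\rho)) - m_n\,n_n(1-\rho)}{n_t\,\rho}.$$

The identical algebra applies to the proportion of discordant reads (PDR),
the per-locus fraction of multi-CpG reads carrying both methylated and
unmethylated calls. `mix_forward()` is kept as a public function precisely so
it can serve as the brute-force oracle for the inversion: the test suite
verifies `deconvolve(mix_forward(x)) == x` to $10^{-12}$ over random
parameter grids.

Numerical choices:

* Sampling noise can push $\hat m_t$ outside $[0,1]$. Estimates are clipped
  and flagged (`clipped = TRUE`) rather than dropped, preserving site counts
  for downstream ubiquity denominators. For *cohort-level* aggregation the
  unclipped estimates are averaged first and the aggregate clipped once,
  because per-site clipping is biased near the 0/1 boundaries.
* CpGs falling in copy-number segment gaps are retained with
  `excluded = "no_segment"`; sites with $n_t\rho = 0$ (homozygous deletion in
  a pure tumor) are an explicit error at the scalar level and an exclusion
  reason at the cohort level — the tumor rate is undefined there.
* Purity appears in some derivations as both $\rho$ and $p$; it is one
  parameter here.

# Differential methylation

A CpG is a DMP in a sample when $\hat m_t - m_n$ exceeds 0.2 in absolute
value at $P < 0.01$. The p-value deserves a note: since

$$\hat m_t - m_n = (m_b - m_n)\,\frac{n_t\rho + n_n(1-\rho)}{n_t\rho},$$

the null "deconvolved tumor rate equals normal" is *algebraically identical*
to "bulk rate equals normal". `call_dmps()` therefore tests the raw bulk
versus normal read counts with a two-proportion z-test (no continuity
correction), falling back to Fisher's exact test when any expected cell of
the 2×2 table is below 5. This keeps the test exactly calibrated without
inventing "effective" read counts, and the exact branch is cross-checked
against `stats::fisher.test` in the tests. A single tumor region at 30×
coverage and moderate purity has little power for one CpG at these
thresholds, so `call_dmps_cohort()` additionally pools read counts across
all tumor samples (normals counted once per patient) for locus-level
recovery; the per-sample caller remains the input for everything clonality-
related. A third caller, `call_dmps_methsig()`, implements the distinct
definition used by driver ranking: a chi-squared count test at 15% FDR
(Benjamini–Hochberg within sample, a deliberate reading of an ambiguous
protocol), hyper direction required.

DMRs chain covered CpGs within 100 bp into bins; a bin is a DMR when it has
four or more *consecutive* same-direction DMPs and at least five in total.
"Consecutive" means adjacent covered CpGs in the series — missing coverage
does not break a run, because absent CpGs are absent from the series. The
implementation is validated against a literal brute-force bin-and-scan
oracle on hundreds of random instances. Promoter status per gene and sample
is then driven by DMRs, not DMPs: a promoter (2,500 bp upstream to 250 bp
downstream of the TSS, strand-aware, hence always 2,751 bp) is `hyper` if at
least one hyper-DMR overlaps it; a promoter with covered CpGs but no
qualifying DMR is `none`, and a promoter with no covered CpGs is missing —
the three-way distinction matters for ubiquity denominators.

# Driver ranking from DHcR

The differentially hypermethylated cytosine ratio (DHcR) of a gene in a
sample is the fraction of its profiled promoter CpGs called hyper by the
chi-squared caller. `methsig_rank()` selects the highest-purity region per
patient (ties broken lexicographically), filters genes with no normal-tissue
expression (mean counts < 1), and fits a beta regression of DHcR on nuisance
covariates — deconvolved promoter PDR, normal promoter methylation, normal
expression, promoter CpG count — per sample. The beta likelihood is fitted
with `mgcv::gam(family = betar())`; DHcR values are squeezed into the open
interval with the usual $(y(n-1)+0.5)/n$ transformation. Each gene's
one-sided p-value for observed exceeding expected DHcR comes from the fitted
beta distribution; p-values are combined across samples by Stouffer's method
with equal weights (the combination scheme is not prescribed anywhere we
could follow, so the simplest defensible one is used) and BH-adjusted.
Replication-timing covariates are omitted by default since they require
external genome tracks; the covariate set is an argument.

# Heterogeneity distances

ITMD is the pairwise Pearson distance ($1-r$, range $[0,2]$) between region
methylation-rate vectors over the CpGs covered in both members of a pair;
intra-patient pairs measure intratumor heterogeneity and cross-patient pairs
the between-tumor scale. Shared coverage is resolved per pair (not
cohort-wide) to maximize usable CpGs, and `n_features` is reported so users
can enforce a floor (default 5,000 for real data; the examples lower it for
small simulations). Distances within $10^{-12}$ of 0 or 2 are snapped to the
exact boundary so that duplicated regions are at distance exactly 0.
Zero-variance vectors make the correlation undefined; such pairs are skipped
with a warning. ITED applies the same distance to expression after
`log2(x+1)` and per-gene z-scoring, reporting each region's mean distance to
its sibling regions. Both intra- and inter-patient modes use all eligible
pairs by default.

# The regulatory-selection ratio

Promoter CpGs that are hypermethylated somewhere in the cohort are
classified *regulatory* when the samples in which they are hyper express the
cognate gene significantly lower (two-sample t-test on `log2(x+1)`,
$P<0.05$, lower mean) and *nonregulatory* otherwise; CpGs whose groups are
smaller than two samples get a missing assignment and drop out of all
denominators. Per gene, events are indexed by covered (CpG, sample) pairs
— the reading that makes "the number of hypermethylation events in all the
DMPs covered in every sample" literal — with a `mode = "cpg"` alternative
in which a CpG counts once if hyper anywhere. With $H_i$ the event indicator
and $R_i$ the CpG's regulatory status,

$$\frac{M_R}{M_N} =
 \frac{(\sum_i H_iR_i + 1)/(\sum_i R_i + 1)}
      {(\sum_i H_i(1-R_i) + 1)/(n - \sum_i R_i + 1)}.$$

Both components lie in $(0,1]$, the ratio is finite and positive, and genes
lacking either class are non-calculable. Deviation from 1 is tested with an
exact conditional test on the 2×2 event table (valid at the small counts the
pseudocounts anticipate), BH-adjusted per subtype, classes `gt1`/`lt1` at
$q<0.05$. Ratios are reported raw and log2-transformed.

One subtlety the synthetic experiments exposed: the two-step procedure
(assign by expression, then count events) couples the assignment to the
event patterns, so a *label-independent* null is needed to ask whether the
ratio statistic itself depends on promoter CpG count. The acceptance check
therefore randomizes regulatory labels across hyper CpGs of null genes
before computing that correlation; with pipeline assignments the same check
would confound assignment selection effects with the statistic's own
behavior (and rest on far fewer calculable genes).

# Copy-number interplay, timing, dosage compensation

Per gene and region, copy-number state is taken at the TSS (promoters
spanning a segment boundary are flagged): `loss` below rounded ploidy,
`amplification` at ploidy + 2 or more, `gain` in between. The amplification
threshold is a package choice — no numeric definition was available to
follow — and is an argument. Interplay per gene and tumor:
`double_hit` (hypermethylation and loss in the same region), `parallel`
(both present, never together), `single_mechanism`, `other`, `none` — a
partition, which the tests assert over all 16 two-region event patterns.
Concordant regions pair hypermethylation with loss, or hypomethylation with
gain/amplification. Timing uses ubiquity: an event is clonal in a patient
when present in all of at least two assessable regions. The timing
contingency test (chi-squared without continuity correction, exact fallback
below expected counts of 5) exposes its table and statistic; no claim is
made to reproduce any particular published p-value from printed event
counts, whose underlying table construction is ambiguous.

Dosage compensation: per gene with at least three amplified and three
non-amplified tumor regions, the difference in median promoter methylation
between strata (flag at > 0.2) and an expression class from a t-test on
`log2(x+1)` (`scaling` up, `antiscaling` down, `buffered` otherwise). A
flagged, buffered gene is the compensation signature — extra copies silenced
by promoter methylation.

# Chromatin transitions at co-amplified loci

Candidate pairs are each annotated oncogene with every gene within 20 Mb on
the same chromosome (assumed to share the copy-number event); copy-number
input for this analysis can be restricted to events of at least 50 Mb with
`filter_cnas_for_allchat()`. Histone H3K4me3/H3K27me3 window sums (2 kb
upstream of the TSS) are normalized by the average of the normal samples
with a pseudocount of 1 and log-transformed. In the gained/amplified
stratum, one-sided t-tests require the oncogene's tumor−normal methylation
differential to be lower than the passenger's, its H3K4me3 log-ratio higher
and its H3K27me3 log-ratio lower, each at $\alpha = 0.05$.

The non-gained stratum requires the *absence* of that divergence. Two
design decisions here:

* "Equal to or more than" is implemented as a no-divergence check — the
  gained-direction test must not be significant — because a reverse
  one-sided test sits at $p \approx 0.5$ for genuinely equal profiles and
  could never pass; the reverse-significance reading remains available via
  `non_gained = "reverse"`.
* The no-divergence rejection uses its own level (`alpha_non_gained`,
  default 0.01). A pair must clear three independent no-divergence checks;
  rejecting each at 0.05 discards truly divergent pairs at roughly
  $3 \times 5\%$ by chance, while a pair whose divergence is
  locus-intrinsic rather than copy-number-driven rejects at far smaller p
  and is still excluded.

A verdict is true only when every stratum test passes; without histone data
the methylation tests decide alone and the verdict is marked `partial`.

# Expression-threshold dichotomization

On a cohort with both methylation and expression, one region per tumor is
drawn uniformly, stratum statistics (mean, Q1, Q2, Q3) of expression in
hypermethylated versus non-hypermethylated tumors are computed, and the draw
is repeated 100 times; per-replicate Q3 values are retained. With one region
per tumor every replicate is identical, so the bootstrap variance is exactly
zero — asserted exactly in the tests. Prediction labels a region `low` when
its expression is strictly below the aggregated Q3 of the *hypermethylated*
stratum (the semantically coherent stratum: expression below the bulk of
hypermethylated tumors; the other stratum is reachable via the `stratum`
argument, and strictness at the threshold is documented as ties-to-high).
A tumor with any `low` region — including region-discordant tumors — is
classified as having hypermethylation-dependent reduced expression.

# The synthetic cohort generator

`sim_config()`/`simulate_cohort()` encode the study conditions:

* **Baseline methylation** is a two-component Beta mixture with modes near
  0.05 and 0.95 (promoter CpGs predominantly unmethylated, intergenic
  predominantly methylated), because the downstream 0.2 effect-size
  threshold presumes near-saturated baselines.
* **Layout**: genes every 400 kb across at least five chromosomes; promoter
  CpG counts vary (Poisson around the density implied by `n_cpgs`), and
  promoter CpGs cluster in a CpG-island-like core around the TSS with ~45 bp
  mean spacing. The clustering matters: RRBS covers promoters as dense
  islands, and the 100 bp DMR chaining rule is vacuous on uniformly spread
  CpGs.
* **Planted events**: hyper DMPs are planted as whole-promoter gene-level
  events (so DMRs have run structure) with per-patient clonal/subclonal
  region patterns and a per-(CpG, patient) participation of 0.9, which
  restores the within-promoter pattern variation per-CpG analyses need;
  hypo DMPs are planted per CpG. Effect size defaults to 0.3 (the floor the
  callers assume is 0.2). `dmp_patient_fraction` below 1 creates
  between-tumor variation, needed when learning expression thresholds.
* **Selection genes** (`n_mrmn_genes`): a latent per-sample silencing event
  at rate 0.8 drives both the hypermethylation of the gene's regulatory
  CpGs and the expression drop; nonregulatory CpGs are hypermethylated
  independently at rate 0.1. Coupling assignment power to the event
  structure this way is what makes the two-step selection analysis testable
  at all: fully independent per-CpG events of one gene cannot carry a
  per-CpG expression signal, because expression is a gene-level quantity.
* **Copy number**: patient-level segmentations (1–3 breakpoints per
  chromosome, $n_t \in 1..4$ with configurable weights) inherited by
  regions, each segment independently redrawn in 15% of regions — the
  region-level SCNA heterogeneity multi-region tumors show, and the source
  of subclonal losses for the timing analysis. Ploidy is the length-weighted
  mean. Amplicons overlay $n_t = 5$ across the oncogene ± 20 Mb in half the
  patients; all co-amplified promoters open mildly (methylation −0.03,
  H3K4me3 up, H3K27me3 down) while designated passengers close instead
  (methylation +0.3, marks reversed) with expression held at baseline. The
  locus-wide mild opening is deliberate: chromatin response to amplification
  is regional, and it is the *passenger's divergence from its locus* that
  the detector must find — otherwise every neighbor of an opening oncogene
  would be called.
* **Expression** is lognormal (natural-log sd 0.3) around a per-gene
  baseline, scaled by bulk-averaged gene dosage (switchable off for
  analyses whose stated noise model excludes dosage effects), and reduced
  multiplicatively (default 0.5) in samples where a regulatory CpG event is
  present.
* **Histone signals** are Poisson window sums around open/closed levels;
  the normal reference is drawn as a 20-fold-deeper pool, reflecting that
  reference epigenomes are deeply sequenced aggregates. This is not
  cosmetic: a noisy per-gene normal mean induces correlated per-gene
  offsets in every tumor log-ratio, which t-tests across samples read as
  real divergence.
* **Heterogeneity structure**: patient-specific tumor-compartment
  signatures (rate sd 0.05) and smaller region effects (sd 0.02) make
  intra-patient distances smaller than inter-patient ones.
* **Epialleles**: reads draw their compartment with probability
  $n_t\rho/(n_t\rho + n_n(1-\rho))$ and are discordant with that
  compartment's planted PDR, so bulk discordance converges to the forward
  mixture.
* One global seed; each stage derives its own substream, so stages are
  independently regenerable and identical configurations are byte-identical.

What the generator does *not* model — and what passing tests therefore do
not show about real data: sequencing error and bisulfite conversion failure,
allele-specific methylation (about 5% of real loci, which total-CN
deconvolution cannot resolve), MspI fragment-size coverage structure,
correlated methylation along chromosomes beyond planted promoters, purity
and ploidy estimation error (both are inputs here, never inferred), and any
realistic gene-gene expression covariance.

# Calibration nulls and problem sizes

Type-I control is assessed on *complete-null* cohorts: no planted DMPs and
patient/region signature effects set to zero, because patient-specific
tumor-compartment signatures are true tumor–normal differences, not false
positives. On such cohorts the per-sample DMP call rate stays below
$0.01 + 3\,\mathrm{SE}$ (the delta filter and exact fallback make it
conservative in practice), no gene reaches a significant selection-ratio
deviation, and the dosage scan — run on cohorts with amplified loci but no
planted methylation response — flags at most 5% of null genes.

The verification cohorts are sized to run comfortably on one CPU: 20
patients × 3 regions × 50,000 CpGs at 30× for recovery; 400,000 tests for
the null rate; 12,000 CpGs × 60 samples at 100× for the selection analysis
(deep coverage and 0.6–0.9 purity are the conditions under which per-sample
event detection supports the 80%-versus-10% contrast); ten five-patient
cohorts for the heterogeneity direction; ten planted amplicons among 100
candidate pairs for the chromatin-transition recall; and a 16-patient
two-region cohort split 8/8 for threshold transfer. `scripts/acceptance.R`
reruns all of these from scratch and prints each measurement.

# A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 4, regions_per_patient = 3,
                  n_cpgs = 4000, n_genes = 80, seed = 42)
cohort <- simulate_cohort(cfg)

deconv <- deconvolve_cohort(cohort$methylation, cohort$samples,
                            cohort$segments)
dmps <- call_dmps(deconv)
dmrs <- call_dmrs(dmps)
status <- promoter_methylation_status(dmrs, cohort$promoters, deconv)

events <- classify_gene_events(status, cohort$segments, cohort$samples,
                               cohort$promoters)
classify_interplay(events)

rates <- select(deconv, chrom, pos, sample_id, m_t_hat)
intra <- compute_itmd(rates, cohort$samples, "intra", min_features = 500)
inter <- compute_itmd(rates, cohort$samples, "inter", min_features = 500)
plot_itmd(dplyr::bind_rows(intra, inter))
```

# Known limitations

* The per-CpG DMP test stands in for an unpublished reference test; it is
  validated by calibration and power simulation, not by equivalence to the
  original.
* Allele-specific methylation is not handled; affected loci enter the
  concordant/discordant counts as-is.
* The MethSig p-value combination (Stouffer) and the per-sample scope of
  its 15% FDR are documented choices where the protocol is silent.
* Beta-regression non-convergence flags and skips the affected sample
  rather than the gene; with very few genes per sample the ranking is
  underpowered rather than wrong.
* `timing_contingency()` reports the table it tested; published
  timing p-values cannot be audited without the underlying table.
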