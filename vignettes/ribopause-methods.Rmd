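---
title: "Statistical methods and design choices in ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in ribopause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

# Scope

`ribopause` detects single-nucleotide ribosome pause sites from footprint
coverage, tests them for condition dependence, and characterises the
amino-acid context around crosslink or pause anchors. The pipeline starts
from footprints or P-site coverage in transcript coordinates: read
trimming, alignment and deduplication are upstream of this package. A
synthetic-data generator with full ground truth stands in for deposited
sequencing data, so every stage is verifiable end to end.

All coordinates are 0-based half-open in transcript space. The CDS
includes its terminal stop codon; derived protein sequences exclude it.

# The pause-site model

For one gene and one replicate library, the per-nucleotide P-site counts
over the CDS are treated as draws from a single negative binomial
NB(μ, k), variance μ + μ²/k. A pause site is a position whose count is
improbable under that law. The procedure per gene and replicate:

1. **Trim**: remove the m = ⌊0.05 L⌋ largest and m smallest counts (ties
   broken leftmost-first). Trimming protects the fit from the very pauses
   being sought, which occupy far less than 5% of positions.
2. **Fit**: estimate (μ, k) from the retained counts.
3. **Test**: every position — including the trimmed ones, since a pause is
   by definition a top outlier and must remain testable — gets the
   inclusive exceedance p-value P(X ≥ x). Inclusive tails are the standard
   convention for discrete exceedance and make p(0) = 1 exactly.

Replicate p-values are combined with Fisher's method, −2Σln pᵢ against
χ² with 2R degrees of freedom, and positions with combined p strictly
below 10⁻⁷ are called. Per-replicate fits (rather than one pooled fit)
keep the combined p-values a product of independent replicate evidence.

## Fitting a distribution to a trimmed sample

The naive estimator — method of moments on the retained counts
(μ̂ = m̄, k̂ = m̄²/(s² − m̄)) — is exposed as `fit_nb()` and is exact for
untrimmed samples. Applied to a rank-trimmed sample, however, it is
systematically biased: removing 5% of the probability mass from each tail
shrinks the sample variance far more than the mean, roughly doubling k̂
for realistic parameters, which makes the exceedance p-values strongly
anti-conservative (measured ~3–10× inflation of tail fractions across
μ ∈ [1, 50], k ∈ {0.5, 5}).

`call_pauses()` therefore defaults to `fit_nb_trimmed()`: it solves for
the (μ, k) whose *expected trimmed moments* — the mean and variance of the
central 1 − 2f portion of NB(μ, k), with boundary atoms partially removed
to match rank-based trimming of a discrete sample — equal the observed
trimmed moments. This estimates the full per-position count law while
keeping the robustness that motivated trimming: planted pauses sit in the
removed tail either way. On simulated NB(10, 5) data the corrected fit
recovers both parameters within a few percent where the naive fit returns
k ≈ 11, and null combined p-values become conservative (the empirical
fraction below α stays under α, because discrete inclusive tails are
conservative by construction). Equidispersed data fall back to a
trimming-corrected Poisson; all-zero vectors are flagged degenerate and
produce p = 1 everywhere. The naive and maximum-likelihood estimators
remain available via `fit_method = "mom"` / `"mle"`.

## The initiation mask

Real profiles — and the generator, which needs it for offset calibration —
carry a strong footprint peak at the start codon. That peak reflects
initiation, not an elongation pause, so `call_pauses()` excludes the first
`mask_start = 5` codons from *calling* (their p-values are still
reported). Planted pauses always sit downstream of a charged tract and are
unaffected.

# P-site offsets and the expression filter

Offsets are calibrated per read length as the arg-max, over a search
window of 8–16 nt, of the histogram of (cds_start − 5′ end) distances;
ties break toward the smaller offset, and lengths with fewer than 100
reads stay uncalibrated and are excluded (and counted) downstream. The
window brackets the canonical ~12 nt 5′-to-P-site distance without
hard-coding it.

Genes enter the analysis when their normalized CDS coverage — mean P-site
count per CDS nucleotide — is at least 1 in *every* library of every
condition. The threshold is inclusive. An RPKM-based variant of the filter
is available (`method = "rpkm"`), since expression cutoffs are sometimes
phrased that way; mean coverage is the default because it is the quantity
the NB fit actually sees.

# Differential pause analysis

Pause-site counts are compared between conditions with a negative binomial
likelihood-ratio test: group-mean model against shared-mean model at a
common dispersion φ, p from the χ²₁ upper tail. Normalization uses
median-of-ratios size factors computed on gene-level CDS totals (falling
back to total-count ratios when fewer than 10 genes are everywhere
nonzero), rescaled to geometric mean 1.

The common dispersion is a moment estimator pooled across sites: for each
site and group the within-group variance of normalized counts estimates
c·μ_g + φ·μ_g² (c = mean 1/size factor); φ is the regression of the
variance excess on an approximately unbiased estimate of μ_g² (m_g² minus
its sampling variance), pooled over sites and groups and floored at 10⁻⁸.
Using *group* means rather than overall site means matters: with strongly
differential sites, an overall-mean regressor absorbs the between-group
signal into the dispersion and inflates it.

Fold changes use a 0.5 pseudo-count on normalized group means
(log2((m₂ + 0.5)/(m₁ + 0.5))), oriented perturbed over control, so zero
counts never produce infinite log-ratios. Site p-values are BH-adjusted;
the significance threshold is FDR ≤ 0.05.

**Gene coherence.** Gene-level differential occupancy is the same NB LRT
applied to summed CDS counts, BH across genes at FDR 0.05. Significant
sites in differential genes whose |log2FC_site − log2FC_gene| < 0.8 are
labelled `removed_coherence` — their change merely tracks the gene;
significant sites in non-differential genes are always retained.
Differential count testing of this kind is usually delegated to edgeR or
DESeq2; this package uses the self-contained LRT above instead, because
only the differential flag and the two fold changes feed the coherence
filter and a self-contained test keeps the pipeline fully verifiable
against its own generator. Reproducing edgeR's exact p-values (exact-test
flavor, TMM normalization, dispersion moderation) is a non-goal.

A caveat worth stating: with few replicates and substantial replicate
dispersion (φ ≈ 0.2, i.e. the generator's default nb_size = 5), reaching
FDR 0.05 at 3 vs 3 replicates requires an observed |log2FC| of roughly
1.5–1.8. Under a pure 2-fold gene-level shift, selection on significance
(winner's curse) therefore concentrates the *significant* sites at
observed fold changes near or beyond gene_fc + 0.8, and the coherence rule
removes a smaller share of them than it would in a high-power regime. The
filter's logic is exact (verified against worked examples); its yield
under selection depends on power.

# Context enrichment

Anchors are codon indices: peak centers map via
⌊(center − cds_start)/3⌋ (UTR centers are excluded and tallied), pause
sites via ⌊position/3⌋ — the P-site codon, the natural default when no
offset codon is specified. The peak
*center* is the floor midpoint of the peak interval — the
least-assumption choice when a summit is not recorded.

For offsets d ∈ [−30, +30], f(a, d) is the frequency of residue a at
codon + d over all anchors in range; the background g(a) is the residue
frequency over the full CDSs of anchor-bearing transcripts, which controls
for target composition (a proteome-wide background vector can be supplied
instead). Enrichment is log2((f + ε)/(g + ε)) with ε = 10⁻⁴; the log-ratio
form with an explicit permutation null was chosen over z-scores so the
reported quantity stays interpretable as a fold.

The permutation null redraws each anchor uniformly within its own
transcript's codon range, preserving per-transcript anchor counts and
hence transcript-level composition. It yields per-cell two-sided empirical
p-values with a +1 correction and, as a family-wise reference, the 95%
quantile of the per-permutation maximum |log2 enrichment| over all
20 × 61 cells (`max_envelope`). Positions whose residue is X (from N
bases) are dropped from counts rather than imputed.

Charge classes are positive = {K, R}, negative = {D, E}; histidine is
treated as neutral because it is mostly uncharged at cytosolic pH — the
class membership is a package decision, stated here because the source
analyses never enumerate it. Region distributions classify peak centers
into 5′UTR/CDS/3′UTR and histogram center/length into equal bins;
set-overlap significance is the hypergeometric upper tail
P(X ≥ overlap) with fold = observed/(|A||B|/|U|).

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
sequencing reads per se:

* transcripts with random UTRs (30–60 nt) and CDSs of 600–3000 nt;
  non-overlapping charged tracts (Poisson rate 2 per gene, 5–12 aa,
  residues E/K, placement resampled up to 100 times before erroring);
* per-gene mean coverage drawn log-normal (meanlog = log 5, sdlog = 1) so
  the coverage ≥ 1 filter boundary is genuinely exercised; per-nucleotide
  counts NB with size k = 5 — a moderate overdispersion; replicates are
  independent draws sharing the mean;
* pauses as single-nucleotide multiplicative elevations (factor 10) at the
  first nucleotide of a codon 1–3 codons downstream of a tract end,
  matching nucleotide-resolution calling; the knockdown condition retains
  fraction 0.2 of the elevation; a start-codon initiation peak (factor 2)
  makes metagene offset calibration identifiable while staying far from
  the pause-calling threshold;
* footprints of 26–34 nt emitted per P-site count with true offsets 11–14
  nt; reads clipped at transcript bounds are dropped and counted, so
  coverage rebuilt from footprints is exactly conserved;
* crosslink peaks centered 1–3 codons downstream of tract ends with
  fold/p columns drawn so a configurable fraction fails the
  8-fold / 10⁻⁵ filter;
* spectral-count tables with Poisson counts, a per-protein true ER
  fraction 0.5 + bias·(u − ½), true interactor labels, and a mock-bead
  background common to interactors and non-interactors.

What it deliberately does **not** model: sequencing error, UMI artifacts,
rRNA contamination, alignment multimapping, codon-level coverage
periodicity, positional autocorrelation, or replicate-correlated
dispersion. Passing recovery checks on this generator therefore
demonstrates the statistical machinery under its stated assumptions — not
robustness to alignment artifacts or to overdispersion structure the
generator lacks.

A uniform gene-level shift applied to *every* gene is absorbed by
median-of-ratios normalization (it is indistinguishable from library
depth), so condition-level occupancy-shift scenarios are generated by
scaling a subset of genes via the `mean_scale` argument of
`gen_coverage()`.

# Fractionation proteomics decisions

Presence requires detection in ≥ 2 of 3 replicates. The oligo-dT
enrichment rule (fold over mock, per experiment) and the presence rule
pull in different directions when a protein goes undetected in one
experiment; the package resolves this by testing the ≥ 2-fold-over-mock ratio in every
experiment where the protein was detected, with a 0.5 pseudo-count for
zero mock totals. Percent-ER excludes zero-total experiments from its
average and returns a flagged NA when every experiment is empty.
High confidence = mRNP-bound AND (ribosome-bound OR RNA-dependent);
curated contaminants are removed via a user-supplied exclusion list and
counted.

# Problem sizes and runtime of the built-in checks

The test-suite calibration and recovery runs use: ~1.1 million positions
(380 genes × 3 kb × 3 replicates) for null calibration of combined
p-values; 60–150 genes at fixed mean coverage 10/nt for pause and
differential recovery; 10⁴ sites for the site-test size check; ~1000
anchors and 150–200 permutations for context enrichment. These sizes give
stable estimates (binomial standard errors well inside the asserted
margins) while keeping the whole suite under a minute of compute for the
acceptance checks.

# Known limitations

* Pause calling assumes a single NB law per gene and replicate; systematic
  within-gene coverage trends (ramps, codon effects) would inflate calls.
* The common-dispersion LRT is mildly anti-conservative at 3 + 3
  replicates (empirical size ~0.06 at nominal 0.05), inherent to
  chi-square asymptotics at this sample size.
* The coherence filter's removal yield degrades under winner's curse at
  high replicate dispersion, as discussed above.
* Offset calibration relies on a start-codon metagene peak; profiles
  without one (e.g. initiation-depleted protocols) need offsets supplied
  externally.
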