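---
title: "Imputation from low-coverage sequencing and polygenic scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputation from low-coverage sequencing and polygenic scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package does

Low-coverage whole-genome sequencing (lcWGS, roughly 0.5–1.2 reads per
genomic position) observes only a minority of sites in any one sample, and
usually with a single read. Nevertheless, because human haplotypes are
mosaics of a modest number of ancestral segments, a phased reference panel
lets one impute accurate expected genotypes — *dosages* in [0, 2] — at every
panel site, and those dosages are all a genome-wide polygenic score (GPS)
needs. `lcgps` implements that whole chain as a self-contained, desk-scale
toolkit: a synthetic-data generator standing in for a reference cohort, a
read simulator, genotype likelihoods, identity-by-state (IBS) custom panel
selection, a genotype-likelihood-aware diploid Li-Stephens imputation HMM, a
genotyping-array comparison arm, polygenic scoring with
principal-component (PC) normalization, and the accuracy metrics used to
judge it all.

Everything is driven by explicit seeds: a fixed configuration and seed
reproduce every object byte-identically.

# The synthetic cohort generator

The generator is a founder-mosaic model, not a demographic simulation. For
each of five populations (labelled after continental super-population
codes), founder haplotypes are drawn i.i.d. per site from
population-specific frequencies; every panel haplotype is then a recombinant
mosaic of its population's founders. Switch points are Poisson on the
genetic map at `mosaic_switch_rate` (default 1 per cM) and each copied
allele is flipped with probability `mutation_miscopy_rate` (default
10^-3^). Held-out target samples are, in turn, mosaics of the *panel*
haplotypes, which gives the imputation model a realistic target: panel
segments genuinely present in each target, of plausible genetic length.

Population structure uses a Balding-Nichols drift model: each population's
frequency is Beta-distributed around a shared ancestral frequency with
divergence `drift` (default F~ST~ = 0.05). The ancestral site-frequency
spectrum is a three-part mixture (55% common, 27% low-frequency, 18% rare)
chosen so that, after filtering, the default panel places several hundred
sites in each of the minor-allele-frequency buckets used by the accuracy
reports (> 5%, 1–5%, < 1%). Sites are dropped when monomorphic in the
emitted panel or when their alternate-allele frequency is below 1% in every
population; `n_sites` counts candidate sites before this filter, so the
default 4,500 candidates yield roughly 4,000 usable sites over a 10 Mb
region mapped at 1 cM/Mb.

What this generator does *not* emulate: realistic coalescent tree shapes and
allele ages, recombination hotspots, indel/multi-allelic complexity (all
markers are generic biallelic sites), sex chromosomes, genotyping batch
effects, and cryptic relatedness beyond the explicitly constructed
relatives. Accuracy numbers obtained on it therefore demonstrate that the
pipeline's inference machinery is correct and well-calibrated, not that the
same r² would be observed on any particular real cohort.

Relatives are constructed, not inferred: a designated "child" target copies
one parental haplotype unrecombined, and the relationship is recorded in
the panel pedigree. This makes the relative-exclusion rule in custom-panel
selection directly testable against ground truth.

# Reads, genotype likelihoods

Read depth per site is Poisson at the nominal coverage; each read draws one
of the sample's two alleles, is emitted as an off-target base with
probability `frac_other` (default 0.002, exercising the discard rule), and
otherwise flips to the opposite allele with probability `base_error`. The
post-filter base error default of 0.005 reflects a modern short-read
instrument after mapping- and base-quality filtering; it is configurable,
and the same value is used by default in simulation and inference (a
mismatch can be forced for robustness experiments). Mapping-quality
filtering is folded into the generator — only "passing" reads are emitted —
because no aligner is in scope; the pileup text format is the entry point
for real data produced by external pileup tools.

With k reference and m alternate reads retained at a site (off-target reads
discarded), the genotype likelihoods are

$$L^*(0) = (1-e)^k e^m, \qquad L^*(1) = 0.5^{k+m}, \qquad L^*(2) = e^k (1-e)^m,$$

normalized to max 1. Error mass goes entirely to the opposite allele — not
e/3 per base — because non-ref/alt bases were already discarded upstream.
Sites with no retained read are omitted; downstream stages treat them as
uninformative. Binomial thinning implements downsampling, with the
retention rule that a sample already at or below the target coverage is
returned unchanged. Realized (not nominal) coverage drives the 0.5×
coverage QC threshold, matching how a laboratory would measure it.

# The imputation HMM

The core model is a diploid Li-Stephens haplotype-copying HMM over the
ordered pair of copied panel haplotypes (K² states for K haplotypes). Over
an interval of genetic length d cM each haplotype independently switches to
a uniformly random template with probability

$$\tau = 1 - \exp(-s\,\rho\,d/K),$$

and emissions mix the per-site genotype weights with a per-allele copy
fidelity 1 − λ (λ default 10^-3^). The forward-backward pass is exact: it
is checked against exhaustive path enumeration on small instances in the
test suite, at 10^-10^.

Parameter conventions deserve a note. The switch intensity ρ defaults to
the *population-scaled* choice ρ = K, so the effective per-haplotype switch
rate is s·1.0 per cM regardless of panel size; with the model-scale
multiplier s = 2 (the default) the model expects about twice the generator's
default switch rate, a deliberate mild overestimate that makes the copier
more willing to change templates than the truth requires — robust, and in
our experiments slightly better than an exactly matched rate at 0.5×
coverage. The interpretation of "model scale" as a multiplier on switch
intensity is this package's definition; external imputation engines expose
a similarly named knob whose exact meaning is not documented, and no
equivalence is claimed.

Imputation is two-stage, per sample:

1. **Stage 1 — reference-aware calling.** Forward-backward over the
   *covered-site subsequence* (inter-site distances summed along the map),
   with genotype-likelihood emissions, against a per-sample custom panel:
   the 250 panel samples most similar to the target by IBS, where target
   IBS uses genotype-likelihood posterior-mean dosages under a uniform
   prior at the sample's densest-covered decile of sites (a stand-in for
   regions consistently sequenced at high depth). Dosage-based IBS was
   chosen over pseudo-hard calls as the least-assuming reading of
   low-coverage data; both are simple to compute and the comparison sites
   and similarity inputs are recorded per run. The target itself and its
   pedigree relatives are never eligible. A single pass is made — no
   phasing iterations.
2. **Stage 2 — imputation to all sites.** Forward-backward over *all* panel
   sites against the full panel (again minus target and relatives), with
   stage-1 posterior triplets as emissions at covered sites and uniform
   emissions elsewhere. The posterior dosage P(g=1) + 2·P(g=2) is emitted
   everywhere.

A single-pass variant (GL emissions at covered sites, flat elsewhere, full
panel, one run) is provided as an internal-consistency comparator; on the
default simulation the two agree to a mean absolute dosage difference well
under 0.05.

## Numerical and performance choices

The K² transition operator factorizes into stay/uniform-jump terms, so each
site costs O(K²) rather than O(K⁴). Per-site normalization is folded into
the update coefficients, row/column sums are accumulated in double
precision during the same pass that writes the state matrix, and forward
matrices are checkpointed every ~√M sites, bounding memory at O(K²√M).
State matrices use double precision for panels up to 64 haplotypes — the
regime where exhaustive-enumeration agreement at 10^-10^ is checked — and
single precision with double accumulators above that, where per-site
normalization keeps entries well scaled (duplication-invariance checks show
agreement with the double path to ~10^-7^). An all-zero emission row, an
impossible emission, and an empty covered-site list are hard errors naming
the site or sample.

# The genotyping-array arm

The array simulator types a configurable fraction of sites with sampling
weights MAF^w^ (w = 1 by default), emulating common-variant ascertainment;
w = 0 gives an unbiased draw. Entries go missing at `miss_rate` and are
perturbed at `geno_error`. QC applies, in a fixed order that is part of the
contract: site missingness > 5%; Hardy-Weinberg exact-test p < α; removal
of all A/T and C/G (strand-ambiguous) pairs; then sample call rate < 97%.
The HWE test is the two-sided exact conditional test (sum of Levene-Haldane
probabilities no larger than the observed heterozygote count's); α defaults
to 10^-6^, a conventional array-QC choice made here because "significant
deviation" has no canonical numeric value. Array-based imputation reuses
the same HMM with near-delta emissions (weight 1 − ε on the observed
genotype) at typed, non-missing sites.

# Polygenic scores, normalization, association

The raw score is the weighted sum of effect-allele dosages, with
`2 − dosage` used when the effect allele is the reference allele; no entry
is ever dropped for poor imputation quality, so score concordance reflects
the pipeline end to end. The synthetic score generator orients half its
entries to each allele to force this handling, and can instead orient all
entries toward the allele more frequent in one population — a planted
ancestry confound used to exercise normalization.

Normalization regresses the raw score on the first 10 reference-projection
PCs (panel PCA on genotypes standardized by √(2p(1−p)); cohort dosages
projected onto the reference loadings with the same standardization) and
standardizes the residual. Projection is plain reference-loading
projection; no Procrustes correction is applied, a simplification that is
adequate when cohort and panel share the simulated site set. Normalized
scores with |z| > 5 are flagged as outliers but never dropped.

Association is a maximum-likelihood logistic fit of phenotype on the
normalized score plus covariates; the odds ratio per SD is exp of the score
coefficient with a Wald 95% CI, and AUC is the Mann-Whitney rank statistic
(ties split), both for the score alone and for the full model's linear
predictor. The phenotype generator inverts this model: slope ln(OR), with
the intercept found by root-finding so the expected prevalence matches.

# Study conditions and problem sizes

The package's reference conditions — used by the test suite and by
`scripts/acceptance.R` — are the generator defaults: 5 populations, 250
panel samples, ≈4,000 sites over ≈10 cM, 20 held-out targets at 0.5× for
accuracy (with MAF-bucket stratification), 50 targets at 1.2× with a
1,000-variant score for GPS concordance, and a 10,000-sample cohort (on a
compact 900-site panel, since association depends on scores rather than
site count) with a planted OR of 1.6 at 10% prevalence for association
recovery. The coverage-ladder experiment runs the rungs 0.1–2.0× with two
independent thinning seeds per rung on a 100-sample, ≈1,450-site panel
with 8 targets; these sizes give stable orderings while keeping a full
ladder to a couple of minutes. The OR-recovery acceptance envelope
([1.42, 1.82]) was pre-computed from 200 generator seeds at n = 10,000
before the corresponding test was frozen.

# Known limitations

* The founder-mosaic generator makes targets *exact* mosaics of panel
  haplotypes; real targets also carry private variation, so real-data r² at
  matched coverage will be somewhat lower, especially for rare variants.
* Rare-variant (< 1% MAF) accuracy is limited by panel size here exactly as
  it is in practice; the rare bucket is reported but no acceptance bar is
  set for it.
* Per-sample r² pools all sites (no per-chromosome averaging); the site
  universe is a single synthetic contig.
* The PC projection omits Procrustes-style correction and will drift if
  cohort dosages are systematically shrunk relative to panel genotypes at
  many sites.
* Indels and multi-allelic sites are represented only as generic biallelic
  markers; there is no indel-specific error model.
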