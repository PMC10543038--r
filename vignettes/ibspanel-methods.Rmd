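---
title: "Methods: candidate-gene variant analysis of carbohydrate-digestion genes in IBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene variant analysis of carbohydrate-digestion genes in IBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibspanel)
```

## The analysis

`ibspanel` implements a complete case-control analysis of a targeted
panel of seven carbohydrate digestive-enzyme and transporter genes
(*SI*, *MGAM*, *LCT*, *TREH*, *SLC5A1*, *SLC2A5*, *ALDOB*) in irritable
bowel syndrome (IBS) cohorts. Congenital deficiencies of these enzymes
produce symptoms that closely mimic IBS, so the pipeline looks for both
common-variant association signals and rare, putatively recessive
variation concentrated in cases. The package consumes a multi-sample
VCF, a sample sheet with case/control status, IBS subtype, sex, site,
self-reported ethnicity and 0–4 Rome symptom ratings, and a per-variant
annotation table; all results are emitted as tidy tibbles and TSV
tables.

The stages, in pipeline order:

1. **Genotype QC** (`apply_qc`). The common-variant stage removes
   multiallelic-origin records, variants failing the Hardy–Weinberg
   exact test at p < 1e-6, variants with cohort minor allele frequency
   (MAF) below 0.01 or call rate at or below 0.95, and then applies
   greedy windowed LD pruning at r² < 0.2 (windows of 50 variants,
   step 5). The rare-variant stage masks genotype calls whose read
   balance violates the 70:30 allelic-ratio rule and restricts to
   gnomAD-rare (MAF < 0.01) variants.
2. **Ancestry** (`run_ancestry`). Identity-by-state distances over the
   QC-passed variants, classical (Torgerson) MDS computed jointly on
   cohort plus a labelled reference panel, nearest-superpopulation
   assignment over the first three components, and concordance with
   self-reported ethnicity.
3. **Common-variant association** (`run_association_scan`,
   `subtype_scan`). Per-variant additive logistic regression of case
   status on minor-allele dosage, adjusted for sex and the first two
   MDS components, with Wald 95% intervals; flagged results (p < 0.01)
   are refit with up to six components as a sensitivity analysis.
   Subtype scans restrict cases to one subtype while keeping all
   controls.
4. **Rare-variant prioritization** (`score_matrix`,
   `qualify_rare_variant`, `detect_monogenic`, `detect_oligogenic`).
   Voting matrices over six damage assessments and four conservation
   metrics; qualification by either the voting route or the
   CADD/REVEL/TRaP route; case-exclusive biallelic (monogenic)
   screening and digenic/oligogenic combination screening; carrier
   tables with symptoms rescaled to the 0–10 reporting scale.
5. **Burden** (`run_burden`). A variance-component (SKAT-style) score
   test per gene over three nested marker sets: all variants, rare
   variants (MAF ≤ 0.05), and rare variants passing qualification.

## Statistical engines and numerical choices

**Hardy–Weinberg exact test.** The two-sided conditional exact test:
given the observed allele counts, sum the probabilities of all
heterozygote counts whose conditional probability does not exceed the
observed one (no mid-p correction, matching the default of the standard
genotype-QC tool family). The conditional distribution is evaluated
with the stable ratio recurrence over heterozygote counts and
normalised; probabilities "at" the observed one are included using a
relative tolerance of 1e-9 so exact ties are handled identically across
evaluation orders. The test is computed on all samples; a controls-only
variant is a one-line change via the filter log. The test suite checks
the implementation against an independent log-gamma enumeration oracle
for every genotype configuration with up to 200 alleles, at 1e-12.

**LD pruning.** Windows are counted in *variants* (50, step 5), not
base pairs: over a sparse targeted panel a literal 50-bp window would
almost always contain a single variant, and the 50/5/0.2 triple is the
canonical windowed-pruning parameterisation. Within a window, the
later-positioned member of any violating pair is removed — a
deterministic, order-independent tie-break for sorted input. The sweep
is repeated to a fixed point so that pruning is idempotent: the output
is a set in which no within-window pair reaches the threshold.

**MDS.** Classical scaling via the double-centred squared-distance
matrix; components are ordered by decreasing eigenvalue and each
component's sign is fixed by making its largest-magnitude loading
positive, so coordinates are reproducible across platforms. Degenerate
geometries (fewer positive eigenvalues than requested components) are
padded with zero coordinates. "Distance to a superpopulation" is the
Euclidean distance to the group *centroid* over the first three
components — chosen over nearest-member for robustness and determinism;
ties go to the lexicographically first label and are flagged.

**Logistic fits.** Maximum likelihood by iteratively reweighted least
squares (`stats::glm.fit`, tolerance 1e-10, 50 iterations), Wald
intervals `exp(beta ± 1.96·SE)` to match the reporting convention of
the association tool family this analysis mirrors. Complete or
quasi-complete separation is flagged (`converged = FALSE`) via the
coefficient magnitude and standard error rather than silently reported.
Sex is coded 0/1 with female = 1; missing sex drops the sample from the
fit. The minor allele is defined on the pooled cohort so dosage coding
is stable across overall and subtype scans. No multiple-testing
correction is applied by default (results are reported at raw p <
0.01); standard corrections can be applied to the returned tibble.

**Voting scores.** Damage votes: CADD strictly above 12, and
categorical calls of "damaging", "possibly damaging", "probably
damaging" or "disease causing" from SIFT, PolyPhen2, LRT, FATHMM and
PROVEAN. Conservation votes: SiPhy > 12, GERP > 4.4, phyloP > 1.6,
phastCons > 0.5 (all strict). Denominators use *available* assessments
— observed score tables include values such as 0.7 that are impossible
with a fixed denominator of six — while the classification cutoffs stay
absolute: damaging means at least 4 votes of 6, conserved at least 2 of
4, even under missingness. Both the vote counts and the denominators
are reported.

**Qualification routes.** The `matrix` route requires gnomAD MAF <
0.01 plus both voting classifications. The `seqr` route requires MAF ≤
0.05 and, for missense variants, CADD ≥ 10 *or* REVEL ≥ 0.3. The
disjunction is deliberate: published candidate tables contain rows
(e.g. REVEL 0.16 with CADD 23.5) that a conjunctive reading would
exclude; the conjunctive mode remains available via
`cadd_revel_mode = "and"`. Splice-region variants, for which REVEL is
undefined, use CADD ≥ 10 or TRaP ≥ 0.1; the TRaP cutoff is
configurable because retained splice variants in published tables carry
TRaP values from 0.127 up without a stated threshold. Both routes
restrict to non-synonymous (missense or splice-region) consequences.

**Inheritance screening.** A biallelic candidate carries two or more
qualifying heterozygous variants in one gene or one qualifying
homozygous-alternate variant (the homozygous case is included because
the recessive model requires it, even though published candidate tables
happen to show only compound-heterozygous pairs). No phasing is
attempted — without parental data all co-occurring pairs are treated as
potentially *in trans* and flagged unphased. Monogenic events are
suppressed when any control is biallelic over the same variant set;
oligogenic events are emitted for controls too and flagged, so
case-exclusivity is reported rather than silently enforced. The
qualifying-variant requirement is applied per variant, not per pair.

**Burden test.** With null-model residuals `r = y − μ̂` (logistic fit
on sex and two MDS components — the same covariates as the
common-variant model, recorded in the output), the statistic is
`Q = rᵀ G W² Gᵀ r` with the weighted linear kernel and default
Beta(1, 25)-density weights of the cohort MAF, the canonical
rare-variant upweighting for this test family; flat weights are
selectable. The null distribution is the usual mixture of one-degree
chi-squares with eigenvalues from the projected weighted kernel.
P-values come from Liu moment-matching by default (dependency-free and
fast), an exact characteristic-function inversion (`"davies"`), or
phenotype permutation; the permutation mode re-fits the null per
replicate, which is exact for an intercept-only null and approximate
with covariates. Set-membership MAFs are computed on the analysis
cohort, not an external reference. Missing dosages are mean-imputed
within the kernel; `n_snvs` reports set cardinality.

**Symptom rescaling.** Rome 0–4 ratings map to the 0–10 reporting
scale through a monotone table with fixed endpoints, default
`{0→0, 1→4, 2→6, 3→8, 4→10}`; the even intermediate scores match the
6/8/10 values seen in published carrier tables.

## The synthetic cohort generator

Every downstream stage is exercised against `simulate_cohort`, whose
defaults are frozen to the study conditions the package targets: 687
cases and 439 controls, about 74.5% female with a female case log-odds
of 0.27 (the value implied by the published sex split), five
superpopulations dominated by EUR, Balding–Nichols divergence fst =
0.1, and 1,449 common variants (the scale of the QC-filtered panel)
plus per-gene rare variants. Population-specific allele frequencies are
Beta-distributed around ancestral frequencies; genotypes are
Hardy–Weinberg within population. Case status follows a logistic model
with optional planted per-allele odds ratios, and the configured
case/control counts are reached by retrospective sampling so planted
odds ratios are recoverable by logistic regression. Planted inheritance
events occupy dedicated, initially monomorphic rare-variant slots, so
ledger recovery is exact by construction when annotation missingness is
zero; carriers' symptom ratings are shifted upward (default +2 on the
0–4 scale, clamped) to emulate the reported moderate-to-severe symptom
burden of carriers. Read depths are Poisson with binomial allele
balance (mean 60×, heterozygous balance SD 0.05), which exercises the
70:30 rule with known truth.

What the generator does *not* emulate: LD haplotype structure beyond
duplicated variants, sequencing batch effects, admixed individuals,
genotyping error correlated with depth, and the site-by-age structure
of a real multi-site cohort. Passing tests therefore demonstrate the
correctness of the statistical machinery under the stated models, not
robustness to every artefact of real sequencing data.

## Problem sizes used in the test suite

The property suites run at deliberately desk-scale sizes chosen to give
stable Monte-Carlo behaviour: the Hardy–Weinberg sweep covers all
configurations with up to 100 diploids; odds-ratio recovery uses 200
replicates of 2,000 cases and 2,000 controls; the null-scan calibration
uses one 2,000-sample, 1,000-variant cohort; ancestry assignment uses
five equal clusters at fst 0.1 with a 150-member reference panel;
burden type-I error uses 2,000 permutation replicates at n = 500 with
20 markers. Full-scale cohorts (thousands of samples, tens of thousands
of markers) run through the identical code paths.

## Known limitations

- Logistic separation is flagged, not resolved; a penalised
  (Firth-type) fit is out of scope.
- The burden test does not implement the combined burden/
  variance-component (optimal-rho) variant or small-sample moment
  adjustments.
- Ancestry assignment is distance-based, not model-based
  (no admixture proportions).
- The pipeline consumes called genotypes; alignment and variant
  calling are upstream concerns.
- `run_pipeline()` / `generate_report()` are the orchestration surface;
  the package deliberately ships no shell wrapper beyond
  `Rscript`-able scripts, since its users drive analyses from R.
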