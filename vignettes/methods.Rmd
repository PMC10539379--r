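---
title: "Methods: register-based TRD phenotyping and PRS association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: register-based TRD phenotyping and PRS association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdprs)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where the design was
genuinely open.

## 1. Treatment episodes and the TRD phenotype

All dates are integer day offsets from an arbitrary study epoch; the
phenotype rules are pure day arithmetic, so calendar handling belongs at I/O
boundaries only.

**Episode construction.** `build_episodes()` groups dispenses by
(subject, full 7-character ATC code), sorts by date, and starts a new
episode whenever the gap to the previous dispense of the same drug *strictly
exceeds* `gap_days` (default 120). A gap of exactly 120 days therefore stays
within one episode: the register rule is phrased as dispenses "within 120
days", which we read inclusively. Episode duration is last minus first
dispense date; a single dispense has duration 0. Duplicate
(subject, drug, date) rows are collapsed before chaining. `adequate_episodes()`
keeps episodes with duration ≥ `min_days` (default 42 days = 6 weeks,
inclusive at the boundary: a 42-day episode is adequate).

**Adequacy before ECT.** `count_distinct_adequate_before()` restricts to
dispenses *strictly before* the cutoff (a dispense on the day of the first
ECT session does not count — treatment received on or after the ECT day
cannot have justified the referral), rebuilds episodes on the truncated
records, and counts distinct ATC codes with ≥ 1 adequate episode. Episodes
spanning the cutoff thus contribute only their pre-cutoff chain, and
adequacy is re-evaluated on that chain. Distinct drugs are distinguished at
the full ATC-code level, the finest register-available unit; this is a
configurable choice (`atc_antidep` prefix and code granularity live in
`phenotype_params()`).

**Classification.** `classify_subjects()` assigns three labels per subject:

* *broad*: TRD iff any ECT event; otherwise non-TRD.
* *narrow_1* / *narrow_2*: TRD iff ECT and ≥ 1 / ≥ 2 distinct adequate
  antidepressants before the first ECT. ECT subjects failing the criterion
  are **excluded** from that comparison, never moved to the control side:
  the narrow control group is defined independently as subjects with no ECT
  ever, at least one antidepressant record, and at most two adequate
  antidepressants. Non-ECT subjects with ≥ 3 adequate antidepressants are
  excluded from the narrow comparisons (they are neither treatment-resistant
  by the ECT anchor nor plausible antidepressant responders) but remain
  broad controls.

Two points were genuinely open and are resolved as explicit defaults:
whether narrow controls need an antidepressant record at all
(`controls_require_antidep = TRUE`; the control definition targets subjects
*treated* with antidepressants who did not progress), and the lithium
exposure window for the sensitivity flag (`lithium_window = "full"`: the
sensitivity analysis targets lithium exposure generally, not only pre-ECT
use; `"pre_ect"` is available).

## 2. Genotype and sample quality control

`snp_qc()` applies, in order: a lenient call-rate pre-screen (missingness
> 5%), the strict per-variant call-rate filter (< 0.98), monomorphism,
Hardy–Weinberg disequilibrium, case/control differential call rate
(> 0.01), and MAF (< 0.01). HWE is tested *separately in cases and in
controls* with an exact test (`hwe_exact_test()`), removing a variant when
either stratum gives p < 1e-6; the exact test is used because the removal
threshold sits far in the tail where the chi-squared approximation is
unreliable. The test conditions on observed allele counts and sums the
probabilities of all heterozygote configurations no more probable than the
observed one; it agrees with full enumeration to 1e-12 for totals up to 200
(tested), and a tiny relative slack (1e-12) in the "no more probable"
comparison protects the tie with the observed configuration against
floating-point noise.

`sample_qc()` removes samples with call rate < 0.98, inbreeding coefficient
|F| > 0.20 where F = 1 − observed/expected heterozygosity (expectation from
per-variant allele frequencies over called genotypes), and sex mismatches.
X-chromosome genotypes are not required: sex is inferred from a per-sample
X-marker heterozygosity rate (male < 0.02, female > 0.20, ambiguous
otherwise and never removed), supplied as a summary statistic.

`relatedness_prune()` estimates pairwise π̂ by the method-of-moments
inversion of identity-by-state counts: per-variant P(IBS | IBD state) are
computed from allele frequencies, P(IBD = 0, 1, 2) are solved step-up, and
π̂ = P(IBD=1)/2 + P(IBD=2), clamped to [0, 1]. No finite-sample bias
corrections are applied; the estimator is accurate when allele frequencies
come from a reasonably large sample (the pipeline estimates them from the
post-QC sample; `pihat_matrix(freqs = )` accepts external frequencies for
small subsets). Recovery on simulated duplicate / parent-offspring /
unrelated pairs is 1.0 / 0.5 / 0 within ±0.05 at 5,000 common variants
(tested over 50 seeded replicates). For each pair with π̂ > 0.2 the member
with the lower call rate is removed (ties: the later subject).

`ancestry_outliers()` computes the top two principal components of the
standardized reference panel, projects study samples onto the reference SNP
loadings, and flags samples beyond 6 SD (on PC1 or PC2) of the reference
target population's mean. The generator provides a self-contained
two-population reference (target frequencies vs frequencies shifted by a
configurable delta, default 0.2) in place of an external panel.

## 3. Polygenic scores

`filter_weights()` applies the pre-scoring filters to the summary-statistic
weight table, in order: effect-allele frequency outside [0.1, 0.9] (the MAF
filter is taken from the *source GWAS* frequency column, not the target
sample, since the filters are defined on the summary statistics); INFO
< 0.9; duplicate ids (all copies); strand-ambiguous A/T and C/G pairs; and
the MHC region, chr6:28,000,000–34,000,000 inclusive (GRCh37, the build of
the imputation reference assumed throughout). An optional id whitelist
(e.g. a HapMap3 list read from a file) can be intersected. Surviving rows
are matched to the target variants by id with allele reconciliation: when
the effect allele equals the target's second allele the weight's sign (and
frequency) are flipped so that scoring over first-allele dosages is
effect-allele consistent; irreconcilable allele pairs are dropped. Scoring
both orientations of the same variant yields identical raw scores (tested).

`prs_score()` computes raw scores Σ w·dosage and standardizes within the
scored sample (mean 0, SD 1, tolerance 1e-8). Missing dosages default to
frequency imputation (2 × effect-allele frequency), the common behavior of
scoring tools on imputed data; `omit_rescale` instead omits missing
variants and rescales by total/observed weight magnitude. Zero score
variance is an error, never silently propagated.

## 4. The association battery

`run_battery()` fits, for each of the three definitions × two
treatment-response scores:

* the mean-difference t-test (`mean_difference_test()`), Welch by default —
  the unequal-variance form is the safer default when case and control
  score variances differ; the pooled form is available (`var_equal`);
* logistic regression of status on the standardized score plus the first
  four within-sample principal components (`fit_logistic()`), reporting OR
  per SD with a Wald 95% CI (profile likelihood optional). Convergence uses
  an IRLS tolerance of 1e-10; complete separation (all fitted probabilities
  numerically 0/1) and rank-deficient designs are errors naming the
  offending direction/columns;
* Nagelkerke R² comparing the full model against the covariate-only
  baseline, and its liability-scale conversion
  R²_liab = R²_obs·K²(1−K)²/(z²P(1−P)) with z = φ(Φ⁻¹(1−K)), at K = 0.10
  (the working assumption that one MDD case in ten meets the stringent TRD
  definition). Which observed-scale R² enters this threshold-model map is a
  convention, not a fact; this package applies it to Nagelkerke R² with P
  the per-comparison case fraction, and keeps the conversion behind the
  named function `liability_r2()` so the convention is auditable;
* a Cochran–Armitage trend test over score quartiles (`quartile_trend()`,
  scores 1–4, pooled-sample boundaries, boundary ties to the lower
  quartile).

Benjamini–Hochberg FDR (`bh_fdr()`) is applied separately to the six
t-test p-values and the six regression p-values — exactly six tests per
family enter the adjustment. Sensitivity refits add MDD and
bipolar-disorder scores as covariates (sets: +MDD, +BIP, +both) and, for
the lithium score, drop lithium-using cases from the TRD side only.

## 5. The synthetic study generator

`simulate_study()` emulates the structure the analysis assumes, not any
real dataset:

* **Design defaults** (`sim_config()`): 4,572 MDD cases split 1922/964/1686
  across an ECT-referral, a psychotherapy, and a population cohort; TRD
  base rate 0.44; per-SD OR 1.12 (lithium response) and 0.98
  (antidepressant response); gap 120 d; adequacy 42 d; register window
  4,700 days (roughly the 13-year span of a national prescribed-drug
  register).
* **Genotypes**: per-variant frequencies uniform on `maf_range`
  (default 0.05–0.5), dosages binomial and independent across variants —
  the weights are treated as already LD-rescaled, so simulating LD would
  add nothing the pipeline consumes. Genotypes are emitted
  imputation-complete; missingness (default 0.2%) is injected only to
  exercise the QC path, matching near-complete post-imputation hard calls.
* **Weight tables**: one per trait (lithium, antidepressant, MDD, bipolar),
  with 12 variants per scoring filter deliberately planted to violate it
  (low source MAF, low INFO, A/T-C/G alleles, MHC positions, duplicated
  ids); planted rows are recorded and excluded from the true scores, and a
  test asserts the filters catch exactly them.
* **Truth**: true scores are the weighted allele counts standardized within
  the simulated sample; TRD status is Bernoulli with
  logit p = logit(base rate) + log(1.12)·z_lithium + log(0.98)·z_antidep —
  the generator inverts the model the battery later fits, which is what
  makes parameter-recovery testing meaningful.
* **Registers**: TRD subjects receive a first ECT date and an
  antidepressant history drawn from an adequacy profile (5.8% no
  antidepressant before ECT, 10.6% inadequate episodes only, 22.8% exactly
  one adequate drug, 60.8% two or more — the proportions that make the
  broad/narrow case counts differ the way a real ECT cohort's do); 28%
  also receive lithium. Non-ECT subjects carry 1–2 antidepressants, except
  a 33.5% fraction with ≥ 3 adequate drugs that the narrow comparisons must
  exclude. Dispensing chains are built with gaps of 21–84 days and exact
  target spans, so intended labels are realized deterministically: with the
  noise knobs at zero, downstream classification reproduces the generator's
  intent exactly (tested round-trip).
* **Sex and ancestry**: X-markers are not simulated; each subject carries
  an X-heterozygosity summary consistent with their sex (flipped reported
  sex in 0.3% to exercise the mismatch screen). A 1% subject fraction is
  drawn from a frequency-shifted second population for the ancestry screen.
* The inter-dispense gap distribution and episode counts are chosen for
  rule coverage, not distributional realism — no public source reports
  them.

What passing tests on this generator do **not** show: robustness to LD
between scoring variants, dosage (non-hard-call) genotypes, calendar
artifacts (register start/end truncation of episodes), drug switching
within ATC classes, or confounding between ancestry and phenotype. Those
belong to real-data validation.

## 6. Numerical choices and reproducibility

* A single global seed fans out to fixed per-stage child seeds
  (`genotypes`, `phenotypes`, `treatment`, `subjects`, `reference`), so any
  stage can be re-run in isolation bit-identically; the same config + seed
  reproduces every results table byte-for-byte (tested).
* PCs are computed by SVD of the standardized post-QC dosage matrix with
  mean imputation of missing calls.
* Quartile boundaries use the pooled empirical quartiles; a quartile with
  zero subjects is an error rather than a silent degenerate trend.
* Degenerate inputs fail loudly: empty weight intersections, all-removed QC
  axes, zero-variance scores, unanalyzable comparisons (zero cases or
  controls), perfect separation.

**Problem sizes.** The test suite validates statistical behavior at reduced
but adequate scales chosen per quantity: QC and scoring fixtures at
hundreds of subjects; π̂ and inbreeding recovery at 5,000 variants (where
their sampling SDs are ≈ 0.01–0.02); parameter recovery at the narrow_1
group sizes 1,487/1,483 over 500 replicates; type-I calibration over 2,000
replicates at n = 500; and the orchestrated pipeline at 500 subjects ×
600 variants in tests, with the documented worked example at 3,000 × 2,000
(≈ 40 s on one CPU).

## 7. Known limitations

* π̂ lacks PLINK's small-sample corrections; with few samples *and*
  sample-estimated frequencies it is biased (documented above; supply
  external frequencies in that regime).
* The liability conversion convention (Nagelkerke input, per-comparison
  case fraction P) is one of several in circulation; comparisons across
  studies should check conventions first.
* The generator draws cohort labels consistently with TRD status (ECT
  cohort = TRD) rather than modeling cohort-specific recruitment noise.
* No meta-analysis across cohorts, no GWAS, no genotype imputation, no
  build liftover, and no LD-aware weight rescaling: the pipeline consumes
  already-rescaled weights.
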