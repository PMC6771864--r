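---
title: "Methods: dissecting APOE-driven amyloid deposition from polygenic conversion risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting APOE-driven amyloid deposition from polygenic conversion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsdissect)
```

## The model

Alzheimer disease is modelled here as a two-stage process on the liability
scale. Stage one is amyloid deposition: a latent amyloid liability
$L_A = G_A + \varepsilon_A$, with $\varepsilon_A \sim N(0,1)$, crosses a
threshold and the subject becomes amyloid-positive. Stage two, defined only
among the amyloid-positive, is clinical conversion: a latent conversion
liability $L_C = G_C + \varepsilon_C$ crosses its own threshold and the
subject progresses from MCI to AD. The genetic hypothesis the package is
built to interrogate is a *dissociation*: the APOE locus contributes to
$G_A$ (and, more weakly, $G_C$), while the diffuse polygenic background
contributes only to $G_C$. Under this structure a polygenic score that
excludes the APOE region should (i) add nothing to the prediction of
amyloid status, (ii) predict conversion among amyloid-positive MCI
subjects over and above APOE, and (iii) improve AD-vs-control prediction
when combined with APOE. The probit (standard-normal) liability noise is
deliberate: it gives closed-form AUC benchmarks
($\mathrm{AUC} = \Phi(\delta/\sqrt{2})$ for unit-variance arms separated by
$\delta$) used in the tests.

The predictive analysis never sees the latent variables. It works from
three nested logistic models per case/control contrast — APOE
($\varepsilon_2 + \varepsilon_4$ allele counts), PRS without APOE, and the
full model — always with sex and age as covariates, and reports rank-based
AUCs with and without the covariates plus the likelihood-ratio (deviance)
test of the full model over APOE. The likelihood-ratio test is the
chi-square deviance comparison that `anova()` performs for nested binomial
fits; we implement it directly from the two deviances and cross-check it
against `anova()` in the test suite.

## PRS construction and its parameters

The scoring pipeline has a fixed order — QC → allele match → p-selection →
LD clumping → APOE-region exclusion → scoring — and every stage logs its
variant count.

* **QC** (target sample): missingness > 0.02, exact Hardy–Weinberg
  p < 1e-6, minor allele frequency < 0.01. The HWE test is the exact
  conditional test on heterozygote counts, written in-package because no
  installed dependency exposes it.
* **Harmonisation**: variants are keyed by chromosome:position; swapped
  alleles negate the discovery beta, strand flips are resolved by
  complementation, and palindromic A/T and C/G variants are dropped
  (without discovery allele frequencies their strand is unresolvable; a
  flag re-admits them).
* **Selection**: discovery $p \le 0.5$, boundary inclusive. The threshold
  is the one reported to maximise AD prediction accuracy; it is a
  parameter (`p_max`) everywhere.
* **Clumping**: greedy, association-ranked — take the smallest-p unclaimed
  variant as index, remove unclaimed variants within ±1,000 kb whose
  dosage $r^2 \ge 0.1$ with the index, repeat. Ties on p break by
  (chromosome, position); window and $r^2$ boundaries are inclusive. The
  phrase "keeping the SNPs most associated" decides the index ordering:
  this is p-value-ordered clumping, not MAF-ordered pruning. $r^2$ is the
  squared Pearson correlation of dosages in the target sample itself — the
  single-cohort setting has no external LD reference. The implementation
  is verified against an independent brute-force greedy oracle on hundreds
  of random instances.
* **APOE region**: chr19:44,400,000–46,500,000, read from the kilobase
  coordinates "19:44,400–46,500 kb" (the only reading that contains APOE),
  1-based closed. Excluding it guarantees the full model's decomposition:
  no variant contributes to both the APOE terms and the PRS.
* **Adjustment**: scores are OLS-residualised on the top 8 genotype
  principal components (computed once, on the final clumped variant set,
  after frequency-standardising columns by $2f$ and $\sqrt{2f(1-f)}$) and
  z-scored. Pathway scores are additionally adjusted for age and sex
  before standardisation, mirroring how the genome-wide and pathway
  analyses differ. Missing dosages are mean-imputed at scoring time only,
  so QC sees true missingness.

APOE enters the models as ε2/ε4 counts decoded from the two coding SNPs
via the standard diplotype table (ε4 = count of C alleles at the
rs429358-like site, ε2 = count of T alleles at the rs7412-like site); the
doubly heterozygous genotype is resolved as ε2/ε4, the convention that is
exact when the rare ε1 haplotype is absent — which the generator enforces
and real data violate only marginally. Effect sizes for the two counts are
estimated by joint logistic regression in the target's AD-vs-control
contrast; the published magnitudes (−1.04, +1.55) can be supplied as a
fixed override when no suitable contrast exists. In the model battery the
two counts are free coefficients, so this summary estimate never
constrains the fits; a sparse ε2 cell in a small AD arm (quasi-separation)
degrades only the summary, which is then reported as failed rather than
propagated.

## Longitudinal labels and contrasts

Subjects are labelled from their (first, last) diagnosis pair: stable
CN/MCI/AD map to CONTROL/MCI/AD; CN→MCI and MCI→CN reversions are
excluded; AD→MCI reverters are labelled MCI. MCI→AD converters are
labelled MCI — the cohort-usage convention — even though their last
diagnosis is AD; because the two conventions genuinely conflict in the
source material, the package warns once and offers
`last_diagnosis_wins = TRUE` as the alternative. The converter flag is
true whenever the baseline is MCI and any later visit is AD. Amyloid
status is the latest available SUVR against an inclusive 1.11 cutoff
(inclusive matches common usage of the AV45 threshold; the boundary
convention is pinned by a test). The four contrasts are AD vs CONTROL,
MCI vs CONTROL, amyloid-positive vs -negative, and — among
amyloid-positive subjects with baseline MCI — converters vs
non-converters. Excluded subjects appear in no contrast.

## The synthetic cohorts

The generator is a pure function of its configuration, including the seed.
Genotypes come from a first-order haplotype copying chain within LD blocks
(adjacent-variant correlation $1 - \texttt{ld\_decay}$, default 0.9, so
$r^2$ decays geometrically and 1,000 kb clumping windows have real work to
do), blocks mutually independent and separated by >1 Mb; one block sits on
chromosome 19 inside the APOE region and carries the two-SNP ε locus with
haplotype frequencies ε2/ε3/ε4 = 0.08/0.77/0.15, approximating European
values. The remaining variants of that block chain off the ε4 indicator
and therefore tag the locus, which is what makes the region exclusion and
the "pathway without APOE" subtraction meaningful.

Defaults define the reference study conditions: a target cohort of 770
subjects aged 55–90 (the scale of the longitudinal imaging cohort the
analysis is modelled on), a disjoint discovery cohort of 2,500, 20 blocks
of 25 SNPs, 150 causal background variants whose conversion-stage effects
are scaled so the polygenic conversion component has standard deviation
`w_convert_poly` = 1.2, APOE amyloid-stage weight 1.0 (ε2 signed negative,
ε4 positive) and a small APOE conversion-stage weight 0.3. Amyloid
positivity is thresholded at the 0.55 quantile of realised amyloid
liability (≈45% positive, matching the reference cohort's 357/770), and
half of the amyloid-positive convert. Converters with the highest
conversion liability are already AD at baseline; amyloid-positive
non-converters are mostly stable MCI; amyloid-negative subjects split
60/40 between stable controls and stable (non-amyloid) MCI — this
reproduces the qualitative cross-tabulation in which amyloid positivity is
far commoner in AD than in controls. Small label-flip rates (2%/1%/1%)
create the CN→MCI, MCI→CN and AD→MCI trajectories that exercise the
exclusion rules. SUVR is emitted as
$1.11 + 0.3\,(L_A - \text{threshold})$, floored at 0.6 to stay on a
physiological scale, so the published cutoff reproduces the liability
threshold exactly; 10% of subjects have no scan.

Discovery summary statistics are computed by the vectorised logistic score
test (beta = score/information, SE = information$^{-1/2}$, Wald-style
p-values) of disease status — amyloid-positive *and* converted — on
dosage. At these cohort sizes the score test is indistinguishable from the
Wald test of a full logistic fit and orders of magnitude faster, which is
what makes the replicate-level experiments and the overlap simulation
affordable.

The generator's overlap arguments place a requested number of target
disease cases and non-cases inside the discovery GWAS sample, carrying
their single simulated phenotype into both cohorts — the mechanism that
produces genuine overlap bias. The default is zero overlap (disjoint
cohorts): the published exclusion counts of 266 cases and 173 controls
describe overlap with a 54,000-sample discovery meta-analysis and cannot
be realised as target-case counts in a 770-subject synthetic target (which
has only ~170 disease-true cases); those counts instead remain the
defaults of the overlap-correction stage, where they belong.

What the generator does *not* emulate: realistic human LD maps,
imputation uncertainty, allele-frequency spectra tied to ancestry
(population structure is limited to an optional two-population
Balding–Nichols toggle used for the principal-component tests), age- and
sex-dependent risk (both covariates are generated independently of
disease, so covariate-adjusted results on synthetic data test machinery,
not epidemiology), informative dropout, or measurement error in the
diagnoses beyond the fixed label-flip rates. Passing tests therefore
demonstrate the correctness and calibration of the machinery under the
stated generative model, not performance on real cohorts.

## The overlap correction

When target samples sit inside the discovery GWAS, the discovery betas are
partly fit to the target's noise and the PRS evaluation is optimistic. The
correction proceeds in two stages. First, the per-variant effect-size
wobble attributable to the overlapping samples is estimated by refitting
the discovery associations under replicates that randomly exclude the
overlapping counts of cases and controls; the wobble is summarised as a
single multiplier $c$ = mean over variants of SD(beta)/SE (a single
constant because the reference analysis reports a single constant, 0.053;
a per-variant option exists). Second, the whole scoring pipeline is
averaged over summary statistics perturbed per variant as
$\beta_{\text{adj}} \sim N(\beta, c\cdot SE)$ with p-values redefined by
the normal approximation $p = 2\Phi(-|\beta_{\text{adj}}|/SE)$ — the
approximation is appropriate because the betas are themselves Wald/score
statistics — re-selecting at $p \le 0.5$ and re-clumping each time. With
$c = 0$ every replicate reproduces the deterministic pipeline exactly.
Replicate counts are configurable; desk-scale runs default to 200
(the reference procedure's 10,000 is supported but unnecessary for the
experiments here), and every summary records the count used. The package's
overlap experiment (30% of target disease cases inside a 300-sample
discovery cohort) shows the naive evaluation exceeding the
disjoint-discovery evaluation, with the corrected mean lying between the
two, closer to the disjoint value.

## Pathway scores

Gene sets partition the clumped genome-wide weight table: a variant
belongs to a pathway iff its position falls inside a member gene's
interval (1-based closed; a configurable flank defaults to 0 bp because
the source analysis states none), variants may belong to several
overlapping pathways, and the complement — the whole genome minus all
pathways — quantifies what the pathways leave unexplained. Pathway tables
are derived by restricting the already-clumped genome-wide selection
rather than re-clumping within each pathway: this is order-stable,
guarantees pathway ∪ complement = genome, and is the default (re-clumping
within pathways is a plausible alternative reading and is left behind a
flag at the partition level). With `drop_apoe = TRUE` the APOE region is
excluded from each pathway first, which is the manipulation that reveals
whether a pathway's signal is just the APOE region in disguise. The
synthetic annotation tiles each block with disjoint genes, guarantees the
APOE-like gene sits in one designated set, and defaults to nine sets with
gene counts echoing the published AD pathways (the very large
immune-response set scaled to the simulated gene pool). Pathway
associations are tested as `case ~ score + sex + age` and flagged against
the Bonferroni threshold $0.05/27 = 1.85\times10^{-3}$ (3 scenarios × 9
pathways).

## Numerical conventions and degenerate inputs

* All boundary decisions are inclusive and pinned by tests: $p \le 0.5$
  selection, SUVR ≥ 1.11 positivity, clump window ≤ 1,000 kb, clump
  $r^2 \ge 0.1$ removal, region exclusion endpoints.
* Standardised scores have mean 0 and SD 1 to 1e-8; residual
  orthogonality to covariates holds to 1e-8; scoring agrees with a
  dot-product oracle to 1e-10.
* Seeded determinism is end-to-end: rerunning a pipeline with the same
  configuration writes byte-identical reports. Generators restore the
  caller's RNG state.
* Perfect separation in a logistic fit (deviance numerically zero) is a
  hard error naming the offending predictor; sparse-cell quasi-separation
  is left to the caller, because at reference cohort sizes an empty ε2
  cell in a 70-subject AD arm is an expected event, not a pathology.
* Monomorphic variants are excluded from summary statistics (counted), and
  always fail QC's MAF filter.
* Empty contrast arms, constant phenotypes, rank-deficient covariates and
  empty weight tables raise immediate, named errors.

## Problem sizes used by the test suite

The replicate-level experiments run at sizes chosen to finish on a single
CPU while leaving the statistical conclusions unambiguous: the
dissociation pattern uses 100 replicate cohorts of 770 target subjects;
the clumping oracle comparison uses 500 random instances of up to 500
variants; null calibration of the likelihood-ratio test uses 1,000
replicates; the overlap experiment uses 20 replicates with 100 exclusion
simulations and 40 perturbation replicates each; the extremes property
uses 200 replicates of 2,000 subjects. The acceptance script reports every
quantity together with the problem size it was computed at.

## Known limitations

The LD model is first-order within blocks, so long-range LD and MAF-LD
coupling are absent; clumping behaviour on real data (where window edges
interact with recombination hotspots) is exercised only in caricature.
The score-test betas differ from full-likelihood logistic betas at extreme
case-control imbalance. The overlap correction averages a single $c$
across variants. The trajectory model has no time-to-event structure —
converters convert at a uniformly random visit — so nothing here supports
hazard-scale inference. Finally, all power statements are conditional on
the generator's effect sizes; they are study conditions, not estimates of
any real cohort's power.
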