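---
title: "Methods: case-control meta-analysis of HTRA1 rs11200638 and AMD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control meta-analysis of HTRA1 rs11200638 and AMD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
library(dplyr)
```

## The problem and the data

Age-related macular degeneration (AMD) is the leading cause of vision
loss in the elderly, in an exudative ("wet", neovascular) and an
atrophic ("dry") form. The HTRA1 promoter variant rs11200638 (G→A, on
10q26) is one of the most-studied genetic risk factors for AMD, but
individual case-control studies disagree. A meta-analysis from
per-study genotype counts is the standard way to combine them: each
study contributes the numbers of AA, AG and GG individuals among cases
and among controls, and everything else — effect sizes, heterogeneity,
subgroup structure, publication-bias diagnostics — is derived from
those 2×3 tables.

`genemeta` ships the two published HTRA1/AMD study tables as CSV
fixtures (`load_fixture("table1")`, 38 whole-AMD studies;
`load_fixture("table2")`, 21 wet + 6 dry subset studies), transcribed
exactly as printed. Multi-cohort publications appear as separate rows
(e.g. four Tuo 2008 cohorts), matching the unit of analysis of the
source tables; `study_id` disambiguates them deterministically.

## Hardy-Weinberg screening

Departure of control genotypes from Hardy-Weinberg equilibrium (HWE)
signals genotyping error or sampling problems, so studies whose
controls fail HWE are excluded before pooling. `hwe_test()` is
Pearson's χ² goodness-of-fit test: with sample allele frequency
$\hat p = (2n_{AA}+n_{AG})/2n$, expected counts are $n\hat p^2$,
$2n\hat p(1-\hat p)$, $n(1-\hat p)^2$ and the statistic is referred to
χ² with 1 df (three classes minus one minus one estimated parameter),
without a Yates correction — this recomputes the printed control P
values (0.423, 0.94, …) to three decimals. A conditional exact test
(`method = "exact"`) is available for small samples; the χ² form is the
default because it is the test the source analysis names. Monomorphic
arms admit no test and return χ² = 0, P = 1 with a warning flag.

`filter_hwe()` removes studies with control HWE P < α (default 0.05).
Its default P source is the *printed* HWE column, falling back to
recomputation when no printed value exists; `source = "recomputed"`
recomputes everything. The distinction matters for exactly one row:
Losonczy 2011 prints P = 0.133, but its printed counts (3/49/43) give
P = 0.0133 — almost certainly a dropped digit in the source table. The
published analysis kept that study (it excluded exactly five), so the
printed column is the default; the recomputed filter honestly yields 32
studies instead and the row sits on the `known_discrepancies()` list.

## Genetic models and zero cells

A 2×3 genotype table collapses into a 2×2 exposed/unexposed table in
five standard ways (`genetic_models()`): allelic A vs G (counted on
alleles, $n_A = 2n_{AA}+n_{AG}$), heterozygote AG vs GG, dominant
AA+AG vs GG, homozygote AA vs GG and recessive AA vs AG+GG. The allelic
table counts two alleles per person and so treats alleles within a
person as independent — adequate under HWE, which is why screening
precedes pooling.

Zero cells (one study has no AA controls) make the odds ratio and its
variance undefined. The package applies the Haldane–Anscombe continuity
correction: 0.5 is added to **all four cells** of any table containing a
zero, per study, before effect estimation (`apply_continuity()`,
automatic in `contrast_tables()`). The source analysis never states its
zero-cell policy, but this choice is validated empirically: the printed
fixed-effect homozygote odds ratio for the two real-time-PCR studies,
9.83 (5.18–18.65), is recovered to rounding with the correction and
misses by ≈0.4 without it (the uncorrected Mantel–Haenszel estimate is
10.22), so the correction is the discriminating reproduction check in
the test suite.

## Effect estimation and pooling

Per-study effects are log odds ratios $y_i = \log(a_id_i/b_ic_i)$ with
Woolf variances $v_i = 1/a_i+1/b_i+1/c_i+1/d_i$. Heterogeneity is
Cochran's $Q = \sum w_i (y_i - \bar y_w)^2$ with fixed inverse-variance
weights $w_i = 1/v_i$, tested against χ²(k−1), with
$I^2 = \max(0, (Q-df)/Q)$ and the DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\!\big(0,\,(Q-df)/(\sum w - \sum w^2/\sum w)\big)$.
Q is always computed on the Woolf effects (the standard DL
construction), even when the reported point estimate is
Mantel–Haenszel.

Two pooled estimators are implemented:

- **Mantel–Haenszel fixed effect** (`pool_mh()`):
  $\widehat{OR}_{MH} = \sum(a_id_i/n_i) \big/ \sum(b_ic_i/n_i)$, with
  the Robins–Breslow–Greenland variance for its confidence interval and
  Z test. The inverse-variance fixed estimator (`pool_iv()`) is also
  exposed; on the published tables the two agree to two decimals, and
  the source software's internals are not documented, so the choice is
  recorded rather than guessed.
- **DerSimonian–Laird random effects** (`pool_dl()`): weights
  $w^*_i = 1/(v_i+\hat\tau^2)$; when $Q \le df$ this collapses exactly
  to inverse-variance fixed pooling (a tested numerical identity).

`pool_auto()` applies the published dispatch rule: Mantel–Haenszel when
the Q-test P value exceeds 0.1 (strictly), DerSimonian–Laird otherwise.
Confidence limits are $\exp(y \pm z_{1-\alpha/2}\,se)$ with the normal
quantile (1.96 at 95%); Z-test P values are two-sided normal tails.
These conventions reproduce every printed pooled OR and CI bound in the
total, HWE-screened, ethnicity, source-of-control, AMD-type and
genotyping-method strata to within 0.01–0.05 (the resolution of the
printed two-decimal values), as asserted in `test-acceptance.R`.

## Publication bias and sensitivity

`egger_test()` regresses the standardized effect $y_i/se_i$ on
precision $1/se_i$ by ordinary least squares; the intercept estimates
the small-study effect and is tested two-sided against t with k−2 df. A
perfect fit (degenerate funnel) is reported with P = 1 rather than an
unstable t ratio. `begg_test()` computes Kendall's score between the
standardized deviates $u_i = (y_i-\bar y_w)/\sqrt{v_i - 1/\sum w}$ and
the variances $v_i$, with the tie-corrected variance
$[k(k-1)(2k+5) - \sum t(t-1)(2t+5)]/18$ and a continuity correction of
1 on the absolute score (deviate variances at or below zero are floored
at 10⁻¹² with a warning — ties and degenerate variances arise readily
in synthetic data even though real Woolf variances rarely tie).

The source publication reports two conflicting sets of allelic bias
statistics (body text t = 0.89/z = 0.85 versus its bias-test table
t = 0.23/z = 0.42). Our implementation reproduces the *table* exactly
on the 33-study allelic set (intercept 0.212, SE 0.924, t 0.23,
P 0.820, CI −1.67 to 2.10; Begg z 0.42, P 0.676), which identifies the
table as the internally consistent computation; the tests therefore
validate the bias machinery primarily by oracle properties
(normal-equations least squares; brute-force O(k²) pair counting) and
by type-I-error simulation, with the table reproduction as a
cross-check rather than a pinned target.

`leave_one_out()` repeats `pool_auto()` k times with one study omitted
and flags the analysis stable when every omitted-study interval
excludes OR = 1 on the same side as the full analysis. On the
33-study allelic analysis all 33 omissions keep the lower confidence
limit above 1 (range of leave-one-out ORs 2.53–2.62), matching the
published stability claim.

## The full pipeline

`run_analysis()` reproduces the published layout: the Total row pools
*all* studies — deliberately including the five HWE-violating ones,
because the published total does — while every other row uses the
screened sets; wet/dry rows come from the second fixture. Subgroups
with fewer than two studies are emitted flagged "not pooled" rather
than raising. Genotyping methods are normalized into the published
strata (`Sequencing`, `TaqMan`, `PCR-RFLP`, `RT-PCR`,
`MassARRAY MALDI-TOF`, with array/SNaPshot/multiplex platforms as
`Others`). `render_report()` is a pure function of the report (fixed
column order, ORs to 3 decimals, P to 3 significant digits), so
repeated renderings are byte-identical; `forest_data()` returns
per-study rows in fixture order with weights normalized to 100%.

## Inconsistencies in the printed tables

The printed source tables are internally inconsistent in five places;
the package preserves them **as printed** and catalogues them in
`known_discrepancies()` so every reproduction decision is explicit:

1. **Grand totals.** The printed totals (8582/7452 for 38 studies;
   8101/7215 after screening) equal the table sums *minus* the two
   latest-added studies (Matuskova 2020, and Fritsche 2008 for the
   38-study total), although both are counted among k and demonstrably
   enter the pooled estimates. The true transcription sums are
   9649/8192 and 8408/7406.
2. **Losonczy 2011 HWE P** (0.133 printed vs 0.0133 recomputed), above.
3. **Askari 2015 in the wet/dry table** prints HWE P = 0.576 where
   recomputation (and the whole-AMD table) give 0.057–0.058 — a digit
   transposition; the row passes the 0.05 screen either way.
4. **Mori 2007 wet/dry control counts** (5/41/70, n = 116) contradict
   the whole-AMD table (22/57/54, n = 133) and coincide with
   Leveziel's controls; they are kept as printed because the published
   dry subtotals and pooled estimates require them.
5. **The dry-AMD pooled row.** All five printed dry pooled ORs, CIs
   and heterogeneity P values reproduce *only* without the Zeng 2011
   dry cohort (e.g. dominant 2.08 (1.24–3.48), Q-P 0.618 from four
   studies, versus 2.73 (2.13–3.51), Q-P 0.498 from all five — the
   latter being the value the publication's own body text quotes).
   `run_analysis()` pools the honest five-study dry set; the
   acceptance script reproduces the printed value from the
   reconstructed four-study set and reports k = 4.

Relatedly, the published summary allele frequencies (54.2% cases vs
36.5% controls) match no single natural aggregate of the printed
counts: pooled allele counting gives 51.7%/33.7% (38 studies) or
52.1%/32.8% (33 studies), unweighted per-study means 56.5%/36.7% and
56.3%/34.8%. `aggregate_allele_frequency()` exposes both weightings and
the tests assert the direction and a band the data support rather than
the printed pair.

## The synthetic generator

`simulate_meta()` draws k independent case-control studies with known
truth. Controls follow HWE at allele frequency f; cases follow the
multiplicative per-allele odds model: genotype probabilities
proportional to the control triple tilted by $(\psi^2, \psi, 1)$. Under
this model the case allele odds are exactly ψ times the control allele
odds, so the allelic contrast estimates ψ directly — the natural
estimand — while dominant/recessive analyses of the same data
deliberately probe model misspecification. Per-study effects draw
$\log\psi_i \sim N(\log\psi, \tau^2)$; arm sizes draw log-uniformly
over configurable ranges whose defaults (46–1335 cases, 13–1073
controls) mimic the heavy size spread of the published tables; an
optional inbreeding-type coefficient ρ distorts designated control
arms ($f^2+\rho f(1-f)$, $2f(1-f)(1-\rho)$, $(1-f)^2+\rho f(1-f)$) to
exercise the HWE screen. A single integer seed determines the whole
set via per-study substreams derived from (seed, index), so earlier
studies are invariant to k.

What the generator emulates is the *count structure* of published
tables — multinomial sampling, HWE controls, a log-normal random
effect. It does not emulate covariate confounding, linkage
disequilibrium with neighbouring variants, genotyping error beyond the
ρ distortion, or selective publication; passing recovery tests
therefore validates the estimators' arithmetic and calibration, not
robustness to those real-data features.

`power_two_proportions()` is the normal-approximation power of the
two-sided two-proportion test with unpooled variances; it returns
exactly α under the null. Applied to the pooled case/control allele
frequencies and allele counts of the screened set it gives power ≈ 1,
the most plausible reading of the published "power = 1.00" (whose
inputs are not stated).

## Validation conditions and numerical choices

The simulation checks in the test suite run at fixed seeds under these
conditions, chosen once as realistic for this literature:

- HWE test size: 5 000 multinomial draws at f = 0.3, n = 500; rejection
  rate required in [0.035, 0.065].
- Egger type-I error: 2 000 null meta-analyses (ψ = 1, τ = 0, k = 10,
  arms 100–1000, no small-study mechanism); rejection in 0.05 ± 0.02.
- Parameter recovery: 2 000 replicates at ψ = 2.5, f = 0.35, k = 30,
  500/500 per arm, τ = 0; mean pooled allelic OR within 5% of ψ and
  95% CI coverage in 0.95 ± 0.02.
- Pooled Z-test size under the null: 1 200 replicates, required in
  0.05 ± 0.02.

Numerical conventions: normal (not t) quantiles for pooled CIs;
two-sided tails throughout; χ² upper tails for Q and HWE; τ² and I²
floored at 0; expected HWE counts floored at machine epsilon before
division; Kendall variance tie-corrected; the Begg continuity
correction max(|score|−1, 0); Egger's degenerate-fit branch triggers
when the intercept's standard error falls below 10⁻¹²; continuity
increment 0.5 applied only to tables that contain a zero. All
quantities are pure functions of the inputs — reports render
byte-identically on repeated runs.

## Known limitations

- The estimators are the classical large-sample ones: DerSimonian–Laird
  τ² is moment-based (no REML/Paule–Mandel), CIs use normal quantiles
  (no Hartung–Knapp adjustment), and coverage at very small k is
  accordingly slightly below nominal.
- No Peto odds ratio, risk ratios/differences, meta-regression,
  trim-and-fill, or selection-model bias correction.
- Biallelic autosomal markers only; no multi-allelic or X-linked HWE.
- The fixtures are transcriptions of printed tables; where the source
  publication is internally inconsistent the package documents the
  conflict rather than resolving it, and the reproduction of the dry
  subgroup depends on the reconstructed analysis set described above.
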