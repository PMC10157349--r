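---
title: "Methods: germline panel burden analysis for endometrial cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline panel burden analysis for endometrial cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgermline)
```

## The problem

Endometrial cancer (EC) is the most common gynecological malignancy in
developed countries, and a noticeable fraction of cases carries a germline
pathogenic variant (PV) in a cancer-predisposition gene — most prominently
the Lynch-syndrome (LS) mismatch-repair genes (*MLH1*, *MSH2*, *MSH6*,
*PMS2*, *EPCAM*), and, less strongly, the hereditary breast/ovarian cancer
(HBOC) genes (*BRCA1*, *BRCA2*, *CHEK2*, *ATM*, ...). Quantifying how much EC
risk a PV confers requires (i) a defensible variant triage from raw
annotated calls to countable PV, (ii) a case-control carrier comparison with
appropriate interval estimates for rare carriers, and (iii) stratification
by the clinical criteria that decide who is offered germline testing in the
first place. `ecgermline` implements this analysis chain for a
527-case / 1,662-control design, together with a synthetic cohort generator
that makes the whole pipeline testable without access to protected patient
data.

## Variant prioritization

A variant arrives annotated with a quality score $q$, up to three population
minor allele frequencies (MAFs), an allele frequency in an in-house
777-subject reference panel, a consequence class, and ClinVar assertion
metadata (assertion, review stars, submitter count). Six exclusion rules are
evaluated; all firing rules are recorded, so traces are order-independent
and auditable:

1. low sequencing quality, $q < 150$;
2. population MAF $> 0.001$ in any database (maximum across the provided
   sources; an *all-databases* aggregation is available as an option);
3. reference-panel allele frequency $> 0.5\%$ (interpreted as allele
   frequency among $2 \times 777$ alleles, supplied as an input column);
4. UTR, intronic outside the ±2 bp consensus splice dinucleotides,
   synonymous, or in-frame indel;
5. ClinVar benign/likely benign with at least a two-star review status;
6. the two enumerated low-risk alleles, *BRCA2* c.9976A>T and *CHEK2*
   c.470T>C, regardless of any other field.

Rules 2–4 are *rescued* — do not fire — when ClinVar asserts
pathogenic/likely pathogenic (P/LP). All exclusion comparators are strict:
$q = 150$, MAF $= 0.001$ and panel frequency $= 0.5\%$ are retained.

Retained variants are classified by a deliberately simple surrogate for a
full ACMG evaluation, which a clinical laboratory would perform per variant
with evidence types this artifact does not model (functional data,
segregation, literature):

* ClinVar P/LP with ≥ 2 submitters (and no conflict) → that class;
* a single-submitter or conflicting ClinVar record → VUS;
* any other ClinVar record → VUS;
* no usable ClinVar: loss-of-function (nonsense, frameshift, canonical
  splice, whole-gene deletion) outside the last exon → pathogenic;
* whole-gene duplications, last-exon truncations, and everything else
  (notably ClinVar-absent missense) → VUS.

The consequence of the surrogate is one-sided: a missense variant that a
laboratory would call pathogenic from non-ClinVar evidence lands in VUS
here. Downstream counting merges pathogenic and likely pathogenic into "PV".

## Testing-indication criteria

The engine encodes the national HBOC and LS germline-testing indication
criteria as explicit per-patient rules over ICD-10-coded diagnoses
(prefix-matched, e.g. `C50` matches `C50.9`), ages, receptor/histology
flags, and first/second-degree relative records. Unknown values use
three-valued logic: a comparison against an unknown age is false, so no
age-bounded rule ever fires on missing data. The four-way partition
(LS-only / HBOC-only / both / non-indicated) is the cross-product of the
two boolean outcomes.

Two readings were genuinely open and are exposed as options:

* **LS-4** ("patient and one first-degree relative have diagnoses linked to
  LS < 50 years") does not say whose diagnosis must be early. The default is
  `either` (at least one of the two diagnoses under 50), with `both` and
  `relative_only` available. `either` is the most inclusive reading
  consistent with the text and the only one a screening criterion would
  plausibly intend.
* Whether EC itself counts as an LS-linked diagnosis on the relative side of
  LS-4/LS-5 is unstated; the default includes it (EC is the index LS
  malignancy in this setting), and it can be switched off.

Two representational limits are deliberate. The relative schema carries
degree, direct-line flag, ICD-10 code, age and sex only, so the HBOC family
rule iii cannot condition on a relative's receptor status or Gleason grade;
prostate cancer in a direct relative therefore qualifies at any grade, and
breast cancer in a relative qualifies through that rule only for male
relatives. Second, the proband-side precondition of that rule is read as
requiring a qualifying breast/gynecologic diagnosis in the proband (the
criteria are published under the breast/ovarian heading); an EC-only proband
cannot satisfy it.

The MSI rule (LS-2) is implemented but inert on cohorts like the simulated
default, where tumor MSI status is unavailable and recorded as unknown.

## Carrier burden estimation

For a gene (or gene set) with $a$ carriers among $n_1$ cases and $c$
carriers among $n_0$ controls, the burden is summarized by the odds ratio

$$\widehat{OR} = \frac{a\,d}{b\,c}, \qquad b = n_1 - a,\; d = n_0 - c,$$

with the Woolf log-method confidence interval

$$\exp\!\left(\ln \widehat{OR} \pm z_{1-\alpha/2}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

Any zero cell makes the estimate undefined and it is reported as `N.A.`;
no Haldane–Anscombe continuity correction is applied, because the reference
analysis reports such rows as not available rather than corrected. P-values
use Pearson's chi-square without continuity correction, or Fisher's exact
test (two-sided, sum of hypergeometric probabilities not exceeding the
observed table's) when any expected cell count is below 5; the policy can be
forced either way. Aggregate rows ("all LS genes", "all carriers") count
*unique* subjects, so double carriers are not double-counted. No
multiple-testing correction is applied across genes — the reference analysis
applies none, and adding one silently would change what the numbers mean.

The candidate-gene analysis removes every carrier of a PV in an
EC-predisposition gene from **both** numerators and denominators (cases
527 → 467, controls 1,662 → 1,616 under the default conditions) before
computing candidate-gene burden, including a pooled *POLE*/*POLD1*
loss-of-function row.

Clinicopathological comparisons assign each patient one carrier group with
precedence LS > HBOC > candidate > none (the full per-gene membership
remains in the triage summary); age at the EC diagnosis specifically is
compared across groups by one-way ANOVA with Tukey-Kramer adjusted pairwise
contrasts, with medians reported alongside because group age distributions
are skewed.

## The synthetic cohort generator

The generator's defaults are the study conditions, not free dials:

* 527 cases and 1,662 controls;
* case phenotypes built from per-group archetypes (early-onset EC;
  EC with concurrent colorectal or ovarian primaries; breast-cancer
  presentations meeting the HBOC rules; late-onset EC with non-qualifying
  history) such that the criteria engine partitions the cohort exactly
  151 / 16 / 82 / 278 — the partition is always re-derived by the engine,
  never assigned;
* per-gene PV carrier counts per indication group fixed at the published
  burden-table values, including the two cross-syndrome double carriers
  (*MLH1*+*BRCA1*, *MSH2*+*ATM*) and the candidate-gene carriers (58 outside
  and 8 inside the EC-predisposition carrier set; 139 in controls);
* ages drawn from truncated normals parameterized by the published subgroup
  means and ranges (only means/medians/ranges are printed, so a truncated
  normal is the least-structured compatible choice), floored to whole years;
  histology, FIGO grade and stage sampled from the published margins.

Carrier placement has two modes. `exact` (default) places exactly the
configured number of carriers and randomizes only *which* patients carry —
appropriate because the published counts are the observed study data the
pipeline must reproduce. `binomial` draws counts binomially at the implied
frequencies and is used by the parameter-recovery harness
(`recovery_experiment()`, `ci_coverage_sim()`) to check Woolf-interval
coverage and log-OR bias.

Carrier variants are mid-gene frameshifts with a two-star P/LP ClinVar
record (retained-class by construction); background variants exercise every
cascade-failure class plus ClinVar-weak records that are retained as VUS.
`make_triage_fixtures()` additionally emits a deterministic one-variant-per-
branch table with a truth sidecar used by the tests.

What the generator does **not** emulate: joint distributions beyond the
published margins (covariates are sampled product-form within archetypes),
haplotype/LD structure, sequence-level data, variant-level allele frequency
spectra, and pedigrees beyond flat relative lists. Passing tests therefore
demonstrate the pipeline's correctness on data with the study's *marginal*
structure, not performance on real sequencing output.

## Numerical and design choices

* Coordinates are 1-based and fully closed (VCF convention); gene-level CNV
  events travel as symbolic records without breakpoints.
* Unknown is an explicit state (`NA`), never 0 or an empty string.
* $z_{0.975} = 1.959964$ via `qnorm`; confidence level configurable.
* Fisher's exact p comes from `stats::fisher.test`; the test suite verifies
  it against an exhaustive `choose()`-based hypergeometric enumeration for
  all tables with $N \le 60$.
* ANOVA uses `stats::aov` / `stats::TukeyHSD` (Tukey-Kramer on unbalanced
  groups); with two groups the F statistic equals the squared pooled-variance
  t statistic, which the suite checks.
* The generator pins the RNG kind (`Mersenne-Twister`/`Inversion`/
  `Rejection`), so identical seeds give byte-identical tables across
  platforms.
* Problem sizes in the test suite: the default-condition cohort is simulated
  once and reused across test files; Monte-Carlo checks use 200 replicates
  for CI coverage and 40 seeds for the age-contrast power simulation —
  enough for the binomial bands asserted while keeping the suite quick.

## Known limitations

* The pathogenicity surrogate cannot reproduce classifications that rest on
  evidence outside ClinVar; missense variants absent from ClinVar are always
  VUS here.
* Printed p-values of the reference analysis are not exactly reproducible
  because it does not state which test produced which value; the package
  fixes a documented expected-count policy instead.
* The control cohort is used as published — all 1,662 subjects, although
  1,170 are male and the disease is female-specific; a female-only
  sensitivity analysis can be run by passing a restricted control variant
  table and denominator.
* "Last exon" status of truncating variants is an input annotation, not a
  computation (the transcript set used upstream is not modeled).
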