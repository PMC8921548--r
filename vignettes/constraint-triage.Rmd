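---
title: "Constraint-metric variant triage: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-metric variant triage: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vustriage)
```

## The problem

Diagnostic gene-panel sequencing for inherited cardiomyopathies (HCM, DCM,
ACM, LVNC) produces many variants of uncertain significance (VUS). Population
constraint metrics offer a way to shrink that pile: if rare variants of a
given class (truncating vs non-truncating) in a given gene are strongly
enriched in disease cohorts over population references, then a *new* rare
variant of that class in that gene in an affected patient is likely causal,
and that likelihood can be quantified and folded into ACMG/AMP
classification. This package implements that interpretation pipeline
end-to-end: burden statistics, gene intolerance screening, EF-banded ACMG
evidence, VUS triage and cohort reporting.

## Case excess and etiological fraction

For a (gene, subtype, variant-class) combination with `case_carriers` of
`case_n` cases and `control_carriers` of `control_n` reference samples,
write \(f_\text{case}\) and \(f_\text{ctrl}\) for the carrier frequencies.
Then

\[
\mathrm{CE} = f_\text{case} - f_\text{ctrl}, \qquad
\mathrm{EF} = \frac{f_\text{case} - f_\text{ctrl}}{f_\text{case}}
            = 1 - \frac{f_\text{ctrl}}{f_\text{case}} .
\]

EF is the attributable fraction among exposed: the probability that a rare
variant of that class, found in an affected carrier, is actually
disease-causing. It is bounded above by 1 (attained exactly when no control
carries such a variant), shares its sign with CE, and is *undefined* when
there are no case carriers — `compute_burden()` then reports it missing,
never zero, because an attributable fraction is meaningless without exposed
cases.

Significance of the case excess is assessed with a two-sided exact test on
the 2×2 carrier table (`fisher.test`); a combination is called significant
at level `alpha` (default 0.05) only when the test rejects *and* CE is
positive. The EF confidence interval is obtained by mapping the exact
conditional-MLE odds-ratio interval through \(1 - 1/\mathrm{OR}\) and
clamping at 1; with any zero cell the CI is reported missing rather than
patched with continuity corrections. At the rare frequencies this pipeline
operates on, the odds ratio and the carrier-frequency ratio nearly
coincide, so the mapped interval is a faithful EF interval; the identity
\(\mathrm{EF} = 1 - 1/\mathrm{RR}\) holds exactly for the frequency ratio
\(\mathrm{RR} = f_\text{case}/f_\text{ctrl}\) and is verified numerically
in the test suite.

```{r burden}
compute_burden(list(case_carriers = 20, case_n = 100,
                    control_carriers = 2, control_n = 1000))
```

## The gnomAD intolerance screen

Genes never analysed in the case-control burden studies can still be
screened with gene-level population constraint: a truncating variant in a
loss-of-function-intolerant gene (pLI > 0.90) or a missense/in-frame
variant in a missense-constrained gene (mis\_z > 3) is putatively
detrimental. The class–metric pairing is strict — pLI is never applied to
missense variants, nor mis\_z to truncating ones — because the two metrics
measure depletion of different mutation classes. When the class-matched
metric is missing the screen returns `FALSE` with a warning: absence of
evidence of intolerance is not evidence of tolerance, and the screen must
not silently borrow the other metric.

## EF-banded ACMG evidence and combining

The hotspot/functional-domain criterion PM1 is applied at a strength set by
the EF of the matched gene or protein region, with left-closed bands:

| band            | strength   |
|-----------------|------------|
| EF ≥ 0.95       | strong     |
| 0.90 ≤ EF < 0.95| moderate   |
| 0.80 ≤ EF < 0.90| supporting |
| EF < 0.80       | (none)     |

applied to non-truncating *and* truncating variants, each through its own
class-specific constraint entry. The other criteria this pipeline can
assert from its inputs are PM2 (popmax allele frequency missing — i.e.
absent from large population studies — or below 0.004%), PP3/PP4 (in-silico
and phenotype-specificity input flags), PS4 (≥ 15 probands) and the tiered
co-segregation criterion PP1 (supporting/moderate/strong at ≥ 3/5/7
segregating meioses; only the highest applicable tier is emitted, because
the tiers are nested — emitting two tiers for one observation would count
the same co-segregation evidence twice).

`combine_acmg()` evaluates the full published combining table over
*effective* strengths: an overridden criterion (PM1 promoted to strong,
PP1 to moderate) counts at its override level in every rule. Pathogenic
rules take precedence over likely-pathogenic; conflicting pathogenic- and
benign-side evidence yields VUS. Benign-side rules are implemented for
engine completeness, but no input path of this pipeline emits benign
criteria: no variant class in these gene panels showed significant
depletion in cases, so provisional benign reclassification is out of scope.
The engine is verified against an independently structured rule-table
oracle on every subset of up to six criteria, at native and overridden
strengths.

## The triage flow

For every prior-VUS observation:

1. **Resolve the constraint entry** (`lookup_constraint()`): match on gene,
   variant class, and subtype (the entry's subtype, `ANY`, or any entry for
   unclassified-CM patients, whose phenotype cannot be matched). A
   region-restricted entry wins over a gene-wide one iff the protein
   position falls inside its inclusive residue interval; among several
   containing regions the highest EF wins (the cluster logic exists
   precisely because causal variants concentrate there). Among gene-wide
   candidates, burden-analysed entries are preferred over gnomAD-only
   entries — the CE/EF route is strictly more informative.
2. **CE/EF route** (entry with significant case excess): assign evidence;
   with EF ≥ 0.90 *and* PM2, PP3 and PP4 all met *and* the combining rules
   reaching (likely) pathogenic, the VUS is immediately reclassified to LP.
   Otherwise it is prioritized for co-segregation or functional follow-up.
   We additionally require the significance flag itself (not only a high
   EF point estimate) on this route; a high EF from a non-significant
   burden is too fragile to act on immediately.
3. **gnomAD route** (no burden data): a variant passing the intolerance
   screen in a gene whose entry establishes it for the patient's subtype is
   prioritized, never reclassified — gene-level intolerance alone is
   insufficient evidence for an (L)P call.
4. Anything else: no action. The pipeline never downgrades a prior class.

`apply_pp1_upgrade()` re-runs the evidence assignment with observed
segregating meioses: modest co-segregation (e.g. PP1 at moderate) can lift
a prioritized variant with EF just under 0.90 over the combining threshold.

Concordance validation (`validate_lp_concordance()`) runs the same routing
over prior (L)P calls: a CE/EF-route variant is concordant when its entry
has significant case excess, a gnomAD-route variant when the screen passes.
Variant-level tallies deduplicate by `variant_id` across patients (a
founder variant carried by several patients counts once), patient-level
tallies count patients with at least one qualifying variant; both are
reported, as cohort summaries conventionally interleave them.

## Thresholds

All cutoffs live in one `cm_thresholds()` object (units in parentheses):

| field | default | why |
|-------|---------|-----|
| `rare_maf` (fraction) | 1e-4 | rarity cutoff for burden comparisons against reference samples |
| `pm2_maf` (fraction) | 4e-5 | PM2 "absent/extremely rare": 0.004%, the adapted cardiomyopathy cutoff |
| `ef_reclass` | 0.90 | immediate VUS→LP cutoff; consistent with the 0.9 posterior consensus for LP |
| `ef_supporting_low`/`ef_moderate_low`/`ef_strong_low` | 0.80/0.90/0.95 | left-closed PM1 band edges |
| `pli_cut` | 0.90 | LoF-intolerance screen (truncating) |
| `mis_z_cut` | 3.0 | missense-constraint screen (non-truncating) |
| `ps4_probands` (count) | 15 | PS4 proband threshold |
| `pp1_supporting`/`pp1_moderate`/`pp1_strong` (meioses) | 3/5/7 | tiered co-segregation |
| `alpha` | 0.05 | two-sided significance for case excess |

A JSON config (`thresholds_from_json()`) may override any field; unknown
keys are rejected so a typo cannot silently revert to a default.

## Missing data conventions

A missing `popmax_af` means *absent from large population studies* and
therefore satisfies PM2 — that is what "absent/extremely rare" says.
`has_case_excess` is deliberately three-valued: `TRUE`/`FALSE` mean the
combination was burden-analysed with/without significant excess, `NA` means
it was never analysed (a gnomAD-only entry). The distinction drives the
route split; collapsing `NA` into `FALSE` would silently move
never-analysed genes onto the CE/EF route as discordant. In the TSV dialect
both the empty cell and `NA` parse as missing (tolerating common lab
exports), while `.` is rejected: it is ambiguous between "missing" and a
malformed number, and a reader that guesses corrupts tables silently.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes: a subtype mix over ~2,000 referrals, 33 burden-analysed genes
(HCM/DCM/ACM) with per-gene EFs drawn from a scaled Beta distribution plus
gnomAD-only genes, prior (L)Ps planted at the ~21.5% diagnostic-yield rate
(with 4% founder contamination), and per-patient VUS counts drawn Poisson
with Bernoulli PM2/PP3/PP4 characteristics. A single integer seed drives
deterministic per-component substreams. What it does *not* emulate:
linkage between variants of one patient, gene-specific variant spectra,
per-variant allele-frequency distributions, pedigree structure, or any
sequence-level realism. Passing tests on generated cohorts therefore
demonstrate the pipeline's decision logic and bookkeeping under known
rates, not performance on real sequencing data.

`table1_fixture()` is different by design: an explicit, hand-allocated
tally construction (no randomness) of a 2,002-patient cohort whose route
tallies hit the published cohort summary cell-for-cell, so that end-to-end
tests are exact rather than stochastic. Two allocation choices deserve
note. First, parenthetical "variants" cells are *unique-variant* counts:
one subtype's concordant cell can show one fewer variant than its patient
count only because a concordant variant is shared by two patients, and the
fixture encodes exactly that. Second, unclassified-CM patients are
generated with `phenotype_specific = FALSE` — an unclassified phenotype
cannot be "highly specific for a single genetic etiology" — which is what
routes every CM-subtype selected VUS to prioritization rather than
reclassification, as observed. The per-gene EF values in the fixture are
plausible stand-ins chosen to drive each variant down its intended decision
branch; they are not the published per-gene estimates, which live in
supplementary material this package does not reproduce.

## Numerical choices

* **Rounding**: every displayed percentage uses half-up (commercial)
  rounding at its printed precision — integers for concordance, one
  decimal for cohort-level yields (so 354/378 → 94%, 25/2002 → 1.2%,
  19/2002 → 1%). Base R's round-half-even would print 0.5% as 0%. A 1e-9
  epsilon guards values a float-ulp under an exact .5 boundary.
* **Serialization**: doubles are written with up to 17 significant digits
  so that read(write(x)) is bit-identical; tables are written in binary
  mode with `\n` separators so identical inputs give byte-identical files.
* **Lookup tie-breaks**: containing region > gene-wide; among regions,
  highest EF; among gene-wide, analysed > unanalysed, significant >
  non-significant, then highest EF, then table order. Fully deterministic.
* **Degenerate inputs**: empty cohorts yield empty results (not errors);
  empty denominators report `NA` percentages; zero-cell tables lose only
  their CI, not their point estimates.

## The EF recovery experiment

`parameter_recovery_experiment()` draws carrier counts under a known true
EF and summarises estimator behaviour. The default regime — true EF 0.9,
control carrier frequency 0.004 (an aggregate rare-variant carrier
frequency typical of a large cardiomyopathy gene under MAF < 1e-4
filtering), 1,000 cases against 60,706 reference samples, 500 replicates —
was fixed before the acceptance suite was run. The plug-in EF estimator is
a ratio estimator, so its mean carries a first-order bias of
\(-(1-\mathrm{EF})(1-f_\text{case})/(n_\text{case} f_\text{case})\)
(delta method); the test therefore asserts the mean within three
Monte-Carlo standard errors *plus* that analytic allowance, rather than
pretending the estimator is unbiased at finite n. CI coverage is asserted
≥ 0.92 (nominal 0.95 minus three binomial standard errors at 500
replicates); exact odds-ratio intervals are conservative, so over-coverage
is expected and accepted.

## Problem sizes in the test suite

The exact-test oracle comparison enumerates every 2×2 table with total
N ≤ 26 (about 19,000 tables) plus a seeded random sample of 2,000 tables
with margins up to 50; the combining-table oracle covers all 64 subsets of
six criteria under several strength-override patterns; simulation-based
checks use cohorts of 250–2,000 patients and 40–500 Monte-Carlo
replicates. These sizes are the package's own choice of a thorough but
quick default; all are trivially enlargeable through the exported function
arguments.

## Known limitations

* The pipeline consumes published constraint tables; it does not re-derive
  per-gene EFs from raw population variant lists, nor does it perform
  multiple-testing correction across genes (significance calls are inputs).
* PP3 is an input flag; no in-silico predictor is run.
* Variant classes are taken as annotated; splice-region edge cases are the
  annotator's responsibility.
* No benign-direction reclassification: the input evidence channels can
  only support the VUS→LP direction.
* Recessive-gene nuances of the PM2 frequency cutoff are not modelled; the
  0.004% threshold is applied uniformly, as is standard for the established
  autosomal-dominant cardiomyopathy genes.
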