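---
title: "Linking infant death registrations to hospital birth records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking infant death registrations to hospital birth records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalink)
```

## The problem

Birthweight- and gestational-age-specific infant mortality rates require each
infant death registration to be joined to the record of the corresponding
birth. Where civil live-birth registration is incomplete, an alternative
reference file — hospital discharge abstracts of births — can stand in for
the live-birth registry. vitalink implements that strategy as a reusable,
testable pipeline: a synthetic generator for the two registry files with a
known ground-truth match map, a deterministic-plus-probabilistic linkage
engine, and a mortality-rates engine.

The package is calibrated to an Ontario-style setting: death registrations
from two calendar years (2010–2011) linked against hospital birth records
spanning those years plus the preceding one (2009–2011), forming a *period
linked file* in which infants born late in the prior year remain linkable
while the live-birth denominator is restricted to births inside the
death-registration window.

## The linkage model

**Deterministic pass.** Each death registration carrying an encoded personal
identifier is joined to the reference record with the same identifier,
provided the identifier is unique on both sides. Duplicates are demoted to
the residual set with a warning rather than guessed at.

**Probabilistic pass.** Residual deaths are linked by the Fellegi–Sunter
model on the four fields shared by the two files: infant date of birth,
place of death, infant sex, and residential postal code. Each candidate pair
is summarised by an agreement pattern with multi-level comparators:

| field  | levels |
|--------|--------|
| date of birth | exact, one day apart, disagree, missing |
| place  | agree, disagree, missing |
| sex    | agree, disagree, missing |
| postal | exact, FSA only (first three characters), disagree, missing |

For field $k$ at level $\ell$, $m_{k\ell} = P(\ell \mid \text{match})$ and
$u_{k\ell} = P(\ell \mid \text{non-match})$; a pair's weight is
$\sum_k \log_2 (m_{k\ell(k)} / u_{k\ell(k)})$. A missing field contributes
zero weight (the $m = u$ convention: missingness is treated as
uninformative, so sparse registrations are not penalised). Parameters and
the class prior $\lambda$ are estimated by EM on the candidate pairs under
conditional independence of fields given class; the observed-data
log-likelihood is non-decreasing by construction and is exposed for
inspection. Estimates reaching 0 or 1 are clamped to $[10^{-6}, 1-10^{-6}]$
with a warning, and an orientation guard swaps the classes if the fitted
"match" class disfavours full agreement (a standard label-switching
safeguard).

**Initialisation** is deterministic so runs are reproducible: $m$ puts 0.9
on each field's top agreement level with the remainder uniform; $u$ uses the
empirical level frequencies over all candidate pairs; $\lambda$ starts at
(residual deaths)/(candidate pairs).

**Blocking.** Candidate pairs are restricted to a blocking key. The default,
date of birth within one day, is aligned with the corruption model (recorded
dates are at most one day off), so the true record is always a candidate;
the union scheme (same birth year or same forward sortation area) and an
unblocked scheme are available. The blocking choice changes the meaning of
the $u$ probabilities — under date blocking, date agreement is common among
non-matches and carries little weight, and discrimination comes mostly from
the postal code — but the decision rule adapts because $u$ is estimated on
the candidate set itself.

**Decision rule.** Weight thresholds are set where the posterior match
probability $\lambda 2^w / (\lambda 2^w + 1 - \lambda)$ equals 0.9 (link)
and 0.1 (non-link). Pairs between the thresholds are reported as *possible*
but counted as unlinked: with no clerical-review stage, a reproducible rule
replaces manual adjudication, and a conservative rule errs toward
under-linkage. One-to-one assignment among candidate links is greedy by
descending weight, ties broken by death then birth identifier; displaced
candidates are demoted to possible. Deterministic links are never overridden
by the probabilistic pass.

**Stillbirth records** are included in the reference file as linkable
targets, because outcomes at the borderline of viability are inconsistently
designated live birth followed by infant death versus stillbirth across data
sources. A link onto a stillbirth record is reported in a reclassification
table rather than counted as a live-birth link, and the death remains in the
crude numerator; the accounting is surfaced rather than silently decided.

## The rates engine

Ages at death are completed days with the day of birth as day 0 (a death on
the date of birth is 0 days, inside the within-24-h bucket). Crude infant
(0–364 days) and neonatal (0–27 days) mortality use **all registered
deaths** — linked or not — per 1000 live births; the post-neonatal rate
(28–364 days) is per 1000 neonatal survivors (live births minus neonatal
deaths). Attribute-specific tables (birthweight, gestational age, maternal
age, parity, sex, plurality, income quintile, region, rurality) can only use
linked deaths, since the attribute comes from the birth record; deaths with
a missing attribute are counted in an exclusion line, and an explicit
`missing` stratum keeps denominators partitioned. Cumulative restricted rows
(births $\ge$ 500 g, $\ge$ 1000 g) are supported through a predicate.

**Confidence intervals.** Two exact binomial inversions are provided. The
default is the *mid-p* exact interval — the variant that reproduces,
digit for digit, the published Ontario 2010–2011 surveillance tables this
package's calibration mirrors (16 of the 17 printed intervals match exactly;
the one exception differs only in a double-rounded terminal digit). The
conservative Clopper–Pearson Beta-quantile inversion is available as
`method = "clopper-pearson"` and is verified in the test suite against
exhaustive tail inversion. Mid-p bounds are obtained by root-finding on the
mid-p tail equations (tolerance $10^{-14}$), with closed forms
$1 - \alpha^{1/n}$ / $\alpha^{1/n}$ at $x = 0$ / $x = n$.

**Suppression.** Rates with numerators of 5 or fewer are flagged and masked
in display, but the computed values are retained in the object for
auditability.

**Cause groups.** ICD-10 underlying causes are mapped to modified ICE
(International Collaborative Effort) groups by longest-prefix matching
against pairwise-disjoint prefix sets, shipped as replaceable reference data
(`ice_groups.yaml`). The exact code boundaries used by surveillance
programmes are not public, so the shipped list is a documented
approximation: the grouping *engine* is exact and order-invariant by
construction, while the *list* is configuration. Cause-specific rates are
computed over all registered deaths.

**Linked-vs-unlinked comparison.** The characteristics table uses Pearson
chi-square tests without continuity correction for categorical rows and the
Mann–Whitney test (midranks, tie-corrected normal approximation) for age at
death. Quartiles use linear interpolation on sorted values (type 7), stated
because IQR endpoints depend on the convention. Displayed p-values below
0.001 print as "< 0.001".

## The synthetic generator

The generator's defaults *are* the study conditions; they ship as a
versioned calibration file (`ontario_cohort.yaml`) and are not tuning knobs.

* **Cohort structure.** 140,462 births per year over 2009–2011 (280,924
  live births in the two-year denominator window at full scale).
  Birthweight-bin sizes and per-bin mortality risks reproduce the published
  two-year provincial table exactly (for example 363 deaths among 1150
  births of 500–999 g). Gestational age is coupled to birthweight through a
  shared latent risk quantile (comonotone coupling), so low birthweight
  co-occurs with short gestation and gestational-age-specific mortality
  decreases monotonically in expectation; the gestational-age margins match
  the published bin sizes while the age-specific rates emerge from the
  coupling rather than being imposed directly.
* **Timing of death.** A four-bucket mixture (within 24 h, 1–6 d, 7–27 d,
  28–364 d) conditional on birthweight class, uniform within buckets,
  calibrated so the overall timing distribution matches published linked
  cohorts (about half of deaths within 24 h, about a fifth post-neonatal).
* **Causes.** ICD-10 codes drawn from group mixtures conditional on timing
  (immaturity dominating neonatal deaths; SIDS and external causes appearing
  post-neonatally), yielding immaturity-related conditions as the leading
  group and congenital anomalies second.
* **Unlinkable deaths.** Three mechanisms remove a birth record from the
  reference file, mirroring how hospital-based reference files genuinely
  miss births: registration thresholds (births under 500 g *and* under 20
  weeks; fraction 1.0e-4 of births with mortality 0.93, about 26 deaths at
  full scale), out-of-hospital or out-of-province birth (2% of term births,
  about 7 deaths), and late terminations resulting in live birth (1.5% of
  deaths at 20–24 weeks, about 9 deaths). Together with the possible-band
  losses of the probabilistic pass (postal corruption, about 5 deaths) the
  expected unlinked share is about 3.6% of registered deaths — the
  calibration target.
* **Field corruption.** Identifiers absent from 15% of death registrations
  (forcing the probabilistic pass); postal code perturbed by one character
  with probability 0.02 (transcription error or address change); date of
  birth shifted one day with probability 0.05 (the smallest realistic
  transcription error, chosen to exercise the date tolerance); sex unstated
  with probability 0.02; borderline-viability deaths carried as stillbirths
  in the reference file with probability 0.01; birthweight and gestational
  age unrecorded with probability 2e-4 (exercising the exclusion line).
* **Stated defaults without a published source** (documented as arbitrary):
  stillbirth records at 0.6% of births, orphan records at 2%, the stratum
  distributions (maternal age, parity, plurality, income quintiles, four
  regions with postal-letter prefixes K/L/M/N, 14% rural), 25 hospitals per
  region, 80% of hospital deaths in the birth hospital, and hospital-death
  probabilities of 0.97 (neonatal) and 0.85 (post-neonatal).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: mortality is independent of the demographic
strata (no maternal-age U-shape or income gradient is built in), multiples
are independent records rather than twin pairs sharing a household,
residential postal codes are near-unique per family (making exact postal
agreement more discriminating than in dense urban housing), and there is no
residential mobility between birth and death beyond the postal-corruption
rate. Linkage accuracy on real files, where several families can share a
postal code and addresses change, should be expected to be somewhat lower
than the near-perfect precision observed here.

## Numerical and design choices

* Dates are ISO-8601; files are UTF-8 RFC-4180 CSV with documented headers.
* A single master seed feeds a named substream per stage
  (`stage_seed(seed, stage)`), so adding a stage never perturbs earlier
  streams; identical configuration and seed give byte-identical outputs,
  recorded as MD5 checksums in the run manifest.
* EM stops when the largest absolute parameter change falls below $10^{-6}$
  or after 500 iterations.
* Degenerate inputs are defined behaviour: empty bins yield rows with a zero
  denominator and an undefined rate; an empty linked or unlinked group
  yields the characteristics table with tests skipped and a warning; a zero
  contingency-table margin and a zero live-birth denominator are domain
  errors.
* Test problem sizes: most unit tests run the generator at 1/10 scale
  (about 42,000 births); the linkage acceptance property runs once at full
  scale (about 421,000 births, 10 seconds), where the unlinked share and
  stage-specific precision/recall are stable enough to assert the
  calibration band. EM parameter recovery at $\lambda = 0.01$ and 50,000
  pairs carries roughly 500 matches, so single-run estimates of the binary
  match probabilities have sampling SD near 0.013; recovery at the 0.02
  tolerance is therefore asserted on the mean over five replicate
  simulations (isolating estimator bias from Monte Carlo noise), with a
  per-replicate divergence guard at 0.05.

## Known limitations

The package links one death to at most one birth and does not model
multiple-cause-of-death data, ICD-9, string-distance comparators, clerical
review, or privacy-preserving (hashed) linkage. The shipped ICE grouping is
an approximation; analyses sensitive to group boundaries should supply their
own mapping file. Geographic structure is schematic (four regions, synthetic
postal codes) and is not a model of real postal geography or census linkage.
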