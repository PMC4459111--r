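---
title: "Constructing AMI admission episodes from hospitalization claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing AMI admission episodes from hospitalization claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amiepisodes)
```

## Why episodes, not claims

In a mandatory universal insurance system, hospitals bill the insurer per
claim, and the billing granularity does not match the clinical one. Three
mechanisms fragment a single acute-myocardial-infarction (AMI) admission
into several claims: inpatient services are billed monthly, so a long stay
produces one claim per calendar month; a transfer produces one claim per
hospital, often with overlapping dates; and an early readmission for the
same event produces a fresh claim days or weeks later. Counting claims
therefore overstates admissions, and any proportion computed per claim
(emergency-department route, procedure use) is diluted by the fragments.
This package reconstructs discrete admission episodes before any
tabulation.

## The case definition

A claim qualifies as an AMI admission when ICD-10 `I21.x` appears as the
primary or any secondary diagnosis. Codes `I22`–`I25` describe subsequent
infarction, post-MI complications and other acute or chronic ischaemic
heart disease; they never qualify a claim. Two reading ambiguities are
resolved as explicit, configurable choices:

* **Co-occurring excluded codes.** A claim carrying both `I21.x` and an
  `I22`–`I25` code is *kept* by default: the excluded codes mark secondary
  conditions, whose presence does not negate a concurrent acute event
  coded `I21`. `case_definition(strict_exclusion = TRUE)` drops such
  claims instead, for sensitivity analyses; `classify_ami_claims()` labels
  every claim with the predicate that decided its fate, so the two
  readings can be compared on any dataset.
* **Code dialects.** Prefix matching ignores dots and case (`I210` ≡
  `i21.0`), because both dialects occur in claims extracts.

Procedure codes are configuration, not nomenclature: fee-schedule codes
differ by country and revision, so the case definition takes arbitrary
code sets for coronary angiography and for revascularization (angioplasty
+ bypass). The shipped defaults (`CAG01`, `PCI01`, `CABG1`) are the
synthetic codes the generator emits. Angiography counts as invasive: it
is routinely performed to evaluate coronary occlusion and frequently
accompanies the therapeutic procedures, and claims data cannot separate
purely diagnostic use.

## The merge rule

Per patient, claims are sorted by admission date (ties: earlier discharge
first, then claim id — a deterministic order, so output never depends on
input row order). Adjacent claims belong to the same episode when at
least one of three conditions holds, with `merge_rule()` defaults:

| | condition | threshold (days) |
|---|---|---|
| C1 | second admission within *w₁* of the first admission | 28 |
| C2 | second admission within *w₂* of the first discharge | 3 |
| C3 | length of stay of the second claim < *s* | 3 |

Design choices the rule statement leaves open, and how this package fixes
them:

* **Inclusivity.** "Within *N* days" is read as ≤ *N*: a gap of exactly
  28 days fires C1, exactly 3 days fires C2. The thresholds are plain
  integers in `merge_rule()`, so the strict reading is one parameter away.
* **Chain anchoring.** The conditions compare each claim with the
  *immediately preceding* claim ("rolling" anchor), so merges chain
  transitively: a 3-month stay billed monthly merges fragment by fragment
  even though the last fragment is far beyond 28 days from the first
  admission. "Adjacent claims" most naturally means consecutive ones, and
  only the rolling reading handles monthly billing of long stays.
  `merge_rule(anchor = "index")` instead evaluates C1 against the
  episode's first claim, which caps episode duration growth via C1;
  C2 and C3 are pairwise by nature and keep their rolling behaviour.
* **Overlaps.** C2 allows negative gaps: a second hospital's claim
  admitted before the first hospital's discharge (a transfer) merges
  via C2.
* **LOS convention.** Length of stay is `discharge − admission` in whole
  days (same-day discharge = 0), so "LOS < 3" means stays spanning at most
  two nights. Claims systems that count both end days are accommodated by
  `merge_rule(los_counts_both_ends = TRUE)`.
* **C3 is literal.** A short second claim merges *regardless of the time
  gap*, because the rule is a disjunction. This is worth flagging: two
  same-patient short stays years apart will merge under C3. It is kept
  because it is what the rule says; narrowing it is a threshold change
  (`short_stay_days = 0` disables it).
* **Attribution.** Year, sex and age come from the index claim; if member
  claims disagree on sex or age (data-entry errors happen), the index
  claim wins and a single warning summarises the conflicts. The
  emergency-department flag uses the index claim's route by default
  (`ed_policy = "index"`), since the route of the admission that started
  the episode is the epidemiologically meaningful one; `ed_policy = "any"`
  is available. The invasive flag is true when *any* member claim carries
  a configured code, because the procedure may be billed by the receiving
  hospital. Episodes spanning a year boundary belong to the index
  admission's calendar year.
* **Degenerate inputs.** An empty claims table yields an empty episode
  table; single claims become single-claim episodes; validation rejects
  discharge-before-admission rows before the builder runs, naming the
  offending claim.

The production builder is a vectorized sequential scan (a cumulative sum
over per-pair merge decisions). `oracle_build_episodes()` reconstructs the
same partition independently as connected components (via igraph) of the
consecutive-pair merge graph; the test suite requires the two to agree
exactly on an enumerated grid of threshold-straddling date configurations
(admission offsets {0, 1, 2, 3, 4, 27, 28, 29, 31, 56, 60} and stays
{0, 2, 3, 4, 29} on 3-claim patients, ~8,000 configurations — the
boundary-critical portion of the full date grid, which is too large to
enumerate usefully) and on 1,000 random patients with up to 6 claims.
Two structural properties are also tested: claims are conserved (episode
member counts sum to the qualifying-claim count on every dataset) and
widening any threshold never increases the episode count.

## The synthetic generator

`simulate_claims()` exists because national claims extracts cannot be
shared: every downstream stage must be testable against known truth. Each
patient receives 1–3 planted episodes; each episode is billed as a single
claim or fragmented by one mechanism — monthly split (cut at calendar-month
boundaries, fragments abutting with a 1-day gap, so C2 fires), transfer
(two overlapping claims from distinct providers, C2), or early readmission
(second claim within the admission window, C1, or right after discharge,
C2). Ground truth (claim → planted episode, planted route and procedure
flags) is returned separately, never embedded in the claims file, keeping
the pipeline blind.

Defaults are fixed once from published national margins for AMI admissions
(2007–2011): 56.3% male; age-band weights proportional to the published
episode counts per ten-year band; per-sex emergency-route probabilities
0.567/0.492 and invasive-procedure probabilities 0.351/0.179; 2.4% of
claims with unrecorded route; episodes per patient categorical
(0.92, 0.07, 0.01) over 1–3, matching the published episodes-per-patient
ratio of about 1.09. Where no published value exists the choices are
structural-realism ones, stated here once: length of stay negative
binomial with mean 7 days and dispersion 2 (typical acute cardiac stays,
right-skewed); monthly-split episodes draw 20–70 extra days because
monthly billing only matters for long stays; the fragmentation mix
(none 0.45, monthly 0.20, transfer 0.15, readmission 0.20) yields about
1.6 claims per episode, the same order as the published claims-to-episode
ratio of 1.74.

**The separation guarantee.** With `guarantee_separation = TRUE`, distinct
episodes of one patient are placed so that no merge condition can fire
across a boundary: the next index admission is more than the admission
window after the previous episode's last claim admission, more than the
discharge window after its final discharge, and the next *index claim* —
not merely the index stay — lasts at least `short_stay_days` (the
fragmenters respect this: a monthly cut or transfer split never leaves a
short first fragment on a non-first episode). Under these constraints the
builder's recovery of the planted partition is exact by construction, and
the acceptance suite verifies exactness across 50 seeds at 200 patients
each. With `guarantee_separation = FALSE` the constraints are dropped and
inter-episode gaps shrink to 1–45 days, so conditions fire across planted
boundaries — the tool for measuring the rule's undercounting bias, which
the test suite demonstrates but the package deliberately does not tune.

**What the generator does not emulate.** Diagnostic miscoding (every
generated claim truly is AMI-spectrum), claims from patients with no AMI
at all, secular trends (rates are constant over the window), mortality and
censoring, re-infarctions close in time (the guarantee forbids exactly the
configurations real re-infarctions would produce), and correlated
missingness. Passing tests therefore show the *algorithm* is correct under
the stated fragmentation model, not that the merge thresholds are
clinically optimal for any particular country's data.

## Tabulation and intervals

`tabulate_by()` stratifies episodes by any subset of year, sex and
ten-year age band (`0-9` … `≥80`), always appending a Total row, and
reports for each stratum the emergency-department and invasive-procedure
proportions. Episodes with unknown route remain in the denominator and
count as non-ED — the convention of keeping unrecorded routes in totals
rather than dropping them, which leaves proportions interpretable as
"share of all admissions".

The default interval is the Wald normal approximation with
z = `qnorm(0.975)` ≈ 1.959964, clipped to [0, 100]. At the sample sizes
of national tabulations (tens of thousands per stratum) Wald, Wilson and
exact intervals agree to the printed decimal; Wald is chosen because it
exactly reproduces the published interval triples the package replays in
its acceptance tests (all 30 of them), and a Wilson option
(`method = "wilson"`, via `prop.test` without continuity correction) is
provided for small-stratum use where Wald misbehaves. Display rounding is
half away from zero at one decimal — the convention of printed tables —
applied only at display; `estimate`, `lower`, `upper` keep full precision.
With zero episodes the Total row carries `NA` proportions rather than
silently dividing by zero.

## Problem sizes

The shipped test suite runs the enumerated oracle grid (~8,000 3-claim
patients), 1,000 random patients for the randomized oracle check, 50
generator seeds at 200 patients for exact recovery, and generator runs up
to 3,000 patients for the missingness and margin checks; these sizes give
binomial standard errors well below the tolerances being asserted while
keeping the suite quick to run. The acceptance script uses 25 seeds at
200 patients plus one 3,000-patient run.

## Known limitations

* `patient_id` is assumed exact; no probabilistic record linkage.
* Episodes truncated by the study window are kept as observed; no
  boundary correction.
* Prefix logic only — ICD-10 codes are not validated against an official
  code list.
* No trend tests or age standardization; the tables are descriptive.
* The C3 condition can merge arbitrarily distant short claims (see above).
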