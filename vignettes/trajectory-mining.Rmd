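---
title: "Mining temporal disease trajectories: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining temporal disease trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmine)
```

## The problem

Longitudinal hospital registers code every contact with a time stamp and an
ICD-10 diagnosis. Two diseases that tend to occur in the *same patients in
the same order* — hypertension followed by heart failure, Down syndrome
followed by otitis media — trace out progression patterns that no
cross-sectional prevalence table can show. `trajmine` mines such patterns as
(i) ordered diagnosis pairs with statistically significant excess
co-occurrence and direction, (ii) linear trajectories of 2–6 codes obtained
by chaining pairs, and (iii) merged trajectory networks.

All analysis operates on **level-3 ICD-10 codes** (letter + two digits;
national dialects such as the Danish `DI10` prefix convention are truncated
by `truncate_to_level3()`) and on **first occurrences**: per patient and
code, the earliest event date. Chapters dominated by administrative or
unspecific content (XVI, XVIII–XXI) are excluded up front; the reserved
death code `Y99`, injected at each patient's death date by
`inject_death_events()`, is exempted from the chapter-XX exclusion through
an explicit allow-list because mortality is an analysis endpoint, not an
administrative artifact. `Y99` never starts a pair or trajectory. The
5-year horizon linking a diagnosis to death is enforced by the same pairing
window used for every other pair, so death needs no special-case logic
downstream of injection.

## Step one: directional pairs

For an ordered pair (D1, D2), with the anchor at each exposed patient's
first D1 event:

* **Pre-filter.** The count of D1 patients receiving any D2 diagnosis
  within `window_years` (default 5) after the anchor is tested against the
  marginal frequency of D2 in the whole population with a one-sided exact
  binomial tail. The default threshold 1.21e-9 is deliberately taken
  verbatim from the published analysis of the Danish register rather than
  recomputed: the exact family size behind that Bonferroni correction is
  not derivable from first principles here, and the pre-filter only needs
  to behave as a conservative superset screen. Because the null uses the
  *lifetime* D2 frequency while the alternative counts a 5-year window,
  the screen is strongly conservative for unrelated code pairs.
* **Matched controls.** Each exposed patient is matched on sex, whole-year
  age at the anchor event, discharge type and ISO discharge week (the week
  covariate absorbs seasonal admission waves). Matching anchors at the
  *first* D1 event per patient — the specification of per-patient versus
  per-discharge matching is genuinely open, and first-event anchoring keeps
  C_exposed and the Cᵢ commensurable: replicate i draws one control per
  exposed anchor, so all counts range over the same number of draws.
  Empty matching cells relax week → calendar quarter → no week → sex +
  discharge type → any non-exposed patient, and every relaxation is counted
  in the returned `tiers` vector. Controls are drawn uniformly with
  replacement; a draw-and-test of one pool member is distributionally a
  Bernoulli trial on the pool's success fraction, so control counts are
  sampled groupwise as binomials — exact in distribution and orders of
  magnitude faster than materialising 10,000 × n_exposed individual draws.
* **Pair test.** Each replicate contributes one Bernoulli comparison
  (success: C_exposed > Cᵢ; ties count ½, which is unbiased under the
  null); the P-value is the exact binomial tail at probability ½. The
  default threshold 1.21e-8 is again the published constant.
* **Directionality.** Among patients whose first occurrences of both codes
  lie within the window of each other, D1-first versus D2-first orderings
  are compared by a one-sided exact binomial test at level 0.05. Same-day
  first occurrences carry no direction and are excluded — the same
  convention that makes equal dates break a trajectory chain. The window
  is applied to the directionality comparison as well as to co-occurrence
  (configurable); applying it consistently keeps the two stages' patient
  sets nested.

**Counting semantics.** C_exposed, the Cᵢ and the pre-filter count *any* D2
occurrence in the window after the anchor; first occurrences are reserved
for the stages where temporal order is itself the object (directionality,
follower counting). Requiring the *first* D2 occurrence inside the window
on the control side would build in a structural bias: control anchors sit,
on average, later in a patient's observed history than first-diagnosis
anchors, so they fail a first-occurrence condition more often for reasons
unrelated to risk, and in small code universes the target code's own
discharges can even serve as anchors that fail tautologically.

**Residual estimator bias.** Even with any-event counting, the matched
estimator is not perfectly exchangeable: exposed anchors are first
diagnoses (early in the at-risk period), control anchors are arbitrary
discharges. On 20,000-patient synthetic registries the estimated RR sits
within ~15 % of the closed-form expectation; the parameter-recovery test
budgets 25 %.

## Step two: trajectories and networks

`build_trajectories()` chains pairs depth-first. A patient follows a
trajectory when the first occurrences of all its codes are strictly
increasing in trajectory order; intervening other diagnoses are irrelevant
("without skipping" refers to the order of the listed codes, not to an
absence of other events). Follower counts are anti-monotone along
extensions, so the search prunes exactly when a chain drops below
`min_followers` (default 20) — the pruning is lossless, which the test
suite verifies against an exhaustive enumeration oracle on 100 random
instances. All qualifying lengths are reported (a retained length-3
trajectory does not suppress its length-2 prefixes, mirroring how browsers
display both simultaneously); codes never repeat within a chain; a direct
pair D1→D3 is never synthesised from D1→D2→D3. The minimum-follower rule is
applied to every reported trajectory of every length — whether the
published browser applies it per displayed trajectory or recursively during
construction is not decidable from the description, and the recursive
reading is at least as strict.

`merge_network()` unions trajectory edges into a directed graph. Edge
statistics always come from the underlying pair table (stable no matter how
many trajectories share an edge); edge follower counts and mean gaps come
from the corresponding length-2 trajectory, while longer-chain counts live
in the trajectory table — the dual display convention of trajectory
browsers. Node annotations (unique patients, deaths within five years of
first occurrence) are recomputed from the registry.

Serialisation (`export_cyjs()`, `export_csv()`) passes through
`suppress_small_counts()` by default: any node, edge or trajectory referring
to fewer than `min_patients` (default 5) individuals is removed, and
mortality counts in (0, 5) are masked to missing rather than rounded —
masking is honest, rounding would fabricate a value. The Cytoscape JSON
schema (`elements` with `data` objects; node `id` = code, edge
`source`/`target` plus statistics) is documented by the bundled reader
`read_cyjs()`, which round-trips exports at full precision.

## The synthetic registry

The simulator is the package's ground truth, not a fixture. Design:

* **Event process.** Per code, a homogeneous Poisson process at the
  baseline annual rate over the patient's at-risk interval (observation
  window clipped to birth and death), thinned by a sinusoidal weekly
  intensity (`seasonal_amplitude`, default 0.3) so the discharge-week
  matching covariate is non-trivial. The paper-scale window
  (1994-01-01 to 2018-04-30) is the default.
* **Planted progressions.** A rule (source → target, multiplier m, lag)
  adds, after the source's first occurrence at t_s, excess target events:
  their number is Poisson with mean (m−1) × baseline × remaining at-risk
  years, their timing t_s + lag with a log-normal lag truncated to the
  remaining interval. Log-normal lags are strictly positive and
  heavy-tailed, like clinical progression delays. Rules chain: a triggered
  code can itself trigger further rules, which is what makes transitively
  induced pairs (D1→D3 behind D1→D2→D3) appear in demos exactly as they do
  in real registers.
* **Demographics.** Sex by a fixed ratio (default 0.5), birth dates uniform
  over 1925–2010, deaths from a piecewise-constant age hazard
  (0.0015/y under 50 rising to 0.15/y over 85) — enough age structure to
  exercise age matching and Y99 injection without claiming demographic
  realism. The default 26-code universe spans one code per ICD-10 letter,
  rates 1–20 per 1000 person-years, including seven codes in excluded
  chapters so chapter filtering is always exercised.
* **Closed-form oracle.** `expected_pair_rr()` integrates the model's
  exposed and control window probabilities over the birth-year and
  first-exposure-time distributions (80-point time grid per birth year,
  truncated-exponential exposure density). It ignores deaths, seasonality
  and indirect rules; the test suite confirms agreement with a
  200,000-patient Monte-Carlo estimate within 2 % under matching
  assumptions (negligible mortality), and uses it as the reference for the
  25 % parameter-recovery budget elsewhere.

What passing tests on this simulator do **not** show: robustness to
age-dependent incidence (codes fire age-independently here, so age
confounding of code–code pairs is absent by construction — only death is
age-linked), to coding-practice drift over calendar time, to ICD revision
changeovers, or to informative censoring. Conclusions about real registry
data need the matched design to carry that weight, as it does in the
published analyses this package's procedure follows.

## Numerical and degenerate-input conventions

* RR with a positive exposed count over an all-zero control ensemble is
  `Inf` (ranked above any finite RR); both zero is an error, because such a
  pair cannot have passed the pre-filter.
* Exact binomial tails are computed with `pbinom`; the half-tie success
  count s maps to the tail P(X ≥ ⌈s⌉).
* Ages are whole years at the event date, computed calendar-exactly (month
  and day comparison, not division by 365.25), because matching needs a
  discrete key.
* ISO-8601 week numbering for the week covariate; weeks 1–53.
* Dates are calendar days throughout; no time-of-day.
* All randomness funnels through explicit integer seeds: the simulator
  seeds from its config, mining derives one sub-seed per candidate pair
  from its `seed` argument, so identical inputs give byte-identical
  outputs.

## Test problem sizes

The statistical suite runs at sizes chosen to make its assertions sharp but
cheap: 400 replicates of 60 patients for the directionality test's type-I
error (the exact test's attainable level at n = 60 is 0.0494, so the
0.05 ± 0.02 band is meaningful), 20 seeds of 20,000-patient registries for
null calibration and planted-effect recovery (five rules, multipliers
15–25, every source code with well over 500 exposed patients), 100 random
instances against the exhaustive trajectory oracle, and a 200,000-patient
single registry for the Monte-Carlo check of the closed-form RR. Control
ensembles use N = 100 in tests; the published default N = 10,000 remains
the package default.

## Known limitations

* The matched estimator's residual anchor-position bias (above) is
  inherent to matched-discharge designs; it is documented and budgeted,
  not corrected.
* The pre-filter's null (lifetime marginal frequency) makes it
  conservative; genuinely protective pairs (RR < 1) are only surfaced
  through the separately returned deficit-significant table, mirroring how
  such pairs are published as downloads rather than displayed.
* Trajectory search is exponential in the worst case (dense pair graphs);
  real pair graphs are sparse at the published thresholds, and the
  anti-monotone pruning keeps practical cost linear in the output size.
* The simulator plants *pairwise* rules only; it cannot represent latent
  common causes with independent lags, so tests cannot distinguish the
  pipeline's behaviour under confounding from its behaviour under genuine
  progression — a limitation shared with any generative check of an
  observational method.
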