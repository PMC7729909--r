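---
title: "Methods: suppression-only anonymization of categorical registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suppression-only anonymization of categorical registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufanon)
```

## The release problem

A registry that publishes record-level data while collection is ongoing
faces three attack surfaces: *singling out* (isolating a record that must
belong to one individual), *linkability* (joining the file to external
sources on demographics and dates) and *inference* (learning a sensitive
value for a known individual from their group). `pufanon` addresses them
with three composable models, all enforced purely by removing records.

### Variable roles

Every variable carries a role. *Key* variables (quasi-identifiers) are the
linkage surface; which variables those are is a qualitative judgment,
mechanized by `classify_key_variables()`: three expert scores in
{1, 2, 3} for replicability, availability and distinguishability are
summed, and a variable is a key iff the sum strictly exceeds the threshold
(default 5; a sum of exactly 5 is deliberately non-key — phase indicators
and the outcome variable sit exactly there in the bundled score sheet).
*Sensitive* variables are protected from inference. *Derived* variables
(the clinical-phase indicators) are excluded from both checks: their value
is a deterministic function of whether the phase-specific sensitive fields
are populated, so protecting those fields protects the indicators for
free; they are still released and still subject to the value-frequency
rule.

### k-anonymity and prosecutor risk

With classes built on the key variables, k-anonymity (`k = 11` by default)
caps each record's prosecutor risk `1/|class|` at `1/11 ≈ 9.09%`, the risk
ceiling conventionally applied to openly shared clinical trial data. The
engine suppresses entire violating classes: partial-class suppression
would just create a smaller violating class, and no utility-optimized
record selection within classes is attempted (out of scope by design — the
released risk profile is what matters, and it is capped exactly at `1/k`).

### t-closeness with a hierarchy-aware EMD

For each sensitive variable separately, each class's empirical
distribution must lie within `t = 0.5` of the reference distribution under
an earth mover's distance whose ground distance respects the semantics of
the values: codes are leaves of a balanced hierarchy of height `H`, and
moving probability mass between two codes costs `height(LCA)/H` per unit.
Two design points deserve emphasis:

* **The recursive tree formula.** `hierarchical_emd()` computes, for every
  node, the signed surplus of one distribution over the other below that
  node; each internal node at height `h` contributes
  `h/H · min(Σ positive child surpluses, Σ negative child surpluses)`.
  This equals the minimum-cost transport value for the tree ground
  distance; the test suite verifies that equality on 400+ random
  hierarchies against an independently written successive-shortest-paths
  min-cost-flow solver, to 1e-9, and checks symmetry, the triangle
  inequality, and the reduction to total variation on flat trees.
* **The reference distribution is the retained set.** At every fixpoint
  iteration the overall distribution is recomputed from the records still
  retained, not frozen at the input: the requirement is a property of the
  *released* file. This is a divergence risk when comparing against tools
  that freeze the input distribution; re-verification of any release with
  `verify()` uses the same retained-set convention.

Per-variable checking (eight separate checks rather than one joint
distribution) matches how the requirement is stated variable-by-variable;
a joint check over the product domain would be strictly stronger but
needs sample sizes far beyond a class of 11.

#### Hierarchies

Bundled defaults: outcome `root → {alive, dead} → {alive-recovered,
alive-not-recovered | dead-covid, dead-other}` (`H = 2`), so confusing the
two death causes is half as costly as confusing death with survival;
superinfection `root → {none, infected, NA} → {… | bacterial, fungal,
bacterial+fungal | …}` (`H = 2`); flat trees (`H = 1`) for the yes/no/NA
intervention variables. Explicit `"NA"` codes are ordinary leaves sitting
conceptually directly under the root (ground distance 1 to everything), so
not-applicable mass never silently vanishes from a distribution; equal
leaf depth is maintained with single-child chain nodes. User hierarchies
with unequal leaf depths are rejected rather than padded — padding would
rescale `height/H` distances invisibly.

### The value-frequency rule

Any value present in the release must be carried by at least
`min_value_count = 10` individuals; the comparison is strict (`count <
10` triggers, exactly 10 passes), values absent from the data are
vacuously safe, and only the carrying records are suppressed. Occurrences
of a variable's explicit `"NA"` code are exempt by default: in the bundled
schema every such occurrence is structurally forced by an absent phase and
carries no information beyond the phase indicator, which is itself
checked. Set `exempt_na = FALSE` to count them like any other value (the
right choice if a schema uses `"NA"` as an informative category).

### The fixpoint engine

`anonymize()` runs k-anonymity → t-closeness → value-frequency within each
iteration, re-partitioning between steps, and loops until a full pass
suppresses nothing. The check order is a fixed, documented choice; any
order reaches a release satisfying the conjunction, because each step only
removes records and each check is re-validated at the end. Termination is
bounded by `nrow(data)` iterations (the retained set strictly shrinks on
every non-final pass); the engine uses no randomness anywhere. An empty
release is legal and flagged, not an error — it is the correct outcome for
small early snapshots. The audit trail records, per iteration and
requirement, exactly which records were removed and why; `verify()`
re-checks any file by direct calls to the three checkers and never trusts
that log.

### Continuous release

`continuous_release()` anonymizes every snapshot of a growing registry
from the full current primary file. Appending freshly anonymized
increments to an earlier release is deliberately unsupported: increments
that are individually compliant can combine into a file that is not.
Growth is modeled as pure record accretion (cases are entered once,
retrospectively), which `simulate_growth_series()` mirrors by taking
nested prefixes of a single draw.

## The synthetic generator

The generator exists so the full pipeline, including its evaluation, runs
without access to any real patient data. Its defaults encode the study
conditions the package is exercised under, chosen once:

| parameter | default | rationale |
|---|---|---|
| `p_male` | 0.60 | ~60/40 gender split typical of hospitalized early-pandemic cohorts |
| `age_band_weights` | 0.04…0.22…0.05, peaked at 56–65 | mid/old-skewed hospital age profile; both tails rare |
| `month_weights` | 0.45, 0.25, … over months 3–12 | diagnoses concentrated at the start of the 2020 observation window |
| `p_complicated_given_uncomplicated` | 0.40 | with the next row, critical share = 0.40 × 0.6068 ≈ 0.243 |
| `p_critical_given_complicated` | 0.6068 | calibrates P(critical) to ≈ 24.3% of cases |
| `death_logit_intercept` / `_age_slope` | −4.5 / 0.55 per band | death risk rising from ~1% (youngest band) to ~34% (oldest), given a complicated phase; overall CFR ≈ 4–5% |
| `superinfection_weights` | none .93, bacterial .055, fungal .01, both .005 | fungal involvement well below 1% per phase, so rare-value suppression is actually exercised |
| intervention rates | 0.15 / 0.45 / 0.55 / 0.30 | plausible placeholders; no published phase-conditional rates exist to fit |

Structural invariants hold for 100% of generated records: phases nest
(critical ⇒ complicated ⇒ uncomplicated), a phase indicator of `"no"`
forces `"NA"` in every dependent variable of that phase, death requires at
least a complicated phase, and the recovery-phase indicator coincides with
the recovered outcome. `simulate_development_file()` is the opposite
object: every cell uniform over its domain, no structure at all — the kind
of shareable schema-only file a data holder can hand to external pipeline
developers.

What the generator does **not** emulate: the real registry's much stronger
concentration of cases on few months and sites (so the synthetic
suppressed fraction at 2,200 records, ~16–18%, is far above what a real
concentrated registry experiences), case-mix drift over time,
within-hospital correlation, missingness other than structural, and any
longitudinal structure. Passing tests therefore demonstrate the *pipeline
guarantees* (risk caps, distribution closeness, value floors, convergence
of bias as n grows) — they do not certify utility numbers for any real
dataset.

## Numerical and edge-case choices

* All threshold comparisons are strict exactly where the models state
  them: class size `< k`, EMD `> t`, value count `< min_value_count`,
  score sum `> 5`.
* Distributions must sum to 1 within 1e-6 on input; the EMD accumulates
  exact partial sums and clamps the result to [0, 1] against rounding.
* Class and violation lists are always sorted by key signature, audits and
  releases are fully deterministic, and the generators take explicit seeds
  while leaving the caller's RNG stream untouched.
* The CFR of an empty dataset is undefined (an error); `release_trend()`
  adopts the convention that an empty release loses the whole signal and
  reports the primary CFR as the bias for that snapshot.
* The age–death association uses the closed form `ln(ad/bc)` of the
  collapsed 2×2 table (identical to the univariate logistic slope, and
  cross-checked against `glm()` in the tests); a zero cell yields an
  *undefined* value, not an error — that is the expected regime for small
  snapshots with no deaths, visible in the worked example where the
  500-case release contains none.
* The "age > 45" cutoff is mapped to "band strictly above 36–45", the only
  reading compatible with banded ages.
* `read_dataset()` assigns 0-based row-index record ids (unless an id
  column is named) and reads every cell literally, so the explicit `"NA"`
  code round-trips through CSV without ever becoming a missing value.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make every phenomenon observable while keeping runs quick:
n = 2,000 for single-release checks (five seeds where a maximum over runs
is measured), growth series 150 → 500 → 1,000 → 2,200 over five seeds for
the convergence checks, and 200+ random hierarchies with ≤ 6 leaves for
the EMD–transport equivalence. At these sizes the full suite finishes in
well under a minute.

## Limitations

Suppression-only protection buys unbiased *retained* records at the cost
of selection bias against rare key combinations — visible here as the
over-suppression of the youngest and oldest age bands, which inflates the
released age–death association. The toolkit offers no generalization or
recoding, no continuous variables, no l-diversity or differential privacy,
and no utility-optimized choice of which records to sacrifice; those are
deliberate non-goals of the suppression-only design, not gaps to be tuned
around.
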