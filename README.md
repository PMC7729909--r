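# pufanon

Suppression-only statistical disclosure control for categorical registry
microdata.

Open patient registries want to publish a Public Use File (PUF) — a
record-level table anyone can download — while the data is still being
collected. The privacy problem is concrete: even without names, a row
`(age band, gender, month of diagnosis, year)` can single a patient out, be
linked to external sources, or let an attacker infer sensitive clinical
facts about a known individual. `pufanon` implements the anonymization
strategy used for open COVID-19 cohort releases as a reusable R toolkit:

* **Qualitative key-variable assessment.** Each variable is scored 1–3 for
  *replicability*, *availability* and *distinguishability*; variables whose
  score sum exceeds 5 are treated as quasi-identifiers ("key" variables).
* **k-anonymity (k = 11).** Every released record must share its key-variable
  signature with at least `k − 1` others, capping the prosecutor
  re-identification risk at `1/k = 1/11 ≈ 9.09%` — the risk ceiling
  recommended for open clinical data.
* **t-closeness (t = 0.5) with a hierarchy-aware earth mover's distance.**
  For each sensitive variable, the distribution within every equivalence
  class must stay within `t` of the overall distribution. Distance is EMD
  with ground distance `height(LCA(u, v)) / H` over a semantic value
  hierarchy of height `H`, computed by the recursive tree formula

  `D(P, Q) = Σ_N (height(N)/H) · min( Σ_c max(extra(c), 0), Σ_c max(−extra(c), 0) )`

  summed over internal nodes `N` with children `c`, where `extra(c)` is the
  signed surplus of `P` over `Q` below `c`. On a flat hierarchy this is
  total variation distance; in general it equals the minimum-cost transport
  value (verified in the tests against an independent network-flow solver).
* **Value-frequency rule.** No published value may be carried by fewer than
  10 individuals.
* **A suppression-only fixpoint engine.** Records violating any requirement
  are removed — never edited — and the three checks are iterated until the
  released file simultaneously satisfies all of them. Because the whole
  current primary file is re-anonymized at every release, the guarantees
  also hold under *continuous release* of a growing registry.

The package ships the 16-variable COVID-registry PUF schema with semantic
hierarchies, a synthetic registry generator (so the entire pipeline is
testable without any real data), prosecutor-risk profiling, and
before/after quality reporting (distribution bias, case fatality rate,
age–death association).

## Worked example

```r
library(pufanon)

# 1. which variables are quasi-identifiers?
scored <- classify_key_variables(leoss_variable_scores())
scored[scored$is_key, c("variable", "score_sum")]
#>   variable              score_sum
#> 1 Age at diagnosis              9
#> 2 Gender                        8
#> 3 Month first diagnosis         6
#> 4 Year first diagnosis          6

# 2. anonymize a synthetic primary dataset
config  <- leoss_config()          # k = 11, t = 0.5, min_value_count = 10
primary <- simulate_primary(2000, seed = 1)
res     <- anonymize(primary, config)
res
#> <puf_anonymization> 1632 of 2000 records released (368 suppressed, 18.40%), 2 iteration(s)

verify(res$released, config)$ok    # independent re-check of all three models
#> [1] TRUE

# 3. how much did suppression bias the data?
quality_report(primary, res$released, config)
#> <quality_report>
#>   records: 2000 -> 1632 (suppressed 18.40%)
#>   mean |freq diff|: 0.90% (all variables), 0.42% (clinical variables)
#>   CFR: 3.75% -> 3.55% (diff -0.20 pp)
#>   highest risk: 100.00% -> 9.09%
#>   age>cutoff vs death log-odds: 1.489 -> 1.302
```

The highest re-identification risk drops from 100% (unique records exist in
the raw file) to exactly `1/11 = 9.09%`, at the cost of suppressing 18% of
this synthetic file; value frequencies shift by under 1% on average and the
case fatality rate by 0.2 percentage points.

The "hiding in the crowd" effect over a growing registry:

```r
trend <- release_trend(simulate_growth_series(c(150, 500, 1000, 2200), seed = 1), config)
trend[, c("size", "suppressed_fraction", "cfr_primary", "cfr_released")]
#>   size suppressed_fraction cfr_primary cfr_released
#> 1  150               1.000       4.667           NA
#> 2  500               0.582       4.400        0.000
#> 3 1000               0.350       4.400        3.385
#> 4 2200               0.162       4.773        4.501
plot_release_trend(trend)
```

At 150 cases nothing can be published; as the registry grows, less
protection has to be paid for and the released CFR converges to the true
one.

A command-line front end wrapping these functions (subcommands `simulate`,
`assess`, `anonymize`, `release-series`, `report`) is installed at
`system.file("cli", "pufanon.R", package = "pufanon")`.

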