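# hrbnet

Co-occurrence and network clustering of binary health-risk behaviors in
survey data on older adults.

A large fraction of older adults carry several modifiable risk behaviors at
once — short sleep, low fruit and vegetable intake, a salty diet, smoking,
drinking, and lack of regular exercise. For intervention design it matters
not only *how many* behaviors co-occur, but *which ones cluster together*
beyond chance. `hrbnet` implements the complete analysis chain for this
question on seven dichotomized behaviors:

1. **Behavior coding** — raw survey responses (sleep hours, A–D frequency
   items, flavor preference, yes/no items) are dichotomized into an N×7
   binary matrix; exclusion rules (age ≥ 65, complete demographics and
   behavior fields) are applied with a full attrition log.
2. **Descriptives** — per-behavior prevalence with Wilson 95% CIs, the
   behavior-count distribution, the proportion with ≥ 2 behaviors, and
   Spearman correlations (midrank ties, t-approximation p-values) between
   behavior count and two ordinal self-rated outcomes.
3. **Co-occurrence regression** — binary logistic regression (IRLS) of the
   "≥ 2 behaviors" indicator on demographics, with odds ratios, Wald 95%
   CIs, and the reference-level layout conventional in epidemiology tables.
4. **O/E clustering** — for each of the 21 behavior pairs, the
   observed-to-expected ratio

   O/E = P(A∩B) / [P(A)·P(B)],

   which equals 1 under independence and exceeds 1 when behaviors cluster;
   with percentile-bootstrap (default) or log-delta confidence intervals,
   ranked tables, and sex stratification.
5. **Ising network (eLasso)** — the joint dependence structure is estimated
   as a binary Markov random field: each behavior is regressed on the
   others by L1-penalized logistic regression over a 100-point λ path,
   the penalty per node is chosen by the extended BIC
   (−2ℓ + k ln N + 2γk ln(p−1), γ = 0.25), and edges are symmetrized by
   the AND rule. Topology metrics: density, mean node strength, average
   local clustering coefficient.
6. **Stability** — nonparametric bootstrap CIs for edge weights and the
   case-dropping bootstrap with the CS-coefficient (largest drop fraction
   keeping subset–full edge correlations ≥ 0.7 in ≥ 95% of subsets).
7. **Communities** — Louvain modularity maximization (deterministic
   multi-start, seeded) with adjusted-Rand / NMI partition comparison.

Because the motivating survey data (CLHLS 2018) requires a download
agreement, the package ships a **fully synthetic generator**:
`generate_survey_table()` samples behavior vectors *exactly* from an
enumerated 7-node Ising model (128 states), plants demographic odds-ratio
effects on the "≥ 2 behaviors" indicator, links ordinal outcomes negatively
to behavior count, and emits raw response fields that round-trip through
the coding rules. Every stage is therefore testable offline, including
parameter-recovery checks against known truths.

## Worked example

```r
library(hrbnet)

cfg <- pipeline_config(
  synthetic = synthetic_config(n_records = 5000, seed = 42),
  B = 500, B_edge_ci = 200, B_per_fraction = 50,
  drop_fractions = seq(0.1, 0.5, 0.1))
rep <- run_pipeline(cfg)
print(rep)
#> hrbnet analysis report (n analyzed = 5000 )
#> stages: exclude, code, describe, correlate, regress, oe, network, stability, communities
#> proportion with >= 2 behaviors: 0.8014
#> network density: 0.619 | mean strength: 2.319
#> communities: 2 (Q = 0.4029 )

rep$correlation$qol$rho        # -0.158: more behaviors, worse rated life
head(rep$oe$overall[, c("label", "oe", "n_ij", "joint_percent")], 3)
#>                 label       oe n_ij joint_percent
#> 1 salty_diet+drinking 2.045248  414          8.28
#> 2  salty_diet+smoking 1.948447  439          8.78
#> 3    smoking+drinking 1.798007  466          9.32
rep$communities$membership
#> insufficient_fruit insufficient_vegetable salty_diet smoking drinking
#>                  0                      0          1       1        1
#> irregular_exercise inadequate_sleep
#>                  0                0
```

Reading the output: about 80% of the synthetic records carry two or more
risk behaviors (the generator's planted logistic model drives this rate);
behavior count correlates negatively with self-rated quality of life; the
top-ranked O/E pairs are the planted "addictive" trio (salty diet, smoking,
drinking), each co-occurring ~2× more often than independence predicts;
and Louvain splits the estimated network into exactly the two planted
communities — an addictive pattern {salty diet, smoking, drinking} and an
activity–eating pattern {fruit, vegetable, exercise, sleep}.

A shell entry point with `simulate` / `validate` / `run` subcommands is
installed at `inst/cli/hrbnet`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
synthetic world, numerical choices, and known limitations.
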