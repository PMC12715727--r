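---
title: "Models and methods behind hrbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hrbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrbnet)
```

## The scientific question

Health-risk behaviors in older adults — inadequate sleep (< 6 h),
insufficient fruit and vegetable intake, a salty diet, current smoking and
drinking, and irregular exercise — rarely occur alone. Two distinct
questions arise from survey data: *co-occurrence* (how many behaviors does
an individual carry, and which demographics predict carrying ≥ 2?) and
*clustering* (which specific behaviors occur together beyond what their
marginal prevalences predict?). `hrbnet` answers both, on the canonical
seven-column binary matrix defined by `hrb_behaviors()`.

## Behavior coding

Raw survey responses are dichotomized record-wise: sleep strictly under six
hours codes 1 (exactly 6 h is *not* inadequate); frequency responses C or D
on the A–D fruit/vegetable items code 1; flavor preference exactly `salty`
codes 1 (any other preference, including "so-so", codes 0); current smoking
or drinking `yes` codes 1; regular exercise `no` codes 1. Exclusions apply
in a fixed order — age under 65, then missing essential demographics
(gender, age, residence), then missing behavior fields — so the attrition
log sums to the total drop. Records missing only the regression
demographics (education, co-residence, economic status) stay in all
behavior analyses and are deleted case-wise from the regression; a
mode-imputation flag (`mode_impute`, off by default) is offered instead of
the EM / multiple-imputation machinery that full survey workflows use,
which is out of scope here. Self-rated quality of life and health (A–E) are
scored 5–1.

## The O/E clustering statistic

For behaviors A and B, O/E = P(A∩B) / [P(A)·P(B)], estimated by replacing
probabilities with sample proportions. The ratio is exactly 1 under
independence (the implementation returns a literal 1 whenever
n~AB~·N = n~A~·n~B~, so the identity is exact, not approximate), above 1
when behaviors cluster. Pairs are ranked by descending O/E with ties broken
by larger joint count, then pair label; joint percentages are rounded
half-up to two decimals as in printed tables.

Confidence intervals: the default resamples the pair's 2×2 cell vector from
its multinomial distribution (B = 1000) and takes percentile bounds —
distribution-free and valid at any O/E. The `log_delta` alternative uses a
normal interval on ln(O/E) with variance 1/n~AB~ − 1/n~A~ − 1/n~B~ + 1/N.
That variance is the *near-independence* form of the full multinomial delta
variance (whose extra term is (2·O/E − 1)/N rather than 1/N), so the two
methods agree closely only around O/E ≈ 1; the test suite checks their
concordance at an exactly independent fixture and calibrates the bootstrap's
coverage (95% ± 2% over 500 independent replicate datasets at n = 2000).

## Ising network estimation (eLasso)

The joint distribution of p binary behaviors is modelled as a pairwise
Markov random field: P(x) ∝ exp(Σ τ~i~x~i~ + Σ~i<j~ w~ij~x~i~x~j~).
Estimation is nodewise: each column is regressed on the other six by
L1-penalized logistic regression (glmnet's coordinate descent, convergence
threshold 1e-10, binary predictors unstandardized) along a 100-point
log-spaced λ path from λ~max~ (smallest penalty giving the empty model)
down by a factor 10^−3^. Per node, λ is selected by the extended BIC,

EBIC(λ) = −2·loglik + k·ln N + 2·γ·k·ln(p−1), k = #nonzero predictors,

with γ = 0.25, the conventional default balancing sparsity and sensitivity;
EBIC ties go to the sparser (larger-λ) model. Directed coefficients are
symmetrized by the AND rule (an edge survives only if both regressions keep
it; weights averaged), with OR available by flag. "Nonzero" means exactly
nonzero from the L1 solver — no epsilon cutoff.

Topology metrics follow the standard definitions: density = nonzero
upper-triangle edges / 21; node strength = Σ|w~ij~|; and the
Watts–Strogatz average local clustering coefficient on the binarized graph
(the Barrat weighted variant is available behind `weighted = TRUE` for
sensitivity analysis, since reported clustering coefficients in the applied
literature rarely name their variant).

## Stability assessment

Two explicit procedures, since applied reports often conflate them:
`bootstrap_edge_ci()` refits the network on B nonparametric row resamples
and reports per-edge percentile intervals (resamples with a constant column
are skipped and counted; > 10% skips is an error).
`case_dropping_stability()` refits on random subsets of size N(1−f) for
f = 0.1…0.7 and records the Pearson correlation between subset and
full-sample edge vectors (all 21 slots, zeros included). The CS-coefficient
is the largest f whose correlation is ≥ 0.7 in ≥ 95% of subsets — the
bootnet-literature convention, configurable. Subset refits whose edge
vector has fewer than two nonzero entries leave the correlation undefined;
they are excluded and logged, which matters for null (empty-network) data.

## Community detection

Louvain greedy modularity maximization with resolution 1: repeated local
node moves in a seed-shuffled visit order, then aggregation, until no gain.
Because the greedy cycle can stall in a visit-order-dependent local
optimum, `louvain()` restarts the full cycle `n_restarts = 5` times with
seed-derived orders and keeps the best-Q partition; the result is still a
deterministic function of (W, settings, seed). At p = 7 the global optimum
is computable by exhaustive search over all 877 set partitions, and the
test suite verifies that the multi-start attains it on at least 80% of
random weighted graphs and never exceeds it; the remaining instances are
unreachable by any greedy visit order, which is the known price of the
Louvain heuristic. Estimated Ising networks can carry
negative edges; modularity requires nonnegative weights, so the default
transform takes absolute values (any conditional dependence counts as
connectivity) with a positive-only alternative — on the planted
structures used here the two agree, and both are worth reporting when they
do not. Partitions are compared by adjusted Rand index and
sum-normalized NMI.

## The synthetic world

`generate_survey_table()` emulates a CLHLS-like cross-section without any
download. Its stated defaults are:

- **Behavior law**: exact sampling from an enumerated 7-node Ising model
  (128 states — no MCMC, no approximation error). The default parameters
  (`two_block_ising()`) plant a positive clique on {salty diet, smoking,
  drinking} (w = 1.2) and a positive block on {fruit, vegetable, exercise,
  sleep} (w = 1.0), no cross-block edges — the two-community structure the
  downstream recovery tests must find. Thresholds are calibrated by Newton
  iteration on the exact marginal map (Jacobian = model covariance) so
  marginal prevalences equal (0.45, 0.10, 0.15, 0.20, 0.18, 0.75, 0.30):
  irregular exercise most prevalent, insufficient vegetable intake least,
  spanning the realistic ~0.1–0.75 range for this population.
- **Covariates**: categorical draws matching the demographic composition of
  community-dwelling Chinese older adults (53.9% female; residence 22/33/44%
  city/town/rural; education mostly 0–6 years; ~80% living with household
  members; economic status centered on "so-so").
- **Planted co-occurrence model**: the "≥ 2 behaviors" indicator is drawn
  from logistic(ln 1.78 + ln 1.86·female + ln 1.15·age/10 + …), the full
  set of planted odds ratios being the published-table values the recovery
  tests refit. The behavior 7-vector is then drawn from the Ising pmf
  *conditioned* on count ≥ 2 vs ≤ 1 (the 128 states partitioned by row
  sum), which makes the planted ORs exactly recoverable — an artifact
  construction, not a claim about how real data arise.
- **Outcomes**: latent score −0.15·count + N(0,1), standardized, cut at
  (−1.5, −0.5, 0.5, 1.5) into scores 1–5. The loading 0.15 was calibrated
  once against the stated target Spearman ≈ −0.17 and is not revisited.
- **Raw fields**: every behavior is emitted as a raw response (e.g.,
  inadequate sleep as a sleep-hours value in 3–5.5), so coding the output
  reproduces the sampled matrix row-for-row — a tested round-trip.

What the generator does **not** emulate: survey weights, longitudinal
structure, proxy respondents, and realistic item-missingness (only an
optional MCAR mask on the three imputable demographics). A green test
therefore establishes that the estimators recover *planted* truths under
clean conditions; it does not certify behavior on messy field data, and
the published headline estimates from the real cohort (e.g., 64.36% with
≥ 2 behaviors, network density 0.667, mean strength 1.467, clustering
0.533) are data-dependent quantities this package can only re-derive when
given that data.

## Numerical choices and degenerate inputs

- Wilson score intervals for prevalence (never outside [0, 1], good small-N
  behavior); Wald intervals for odds ratios, matching the standard
  epidemiology-table format.
- Spearman rho uses midranks; p-values use the t approximation on n − 2 df.
- Zero marginals make O/E an explicit error (or NA inside bulk tables),
  never a silent 0 or Inf; empty graphs make modularity an explicit error;
  isolated nodes become singleton communities.
- Complete separation in the logistic model is detected (|coef| > 15) and
  reported with the offending term.
- Every stochastic routine is a pure function of (data, settings, seed);
  the pipeline derives per-stage seeds from a master seed and stage name,
  and report JSON is written with 12 significant digits so identical
  configurations produce identical bytes.

## Known limitations

- The eLasso sign conventions and λ-grid details follow the dominant
  convention for binary-data network estimation but are not the only ones
  in use; estimated weights are comparable within, not across, conventions.
- The case-dropping CS-coefficient is reported on the tested grid only
  (default 0.1–0.7); it is a summary of a correlation distribution, not an
  inferential statement.
- Multi-start Louvain narrows but does not close the gap to the global
  modularity optimum; at p = 7 an exhaustive search (877 partitions) is
  feasible and used as the oracle in tests.
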