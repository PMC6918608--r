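---
title: "Label-propagation enhanced signal detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-propagation enhanced signal detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsda)
```

## The problem

Spontaneous reporting systems collect voluntary case reports of suspected
adverse drug reactions (ADRs). Disproportionality analysis screens these
databases for signals: drug-ADR pairs co-reported more often than expected
if drug and ADR were independent. The weakness of every purely count-based
screen is the newly approved drug — with few or no reports, no
disproportionality statistic can say anything. `lpsda` addresses this by
combining the report counts with pre-clinical chemistry: drugs with similar
chemical structures tend to share ADRs, so reporting evidence can flow
between chemical neighbors.

## Original signals

For each drug-ADR pair we form the 2x2 contingency table over all reports
(`a` with both, `b` drug only, `c` ADR only, `d` neither; counting is
report-based and a multi-drug report contributes to every listed drug's
margin) and compute one of four scores:

* **PRR05** — the proportional reporting ratio
  $\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$, reported as the lower 95%
  bound $\exp(\ln \mathrm{PRR} - 1.96\,se)$ with
  $se = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
* **ROR05** — the reporting odds ratio $\mathrm{ROR} = ad/bc$ with
  $se = \sqrt{1/a + 1/b + 1/c + 1/d}$, same lower-bound construction.
* **EB05** — the empirical-Bayes gamma-Poisson shrinker: counts are modeled
  as $N_{ij} \sim \mathrm{Poisson}(\lambda_{ij} E_{ij})$ with
  $E_{ij}$ the expected count under independence and a two-component gamma
  mixture prior on $\lambda$. The prior is fitted by maximizing the
  negative-binomial mixture marginal likelihood over all cells with
  $E > 0$ (including zero counts — excluding them biases the prior), by
  bounded quasi-Newton from the canonical start
  $(\alpha_1, \beta_1, \alpha_2, \beta_2, p) = (0.2, 0.1, 2, 4, 1/3)$, with
  log/logit transforms enforcing positivity. EB05 is the posterior 5th
  percentile of $\lambda$, obtained by root-solving the posterior mixture
  CDF to $10^{-12}$.
* **BCPNN25** — the information component
  $\mathrm{IC} = \log_2 \frac{p_{11}}{p_1 q_1}$. We compute its posterior
  by Monte Carlo with independent uniform-prior Beta posteriors for
  $p_{11}$, $p_1$, $q_1$ and report the 2.5% quantile. The Monte-Carlo
  formulation is exactly specifiable and directly testable against oracle
  samplers, which is why it was chosen over the classical closed-form
  variance approximation of the IC posterior. The scalar function defaults
  to $10^5$ draws; the matrix builder uses $10^4$ per pair, which keeps
  the quantile noise (about $\pm 0.02$ bits) far below the score
  differences that matter for ranking while keeping full-matrix runs fast.
  One seed fixes the whole matrix (drawing order is column-major).

Pairs where a formula is undefined (a zero cell in a required position)
receive a fallback so the matrix stays finite for propagation: 0 for
PRR05/ROR05/EB05 and −10 for BCPNN25, ranking such pairs last. This extends
the convention that an unreported drug's signals are zero.

PRR and ROR appear in the pharmacovigilance literature with conflicting
typography; we use the forms above, which are the standard ones consistent
with a drug-in-rows contingency layout, and the standard log-scale Wald
intervals at $z = 1.96$ since the original sources do not print the
standard-error formulas.

## The similarity network and propagation

Each drug is an 881-key binary substructure fingerprint; the similarity of
two drugs is the Jaccard coefficient of their on-key sets (0 when both are
empty). The network matrix $A$ has zero diagonal — the propagation update
already retains each node's own signal through its $(1-\gamma) S$ term, so
self-loops would double-count self-information — and is row-normalized to
$W$. Rows that sum to zero (drugs with no chemical neighbors, or no
fingerprint at all) become unit self-loops, so an isolated drug's enhanced
score equals its original score; this preserves baseline behavior where
chemistry is unavailable. No similarity thresholding is applied: the
network is dense by construction, and sparsification is left to the export
utilities.

Propagation iterates $Y^t = \gamma W Y^{t-1} + (1-\gamma) S$ from
$Y^0 = S$. Because $\rho(W) \le 1$ and $0 < \gamma < 1$ the map is a
$\gamma$-contraction in the max norm and converges to
$Y = (1-\gamma)(I-\gamma W)^{-1} S$. The closed form (a single linear
solve, never an explicit inverse) is the default; the iterative mode is
kept for testing the agreement of the two routes and for very large
networks. Its defaults, tolerance $10^{-9}$ with at most $10^4$
iterations, follow from the geometric rate: at $\gamma \le 0.9$ the
tolerance is reached within about 200 iterations. The absorbing
probability $\gamma$ is selected on a grid $\{0.1, \ldots, 0.9\}$ by
maximum AUC, ties to the smallest value.

A new drug with no reports enters with a zero signal row: the network is
extended by its fingerprint similarities, re-normalized, and the closed
form is solved on the augmented system. Everything the new drug receives
comes from its chemical neighbors.

## Evaluation protocol

Known drug-ADR pairs are positive controls; negatives are sampled uniformly
without replacement from the unknown pairs at twice the number of positives
(one seeded draw per experiment). AUC uses the Mann-Whitney rank statistic
with ties counted 0.5; AUPR uses step-wise precision-recall integration
with no interpolation, tie blocks entering as one step — both choices are
exactly reproducible and oracle-checkable. The binary metrics need a
decision threshold that the literature leaves unstated; the default is the
conventional screening criterion per method (score > 1 for
PRR05/ROR05/EB05, > 0 for BCPNN25), overridable. Per-ADR evaluation ranks
each ADR's full drug column (negatives are all unlabeled drugs in the
column) and drops ADRs with fewer than 10 positive drugs. The
cumulative-year curve re-runs the entire pipeline on the reports
accumulated up to each cutoff year.

## The synthetic benchmark

Real report databases and label-derived reference sets are large external
resources with heavy upstream curation; the package instead ships a
generator that plants the one mechanism the framework needs: chemistry
predicts ADR profiles. Drugs are assigned to clusters; each cluster has a
template fingerprint (120 on-keys of 881), and members keep each template
key with probability 0.9 (off-template keys switch on at a compensating
rate so the expected on-count is preserved — a one-parameter control of
the within/between-cluster Jaccard contrast, which is why the template
model was chosen over independent per-key Bernoulli draws). Each cluster
carries a latent ADR subset (15% of the ADR universe); the ground truth is
every (member, cluster-ADR) pair. Reports pick one drug uniformly among
reporting drugs and mention each ADR at a background rate of 0.05,
multiplied by a relative risk of 5 for the drug's true ADRs; empty ADR
draws are redrawn. Ten percent of drugs are held out of the reports
entirely (each cluster always retains at least two reporting members so
the planted mechanism stays defined), and report years spread uniformly
over 2004-2014.

The default scale — 60 drugs in 6 clusters, 30 ADRs, 5,000 reports — keeps
a full 20-replicate four-algorithm benchmark within a couple of minutes
while giving each drug enough reports (about 80) for stable counts. These
choices are the package's benchmark conditions, stated here so results are
interpretable; they were fixed once, not tuned per experiment.

What the generator does **not** emulate: skewed drug popularity, reporting
biases and duplicates, hierarchical ADR terminologies, imperfect ground
truth (real reference sets omit true associations and include spurious
ones), or realistic report demographics. Because the planted signal is
clean and the truth is exact, absolute metric values on synthetic data run
far higher than anything achievable on real spontaneous-report databases;
the meaningful quantities are the *differences* — enhanced minus baseline,
holdout versus fallback — whose direction and stability the tests assert,
not their absolute levels.

## Numerical and degenerate-input choices

* Universes are ordered lexicographically by ID; every matrix inherits that
  ordering, so results are independent of input row order.
* Duplicate report IDs keep the first occurrence, with a warning.
* The MGPS fit treats optimizer non-convergence as an error, not a silent
  fallback; refitting the same table reproduces the same parameters.
* `bcpnn25`, `sample_negatives` and the generator save and restore the
  caller's RNG state, so seeded pipelines compose without interference.
* All-tied score vectors evaluate to AUC 0.5 by the tie convention; rank
  percentiles average tied ranks.
* Propagation validates row ordering between `W` and `S` and treats any
  non-finite intermediate as a bug, not a recoverable condition.

## Limitations

The similarity network uses a single chemistry view; target- or
indication-based similarities, network fusion, and stratified or
multi-item extensions of the gamma-Poisson shrinker are out of scope. The
binary-metric thresholds are screening conventions, not calibrated
decision rules. Synthetic results demonstrate correctness of the machinery
and the direction of the enhancement, not effect sizes on any real
database.

## A worked run

```{r example, fig.width = 6, fig.height = 4}
ds <- generate_dataset(synth_config(seed = 42))
fit <- lpsda(ds$reports, ds$fingerprints, ds$truth, method = "EB05",
             seed = 42)
summary(fit)
plot(fit)

# score the holdout (zero-report) drugs from chemistry alone
pred <- predict(fit, ds$fingerprints[ds$holdout_drugs])
round(pred[, 1:6], 3)
```
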