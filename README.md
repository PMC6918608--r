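# lpsda — label-propagation enhanced drug safety signal detection

Pharmacovigilance teams screen spontaneous reporting systems (voluntary
post-market case reports) for *signals*: drug-ADR pairs co-reported more
often than independence would predict. Count-based screens are blind where
they are needed most — newly approved drugs with few or no reports. `lpsda`
implements a framework that enhances disproportionality scores with
pre-clinical chemistry: original signals are propagated over a drug-drug
similarity network built from chemical substructure fingerprints, so that
structurally similar drugs share reporting evidence, and a drug with zero
reports can still inherit a meaningful ADR profile from its chemical
neighbors.

## The model

For each drug *i* and ADR *j*, the 2x2 contingency table (a, b, c, d) over
all reports yields one of four original scores S<sub>ij</sub>:

* **PRR05 / ROR05** — lower 95% bounds of the proportional reporting ratio
  PRR = (a/(a+b)) / (c/(c+d)) and the reporting odds ratio ROR = ad/bc
  (log-scale Wald intervals);
* **EB05** — the 5th posterior percentile of the empirical-Bayes
  gamma-Poisson shrinker: N ~ Poisson(λE) with a two-component gamma
  mixture prior on λ fitted by marginal maximum likelihood;
* **BCPNN25** — the 2.5% posterior quantile of the information component
  IC = log2(p11 / (p1 q1)), by seeded Monte Carlo over Beta posteriors.

Drugs are nodes of a similarity network with Jaccard-fingerprint edge
weights (881 substructure keys), row-normalized to a transition matrix W.
The enhanced signal matrix is the fixed point of
Y<sup>t</sup> = γ W Y<sup>t−1</sup> + (1−γ) S, solved in closed form:

```
Y = (1 − γ) (I − γ W)^{-1} S ,   0 < γ < 1
```

γ is chosen on the grid {0.1, …, 0.9} by maximum AUC against positive
controls with 2:1 sampled negatives. A new drug enters with a zero signal
row and is scored purely through its similarity edges.

## A worked example

The package ships a planted-cluster generator (drug clusters share both
fingerprint structure and latent ADR profiles; 10% of drugs are held out of
the reports to emulate newly approved drugs):

```r
library(lpsda)
ds  <- generate_dataset(synth_config(seed = 42))
fit <- lpsda(ds$reports, ds$fingerprints, ds$truth, method = "EB05", seed = 42)
fit
#> Label-propagation enhanced signal detection (LP-EB05)
#>   5000 reports, 54 drugs, 30 ADRs, 216 positive controls
#>   gamma = 0.7 (selected by AUC grid search)
#>   EB05      AUC 0.999  AUPR 0.997
#>   LP-EB05   AUC 1.000  AUPR 1.000
```

The enhanced scores beat the baseline, and the held-out drug `D009` — which
appears in **no report** — recovers its planted ADR profile from chemistry
alone:

```r
pred <- predict(fit, ds$fingerprints["D009"])
round(sort(pred[1, ], decreasing = TRUE)[1:5], 3)
#>  A010  A008  A024  A026  A007
#> 0.743 0.743 0.736 0.700 0.479
sort(ds$truth$adr[ds$truth$drug == "D009"])
#> [1] "A008" "A010" "A024" "A026"
```

Its four true ADRs are exactly the top four predictions; every baseline
method can only give it a constant fallback score. (Synthetic data plants a
clean signal with exact ground truth, so absolute AUCs run far above
anything achievable on real report databases — the informative quantities
are the enhanced-vs-baseline differences.)

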