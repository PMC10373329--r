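# mcqsar — Monte Carlo correlation-weight QSAR for flavonol anti-prostate-cancer activity

`mcqsar` implements a CORAL-style quantitative structure–activity
relationship (QSAR) workflow for predicting the anti-proliferative potency
(pIC50 against the PC-3 prostate-cancer cell line) of flavonol derivatives
from their SMILES strings alone, and ships the 80-compound flavonol dataset
it was built around. It is aimed at cheminformaticians who want a fully
scripted, testable re-implementation of the Monte-Carlo optimal-descriptor
method: no external QSAR software, no binary model files, every number
recomputable from code.

## The model

Each molecule is decomposed into a multiset of structural attributes from
two complementary representations:

* **SMILES attributes** — single symbols S_k, adjacent symbol pairs SS_k,
  and whole-molecule codes (BOND/NOSP/HALO presence flags, their PAIR and
  HARD combinations, ring-closure count Cmax, atom totals Nmax and Omax);
* **hydrogen-suppressed graph invariants** — per-atom Morgan extended
  connectivities of orders 1 and 2, simple-path counts pt2 and pt3, valence
  shells s2 and s3, their sums and absolute differences, and five/six-ring
  codes from SSSR perception.

Every attribute A_k carries a correlation weight CW(A_k). The descriptor of
correlation weights of a molecule is

    DCW(T*, N*) = Σ_k CW(A_k)

summed over the molecule's attributes (threshold T* blocks attributes seen
in fewer than T* training molecules; N* is the number of optimization
epochs), and the activity model is the univariate regression

    pIC50 = C0 + C1 · DCW(T*, N*).

The weights are trained by Monte Carlo hill climbing on a target function
that balances the training and invisible-training correlations

    TF1 = R_TRN + R_iTRN − |R_TRN − R_iTRN| · Const
    TF2 = TF1 + w_IIC · IIC_CAL

where the index of ideality of correlation, IIC = R_CAL ·
min(−MAE, +MAE)/max(−MAE, +MAE), rewards symmetric calibration-set
residuals. Validation compounds are never touched during optimization.
The package also provides the external-validation battery (Q², Lin's CCC,
Roy's rm² metrics, Y-scrambling cRp², s, MAE, F), an applicability domain
built from attribute "statistical defects" (training/calibration prevalence
disagreement), and a mechanistic interpretation step that classifies
attributes as promoters of activity increase or decrease from the sign
stability of their weights across replicate runs.

## Worked example

```r
library(mcqsar)

ds  <- flavonol_pic50()                      # packaged 80-compound dataset
fit <- mc_optimize(ds, "split3", threshold = 1, epochs = 7,
                   tf = "tf2", seed = 1)
print(fit)
```

```
Monte Carlo QSAR fit (TF2, split split3, T = 1, N = 7, seed = 1)
pIC50 = 0.6809 + 0.0243 x DCW(1, 7)
  set  n    r2 r2_det   ccc   iic   q2     s   mae    f rm2_mean rm2_delta
  TRN 30 0.657  0.657 0.793 0.810 0.58 0.322 0.244 53.5       NA        NA
 iTRN 18 0.819  0.814 0.902 0.561   NA 0.215 0.169   NA       NA        NA
  CAL 12 0.615  0.568 0.672 0.783   NA 0.362 0.306   NA       NA        NA
  VAL 20 0.651  0.637 0.802 0.619   NA 0.298 0.247   NA    0.523     0.129
```

The fit reports one row per set: `r2` is the squared Pearson correlation of
observed versus predicted pIC50 (0.651 on the 20 held-out validation
compounds here, against 0.727 for the published split-3 model), `q2` the
leave-one-out cross-validation on the training set, `iic` the index of
ideality of correlation, `s`/`mae` the error magnitudes in pIC50 units, and
`rm2_mean`/`rm2_delta` Roy's external-validation metrics. Applicability
domain flags come from the statistical defects:

```r
X  <- profile_matrix(ds)
md <- molecule_defects(X, ds, "split3", blocked = fit$cw$blocked)
md$id[md$outlier]
#> [1] "3"  "41" "59" "60" "61"
```

i.e. five compounds carry attribute distributions that differ enough
between the training and calibration sets to make their predictions less
reliable.

The `analysis/` directory holds the full narrative workflow as numbered
scripts — dataset overview, descriptor census, the six trained models (TF1
and TF2 on three splits), deterministic reproduction of the published
numbers, applicability domain, promoter interpretation, and the
synthetic-library recovery study. Each writes its tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

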