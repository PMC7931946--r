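# otsa — off-target safety assessment by ensemble target prediction

`otsa` predicts the off-target interaction profile of a small molecule from
its 2-D structure alone, by combining six orthogonal ligand-centric
target-prediction methods into a single normalized **pseudo-score** and a
**consensus filter**. It is aimed at early safety assessment: given a
candidate compound (optionally together with its metabolites) and a reference
database of known compound–target activities, it produces a ranked report of
predicted interactions, classifies each as *training-set*, *previously
confirmed* or *new*, and can restrict the report to targets expressed in a
tissue of interest.

## The model

Each query molecule is scored against every target in the reference database
by six methods:

| Method | Idea |
|---|---|
| **SIM** | nearest-neighbor similarity to the target's actives: mean of fingerprint Tanimoto, pharmacophore-fragment (PHRAG) multiset similarity, and exp(−d) of the Shannon-entropy descriptor (SHED) distance |
| **SEA** | set-wise similarity of the query against the target's entire ligand set, calibrated against random sets and expressed as an extreme-value E-value |
| **SAS** | similarity-active-subgraph: minimal pharmacophore label paths mined to be present in ≥ 80 % of a target's actives and ≤ 10 % of background |
| **SAR** | per-target regularized logistic classifier on feature-pair distributions (FPD) + SHED + global properties, actives vs. 1:3 property-matched decoys |
| **MLM** | per-target consensus of three classifiers (decision-tree ensemble, kernel max-margin, feed-forward network) on FPD vectors |
| **XPI** | cross-pharmacology index: targets linked through shared active ligands, X(t,u) = \|actives(t) ∩ actives(u)\| / min(\|actives\|) |

Scores lie in [0, 1]. The **pseudo-score** is the weighted mean of the
methods that produced a score (a score of exactly 1.00 denotes training-set
certainty: the query's canonical SMILES carries an active annotation for that
target). An interaction is **high-confidence** when at least 3 of the 6
methods score ≥ 0.6; training-set interactions pass unconditionally. All
thresholds (τ = 0.6, k = 3, weights, the SEA Tanimoto cutoff τ_T = 0.57, …)
are exposed in `otsaConfig()` / a YAML config file.

Stereochemistry is deliberately ignored: every molecule is canonicalized with
stereo and isotope labels stripped and the largest fragment retained, so
enantiomers receive identical descriptors, scores and properties by
construction.

The package also ships a physicochemical profiler (Ro5 violations, the
inclusive 3/75 rule, pKa pattern table, promiscuity-by-property-bin tables),
a cohort-comparison statistics battery (ANOVA + Tukey HSD, pairwise Welch,
Wilcoxon rank-sum with exact enumeration for small tie-free samples,
Benjamini–Hochberg FDR), and a synthetic chemogenomics generator with known
ground truth used throughout the test suite.

## Worked example

```r
library(otsa)

m <- parseMolecule("CCN(CC)CCOc1ccc(CC(O)=O)cc1", "example-1")
m
#> Molecule example-1 : CCN(CCOc1ccc(cc1)CC(=O)O)CC (18 heavy atoms)

props <- computeProperties(m)
print(props, digits = 3)
#>      mol_id  MW clogP TPSA HBD HBA n_rotatable n_sp3_carbon pKa_basic
#> 1 example-1 251  2.03 49.8   1   4           8            7      10.6
#>   pKa_acidic logS
#> 1        4.2 -2.4

classifyRules(props)
#>      mol_id      rule_3_75_bin compliant_3_75 ro5_violations pka_7_10
#> 1 example-1 TPSA<75 & clogP<=3          FALSE              0    FALSE
```

End-to-end on the packaged synthetic fixtures (8 targets, one chemotype
each, planted cross-activities, 20 % of each chemotype withheld as queries):

```r
g       <- generateReferenceDb(syntheticSpec())   # seed 17 defaults
queries <- generateQuerySet(g$truth, g$db)        # asserts no leakage
model   <- fitOTSA(g$db)                          # fits all six methods
pred    <- predictTargets(model, queries$queries)
report  <- generateReport(pred)
report
#> OTSAReport: 32 compounds, 58 consensus interactions
#>   (training 0 / confirmed 0 / new 58), 1.8 per compound

head(predictions(report)[, c("mol_id", "target_id", "SIM", "SAR", "MLM",
                             "XPI", "pseudo_score", "n_methods_above")], 3)
#>   mol_id target_id       SIM       SAR       MLM       XPI pseudo_score n_methods_above
#> 1 T01_07       T01 0.8379791 0.9412273 0.8495103 0.6857143    0.7878793               5
#> 2 T01_07       T02 0.7763820 0.6020850 0.2321456 0.6486486    0.5648153               3
#> 3 T01_10       T01 0.8823529 0.9912284 0.9266819 0.6666667    0.8187443               5

str(evaluateRecovery(pred, queries$expected)[1:4])
#> List of 4
#>  $ recall_primary : num 1
#>  $ capture_planted: num 0.833
#>  $ capture_rate   : num 0.974
#>  $ precision      : num 0.638
```

Every withheld query's primary target is recovered, and 5 of the 6 planted
off-target relationships among the withheld queries pass the consensus
filter.

## Command line

A thin CLI wraps the exported API (`inst/scripts/otsa`):

```sh
otsa predict  --db db.tsv --query q.smi [--metabolites meta.tsv] \
              [--truth truth.tsv] [--expr expr.tsv --tissue liver --min-expr 1] \
              [--config otsa.yaml] --seed 17 --out report/
otsa profile  --query q.smi --out profiles.tsv
otsa compare  --profiles-a a.tsv --profiles-b b.tsv --out comparison.tsv
otsa simulate [--spec spec.yaml] --out fixtures/
otsa evaluate --report report/ --truth truth.tsv --out metrics.json
```

`predict` writes `predictions.tsv`, `summary.json` and the full
(pre-consensus) table `predictions_all.tsv`.

## Scope and caveats

- Predictions are qualitative (interaction likely / not supported); no
  affinities, no binding modes, no safety-outcome modeling.
- Prediction quality is bounded by the reference database: a target with no
  annotated ligands is invisible to all six methods, and one with fewer than
  `minActives` (default 5) actives is scored only by SIM/SEA/XPI.
- The synthetic fixtures are engineered for testability, not for realism of
  chemical space; see the vignette for what they do and do not establish.
- SEA E-values at small database scale are necessarily modest (a single-query
  set tops out near E ≈ 10⁻⁶ here), so SEA contributes to the pseudo-score
  but rarely clears the consensus threshold on its own at this scale.

See `vignette("otsa-methods")` for the full model description, parameter
table and numerical choices.
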