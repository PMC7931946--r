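---
title: "otsa: methods, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{otsa: methods, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `otsa`: what each component
computes, which parameters control it, what the synthetic fixtures do and do
not establish, and the numerical choices that make results reproducible.
Empirical performance statements are confined to what the test suite and the
acceptance script (`scripts/acceptance.R`) actually compute.

# Input model

Molecules enter as SMILES (lists, TSV tables or SDF) and are normalized
before anything else happens:

1. the largest covalently bonded fragment is retained (salts dropped, noted
   in the parse report);
2. the structure is re-emitted as canonical SMILES with stereocenters and
   isotope labels stripped;
3. the molecule is re-parsed from that canonical string.

Step 3 is what makes every downstream quantity invariant to the input
spelling and to stereochemistry *by construction* rather than by per-function
discipline: two SMILES that denote the same constitution produce the same
atom ordering, the same graph and therefore bit-identical descriptors. The
2-D model cannot distinguish enantiomers; this is a stated limitation, not an
oversight.

A reference database is a TSV of `(mol_id, smiles, target_id, label)` rows.
Compounds are deduplicated by canonical SMILES (first id wins, aliases
recorded), conflicting activity labels for one pair are fatal, and targets
with zero actives are dropped with a warning.

# Pharmacophore typing and descriptors

Atoms receive zero or more of six feature labels:

| Label | Rule |
|---|---|
| A (acceptor) | any O; N unless amide, nitro, positively charged or aromatic N–H |
| D (donor) | N or O with at least one attached hydrogen |
| H (hydrophobic) | carbon whose heavy-atom neighbors are all carbon |
| N (negative) | acidic oxygen of carboxylic, sulfonic or phosphonic groups |
| P (positive) | protonatable nitrogen (non-aromatic, all single bonds, not amide) or N⁺ |
| R (aromatic) | atom flagged aromatic by the perception toolkit |

Three descriptor families are built on these labels plus one on raw
structure:

- **FPD** (feature-pair distribution): for each of the 21 unordered label
  pairs, a histogram of topological distances in 1…L bins (default L = 10,
  longer distances collapsed into bin L), normalized to sum 1 over the whole
  vector.
- **SHED**: the Shannon entropy (natural log) of each pair's distance
  distribution, a 21-vector in [0, ln L]; profiles are compared by Euclidean
  distance.
- **PHRAG**: the multiset of label sequences along all shortest paths of 2–7
  atoms, each sequence stored in its lexicographically smaller reading
  direction; two multisets are compared by multiset Tanimoto
  (Σ min / Σ max).
- **Fingerprint**: a hashed circular fingerprint (radius 2, 2048 bits) over
  atom invariants (element, degree, H count, charge, aromaticity, ring
  membership). The hash is a 31-polynomial accumulator modulo 2 147 483 647,
  chosen because every intermediate stays below 2⁵³ and is therefore exact
  in doubles — bit patterns are identical on any IEEE-754 platform.

# The six methods

**SIM.** For each target, the maximum over its actives of the mean of three
similarities: fingerprint Tanimoto, PHRAG similarity and
exp(−d_SHED / σ_S) (σ_S = 1). An exact database copy of an active scores
exactly 1.

**SEA.** The raw score of a query against a target's ligand set is the sum
of pairwise Tanimoto coefficients at or above τ_T = 0.57. A background is
calibrated once per database: 300 random set pairs with sizes log-uniform in
[2, min(200, n/2)], raw-score mean and spread fitted as power laws of the
set-size product by least squares on the log scale over 8 log-bins. The
z-score feeds the extreme-value tail
p = 1 − exp(−exp(−zπ/√6 − γ)) (γ the Euler–Mascheroni constant; at z = 0,
p ≈ 0.4296), E = p · n_targets, and the method score is
min(1, −log₁₀E / `seaScoreScale`) with score 0 when E ≥ 1. The default
scale of 10 means E ≤ 10⁻⁶ clears the consensus threshold; the scale should
grow with database size, since larger ligand sets support smaller E-values.

**SAS.** Per target, up to 3 minimal pharmacophore label paths are mined
breadth-first from frequent labeled edges, accepted when present in ≥ f_A
(default 0.8) of the actives and ≤ f_B (default 0.1) of a size-matched
background sample. A query scores 0.6 + 0.4 × (1 − background fraction) of
the best matching path, 0 otherwise. Note the direct consequence: a target
whose ligand set mixes two chemotypes may support no path at all (coverage
of either chemotype's motif falls below f_A), and SAS then simply abstains
for that target.

**SAR.** Per target, a ridge-regularized logistic model (fixed λ = 0.05) on
standardized FPD ⊕ SHED ⊕ global-property vectors; actives vs. decoys at
1:3, drawn from other targets' actives excluding cross-pharmacology
neighbors (X > 0.8), class-weighted. The score is the predicted probability.

**MLM.** Per target, three classifiers on standardized FPD vectors — a
random forest, an RBF-kernel SVM with Platt probabilities, and a
single-hidden-layer network — with the same decoy scheme. If at least
`mlmVotes` (2) of the three vote positive the score is the mean probability,
otherwise the mean capped at `mlmCap` (0.45). Standardization matters here:
FPD entries are normalized counts of order 10⁻², and both the kernel machine
and the network are scale-sensitive.

**XPI.** The target–target matrix X(t,u) = |actives(t) ∩ actives(u)| /
min(|actives(t)|, |actives(u)|) with unit diagonal. A query's score for
target t is max over u of (nearest-neighbor fingerprint similarity to u's
actives) × X(u, t).

Targets with fewer than `minActives` (5) actives are excluded from SAS, SAR
and MLM fitting and remain scoreable by SIM, SEA and XPI. Scores below
`reportFloor` (0.2) are not emitted; an absent score means "method could not
or did not support this pair", never zero.

# Ensemble, provenance and report

The pseudo-score is the weighted mean of the *present* method scores
(equal weights by default; `absentAsZero = TRUE` switches to penalizing
absences). A pair whose query carries an active annotation for that target
in the database — by exact canonical-SMILES match, never by similarity —
scores exactly 1.00. The consensus filter passes a pair when at least k = 3
of the six methods score ≥ τ = 0.6 (the comparator is configurable);
training-set pairs pass unconditionally. The rule is monotone: raising any
method score never converts a pass into a fail.

Consensus-passing predictions get exactly one provenance value:
`training_set`, else `confirmed` (pair present in a user-supplied truth
table), else `new`. The report ranks each compound's predictions by
descending pseudo-score with deterministic tie-breaking (methods-above
count, then target id) and carries the cohort arithmetic: total = confirmed
+ new + training, mean interactions per compound (one decimal when
rendered), per-method coverage among non-training interactions, and the
all-six-methods fraction. An optional expression filter keeps predictions
whose target is expressed at or above a threshold in a chosen tissue;
targets absent from the matrix are kept and flagged `unknown`, because the
filter only removes what the data can rule out.

# Statistics battery

Cohort property profiles are compared per descriptor with one-way ANOVA,
Tukey HSD, pairwise Welch tests and the Wilcoxon rank-sum test, with
Benjamini–Hochberg adjustment across descriptors; raw and adjusted p-values
are both reported. The Wilcoxon p-value is computed by exact enumeration
when both groups have n ≤ 10 and there are no ties, and by the
tie-corrected normal approximation otherwise — the cutoff is where a
brute-force enumeration oracle is feasible, and the test suite checks exact
agreement with that oracle. Degenerate comparisons (all groups constant at
equal means) report p = 1 with a flag rather than an error.

# The synthetic fixtures: scope

`generateReferenceDb(syntheticSpec())` builds the fixtures used by the test
suite: 8 targets in 4 families, one chemotype per target, 20 members per
chemotype (a scaffold from a packaged ~60-scaffold library combined with 24
enumerated alkyl/halogen decorations), each chemotype planted onto its
family partner target at fraction 0.3, 60 unannotated decoys, and 20 % of
each chemotype withheld as queries whose canonical SMILES are asserted never
to occur in the database. The decorations are deliberately
pharmacophore-neutral, so chemotype members are near-duplicates in
descriptor space — that is the construction the recovery invariants rely
on.

What the fixtures establish: the plumbing is sound end to end (fit → score
→ aggregate → filter → report), withheld same-chemotype queries recover
their primary targets, and planted cross-activities are recoverable through
the ensemble. What they do not establish: performance on real chemical
space, realistic decoy difficulty, or anything about absolute hit rates —
the fixtures are engineered to be solvable.

# Numerical and reproducibility choices

- All stochastic steps (background calibration, decoy sampling, classifier
  fits, the generator) are seeded; per-target classifier seeds are derived
  as `seed + hash(target) mod 10000`, keeping every derived seed well below
  2³¹.
- Iteration is over sorted identifiers everywhere, so outputs are
  order-independent and byte-reproducible for a given seed.
- The SEA tail uses `-expm1(-exp(x))` to keep p-values accurate for very
  negative extreme-value arguments, and E-values are floored at 10⁻³⁰⁰
  before the log.
- The fingerprint hash is exact integer arithmetic within doubles (modulus
  2³¹ − 1), avoiding platform-dependent bit patterns.
- Standard numerical machinery is delegated: molecule parsing,
  canonicalization, MW/TPSA/logP to the chemistry toolkit; regularized
  logistic regression, random forest, SVM and neural network to their
  established implementations; ANOVA, Tukey HSD, Welch, Wilcoxon and BH to
  base R.

# Limitations

- 2-D only: enantiomers are indistinguishable on purpose; molecules whose
  activity depends on stereochemistry will be conflated.
- Ligand-centric: targets without annotated ligands cannot be predicted,
  and sparsely annotated targets are served by only three of six methods.
- SEA E-values scale with the database; at desk scale a single-query set
  cannot reach the extreme E-values attainable against large corpora, so
  SEA mostly strengthens the pseudo-score rather than the consensus count.
- The pKa assignment is a pattern table (amine/aniline/imidazole/pyridine,
  carboxylic/sulfonic/phosphonic/phenol), not a prediction model; compounds
  outside those patterns get NA.
- Potency is carried through loading but unused: all predictions are
  qualitative.
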