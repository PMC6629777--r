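---
title: "Methods: features, classifier and synthetic benchmarks in drugsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: features, classifier and synthetic benchmarks in drugsyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsyn)
```

`drugsyn` classifies unordered drug pairs as synergistic (positive class)
or antagonistic (negative class). This vignette documents the scientific
choices behind the package: how each feature is defined, where the design
was genuinely open and what we picked, how the classifier layer is
assessed, and what the synthetic benchmark does and does not demonstrate.

## The seven pair features

**Indication and ADR overlap (`did`, `adrid`).** Jaccard indices over the
two drugs' disease and adverse-drug-reaction annotation sets. When both
sets are empty the ratio 0/0 is undefined; we return `NA` rather than 0,
because an unannotated drug is missing evidence, not evidence of
dissimilarity. This missing-not-zero rule is applied uniformly across all
features.

**Biological-process similarity (`bps`).** Each drug's GO BP term set is
the union of annotations over its protein interactants; the two unions
are compared with Wang's graph-based semantic similarity combined by
best-match average (BMA). Wang's S-value of ancestor `t` for an anchored
term is the maximum over paths of the product of edge weights, with the
conventional weights 0.8 for `is_a` and 0.6 for `part_of` — the defaults
of the standard GO semantic-similarity toolchain. We aggregate at the
drug level (one union, one BMA) rather than averaging per-target
similarities: it is deterministic, insensitive to how targets partition
annotations, and matches the notion of "the biological processes the
drug touches". Only `is_a` and `part_of` edges are read from an OBO
file, since those are the two relations the measure weights; other
relationship types are ignored with a warning.

**Similarity of mode of action (`sma`).** The signed directed protein
network encodes promotive (+1) and inhibitory (−1) interactions. The
influence of drug *b* on a target *t* of drug *a* is carried along
*all* shortest paths from *b* to *t*; a path's sign is the product of
its edge signs, so promote∘promote = promote, promote∘inhibit = inhibit,
inhibit∘inhibit = promote. Each path coefficient is +1 if the propagated
mode equals drug *a*'s own action sign on *t* and −1 otherwise;
coefficients are averaged over the tied shortest paths, per-target means
are summed over both directions, and the total is normalized by the sum
of absolute per-target means, giving a score in [−1, 1] that attains ±1
exactly when the partner reproduces (or opposes) every direct mode.

Three choices here were open:

* *Drug-as-virtual-node.* "A shortest path from drug b to target t" is
  realized by attaching a virtual node per drug with one signed edge to
  each of its direct targets (the drug's own action sign). This makes
  the drug's action part of the propagated sign and handles the case
  where *t* is itself a direct target of *b* (the path is the single
  virtual edge, and the comparison is between the two drugs' direct
  signs).
* *No-path targets* are excluded from numerator and denominator alike.
  Including them (e.g. as zeros) would dilute defined evidence with
  undefined evidence.
* *Balanced evidence* (all per-target path means cancel) leaves a zero
  denominator: the score is `NA` with an explanatory reason in the
  returned breakdown, not 0 — "no verdict" differs from "equally mixed
  verdict" only in the denominator, and we surface the distinction.

**Separation score (`ss`).** Network separation of the two target
modules on an undirected PPI network:
s_ab = ⟨d_ab⟩ − (⟨d_aa⟩ + ⟨d_bb⟩)/2, with hop-count distances. Within a
set, each mapped protein contributes its distance to the nearest *other*
member (singletons contribute 0); across sets, every mapped protein of
A ∪ B contributes its distance to the nearest member of the opposite
set, a protein present in both sets contributing 0. Proteins absent from
the network or unreachable are excluded from the averages and counted in
`n_excluded` instead of being assigned an arbitrary large distance. The
whole network is used as given; we do not restrict to the largest
connected component, since unreachability is already handled explicitly.

**Chemical similarity (`chem`).** Tanimoto coefficient on binary
molecular fingerprints. The default backend hashes linear atom paths of
length 1–7 into 1024 bits (Open Babel's FP2), a standard
topological-path fingerprint; the backend is a plain function argument,
so any SMILES→bits implementation can be swapped in. Unparseable or
absent SMILES, or two empty fingerprints, give `NA`.

**ATC similarity (`atc`).** For one code pair, k/5 where k is the number
of leading ATC levels (prefix lengths 1, 3, 4, 5, 7) on which the codes
agree; the drug-level value is the maximum over all code pairs. The
exact induction formula used by the upstream literature is not fully
specified, so this deepest-shared-level rule is our documented stand-in;
it is symmetric, lives on the grid {0, 0.2, …, 1}, and equals 1 exactly
for identical substances.

## Classifier layer

The classifier is gradient-boosted trees (xgboost) with the binary
logistic objective and library defaults (η = 0.3, depth 6, 100 rounds,
one thread); hyperparameter tuning is deliberately out of scope, and all
values are recorded in run manifests. Boosted trees route missing
feature values through learned default directions, which is why the full
pipeline never imputes. Baselines (logistic regression, naive Bayes,
random forest, all at library defaults) cannot do this and receive
complete-case rows only — mirroring the practice of restricting model
*comparison* to pairs with all features present.

Probabilities above 0.5 lean synergistic and below 0.5 antagonistic; the
0.5 threshold is part of the interpretation scale and is never tuned. A
configurable band (default ±0.05) around 0.5 flags additive-leaning
pairs.

Assessment follows a repeated stratified CV design: each of 50
repetitions draws a fresh 5-fold assignment in which per-fold class
counts deviate from perfect proportionality by less than one member
(shuffle within class, deal round-robin over a shuffled fold order); the
metric panel (AUC by midrank statistic, sensitivity, specificity, PPV,
NPV, accuracy, F1) is computed on each repetition's pooled out-of-fold
predictions and summarized as mean ± SD. Repeat r uses seed
`base_seed + r`, so any single repetition can be reproduced in
isolation. The per-pair, per-repeat correctness record feeds the
applicability-domain analysis.

The subset search evaluates all 2⁷ − 1 = 127 non-empty feature subsets
under a shared fold scheme and ranks them by mean CV accuracy; ties
prefer the smaller subset, then lexicographic order, so the winner is
deterministic. The Y-scrambling permutation test refits the model on
label-shuffled training copies and reports
p = (1 + #{null ≥ observed}) / (n_perm + 1); the +1 correction keeps
p > 0 with finite permutations.

## Interpretation layer

Pairs predicted correctly (or wrongly) in *every* CV repetition define
the always-correct and always-wrong sets. Per ATC anatomical main group
(first letter), drugs in those pairs are tallied — once per pair
membership, so a drug recurring in k consistent pairs contributes k,
preserving pair-level evidence — into a 2×2 table tested with two-sided
Fisher's exact test. Two odds-ratio conventions are reported side by
side: the classic cross-product ratio and the proportion ratio (group
share among correct-pair drugs over group share among wrong-pair
drugs). The verbal definition and the tabulated direction of this
statistic disagree in parts of the upstream literature, so we surface
both rather than silently choosing one. Pathway enrichment is the exact
hypergeometric upper tail against the union of the supplied gene sets
(the most conservative background available without a genome
assumption), Bonferroni-adjusted, significant at adjusted p < 0.01.

## The synthetic benchmark

The generator (`sim_config()` / `sim_study()`) emulates every input at
toy scale: drug annotation tables with Poisson-sized disease/ADR sets,
signed Erdős–Rényi directed networks, an undirected Erdős–Rényi PPI, a
regular GO BP tree with mixed `is_a`/`part_of` edges, random pathway
sets, and a pool of real drug-like SMILES. Labels follow
Bernoulli(logistic(β·z + ε)) on the within-fixture standardized
features, ε ~ N(0, σ), so the feature–label association is known by
construction. Defaults: 40 drugs, 60 proteins, 400 pairs, β = +3 on
`adrid` and −3 on `bps` (the directions in which synergistic pairs
differ most consistently from antagonistic ones in curated data), σ =
0.5, and an intercept of 2.5 chosen from the logistic-normal
approximation so the realized synergistic prevalence sits near the
roughly 3:1 ratio of curated combination datasets. Missing features
contribute 0 to the linear predictor (the label reflects the evidence
that exists), and a configurable per-feature masking rate exercises the
complete-case path.

What the benchmark shows: that the feature extractors implement their
definitions exactly (they are checked against brute-force path
enumeration, BFS, hypergeometric enumeration and hand-computed ontology
arithmetic), that the CV/search/permutation machinery is calibrated
(null fixtures give chance accuracy and flat permutation p-values;
planted signal is recovered in the importance ranking and by the
permutation test), and that the whole pipeline runs end to end. What it
does not show: performance on real pharmacological data. Synthetic
annotations are independent draws, while real indication, ADR and
target data are strongly correlated across features and drugs, real
networks are scale-free rather than Erdős–Rényi, and real labels are
curated with their own biases. Absolute metric values on fixtures
therefore transfer to no real dataset, and the benchmark cohort used by
`scripts/acceptance.R` — complete cases arranged into the reference
design of 115 training pairs (85:30) and 58 validation pairs (42:16) —
reproduces a study *design*, not its data.

## Numerical choices and degenerate inputs

* Distances are unweighted hop counts; all shortest-path ties are
  enumerated, never sampled.
* AUC uses midranks, so tied probabilities contribute ½.
* Metrics with empty denominators (e.g. PPV with no positive calls) are
  `NA`, and one-class AUC is `NA` with a warning.
* Identifiers are compared case-sensitively after whitespace trimming.
* Action-sign vocabulary: {activate, agonist, promote, +, +1} → +1;
  {inhibit, antagonist, block, −, −1} → −1; anything else is an error —
  explicit failure beats silent guessing. Conflicting duplicate signed
  edges, and conflicting drug–target modes, are errors for the same
  reason.
* Self-loops are rejected in the signed network and dropped (with a
  warning) in the PPI; term hierarchies must be acyclic.
* Seeded determinism everywhere: the generator is byte-stable given its
  config; training fixes the RNG and runs single-threaded.

Problem sizes in the test suite were chosen to keep the full run in a
few minutes while leaving the statistical checks well-powered: oracle
comparisons use 100+ random graphs (up to 8 nodes where exhaustive path
enumeration is the oracle, up to 30 for BFS-based checks), metric
identities use 1,000 random confusion settings, permutation-test
calibration uses 20 seeded null runs and a 200-permutation planted-signal
run, and the benchmark cohort uses the full 50 × 5 CV design.

## Known limitations

* The ATC similarity rule and the Wang/BMA configuration are documented
  stand-ins for upstream choices that are not fully specified; other
  configurations would shift `atc` and `bps` values.
* SMA treats all shortest paths as equally informative and ignores
  longer paths entirely; no weighting by path multiplicity or length is
  attempted.
* The separation score inherits the usual caveats of hop-count
  distances on incomplete interactomes.
* Baselines are deliberately untuned; comparisons say "at defaults",
  nothing more.
* The interpretation layer tests one ATC level (anatomical main group)
  and assumes pathway gene sets and target identifiers share a
  namespace.
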