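---
title: "Methods: ranking enzymatic reactions by chemical similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking enzymatic reactions by chemical similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzrank)
```

## Model and procedure

The package answers one question: *given a chemical transformation observed
or hypothesised in a microbial community, which characterised enzymes are
most likely to carry it out?*  The procedure is:

1. **Reaction representation.** A reaction is a pair of dot-separated
   SMILES sides (substrates plus cofactors, and products).  Every molecule
   is fingerprinted individually and the reaction is represented by its
   *difference fingerprint*: the element-wise sum of product fingerprints
   minus the sum of reactant-side fingerprints.  Features unchanged by the
   transformation cancel, leaving a signed count vector that describes the
   chemical change itself rather than the participating scaffolds.
2. **Chemical space.** All `N` reference reactions are compared pairwise
   with a count Tanimoto coefficient, giving an `N x N` similarity matrix.
   Each reaction's row is its coordinate vector.  A query is embedded by
   computing its Tanimoto similarity to every reference reaction, and the
   references are ranked by ascending Euclidean distance between the query
   vector and each reference row.
3. **EC prediction.** The ranked list carries the references' EC
   annotations.  For each candidate EC code a rank-based enrichment walk is
   run down the list; significance comes from a permutation null.
4. **Enzyme reporting.** The top-ranked reactions' annotated enzyme
   families have been searched (as profile HMMs) against a gene catalogue;
   their hits, filtered on e-value and alignment length, are the candidate
   enzymes for the query.

## Fingerprints and similarity

The default fingerprint is the Carhart **atom pair** descriptor set: for
every pair of heavy atoms, the atom types (element, heavy-atom degree,
pi-electron count) plus their topological distance form a feature, and the
fingerprint is the multiset of such features (`ChemmineR::sdf2ap`).  Three
alternatives are available: a hand-enumerated four-atom **torsion**
fingerprint using the same atom invariants, and OpenBabel's **pattern**
(FP4, SMARTS functional groups) and **path** (FP2, linear fragments up to
length 7) bit fingerprints, treated as 0/1 counts.

Two signed difference vectors \(x, y\) are compared with a count Tanimoto
coefficient computed on the positive and negative parts separately:

\[
T(x, y) = \frac{\sum_k \min(x_k^+, y_k^+) + \min(x_k^-, y_k^-)}
               {\sum_k \max(x_k^+, y_k^+) + \max(x_k^-, y_k^-)}
\]

where \(x^+ = \max(x, 0)\) and \(x^- = \max(-x, 0)\).  A gained feature in
one reaction never matches a lost feature in the other, so direction of
change matters.  Conventions: two empty difference vectors (a null
transformation) have similarity 1; an empty versus non-empty vector has
similarity 0.

The choice of atom-pair definition is substantive: with this package's
Carhart atom pairs the methotrexate/folate hydrolysis pair scores
`r round(tanimoto(fingerprint_reaction(reference_reactions()$mtx_hydrolysis),
fingerprint_reaction(reference_reactions()$folate_hydrolysis)), 3)`
(0.6 at one decimal).  Hashed atom-pair variants from other
cheminformatics toolkits include different invariants and score the same
pair near 0.8; they are not interchangeable.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| fingerprint | `atompair` | Carhart atom pairs |
| `n_perm` | 1000 | permutations per enrichment test |
| `alpha` | 0.05 | enrichment significance threshold |
| PCA | off | opt-in reduction, Kaiser criterion (eigenvalue > 1) |
| identity gate | 27% | median pairwise identity required for a multi-sequence profile |
| hit e-value | < 1e-5 | strict upper bound |
| hit alignment | >= 50% | of profile length, inclusive |
| marker coverage | >= 0.75 | per single-copy gene, all 15, inclusive |
| gene presence | >= 0.35 | copies per cell, inclusive |

## Enrichment statistic

Walking down the ranked list, the running sum gains +1 at positions whose
annotation matches the candidate code (truncated to the target resolution;
any code of a multi-annotated reaction may match) and loses 1 otherwise.
The enrichment score (ES) is the maximum *positive* excursion of the walk;
a walk that never rises above zero scores 0 with an undefined (NA) peak
position.  ES is normalised by the number of occurrences `m` of the code
(NES = ES/m, in [0, 1]).  The p-value is the add-one permutation estimate

\[
p = \frac{1 + \#\{\mathrm{NES}_{perm} \ge \mathrm{NES}_{obs}\}}{n_{perm} + 1},
\]

which is never smaller than `1/(n_perm + 1)`.  Significant codes are
reported sorted by ascending peak position (earlier peaks indicate
stronger top-of-list concentration), then the remaining codes by p-value.

Because the observed score is a small non-negative integer, the null
distribution of p-values is *sub-uniform*: whenever the observed ES is 0,
every permutation ties or beats it and p = 1.  The test is therefore
conservative, with near-exact calibration in the small-p tail — the region
that matters for calling significance.

## Synthetic data: what it does and does not emulate

All tests and examples run on a generated database, a pure function of its
seed.  Six EC classes (alcohol oxidation, amine methylation, methyl-ester
hydrolysis, decarboxylation, double-bond migration, amide ligation) are
instantiated on a series of alkyl/aryl scaffolds, eight reactions per
class by default (`N = 48`).  Each reaction carries a four-level EC code,
2–6 synthetic enzyme sequences (a per-class seed protein mutated at a
shared site set; two reactions per class share one enzyme id so
shared-enzyme analyses have signal), and a mock profile-search hit table
with gut-taxonomy annotations.

The generator emulates the *structure* of a curated reaction database —
class-consistent transformation chemistry, multi-sequence enzyme
annotations, hit tables — at a size (tens of reactions) where every
pairwise quantity can be verified against brute-force oracles.  It does
not emulate reaction-database scale (thousands of reactions), unbalanced
class sizes, annotation noise, or realistic protein evolution
(substitutions are uniform over the other 19 amino acids at a fixed site
set; no indels).

Protein families are generated to a target pairwise identity `t`: a site
is mutable with probability `(1 - t/100) * 19/18` and mutable sites are
substituted independently per sequence, so two sequences agree at a
mutable site with probability 1/19 and the expected identity equals `t`.

## Numerical choices

* Ranking ties are broken lexicographically by reaction id, so output is
  deterministic.
* `normalized_distance` is the Euclidean distance divided by `sqrt(N)`,
  making values comparable across database sizes (each coordinate is in
  [0, 1], so the maximum possible distance is `sqrt(N)`).
* Global sequence identity is Needleman–Wunsch (BLOSUM62, gap opening 10,
  extension 0.5) with identities divided by the full alignment length,
  gaps included — the strictest of the common identity definitions, used
  for the 27% profile gate.
* Gene copy number is read depth normalised by the *median* of the 15
  single-copy marker coverages, robust to a single mis-mapped marker.
* In validation, a database reaction used as its own query has its row
  removed from the ranked list before enrichment (leave-self-out), so
  self-matches cannot inflate accuracy.
* Exact 2x2 statistics: the two-sided p-value sums hypergeometric
  probabilities not exceeding the observed table's (with a `1 + 1e-7`
  relative tolerance against ties lost to floating point); the sample odds
  ratio is `ad/bc`, reported as infinite (with a flag) when `bc = 0`.

## Limitations

Chemical-space coordinates depend on the reference database: adding
reactions changes every coordinate vector.  The enrichment test loses
power for codes with a single occurrence (`m = 1`), where the attainable
p-value floor is approximately the code's rank fraction.  Binary
(pattern/path) fingerprints discard count information and are less
discriminating for reactions differing only in feature multiplicity.  The
protonation hook's rule mode handles only carboxylic acids; full
microspecies enumeration is out of scope.
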