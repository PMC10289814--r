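# enzrank

Rank enzyme-annotated reference reactions by chemical similarity to a
query reaction, predict the query's EC code by rank-based enrichment, and
report candidate enzymes from profile-search hits.

## The science

Microbial communities transform drugs and dietary compounds through
enzymes that are mostly uncharacterised. When the chemical transformation
is known (or hypothesised) but the responsible enzyme is not, the
transformation itself is evidence: chemically similar reactions tend to be
catalysed by evolutionarily related enzymes.

`enzrank` operationalises this idea:

1. **Difference fingerprints.** Each molecule of a reaction is
   fingerprinted (Carhart atom pairs by default), and the reaction is
   represented by products-minus-reactants count vectors, so features
   untouched by the transformation cancel.
2. **Chemical space.** Reference reactions are compared all-vs-all with a
   count Tanimoto coefficient on the signed difference vectors; each
   reaction's similarity row is its coordinate. A query is embedded the
   same way and references are ranked by Euclidean distance.
3. **EC enrichment.** A +1/−1 walk down the ranked list scores each
   candidate EC code; significance comes from a permutation null.
4. **Enzyme reporting.** Annotated enzyme families of the top-ranked
   reactions are searched as profile HMMs against a gene catalogue
   (HMMER adapter included); hits are filtered at e-value < 1e-5 and
   alignment ≥ 50% of the profile length. Helpers call species presence
   (all 15 single-copy markers covered ≥ 75%) and per-cell gene copy
   number (read depth over median marker coverage, present at ≥ 0.35).

## Worked example: who hydrolyses methotrexate?

Methotrexate (MTX) is hydrolysed by gut bacteria to DAMPA and glutamate.
Treating MTX + water → DAMPA + glutamate as an uncharacterised query, the
chemically analogous folate hydrolysis (EC 3.4.17.11, glutamate
carboxypeptidase) should surface at the top of the ranking.

```r
library(enzrank)

refs <- reference_reactions()
fp_mtx <- fingerprint_reaction(refs$mtx_hydrolysis)
fp_fol <- fingerprint_reaction(refs$folate_hydrolysis)
tanimoto(fp_mtx, fp_fol)
#> [1] 0.625
```

The two hydrolyses share most of their chemical change: Tanimoto 0.625
(0.6 at one decimal). Embedding MTX hydrolysis against a 49-reaction
space (the packaged synthetic database plus folate hydrolysis):

```r
db <- generate_toy_reaction_db(toy_db_spec(seed = 1L))
space <- build_chemical_space(c(db$reactions, list(refs$folate_hydrolysis)))
ranking <- rank_reactions(space, embed_query(space, fp_mtx), "MTX-HYDROLYSIS")
head(ranking, 3)
#>                   rank       reaction_id euclidean_distance normalized_distance
#> FOLATE-HYDROLYSIS    1 FOLATE-HYDROLYSIS          0.3750303          0.05357575
#> RXN-101              2           RXN-101          1.2265862          0.17522660
#> RXN-201              3           RXN-201          1.2619044          0.18027206
#>                   direct_tanimoto  ec_codes
#> FOLATE-HYDROLYSIS           0.625 3.4.17.11
#> RXN-101                     0.000   1.1.1.1
#> RXN-201                     0.000   2.1.1.1
```

Folate hydrolysis ranks first at normalized distance 0.054; every
unrelated reaction sits three times farther away. Enrichment over the
ranked list recovers its serial EC code:

```r
pred <- predict_ec(ranking, space$annotations$ec_codes,
                   resolution = 4, n_perm = 1000, seed = 1)
pred[pred$significant, ]
#>     ec_code es nes    p_value peak_position significant
#> 1 3.4.17.11  1   1 0.02497502             1        TRUE
```

From here, `enzymes_for_query()` joins the top-ranked reactions to their
profile-search hit tables, and `run_pipeline()` wires the whole procedure
(ranking, EC prediction, enzyme reporting, run log) into per-query output
directories. A thin command-line front end ships at `inst/cli/enzrank`.

## Testing

```r
testthat::test_dir("tests/testthat", package = "enzrank",
                   load_package = "installed")
```

The suite checks every statistic against independent oracles: a
brute-force double-sum Tanimoto, a prefix-sum enrichment walk (10,000
random lists), a Gotoh affine-gap alignment scorer, `fisher.test` for the
exact 2x2 statistics, and brute-force pairwise loops over the full toy
similarity matrix. Null calibration, threshold boundary behaviour, seed
determinism and leave-self-out validation (macro F1 vs a shuffled-label
baseline) are covered by property tests.

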