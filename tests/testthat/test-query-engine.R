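# Embedding, Euclidean ranking, PCA reduction, enzyme join.

test_that("embedding a database reaction reproduces its similarity row", {
  sp <- toy_space()
  for (rid in sp$reaction_ids[c(1, 17, 48)]) {
    v <- embed_query(sp, sp$fingerprints[[rid]])
    expect_equal(unname(v), unname(sp$matrix[rid, ]))
  }
})

test_that("embedding matches an element-wise tanimoto oracle", {
  sp <- toy_space()
  fp <- fingerprint_reaction(parse_reaction("q", "CCCC(=O)OC.O",
                                            "CCCC(=O)O.CO"))
  v <- embed_query(sp, fp)
  for (i in seq_along(sp$reaction_ids))
    expect_equal(unname(v[i]),
                 oracle_tanimoto(fp$counts, sp$fingerprints[[i]]$counts))
})

test_that("an empty-difference query is orthogonal to a non-degenerate space", {
  sp <- toy_space()
  fp <- fingerprint_reaction(parse_reaction("null", "CCCCCO", "CCCCCO"))
  expect_length(fp$counts, 0)
  expect_true(all(embed_query(sp, fp) == 0))
})

test_that("method mismatch between query and space is rejected", {
  sp <- toy_space()
  fp <- fingerprint_reaction(parse_reaction("q", "CCO", "CC=O"), "torsion")
  expect_error(embed_query(sp, fp), "mismatch")
})

test_that("every toy reaction retrieves itself at rank 1 with distance 0", {
  sp <- toy_space()
  for (rid in sp$reaction_ids) {
    r <- rank_reactions(sp, embed_query(sp, sp$fingerprints[[rid]]), rid)
    expect_equal(r$reaction_id[1], rid)
    expect_equal(r$euclidean_distance[1], 0)
    # distances never decrease with rank; ranks are 1..N without gaps
    expect_true(all(diff(r$euclidean_distance) >= 0))
    expect_equal(r$rank, seq_len(nrow(r)))
  }
})

test_that("hand-computed L2 distances order a three-reaction space", {
  m <- matrix(c(1, 0.8, 0.1,
                0.8, 1, 0.2,
                0.1, 0.2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sp <- structure(list(reaction_ids = c("a", "b", "c"), matrix = m,
                       method = "atompair", fingerprints = NULL,
                       annotations = list(ec_codes = list(a = character(0),
                                                          b = character(0),
                                                          c = character(0))),
                       reduced_basis = NULL),
                  class = "chemical_space")
  q <- c(0.9, 0.9, 0.15)
  d_oracle <- apply(m, 1, function(row) sqrt(sum((q - row)^2)))
  r <- rank_reactions(sp, q)
  expect_equal(r$reaction_id, names(sort(d_oracle)))
  expect_equal(r$euclidean_distance, unname(sort(d_oracle)))
  expect_error(rank_reactions(sp, q[1:2]), "length")
})

test_that("duplicate-fingerprint reactions tie and break by id", {
  db <- toy_db()
  dup <- db$reactions[[1]]
  dup$reaction_id <- "RXN-000DUP"   # sorts before RXN-101
  sp <- build_chemical_space(c(db$reactions, list(dup)))
  r <- rank_reactions(sp, embed_query(sp, sp$fingerprints[["RXN-101"]]))
  expect_equal(r$euclidean_distance[1], r$euclidean_distance[2])
  expect_equal(r$reaction_id[1:2], c("RXN-000DUP", "RXN-101"))
})

test_that("PCA reduction follows the Kaiser criterion and preserves ranking", {
  sp <- toy_space()
  spr <- reduce_space(sp)
  # eigenvalue oracle: correlation-matrix eigenvalues above 1
  v <- apply(sp$matrix, 2, sd)
  z <- scale(sp$matrix[, v > 0])
  ev <- eigen(stats::cor(sp$matrix[, v > 0]), only.values = TRUE)$values
  expect_equal(ncol(spr$reduced_basis$rotation), sum(ev > 1))
  # self-retrieval survives the reduction
  r <- rank_reactions(spr, embed_query(spr, spr$fingerprints[["RXN-101"]]))
  expect_equal(r$reaction_id[1], "RXN-101")
  expect_lt(r$euclidean_distance[1], 1e-8)
  # full and reduced rankings agree well for an off-database query
  fp <- fingerprint_reaction(parse_reaction("q", "CCCC(=O)OC.O",
                                            "CCCC(=O)O.CO"))
  qv <- embed_query(sp, fp)
  rf <- rank_reactions(sp, qv)
  rr <- rank_reactions(spr, qv)
  rho <- cor(match(rf$reaction_id, rr$reaction_id), seq_len(nrow(rf)),
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("a variance-free space refuses reduction with a diagnostic", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sp <- structure(list(reaction_ids = letters[1:4], matrix = m,
                       method = "atompair", reduced_basis = NULL),
                  class = "chemical_space")
  expect_error(suppressMessages(reduce_space(sp)), "refused")
})

test_that("enzymes_for_query joins, deduplicates and annotates ranks", {
  sp <- toy_space()
  r <- rank_reactions(sp, embed_query(sp, sp$fingerprints[["RXN-101"]]))
  hits <- mock_hits(sp$reaction_ids)
  e1 <- enzymes_for_query(r, hits, k = 1)
  expect_equal(nrow(e1), 3L)
  expect_true(all(e1$source_reaction_id == "RXN-101"))
  expect_true(all(e1$source_rank == 1L))
  # overlapping hit sets deduplicate on (target, source reaction)
  overlap <- rbind(hits, hits[hits$source_reaction_id %in%
                                r$reaction_id[2], ])
  e2 <- enzymes_for_query(r, overlap, k = 2)
  expect_equal(nrow(e2), 6L)
  expect_equal(sort(unique(e2$source_rank)), c(1L, 2L))
  # manual join oracle for k = 2
  manual <- hits[hits$source_reaction_id %in% r$reaction_id[1:2], ]
  expect_setequal(e2$target_id, manual$target_id)
  # a reaction without a hit table warns but does not error
  expect_warning(e3 <- enzymes_for_query(r, hits[0, ], k = 1), "no hit table")
  expect_equal(nrow(e3), 0L)
})
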