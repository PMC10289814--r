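# Sequence identity, profile routing, hit filtering, search adapters.

test_that("global identity reproduces hand-checked values and symmetry", {
  expect_equal(global_identity("AAAA", "AAAA"), 100)
  expect_equal(global_identity("AAAA", "AAAC"), 75)
  expect_equal(global_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  a <- random_protein(60, 101); b <- random_protein(60, 102)
  expect_equal(global_identity(a, b), global_identity(b, a))
  expect_gte(global_identity(a, b), 0)
  expect_lte(global_identity(a, b), 100)
  expect_error(global_identity("", "AAA"), "empty")
})

test_that("alignment scores match a Gotoh affine-gap oracle", {
  set.seed(55)
  for (i in 1:10) {
    a <- random_protein(sample(6:14, 1), 200 + i)
    b <- random_protein(sample(6:14, 1), 300 + i)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = oracle_blosum62(),
      gapOpening = 10, gapExtension = 0.5, type = "global")
    expect_equal(Biostrings::score(pa), oracle_nw_score(a, b))
  }
})

test_that("median pairwise identity pools all unordered pairs", {
  seqs <- c("AAAA", "AAAC", "AACC")
  # pairs: (1,2)=75, (1,3)=50, (2,3)=75 -> median 75
  expect_equal(median_pairwise_identity(seqs), 75)
  expect_error(median_pairwise_identity("AAAA"))
})

test_that("profile routing honours the identity gate and fallback chain", {
  seed <- random_protein(120, 77)
  fam_hi <- generate_protein_family(seed, n = 4, target_identity = 60,
                                    rng_seed = 1)
  expect_equal(decide_route(fam_hi), "multi_sequence_profile")
  fam_lo <- generate_protein_family(seed, n = 4, target_identity = 10,
                                    rng_seed = 2)
  expect_lt(median_pairwise_identity(fam_lo), 27)
  expect_equal(decide_route(fam_lo), "single_sequence")
  expect_equal(decide_route(fam_lo, fallback_profile = "sub.hmm"),
               "fallback_profile")
  # single sequence can never support a multi-sequence profile
  expect_equal(decide_route(seed), "single_sequence")
  expect_equal(decide_route(seed, fallback_profile = "sub.hmm"),
               "fallback_profile")
  # the gate is inclusive at exactly 27
  two <- c("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
           "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  id <- median_pairwise_identity(two)
  expect_equal(decide_route(two, identity_gate = id), "multi_sequence_profile")
  expect_equal(decide_route(two, identity_gate = id + 1e-9),
               "single_sequence")
})

test_that("families at the documented identity regimes route as expected", {
  seed <- random_protein(150, 500)
  # ~30% target identity clears the 27% gate; ~10% does not
  f30 <- generate_protein_family(seed, n = 3, target_identity = 30,
                                 rng_seed = 9)
  expect_gte(median_pairwise_identity(f30), 27)
  f10 <- generate_protein_family(seed, n = 3, target_identity = 10,
                                 rng_seed = 9)
  expect_lt(median_pairwise_identity(f10), 27)
})

test_that("hit filtering applies both thresholds with exact boundaries", {
  hits <- data.frame(
    target_id = paste0("t", 1:5),
    e_value = c(1e-6, 1e-5, 9.99e-6, 1e-10, 1e-10),
    ali_from = 1L, ali_to = c(60L, 60L, 59L, 60L, 61L),
    ali_length = c(60L, 60L, 59L, 60L, 61L),
    profile_length = 120L, stringsAsFactors = FALSE)
  out <- filter_hits(hits, profile_length = 120)
  # e < 1e-5 strictly; ali_length >= 0.5 * 120 = 60 inclusively
  expect_setequal(out$target_id, c("t1", "t4", "t5"))
  expect_false("t2" %in% out$target_id)  # e == 1e-5 excluded
  expect_false("t3" %in% out$target_id)  # 59 < 60 excluded
  # filtering is monotone: loosening a threshold never drops a hit
  loose <- filter_hits(hits, 120, e_max = 1e-4, min_frac = 0.4)
  expect_true(all(out$target_id %in% loose$target_id))
  expect_equal(nrow(filter_hits(hits[0, ], 120)), 0L)
})

test_that("homolog-expansion predicates conjoin and are order-independent", {
  hits <- data.frame(target_id = c("a", "b", "c"),
                     e_value = c(1e-9, 1e-8, 1e-7),
                     ali_length = c(100L, 90L, 80L),
                     stringsAsFactors = FALSE)
  expect_identical(expand_homologs(hits), hits)
  p_len <- function(h) h$ali_length >= 90
  p_id <- function(h) h$target_id != "a"
  o1 <- expand_homologs(hits, list(len = p_len, id = p_id))
  o2 <- expand_homologs(hits, list(id = p_id, len = p_len))
  expect_equal(o1$target_id, "b")
  expect_equal(o1, o2)
  # an erroring predicate excludes the row and warns
  p_bad <- function(h) if (h$target_id == "b") stop("no data") else TRUE
  expect_warning(o3 <- expand_homologs(hits, list(bad = p_bad)), "row 2")
  expect_setequal(o3$target_id, c("a", "c"))
})

test_that("the mock adapter passes its table through run_profile_search", {
  tab <- mock_hits("RXN-101")
  fam <- enzyme_family("RXN-101", c(s1 = random_protein(80, 1)))
  out <- run_profile_search(fam, database = "unused.fasta",
                            adapter = mock_search_adapter(tab))
  expect_equal(out$target_id, tab$target_id)
  expect_equal(out$e_value, tab$e_value)
  filt <- filter_hits(out, profile_length = 120)
  # h1 (1e-10, 100) and h2 (1e-6, 80) pass; h3 fails the e-value cut
  expect_equal(filt$target_id, paste0("RXN-101_h", 1:2))
})

test_that("the domtblout reader parses coordinates and keeps longest domains", {
  lines <- c(
    "# comment line",
    # fields 16-17 are hmm coords, 18-19 alignment coords, 20-21 envelope
    paste("tgt1 - 200 query - 150 1e-40 130.0 0.1 1 2 1e-41 1e-39 120.0 0.1",
          "5 135 10 140 8 150 0.98 first hit desc"),
    paste("tgt2 - 180 query - 150 2e-08 40.0 0.0 1 2 3e-09 5e-08 38.0 0.0",
          "15 55 20 60 18 65 0.90 -"),
    # tgt2's second, longer domain must win
    paste("tgt2 - 180 query - 150 2e-08 40.0 0.0 2 2 1e-09 2e-08 39.0 0.0",
          "25 115 30 120 28 125 0.95 -"))
  f <- tempfile(fileext = ".domtblout")
  writeLines(lines, f)
  on.exit(unlink(f))
  out <- read_domtblout(f)
  expect_equal(nrow(out), 2L)
  r1 <- out[out$target_id == "tgt1", ]
  expect_equal(r1$e_value, 1e-40)
  expect_equal(r1$profile_length, 150L)
  expect_equal(r1$ali_from, 10L)
  expect_equal(r1$ali_to, 140L)
  expect_equal(r1$ali_length, 131L)
  r2 <- out[out$target_id == "tgt2", ]
  expect_equal(r2$ali_length, 91L)   # 30..120, the longer of the two domains
  expect_equal(r2$e_value, 2e-08)
  # empty and comment-only files yield a typed empty frame
  writeLines("# nothing", f)
  expect_equal(nrow(read_domtblout(f)), 0L)
})

test_that("a live profile search recovers family members from a database", {
  seed <- random_protein(160, 900)
  fam_seqs <- generate_protein_family(seed, n = 4, target_identity = 60,
                                      rng_seed = 4)
  names(fam_seqs) <- paste0("member", seq_along(fam_seqs))
  fam <- enzyme_family("RXN-LIVE", fam_seqs)
  expect_equal(fam$route, "multi_sequence_profile")
  db <- tempfile(fileext = ".fasta")
  decoys <- vapply(1:6, function(i) random_protein(160, 1000 + i),
                   character(1))
  writeLines(c(paste0(">member1\n", fam_seqs[["member1"]]),
               paste0(">decoy", 1:6, "\n", decoys)), db)
  on.exit(unlink(db))
  hits <- run_profile_search(fam, db)
  filt <- filter_hits(hits, profile_length = hits$profile_length[1])
  expect_true("member1" %in% filt$target_id)
  # single-sequence route also finds its own query
  solo <- enzyme_family("RXN-SOLO", c(member1 = fam_seqs[["member1"]]))
  expect_equal(solo$route, "single_sequence")
  hits2 <- run_profile_search(solo, db)
  expect_true("member1" %in% hits2$target_id)
})
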