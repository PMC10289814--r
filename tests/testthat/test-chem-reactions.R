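# Reaction parsing, protonation hook, difference fingerprints, Tanimoto.

test_that("parse_reaction preserves side membership and token counts", {
  r <- parse_reaction("r1", "CCOC(C)=O.O", "CCO.CC(=O)O")
  expect_s3_class(r, "reaction_record")
  expect_equal(nrow(r$reactant_side), 2L)
  expect_equal(nrow(r$product_side), 2L)
  expect_equal(r$reactant_side$smiles, c("CCOC(C)=O", "O"))
  expect_equal(r$product_side$role, rep("product", 2))
})

test_that("parse_reaction rejects malformed input with informative errors", {
  expect_error(parse_reaction("r2", "O>>O", "O"), "arrow")
  expect_error(parse_reaction("r3", "", "CCO"), "empty")
  expect_error(parse_reaction("r4", "CCO.", "CCO"), "empty token")
  expect_error(parse_reaction("r5", "C(C", "CCO"), "token 1")
  expect_error(parse_reaction("r6", "CCO", "C1CC"), "token")
})

test_that("the methotrexate fixture parses with two reactants and products", {
  refs <- reference_reactions()
  expect_equal(nrow(refs$mtx_hydrolysis$reactant_side), 2L)
  expect_equal(nrow(refs$mtx_hydrolysis$product_side), 2L)
  expect_equal(refs$mtx_hydrolysis$reactant_side$role,
               c("substrate", "cofactor"))
})

test_that("protonation hook: identity default, carboxyl rule, water", {
  expect_equal(protonate("CCO", 7.4), "CCO")
  expect_equal(protonate("O", 7.4), "O")
  expect_equal(protonate("CC(=O)O", 7.4, method = "rules"), "CC(=O)[O-]")
  # below the carboxyl pKa nothing changes
  expect_equal(protonate("CC(=O)O", 3.0, method = "rules"), "CC(=O)O")
  # esters are untouched by the rule
  expect_equal(protonate("CC(=O)OC", 7.4, method = "rules"), "CC(=O)OC")
  expect_error(protonate("C(C", 7.4), "invalid SMILES")
  custom <- function(s, pH) paste0(s, "")
  expect_equal(protonate("CCO", 7.4, method = custom), "CCO")
})

test_that("identical sides cancel and direction flips the sign, all methods", {
  for (m in c("atompair", "torsion", "pattern", "path")) {
    same <- parse_reaction("s", "CCCCCO.CC", "CC.CCCCCO")
    expect_length(fingerprint_reaction(same, m)$counts, 0)
    fwd <- fingerprint_reaction(parse_reaction("f", "CCCCCO", "CCCCC=O"), m)
    rev <- fingerprint_reaction(parse_reaction("r", "CCCCC=O", "CCCCCO"), m)
    keys <- sort(names(fwd$counts))
    expect_identical(keys, sort(names(rev$counts)))
    expect_true(all(fwd$counts[keys] == -rev$counts[keys]))
  }
})

test_that("unsupported fingerprint method is a configuration error", {
  r <- parse_reaction("r", "CCO", "CC=O")
  expect_error(fingerprint_reaction(r, "morgan"), "unsupported")
  expect_error(mol_fingerprint("CCO", "morgan"), "unsupported")
})

test_that("tanimoto: identity, disjoint keys, empty conventions, symmetry", {
  fp <- function(counts) structure(list(counts = counts, method = "atompair"),
                                   class = "diff_fp")
  x <- fp(c(a = 2L, b = 1L))
  y <- fp(c(c = 3L, d = 1L))
  expect_equal(tanimoto(x, x), 1)
  expect_equal(tanimoto(x, y), 0)
  e <- fp(integer(0))
  expect_equal(tanimoto(e, e), 1)
  expect_equal(tanimoto(e, x), 0)
  # negative counts are compared in their own key range
  z <- fp(c(a = -2L, b = 1L))
  expect_equal(tanimoto(x, z), 1 / 5)
  expect_equal(tanimoto(z, x), tanimoto(x, z))
  m2 <- structure(list(counts = c(a = 1L), method = "torsion"),
                  class = "diff_fp")
  expect_error(tanimoto(x, m2), "mismatch")
})

test_that("tanimoto matches a double-sum oracle on random signed vectors", {
  set.seed(42)
  for (i in 1:50) {
    ka <- sample(letters, sample(1:8, 1))
    kb <- sample(letters, sample(1:8, 1))
    a <- setNames(sample(c(-4:-1, 1:4), length(ka), replace = TRUE), ka)
    b <- setNames(sample(c(-4:-1, 1:4), length(kb), replace = TRUE), kb)
    fa <- structure(list(counts = a, method = "atompair"), class = "diff_fp")
    fb <- structure(list(counts = b, method = "atompair"), class = "diff_fp")
    expect_equal(tanimoto(fa, fb), oracle_tanimoto(a, b))
    expect_equal(tanimoto(fa, fb), tanimoto(fb, fa))
  }
})

test_that("toy-database similarity matrix equals a brute-force pairwise loop", {
  sp <- toy_space()
  n <- length(sp$reaction_ids)
  expect_true(n <= 50)
  expect_equal(dim(sp$matrix), c(n, n))
  expect_equal(unname(diag(sp$matrix)), rep(1, n))
  expect_equal(sp$matrix, t(sp$matrix))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      expect_equal(sp$matrix[i, j],
                   oracle_tanimoto(sp$fingerprints[[i]]$counts,
                                   sp$fingerprints[[j]]$counts))
    }
  }
})

test_that("a duplicated reaction reproduces its original's similarity row", {
  db <- toy_db()
  dup <- db$reactions[[1]]
  dup$reaction_id <- "RXN-DUP"
  sp <- build_chemical_space(c(db$reactions[1:10], list(dup)))
  expect_equal(unname(sp$matrix["RXN-DUP", setdiff(sp$reaction_ids, c("RXN-DUP", "RXN-101"))]),
               unname(sp$matrix["RXN-101", setdiff(sp$reaction_ids, c("RXN-DUP", "RXN-101"))]))
  expect_equal(unname(sp$matrix["RXN-DUP", "RXN-101"]), 1)
})

test_that("unfingerprintable reactions are excluded and reported", {
  db <- toy_db()
  # bypass parse-time validation to emulate a downstream fingerprint failure
  broken <- db$reactions[[1]]
  broken$reaction_id <- "RXN-BAD"
  broken$product_side$smiles[1] <- "not_a_molecule!!"
  expect_warning(sp <- build_chemical_space(c(db$reactions[1:5],
                                              list(broken))),
                 "RXN-BAD")
  expect_false("RXN-BAD" %in% sp$reaction_ids)
  expect_error(suppressWarnings(build_chemical_space(list(broken))),
               "fewer than 2")
})

test_that("full reactant+product representation separates toy EC classes", {
  sp <- toy_space()
  cls <- vapply(sp$annotations$ec_codes, function(x)
    ec_truncate(x[1], 1), character(1))
  dm <- as.matrix(dist(sp$matrix))
  for (cl in unique(cls)) {
    inside <- cls == cl
    within <- dm[inside, inside][upper.tri(dm[inside, inside])]
    between <- dm[inside, !inside]
    expect_lt(mean(within), mean(between))
  }
})
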