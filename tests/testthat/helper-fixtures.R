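# Shared fixtures, built once per session, and independent oracles used to
# cross-check the package's own computations.

.fixture_cache <- new.env(parent = emptyenv())

toy_db <- function() {
  if (is.null(.fixture_cache$db))
    .fixture_cache$db <- generate_toy_reaction_db(toy_db_spec(seed = 1L,
                                                             n_per_class = 8L))
  .fixture_cache$db
}

toy_space <- function() {
  if (is.null(.fixture_cache$space))
    .fixture_cache$space <- build_chemical_space(toy_db()$reactions,
                                                 "atompair")
  .fixture_cache$space
}

random_protein <- function(len, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# --- independent oracles ---------------------------------------------------

# Prefix-sum walk oracle for the enrichment score: explicit loop, no shared
# code with the package implementation.
oracle_es <- function(match_vec) {
  s <- 0L; best <- 0L; peak <- NA_integer_
  for (i in seq_along(match_vec)) {
    s <- s + if (match_vec[i]) 1L else -1L
    if (s > best) { best <- s; peak <- i }
  }
  list(es = best, peak = peak)
}

# Count-Tanimoto oracle on two named signed integer vectors, written as a
# direct double sum over the split positive/negative parts.
oracle_tanimoto <- function(a, b) {
  keys <- union(names(a), names(b))
  num <- 0; den <- 0
  for (k in keys) {
    av <- if (k %in% names(a)) a[[k]] else 0
    bv <- if (k %in% names(b)) b[[k]] else 0
    for (sgn in c(1, -1)) {
      x <- max(sgn * av, 0); y <- max(sgn * bv, 0)
      num <- num + min(x, y); den <- den + max(x, y)
    }
  }
  if (den == 0) 1 else num / den
}

# Gotoh affine-gap global alignment score oracle (gap of length L costs
# open + extend * L, matching the package's documented scheme).
oracle_nw_score <- function(a, b, open = 10, extend = 0.5) {
  sub <- oracle_blosum62()
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - extend * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

oracle_blosum62 <- function() {
  if (is.null(.fixture_cache$blosum)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fixture_cache$blosum <- e$BLOSUM62
  }
  .fixture_cache$blosum
}

# Mock hit table with a known pass/fail structure around the filters.
mock_hits <- function(reaction_ids) {
  do.call(rbind, lapply(reaction_ids, function(rid) {
    data.frame(
      source_reaction_id = rid,
      target_id = paste0(rid, "_h", 1:3),
      e_value = c(1e-10, 1e-6, 1e-3),
      ali_from = 1L, ali_to = c(100L, 80L, 110L),
      ali_length = c(100L, 80L, 110L),
      profile_length = 120L,
      stringsAsFactors = FALSE)
  }))
}
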