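#' @title Synthetic reference data
#' @description Generators producing a complete toy reaction database
#'   (reactions with EC and enzyme annotations, enzyme sequences, and
#'   profile-search hit tables), synthetic protein families, planted-signal
#'   ranked label lists, and the embedded methotrexate/folate reference
#'   reactions.  Every generator is a pure function of its seed.
#' @name synthetic_data
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# One transformation schema per EC class.  Each is a function of a scaffold
# fragment R (SMILES prefix) returning reactant/product token vectors and
# cofactor roles.  The transformations are deliberately simple and valid so
# difference fingerprints stay small and auditable.
.class_schemas <- list(
  list(ec = "1.1.1", name = "alcohol oxidation",
       f = function(R) list(reactants = paste0(R, "CO"),
                            roles = "substrate",
                            products = paste0(R, "C=O"))),
  list(ec = "2.1.1", name = "amine methylation (thiol donor)",
       f = function(R) list(reactants = c(paste0(R, "N"), "CS"),
                            roles = c("substrate", "cofactor"),
                            products = c(paste0(R, "NC"), "S"))),
  list(ec = "3.1.1", name = "methyl-ester hydrolysis",
       f = function(R) list(reactants = c(paste0(R, "C(=O)OC"), "O"),
                            roles = c("substrate", "cofactor"),
                            products = c(paste0(R, "C(=O)O"), "CO"))),
  list(ec = "4.1.1", name = "decarboxylation",
       f = function(R) list(reactants = paste0(R, "CC(=O)O"),
                            roles = "substrate",
                            products = c(paste0(R, "C"), "O=C=O"))),
  list(ec = "5.3.3", name = "double-bond migration",
       f = function(R) list(reactants = paste0(R, "CC=C"),
                            roles = "substrate",
                            products = paste0(R, "C=CC"))),
  list(ec = "6.3.1", name = "amide ligation",
       f = function(R) list(reactants = c(paste0(R, "C(=O)O"), "CN"),
                            roles = c("substrate", "cofactor"),
                            products = c(paste0(R, "C(=O)NC"), "O")))
)

.scaffolds <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CC(C)C", "CCCCC",
                "C1CCCCC1", "c1ccccc1", "CCCCCC", "CC(C)CC", "CCCCCCC")

#' Specification of a toy reaction database
#'
#' @param seed integer master seed.
#' @param n_per_class reactions generated per EC class (>= 2).
#' @param n_hits_range integer range of mock profile-search hits per
#'   reaction.
#' @return object of class `toy_db_spec`.
#' @export
toy_db_spec <- function(seed = 1L, n_per_class = 8L,
                        n_hits_range = c(2L, 5L)) {
  stopifnot(n_per_class >= 2L)
  structure(list(seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 n_hits_range = as.integer(n_hits_range)),
            class = "toy_db_spec")
}

.random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                       collapse = "")

#' Generate a synthetic protein family from a seed sequence
#'
#' Produces `n` sequences by substituting residues of the seed with uniform
#' replacements from the other 19 amino acids.  A single set of mutable
#' sites is drawn per family (fraction (1 - target/100) * 19/18 of
#' positions) and every sequence is substituted independently at those
#' sites, so the expected pairwise identity between any two generated
#' sequences equals the target: conserved sites always match, mutable
#' sites match with probability 1/19.
#'
#' @param seed_sequence character scalar amino-acid sequence.
#' @param n number of sequences.
#' @param target_identity target median pairwise percent identity (0, 100].
#' @param rng_seed integer seed.
#' @return named character vector of `n` sequences.
#' @export
generate_protein_family <- function(seed_sequence, n, target_identity = 60,
                                    rng_seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 100, n >= 1L)
  r <- min(1, (1 - target_identity / 100) * 19 / 18)
  chars <- strsplit(seed_sequence, "")[[1]]
  with_seed(rng_seed, {
    sites <- which(stats::runif(length(chars)) < r)
    out <- vapply(seq_len(n), function(i) {
      s <- chars
      if (length(sites))
        s[sites] <- vapply(s[sites], function(a)
          sample(setdiff(AA20, a), 1L), character(1))
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(out, paste0("fam_seq", seq_len(n)))
  })
}

#' Generate a complete toy reaction database
#'
#' Builds >= 6 EC classes (oxidoreduction, methyl transfer, ester
#' hydrolysis, decarboxylation, double-bond isomerisation, amide ligation),
#' each with `n_per_class` reactions obtained by applying the class
#' transformation to varied scaffolds.  Every reaction is annotated with a
#' four-level EC code and 2-6 synthetic enzyme sequences; within each class
#' one enzyme id is shared by the first two reactions (so shared-enzyme
#' analyses have signal).  A mock profile-search hit table accompanies each
#' reaction.  Generation is a pure function of the `spec` argument.
#'
#' @param spec a `toy_db_spec`.
#' @param dir optional directory: when given, `reactions.tsv`,
#'   `sequences.fasta` and `hits.tsv` are written there.
#' @return list with `reactions` (list of `reaction_record`),
#'   `reactions_tsv` (data frame), `sequences` (named character vector),
#'   `hits` (data frame).
#' @export
generate_toy_reaction_db <- function(spec = toy_db_spec(), dir = NULL) {
  stopifnot(inherits(spec, "toy_db_spec"))
  npc <- spec$n_per_class
  scaffolds <- .scaffolds
  if (npc > length(scaffolds))
    scaffolds <- c(scaffolds,
                   vapply(seq_len(npc - length(scaffolds)),
                          function(k) strrep("C", 7L + k), character(1)))
  taxa <- list(
    c("Bacillota", "Clostridia", "Eubacteriales", "Lachnospiraceae",
      "Blautia", "Blautia obeum"),
    c("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
      "Bacteroides", "Bacteroides fragilis"),
    c("Pseudomonadota", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Escherichia", "Escherichia coli"),
    c("Actinomycetota", "Actinomycetes", "Bifidobacteriales",
      "Bifidobacteriaceae", "Bifidobacterium", "Bifidobacterium longum"))
  with_seed(spec$seed, {
    reactions <- list(); fasta <- character(0); hit_rows <- list()
    tsv_rows <- list()
    for (ci in seq_along(.class_schemas)) {
      schema <- .class_schemas[[ci]]
      seed_seq <- .random_protein(120L)
      shared_id <- sprintf("enz_c%d_shared", ci)
      for (j in seq_len(npc)) {
        rid <- sprintf("RXN-%d%02d", ci, j)
        parts <- schema$f(scaffolds[j])
        ec <- sprintf("%s.%d", schema$ec, j)
        n_seq <- sample(2:6, 1L)
        fam <- generate_protein_family(seed_seq, n_seq, target_identity = 60,
                                       rng_seed = spec$seed * 1000L +
                                         ci * 100L + j)
        seq_ids <- sprintf("%s_seq%d", rid, seq_len(n_seq))
        if (j <= 2L) seq_ids[1] <- shared_id
        names(fam) <- seq_ids
        # the shared enzyme keeps one sequence identity across reactions
        if (j == 2L) fam[1] <- fasta[shared_id]
        fasta <- c(fasta, fam[!(names(fam) %in% names(fasta))])
        rec <- parse_reaction(rid,
                              paste(parts$reactants, collapse = "."),
                              paste(parts$products, collapse = "."),
                              ec_codes = ec, enzyme_seq_ids = seq_ids,
                              roles = parts$roles)
        reactions[[length(reactions) + 1L]] <- rec
        n_hits <- sample(seq(spec$n_hits_range[1], spec$n_hits_range[2]), 1L)
        plen <- 120L
        for (h in seq_len(n_hits)) {
          tx <- taxa[[sample.int(length(taxa), 1L)]]
          alen <- sample(40:120, 1L)
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            source_reaction_id = rid,
            target_id = sprintf("UHGG%05d_%s_h%d",
                                sample.int(99999L, 1L), rid, h),
            e_value = 10^stats::runif(1, -30, -3),
            ali_from = 1L, ali_to = alen, ali_length = alen,
            profile_length = plen,
            genome_id = sprintf("GUT_GENOME%06d", sample.int(999999L, 1L)),
            phylum = tx[1], class = tx[2], order = tx[3], family = tx[4],
            genus = tx[5], species = tx[6],
            predicted_function = schema$name,
            stringsAsFactors = FALSE)
        }
        tsv_rows[[length(tsv_rows) + 1L]] <- data.frame(
          reaction_id = rid,
          reactant_smiles = paste(parts$reactants, collapse = "."),
          product_smiles = paste(parts$products, collapse = "."),
          ec_codes = ec,
          enzyme_seq_ids = paste(seq_ids, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    out <- list(reactions = reactions,
                reactions_tsv = do.call(rbind, tsv_rows),
                sequences = fasta,
                hits = do.call(rbind, hit_rows))
    if (!is.null(dir)) write_toy_db(out, dir)
    out
  })
}

#' Write a toy database to disk in the pipeline's database layout
#'
#' @param db result of [generate_toy_reaction_db()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_db <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(db$reactions_tsv, file.path(dir, "reactions.tsv"))
  write_fasta(db$sequences, file.path(dir, "sequences.fasta"))
  write_tsv(db$hits, file.path(dir, "hits.tsv"))
  invisible(dir)
}

# Canonical SMILES constants for the reference hydrolysis reactions.
.ref_smiles <- c(
  MTX = "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)N[C@@H](CCC(=O)O)C(=O)O)cc1",
  DAMPA = "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)O)cc1",
  glutamate = "N[C@@H](CCC(=O)O)C(=O)O",
  folate = "Nc1nc2ncc(CNc3ccc(C(=O)N[C@@H](CCC(=O)O)C(=O)O)cc3)nc2c(=O)[nH]1",
  pteroate = "Nc1nc2ncc(CNc3ccc(C(=O)O)cc3)nc2c(=O)[nH]1",
  water = "O")

.ref_formula <- c(MTX = "C20H22N8O5", DAMPA = "C15H15N7O2",
                  glutamate = "C5H9NO4", folate = "C19H19N7O6",
                  pteroate = "C14H12N6O3", water = "H2O")

#' Molecular formula of a SMILES (hydrogens included)
#'
#' @param smiles valid SMILES.
#' @return character scalar Hill-order formula.
#' @export
molecular_formula <- function(smiles) {
  g <- mol_graph(smiles)
  if (is.null(g)) stop(sprintf("invalid SMILES: '%s'", smiles),
                       call. = FALSE)
  pr <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles,
                                                   identity))
  as.character(pr$formula)
}

#' The embedded methotrexate and folate hydrolysis reference reactions
#'
#' Methotrexate (MTX) + water -> DAMPA + glutamate, the reaction carried
#' out by gut bacterial glutamate carboxypeptidases, and the chemically
#' analogous folate + water -> pteroate + glutamate.  Each compound's
#' molecular formula is verified against its known formula at load time;
#' a mismatch raises a fixture-integrity error.
#'
#' @return named list of two `reaction_record`s: `mtx_hydrolysis` (no EC
#'   annotation: it is the query) and `folate_hydrolysis` (annotated EC
#'   3.4.17.11).
#' @export
reference_reactions <- function() {
  for (nm in names(.ref_smiles)) {
    mf <- molecular_formula(.ref_smiles[[nm]])
    if (!identical(mf, unname(.ref_formula[[nm]])))
      stop(sprintf(
        "fixture integrity: %s formula is %s, expected %s", nm, mf,
        .ref_formula[[nm]]), call. = FALSE)
  }
  list(
    mtx_hydrolysis = parse_reaction(
      "MTX-HYDROLYSIS",
      paste(.ref_smiles[["MTX"]], .ref_smiles[["water"]], sep = "."),
      paste(.ref_smiles[["DAMPA"]], .ref_smiles[["glutamate"]], sep = "."),
      roles = c("substrate", "cofactor")),
    folate_hydrolysis = parse_reaction(
      "FOLATE-HYDROLYSIS",
      paste(.ref_smiles[["folate"]], .ref_smiles[["water"]], sep = "."),
      paste(.ref_smiles[["pteroate"]], .ref_smiles[["glutamate"]],
            sep = "."),
      ec_codes = "3.4.17.11",
      roles = c("substrate", "cofactor")))
}

#' Generate a ranked label list with a planted enrichment signal
#'
#' Builds a label list from an EC -> count composition, then orders it by
#' per-position random keys: non-planted positions draw u ~ U(0,1) and
#' planted positions draw u * (1 - strength).  Strength 0 is a uniform
#' shuffle; strength 1 front-loads every planted position.
#'
#' @param composition named integer vector: EC code -> count.
#' @param planted EC code to enrich (must be in `composition`).
#' @param strength numeric in \[0,1\].
#' @param seed integer seed.
#' @return list of length `sum(composition)` of single-code character
#'   vectors, in ranked order.
#' @export
generate_ranked_labels <- function(composition, planted, strength = 0.8,
                                   seed = 1L) {
  stopifnot(length(composition) >= 1L, strength >= 0, strength <= 1)
  if (!planted %in% names(composition))
    stop(sprintf("planted code '%s' absent from composition", planted),
         call. = FALSE)
  codes <- rep(names(composition), composition)
  with_seed(seed, {
    u <- stats::runif(length(codes))
    u[codes == planted] <- u[codes == planted] * (1 - strength)
    as.list(codes[order(u)])
  })
}
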