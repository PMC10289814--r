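#' @title Enzyme families, profile searches and hit filtering
#' @name enzyme_kb
NULL

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment under a fixed, documented scheme
#' (BLOSUM62, gap opening 10, gap extension 0.5); identity is the number of
#' identical aligned positions divided by the full alignment length (gaps
#' included in the denominator), times 100.
#'
#' @param seq_a,seq_b character scalars, amino-acid sequences (X tolerated).
#' @return numeric percent in \[0, 100\].
#' @examples
#' global_identity("AAAA", "AAAC")  # 75
#' @export
global_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("empty sequence", call. = FALSE)
  mat <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(pa, type = "PID1")
}

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Median pairwise global identity of a sequence set
#'
#' @param sequences character vector (>= 2) of amino-acid sequences.
#' @return numeric percent: median over all unordered pairs (mean of the
#'   two central values for an even pair count).
#' @export
median_pairwise_identity <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  pairs <- utils::combn(length(sequences), 2L)
  ids <- apply(pairs, 2L, function(p)
    global_identity(sequences[p[1]], sequences[p[2]]))
  stats::median(ids)
}

#' Decide the profile-construction route for an enzyme family
#'
#' A reaction with at least two annotated sequences whose median pairwise
#' global identity reaches 27% gets a multiple-sequence profile.  Below the
#' gate (or with a single sequence), a supplied fallback profile is used if
#' available; otherwise the search falls back to a single-sequence query.
#'
#' @param sequences character vector of amino-acid sequences (>= 1).
#' @param fallback_profile optional path to a prebuilt profile file standing
#'   in for an external subfamily profile; NULL when none exists.
#' @param identity_gate percent identity threshold (default 27).
#' @return one of `"multi_sequence_profile"`, `"fallback_profile"`,
#'   `"single_sequence"`.
#' @export
decide_route <- function(sequences, fallback_profile = NULL,
                         identity_gate = 27) {
  stopifnot(length(sequences) >= 1L)
  if (length(sequences) >= 2L &&
      median_pairwise_identity(sequences) >= identity_gate)
    return("multi_sequence_profile")
  if (!is.null(fallback_profile)) return("fallback_profile")
  "single_sequence"
}

#' Construct an enzyme family for a reaction
#'
#' @param reaction_id reaction identifier.
#' @param sequences named character vector of amino-acid sequences (names
#'   are sequence ids).
#' @param fallback_profile optional prebuilt profile path, see
#'   [decide_route()].
#' @return object of class `enzyme_family` with `reaction_id`, `seq_ids`,
#'   `sequences`, `route`, `fallback_profile`.
#' @export
enzyme_family <- function(reaction_id, sequences, fallback_profile = NULL) {
  stopifnot(length(sequences) >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- paste0(reaction_id, "_seq", seq_along(sequences))
  structure(list(reaction_id = reaction_id,
                 seq_ids = names(sequences),
                 sequences = unname(sequences),
                 route = decide_route(unname(sequences), fallback_profile),
                 fallback_profile = fallback_profile),
            class = "enzyme_family")
}

# ---- search adapters ------------------------------------------------------

#' Mock profile-search adapter backed by a fixed hit table
#'
#' Returns the supplied table unchanged for every search; used in tests and
#' wherever precomputed hit tables replace a live search.
#'
#' @param table data frame with at least `target_id`, `e_value`, `ali_from`,
#'   `ali_to`, `profile_length`.
#' @return adapter object for [run_profile_search()].
#' @export
mock_search_adapter <- function(table) {
  stopifnot(is.data.frame(table))
  structure(list(search = function(family, database) table,
                 name = "mock"),
            class = "search_adapter")
}

#' HMMER-based profile-search adapter
#'
#' Multi-sequence families are aligned with `mafft`, compiled into a profile
#' HMM with `hmmbuild` and searched with `hmmsearch`; single sequences are
#' searched with `phmmer` (which builds a position-independent profile
#' internally).  All three executables must be on the PATH.
#'
#' @param mafft,hmmbuild,hmmsearch,phmmer executable names or paths.
#' @return adapter object for [run_profile_search()].
#' @export
hmmer_search_adapter <- function(mafft = "mafft", hmmbuild = "hmmbuild",
                                 hmmsearch = "hmmsearch",
                                 phmmer = "phmmer") {
  for (exe in c(mafft, hmmbuild, hmmsearch, phmmer))
    if (Sys.which(exe) == "")
      stop(sprintf("profile search requires '%s' on the PATH", exe),
           call. = FALSE)
  search <- function(family, database) {
    td <- tempfile("profsearch"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    qf <- file.path(td, "family.fasta")
    writeLines(paste0(">", family$seq_ids, "\n", family$sequences), qf)
    dom <- file.path(td, "hits.domtblout")
    if (family$route == "multi_sequence_profile") {
      msa <- file.path(td, "family.msa")
      system2(mafft, c("--quiet", "--auto", qf), stdout = msa)
      hmm <- file.path(td, "family.hmm")
      system2(hmmbuild, c("--amino", hmm, msa), stdout = FALSE,
              stderr = FALSE)
      system2(hmmsearch, c("--domtblout", dom, hmm, database),
              stdout = FALSE, stderr = FALSE)
    } else if (family$route == "fallback_profile") {
      system2(hmmsearch, c("--domtblout", dom, family$fallback_profile,
                           database), stdout = FALSE, stderr = FALSE)
    } else {
      one <- file.path(td, "single.fasta")
      writeLines(paste0(">", family$seq_ids[1], "\n", family$sequences[1]),
                 one)
      system2(phmmer, c("--domtblout", dom, one, database),
              stdout = FALSE, stderr = FALSE)
    }
    if (!file.exists(dom)) return(.empty_hits())
    read_domtblout(dom)
  }
  structure(list(search = search, name = "hmmer"), class = "search_adapter")
}

.empty_hits <- function() {
  data.frame(target_id = character(0), e_value = numeric(0),
             ali_from = integer(0), ali_to = integer(0),
             ali_length = integer(0), profile_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Whitespace-delimited with 22 fixed columns plus a free-text description.
#' One row per domain; the full-sequence e-value (column 7) and the
#' alignment coordinates (columns 18-19) are retained, along with the query
#' profile length (column 6).
#'
#' @param path domtblout file.
#' @return data frame with `target_id`, `e_value`, `ali_from`, `ali_to`,
#'   `ali_length`, `profile_length`, `description`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_hits())
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(target_id = f[1],
               e_value = as.numeric(f[7]),
               profile_length = as.integer(f[6]),
               ali_from = as.integer(f[18]),
               ali_to = as.integer(f[19]),
               description = if (length(f) > 22L)
                 paste(f[23:length(f)], collapse = " ") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ali_length <- out$ali_to - out$ali_from + 1L
  # a target may hit with several domains; keep the longest-alignment row
  # per target with the (shared) full-sequence e-value
  out <- out[order(out$target_id, -out$ali_length), , drop = FALSE]
  out <- out[!duplicated(out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("target_id", "e_value", "ali_from", "ali_to", "ali_length",
          "profile_length", "description")]
}

#' Run a profile search for an enzyme family
#'
#' Delegates MSA construction, profile building and searching to the
#' adapter; the package only owns the routing decision and the downstream
#' filtering.
#'
#' @param family an `enzyme_family`.
#' @param database path to a FASTA sequence database.
#' @param adapter a `search_adapter`; defaults to the HMMER adapter.
#' @return data frame of raw hits (see [read_domtblout()] for columns).
#' @export
run_profile_search <- function(family, database,
                               adapter = hmmer_search_adapter()) {
  stopifnot(inherits(family, "enzyme_family"),
            inherits(adapter, "search_adapter"))
  hits <- adapter$search(family, database)
  stopifnot(is.data.frame(hits))
  if (!"ali_length" %in% names(hits) &&
      all(c("ali_from", "ali_to") %in% names(hits)))
    hits$ali_length <- hits$ali_to - hits$ali_from + 1L
  hits
}

#' Filter profile-search hits on significance and alignment length
#'
#' Keeps a hit iff its e-value is below `e_max` and its alignment covers at
#' least `min_frac` of the query profile (or single-sequence) length.
#'
#' @param hits data frame with `e_value` and `ali_length`.
#' @param profile_length length of the input profile alignment or single
#'   sequence, in residues.
#' @param e_max e-value threshold (default 1e-5).
#' @param min_frac minimum alignment-length fraction (default 0.5).
#' @return filtered data frame.
#' @export
filter_hits <- function(hits, profile_length, e_max = 1e-5,
                        min_frac = 0.5) {
  stopifnot(profile_length > 0)
  if (!nrow(hits)) return(hits)
  keep <- hits$e_value < e_max & hits$ali_length >= min_frac * profile_length
  hits[keep, , drop = FALSE]
}

#' Apply pluggable homolog-expansion predicates to filtered hits
#'
#' Each predicate is a pure function of one hit row returning TRUE to keep
#' it; the conjunction of all predicates is applied.  Dataset-backed
#' predicates (small-intestine presence, metatranscriptome presence,
#' substrate-affinity screens) are supplied by the caller, never built in.
#' A predicate that errors on a row excludes the row with a warning.
#'
#' @param hits data frame of hits (post [filter_hits()]).
#' @param predicates named list of functions `f(hit_row) -> logical`.
#' @return filtered data frame.
#' @export
expand_homologs <- function(hits, predicates = list()) {
  if (!length(predicates) || !nrow(hits)) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (nm in names(predicates)) {
    p <- predicates[[nm]]
    for (i in which(keep)) {
      ok <- tryCatch(isTRUE(p(hits[i, , drop = FALSE])), error = function(e) {
        warning(sprintf("predicate '%s' failed on row %d: %s", nm, i,
                        conditionMessage(e)), call. = FALSE)
        FALSE
      })
      keep[i] <- ok
    }
  }
  hits[keep, , drop = FALSE]
}
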