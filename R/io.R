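#' @title Readers, writers and the end-to-end pipeline
#' @name cli_io
NULL

#' Write a data frame as a UTF-8 tab-delimited file with header
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited file written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8")
}

#' Write named sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a reaction database TSV
#'
#' Columns: `reaction_id`, `reactant_smiles` (dot-separated),
#' `product_smiles` (dot-separated), `ec_codes` (semicolon-separated, may
#' be blank), `enzyme_seq_ids` (semicolon-separated, may be blank).
#'
#' @param path TSV path.
#' @return list of `reaction_record`s.
#' @export
read_reaction_db <- function(path) {
  tab <- read_tsv(path)
  need <- c("reaction_id", "reactant_smiles", "product_smiles")
  if (!all(need %in% names(tab)))
    stop(sprintf("reaction database must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  split_field <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  }
  lapply(seq_len(nrow(tab)), function(i)
    parse_reaction(tab$reaction_id[i], tab$reactant_smiles[i],
                   tab$product_smiles[i],
                   ec_codes = if ("ec_codes" %in% names(tab))
                     split_field(tab$ec_codes[i]) else character(0),
                   enzyme_seq_ids = if ("enzyme_seq_ids" %in% names(tab))
                     split_field(tab$enzyme_seq_ids[i]) else character(0)))
}

#' Read a query TSV into reaction records
#'
#' Columns `query_id`, `reactant_smiles`, `product_smiles`; header
#' required.  Row-level parse failures are collected and reported with line
#' numbers while valid rows are still processed; a duplicate `query_id` is
#' a hard error.
#'
#' @param path TSV path.
#' @return list of `reaction_record`s; failed rows are reported in a
#'   warning and attached as attribute `errors` (data frame `line`,
#'   `message`).
#' @export
read_query_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  tab <- read_tsv(path)
  if (nrow(tab) == 0L) stop("query file has no rows", call. = FALSE)
  need <- c("query_id", "reactant_smiles", "product_smiles")
  if (!all(need %in% names(tab)))
    stop(sprintf("query file must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tab$query_id))
    stop("duplicate query_id values in query file", call. = FALSE)
  out <- list(); errs <- list()
  for (i in seq_len(nrow(tab))) {
    rec <- tryCatch(parse_reaction(tab$query_id[i], tab$reactant_smiles[i],
                                   tab$product_smiles[i]),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = i + 1L, message = conditionMessage(rec),
        stringsAsFactors = FALSE)
    } else out[[length(out) + 1L]] <- rec
  }
  if (length(errs)) {
    e <- do.call(rbind, errs)
    warning(sprintf("%d query row(s) failed to parse (lines %s)",
                    nrow(e), paste(e$line, collapse = ", ")),
            call. = FALSE)
    attr(out, "errors") <- e
  }
  out
}

#' Read a profile-search hit table TSV
#'
#' Accepts the packaged hit-table dialect: columns `source_reaction_id`,
#' `target_id`, `e_value`, `ali_from`, `ali_to`, `profile_length`, plus
#' optional annotation columns.  `ali_length` is derived when absent.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_hit_table <- function(path) {
  h <- read_tsv(path)
  need <- c("source_reaction_id", "target_id", "e_value", "profile_length")
  if (!all(need %in% names(h)))
    stop(sprintf("hit table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"ali_length" %in% names(h)) {
    stopifnot(all(c("ali_from", "ali_to") %in% names(h)))
    h$ali_length <- h$ali_to - h$ali_from + 1L
  }
  h
}

#' Run the full query pipeline against a database directory
#'
#' The database directory holds `reactions.tsv`, `sequences.fasta` and
#' `hits.tsv` (see [write_toy_db()] for the layout).  Cross-references are
#' checked before any query runs: a hit row or an annotated enzyme id
#' referencing an unknown reaction or sequence is a hard error.  For each
#' query, four artifacts are written under `out_dir/<query_id>/`:
#' `ranked_reactions.tsv`, `ec_predictions.tsv`, `enzymes.tsv` and
#' `enzymes.fasta`; a `run_log.json` with seed, method, thresholds and
#' package version is written at the top level.
#'
#' @param queries list of `reaction_record`s (e.g. from
#'   [read_query_tsv()]).
#' @param db_dir database directory.
#' @param out_dir output directory (created).
#' @param method fingerprint method.
#' @param top_k number of top-ranked reactions whose enzymes are reported.
#' @param resolution EC resolution(s) to predict, subset of 1:4.
#' @param alpha,n_perm enrichment test parameters.
#' @param seed master seed (all randomness flows from it).
#' @param pca if TRUE, rank in the PCA-reduced space.
#' @param apply_hit_filter if TRUE (default), hits pass the e-value and
#'   alignment-length filter before reporting.
#' @return invisibly, a named list of per-query result lists (`ranking`,
#'   `ec`, `enzymes`).
#' @export
run_pipeline <- function(queries, db_dir, out_dir, method = "atompair",
                         top_k = 1L, resolution = 1:4, alpha = 0.05,
                         n_perm = 1000L, seed = 1L, pca = FALSE,
                         apply_hit_filter = TRUE) {
  stopifnot(length(queries) >= 1L, all(resolution %in% 1:4))
  reactions <- read_reaction_db(file.path(db_dir, "reactions.tsv"))
  sequences <- read_fasta(file.path(db_dir, "sequences.fasta"))
  hits <- read_hit_table(file.path(db_dir, "hits.tsv"))
  ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  bad <- setdiff(unique(hits$source_reaction_id), ids)
  if (length(bad))
    stop(sprintf("hit table references unknown reaction(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  annotated <- unique(unlist(lapply(reactions,
                                    function(r) r$enzyme_seq_ids)))
  bad_seq <- setdiff(annotated, names(sequences))
  if (length(bad_seq))
    stop(sprintf("reactions reference unknown sequence(s): %s",
                 paste(utils::head(bad_seq, 5), collapse = ", ")),
         call. = FALSE)
  space <- build_chemical_space(reactions, method)
  if (pca) space <- reduce_space(space)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qdir <- file.path(out_dir, q$reaction_id)
    if (!dir.exists(qdir)) dir.create(qdir)
    fp <- fingerprint_reaction(q, method)
    qvec <- embed_query(space, fp)
    ranking <- rank_reactions(space, qvec, query_id = q$reaction_id)
    write_tsv(ranking, file.path(qdir, "ranked_reactions.tsv"))
    ec_rows <- list()
    for (res in resolution) {
      pr <- predict_ec(ranking, space$annotations$ec_codes,
                       resolution = res, alpha = alpha, n_perm = n_perm,
                       seed = seed + 100L * qi + res)
      if (nrow(pr)) {
        pr <- cbind(query_id = q$reaction_id, resolution = res, pr)
        ec_rows[[length(ec_rows) + 1L]] <- pr
      }
    }
    ec_tab <- if (length(ec_rows)) do.call(rbind, ec_rows) else
      data.frame()
    write_tsv(ec_tab, file.path(qdir, "ec_predictions.tsv"))
    enz <- enzymes_for_query(ranking, hits, k = top_k)
    if (apply_hit_filter && nrow(enz))
      enz <- do.call(rbind, lapply(split(enz, seq_len(nrow(enz))),
        function(row) filter_hits(row, row$profile_length)))
    if (is.null(enz) || !nrow(enz))
      enz <- data.frame(target_id = character(0),
                        source_reaction_id = character(0),
                        source_rank = integer(0))
    rownames(enz) <- NULL
    write_tsv(enz, file.path(qdir, "enzymes.tsv"))
    hit_seqs <- sequences[intersect(enz$target_id, names(sequences))]
    # mock hit ids are not real database sequences; fall back to the
    # annotated enzymes of the source reactions so the FASTA is useful
    if (!length(hit_seqs) && nrow(enz)) {
      src <- unique(enz$source_reaction_id)
      fam <- unique(unlist(lapply(reactions[match(src, ids)],
                                  function(r) r$enzyme_seq_ids)))
      hit_seqs <- sequences[intersect(fam, names(sequences))]
    }
    write_fasta(hit_seqs, file.path(qdir, "enzymes.fasta"))
    results[[q$reaction_id]] <- list(ranking = ranking, ec = ec_tab,
                                     enzymes = enz)
  }
  log <- list(seed = seed, method = method, top_k = top_k,
              alpha = alpha, n_perm = n_perm, pca = pca,
              resolution = resolution,
              n_reactions = length(space$reaction_ids),
              excluded = space$excluded,
              package_version = as.character(
                utils::packageVersion("enzrank")),
              date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
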