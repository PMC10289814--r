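#' @title EC code prediction by rank-based enrichment
#' @description A query's reaction type (EC number) is predicted from the
#'   ranked reaction list: codes over-represented near the top of the list
#'   receive a high enrichment score, normalised by database frequency and
#'   tested against a permutation null.
#' @name ec_enrichment
NULL

#' Truncate an EC code to a resolution level
#'
#' @param ec character vector of EC codes (1-4 dot-separated fields).
#' @param resolution integer 1-4.
#' @return character vector; codes with fewer fields than `resolution` are
#'   returned unchanged (and can therefore never equal a full-length target).
#' @examples
#' ec_truncate("3.4.17.11", 2)  # "3.4"
#' @export
ec_truncate <- function(ec, resolution) {
  stopifnot(resolution %in% 1:4)
  vapply(strsplit(ec, ".", fixed = TRUE), function(p)
    paste(p[seq_len(min(resolution, length(p)))], collapse = "."),
    character(1))
}

# Match indicator: does any code annotated at a position, truncated to the
# target's resolution, equal the target?  Unannotated positions never match.
.ec_match <- function(labels, target, resolution) {
  vapply(labels, function(codes) {
    if (!length(codes)) return(FALSE)
    any(ec_truncate(codes, resolution) == target)
  }, logical(1))
}

# Maximum positive excursion of the +1/-1 walk and the earliest index
# attaining it.  Walk never producing a positive sum scores 0 (peak NA).
.walk_es <- function(match) {
  walk <- cumsum(ifelse(match, 1L, -1L))
  es <- max(walk, 0L)
  peak <- if (es > 0L) which(walk == es)[1L] else NA_integer_
  list(es = as.integer(es), peak = peak)
}

#' Enrichment score of an EC code along a ranked reaction list
#'
#' Walks down the list with a running sum starting at zero: +1 whenever the
#' position's annotation set contains a code matching the target (after
#' truncation to the target's resolution), -1 otherwise.  The enrichment
#' score (ES) is the walk's maximum positive excursion; a code never
#' lifting the sum above zero scores 0.  Positions without EC annotation
#' count as non-matches.
#'
#' @param labels list of character vectors: the EC codes annotated to each
#'   position of the ranked list, in rank order.
#' @param target character scalar EC code; its resolution is its number of
#'   fields.
#' @return list with `es` (non-negative integer) and `peak_position`
#'   (earliest 1-based index attaining the maximum; NA when es = 0).
#' @examples
#' enrichment_score(list("1.1", "2.1", "1.1", "1.1", "2.1"), "1.1")
#' # es = 2, peak_position = 4
#' @export
enrichment_score <- function(labels, target) {
  stopifnot(length(labels) >= 1L, is.character(target), length(target) == 1L)
  res <- length(strsplit(target, ".", fixed = TRUE)[[1]])
  w <- .walk_es(.ec_match(labels, target, res))
  list(es = w$es, peak_position = w$peak)
}

#' Normalise an enrichment score by database frequency
#'
#' Reference databases are unbalanced in EC representation, so the raw ES is
#' divided by the number of database reactions annotated with the target
#' code, yielding a normalised ES (NES) in \[0,1\].
#'
#' @param es non-negative integer enrichment score.
#' @param m number of database occurrences of the target code (>= 1).
#' @return numeric scalar in \[0,1\].
#' @export
normalized_es <- function(es, m) {
  if (m < 1L) stop("target EC code does not occur in the database",
                   call. = FALSE)
  stopifnot(es >= 0, es <= m)
  es / m
}

#' Permutation p-value for an observed NES
#'
#' Shuffles the per-position label sets as whole units, recomputes the NES
#' for each permutation, and reports the add-one Monte-Carlo p-value
#' \eqn{p = (1 + \#\{NES_{perm} \ge NES_{obs}\}) / (n_{perm} + 1)}, which is
#' bounded below by 1/(n_perm + 1).
#'
#' @param labels list of per-position EC code sets, in rank order.
#' @param target character EC code.
#' @param n_perm number of permutations (paper-scale default 1000).
#' @param seed integer seed for the shuffles.
#' @return numeric p-value in (0, 1].
#' @export
permutation_pvalue <- function(labels, target, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  res <- length(strsplit(target, ".", fixed = TRUE)[[1]])
  match <- .ec_match(labels, target, res)
  m <- sum(match)
  if (m == 0L) return(1)
  obs <- .walk_es(match)$es / m
  ge <- .perm_count_ge(match, m, obs, n_perm, seed)
  (1 + ge) / (n_perm + 1)
}

# Count permutations whose NES >= observed.  Only the match indicator needs
# shuffling: permuting label sets as units is equivalent to permuting the
# indicator.
.perm_count_ge <- function(match, m, obs_nes, n_perm, seed) {
  n <- length(match)
  with_seed(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      es <- max(cumsum(ifelse(match[perm], 1L, -1L)), 0L)
      if (es / m >= obs_nes) ge <- ge + 1L
    }
    ge
  })
}

#' Predict EC codes for a query from its ranked reaction list
#'
#' Computes an enrichment result for every EC code present in the database
#' at the requested resolution, flags codes with permutation p below
#' `alpha` as significant, and orders significant codes by ascending peak
#' position (where in the ranked list their enrichment culminates).
#'
#' @param ranking a `query_ranking` covering the whole database (see
#'   [rank_reactions()]), or a list of per-position EC code sets.
#' @param annotations named list mapping reaction id to its EC code vector;
#'   unused when `ranking` is already a label list.
#' @param resolution integer 1-4: EC class, sub-class, sub-sub-class or
#'   serial level.
#' @param alpha significance threshold on the permutation p-value.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data frame with one row per EC code: `ec_code`, `es`, `nes`,
#'   `p_value`, `peak_position`, `significant`, sorted with significant
#'   codes first (ascending peak position), then the rest by p-value.
#' @export
predict_ec <- function(ranking, annotations = NULL, resolution = 4L,
                       alpha = 0.05, n_perm = 1000L, seed = 1L) {
  stopifnot(resolution %in% 1:4)
  if (inherits(ranking, "query_ranking")) {
    stopifnot(!is.null(annotations))
    labels <- annotations[ranking$reaction_id]
    labels <- lapply(labels, function(x) if (is.null(x)) character(0) else x)
  } else labels <- ranking
  n <- length(labels)
  codes <- unique(unlist(lapply(labels, function(x)
    if (length(x)) ec_truncate(x, resolution) else character(0))))
  codes <- codes[vapply(strsplit(codes, ".", fixed = TRUE), length,
                        integer(1)) == resolution]
  if (!length(codes))
    return(data.frame(ec_code = character(0), es = integer(0),
                      nes = numeric(0), p_value = numeric(0),
                      peak_position = integer(0), significant = logical(0)))
  if (length(codes) == 1L)
    warning("database carries a single EC code at this resolution; ",
            "significance is not meaningful", call. = FALSE)
  rows <- lapply(seq_along(codes), function(i) {
    target <- codes[i]
    match <- .ec_match(labels, target, resolution)
    m <- sum(match)
    w <- .walk_es(match)
    nes <- w$es / m
    ge <- .perm_count_ge(match, m, nes, n_perm, seed + i - 1L)
    p <- (1 + ge) / (n_perm + 1)
    data.frame(ec_code = target, es = w$es, nes = nes, p_value = p,
               peak_position = w$peak, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  sig <- out[out$significant, , drop = FALSE]
  sig <- sig[order(sig$peak_position, sig$ec_code), , drop = FALSE]
  rest <- out[!out$significant, , drop = FALSE]
  rest <- rest[order(rest$p_value, rest$ec_code), , drop = FALSE]
  out <- rbind(sig, rest)
  rownames(out) <- NULL
  out
}

# Evaluate code under a temporary RNG state so package functions never
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
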