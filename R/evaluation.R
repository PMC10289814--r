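#' @title Validation procedures
#' @description Silhouette-like EC-class distance separation, shared-enzyme
#'   rank analysis, balanced EC-predictor validation, and exact 2x2
#'   contingency statistics.
#' @name evaluation
NULL

# Euclidean distance matrix between the rows of the similarity matrix.
.row_distances <- function(space) {
  as.matrix(stats::dist(space$matrix))
}

#' EC-class distance separation (silhouette-like) with a Kolmogorov test
#'
#' For each reaction annotated at the requested EC resolution, collects its
#' Euclidean distances to all reactions inside its class (within) versus
#' outside (without); per class, the two pooled distributions are compared
#' with a two-sample Kolmogorov-Smirnov test.  Well-separated chemistry
#' shows within-distances stochastically smaller than without-distances.
#' Singleton classes carry no within-distances and are excluded with a
#' warning.
#'
#' @param space a `chemical_space`.
#' @param annotations named list: reaction id -> EC code vector; defaults to
#'   the space's own annotations.
#' @param resolution integer 1-4.
#' @return object of class `separation_report`: list with `per_reaction`
#'   (data frame: reaction_id, ec_class, mean_within, mean_without) and
#'   `per_class` (data frame: ec_class, n, ks_statistic, p_value).
#' @export
ec_separation <- function(space, annotations = NULL, resolution = 1L) {
  stopifnot(inherits(space, "chemical_space"), resolution %in% 1:4)
  if (is.null(annotations)) annotations <- space$annotations$ec_codes
  ids <- space$reaction_ids
  cls <- lapply(annotations[ids], function(x)
    if (length(x)) unique(ec_truncate(x, resolution)) else character(0))
  cls <- lapply(cls, function(x)
    x[vapply(strsplit(x, ".", fixed = TRUE), length, integer(1)) ==
        resolution])
  dm <- .row_distances(space)
  classes <- sort(unique(unlist(cls)))
  sizes <- vapply(classes, function(cl)
    sum(vapply(cls, function(x) cl %in% x, logical(1))), integer(1))
  singletons <- classes[sizes < 2L]
  if (length(singletons))
    warning(sprintf("excluding singleton class(es): %s",
                    paste(singletons, collapse = ", ")), call. = FALSE)
  classes <- classes[sizes >= 2L]
  if (length(classes) < 2L)
    stop("need at least two EC classes with >= 2 members", call. = FALSE)
  per_rx <- list(); per_cl <- list()
  for (cl in classes) {
    inc <- vapply(cls, function(x) cl %in% x, logical(1))
    within_pool <- numeric(0); without_pool <- numeric(0)
    for (i in which(inc)) {
      w <- dm[i, inc]; w <- w[names(w) != ids[i]]
      o <- dm[i, !inc]
      within_pool <- c(within_pool, w)
      without_pool <- c(without_pool, o)
      per_rx[[length(per_rx) + 1L]] <- data.frame(
        reaction_id = ids[i], ec_class = cl,
        mean_within = mean(w),
        mean_without = if (length(o)) mean(o) else NA_real_,
        stringsAsFactors = FALSE)
    }
    ks <- if (length(within_pool) && length(without_pool) &&
              (stats::sd(c(within_pool, without_pool)) > 0 ||
               !identical(sort(within_pool), sort(without_pool)))) {
      suppressWarnings(stats::ks.test(within_pool, without_pool))
    } else list(statistic = 0, p.value = 1)
    per_cl[[length(per_cl) + 1L]] <- data.frame(
      ec_class = cl, n = sum(inc),
      ks_statistic = unname(ks$statistic), p_value = ks$p.value,
      stringsAsFactors = FALSE)
  }
  structure(list(per_reaction = do.call(rbind, per_rx),
                 per_class = do.call(rbind, per_cl),
                 resolution = resolution),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("<EC separation report at resolution %d: %d classes>\n",
              x$resolution, nrow(x$per_class)))
  print(x$per_class)
  invisible(x)
}

#' Ranks of shared-enzyme partner reactions, with a subsampled null
#'
#' For every unordered pair of reactions catalysed by the same enzyme, one
#' reaction is used as a query against the space (its own row removed) and
#' the rank of its partner in the resulting list is recorded.  The null
#' distribution repeats this for pairs of reactions that do NOT share an
#' enzyme, subsampled to the same number of pairs with a seeded generator.
#'
#' @param space a `chemical_space`.
#' @param enzyme_map named list: enzyme id -> reaction ids it catalyses;
#'   defaults to the inversion of the space's enzyme annotations.
#' @param seed integer seed for the null subsample.
#' @return list with `shared_ranks`, `null_ranks` (integer vectors of equal
#'   length) and `pairs` (data frame of the shared pairs).
#' @export
shared_enzyme_ranks <- function(space, enzyme_map = NULL, seed = 1L) {
  stopifnot(inherits(space, "chemical_space"))
  ids <- space$reaction_ids
  if (is.null(enzyme_map)) {
    inv <- list()
    for (rid in ids)
      for (e in space$annotations$enzyme_seq_ids[[rid]])
        inv[[e]] <- c(inv[[e]], rid)
    enzyme_map <- inv
  }
  shared_pairs <- unique(do.call(rbind, lapply(enzyme_map, function(rs) {
    rs <- intersect(unique(rs), ids)
    if (length(rs) < 2L) return(NULL)
    t(utils::combn(sort(rs), 2L))
  })))
  if (is.null(shared_pairs) || nrow(shared_pairs) == 0L)
    stop("no enzyme catalyses two or more reactions", call. = FALSE)
  partner_rank <- function(a, b) {
    qvec <- space$matrix[a, ]
    r <- rank_reactions(space, qvec, query_id = a)
    r <- r[r$reaction_id != a, , drop = FALSE]
    which(r$reaction_id == b)
  }
  shared <- vapply(seq_len(nrow(shared_pairs)), function(i)
    partner_rank(shared_pairs[i, 1], shared_pairs[i, 2]), integer(1))
  # null: pairs not sharing an enzyme, subsampled to the observed count
  key <- paste(shared_pairs[, 1], shared_pairs[, 2], sep = "\r")
  all_pairs <- t(utils::combn(sort(ids), 2L))
  all_key <- paste(all_pairs[, 1], all_pairs[, 2], sep = "\r")
  null_pool <- all_pairs[!(all_key %in% key), , drop = FALSE]
  n_null <- min(nrow(null_pool), length(shared))
  pick <- with_seed(seed, sample.int(nrow(null_pool), n_null))
  null <- vapply(pick, function(i)
    partner_rank(null_pool[i, 1], null_pool[i, 2]), integer(1))
  list(shared_ranks = shared, null_ranks = null,
       pairs = data.frame(query = shared_pairs[, 1],
                          partner = shared_pairs[, 2],
                          rank = shared, stringsAsFactors = FALSE))
}

#' Balanced EC-predictor validation by database subsampling
#'
#' Subsamples the database to an equal number of reactions per EC code at
#' the requested resolution, queries each subsampled reaction against the
#' space, and compares the top significant predicted code against the
#' truth.  When a database reaction is its own query, its row is removed
#' from the ranked list before enrichment (leave-self-out), so the
#' self-match cannot inflate accuracy.
#'
#' @param space a `chemical_space`.
#' @param annotations named list reaction id -> EC codes; defaults to the
#'   space's own.
#' @param resolution integer 1-4.
#' @param n_per_class reactions sampled per code (paper-scale value 96; use
#'   a small value for toy databases).
#' @param seed integer seed (subsampling and permutation tests).
#' @param n_perm permutations per enrichment test.
#' @param alpha significance threshold.
#' @param shuffle_labels if TRUE, annotations are randomly reassigned to
#'   reactions first — the permutation baseline, which should score near
#'   chance.
#' @return list with `per_code` (data frame: ec_code, tp, fp, fn,
#'   precision, recall, f1), `macro_f1`, `accuracy`, `predictions`.
#' @export
ec_predictor_validation <- function(space, annotations = NULL,
                                    resolution = 1L, n_per_class = 8L,
                                    seed = 1L, n_perm = 200L, alpha = 0.05,
                                    shuffle_labels = FALSE) {
  stopifnot(inherits(space, "chemical_space"))
  if (is.null(annotations)) annotations <- space$annotations$ec_codes
  ids <- space$reaction_ids
  annotations <- annotations[ids]
  if (shuffle_labels)
    annotations <- with_seed(seed + 7L,
                             stats::setNames(sample(annotations), ids))
  truth <- lapply(annotations, function(x)
    if (length(x)) unique(ec_truncate(x, resolution)) else character(0))
  classes <- sort(unique(unlist(truth)))
  members <- lapply(classes, function(cl)
    ids[vapply(truth, function(x) cl %in% x, logical(1))])
  names(members) <- classes
  small <- classes[vapply(members, length, integer(1)) < n_per_class]
  if (length(small))
    stop(sprintf("class(es) with fewer than %d members: %s", n_per_class,
                 paste(small, collapse = ", ")), call. = FALSE)
  sampled <- with_seed(seed, unlist(lapply(members, function(m)
    sample(m, n_per_class)), use.names = FALSE))
  preds <- character(length(sampled))
  for (i in seq_along(sampled)) {
    qid <- sampled[i]
    qvec <- space$matrix[qid, ]
    r <- rank_reactions(space, qvec, query_id = qid)
    r <- r[r$reaction_id != qid, , drop = FALSE]     # leave-self-out
    labels <- annotations[r$reaction_id]
    res <- predict_ec(labels, resolution = resolution, alpha = alpha,
                      n_perm = n_perm, seed = seed + i)
    sig <- res[res$significant, , drop = FALSE]
    preds[i] <- if (nrow(sig)) sig$ec_code[1] else NA_character_
  }
  truth_vec <- vapply(sampled, function(q) truth[[q]][1], character(1))
  per_code <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(preds == cl & truth_vec == cl, na.rm = TRUE)
    fp <- sum(preds == cl & truth_vec != cl, na.rm = TRUE)
    fn <- sum(truth_vec == cl & (is.na(preds) | preds != cl))
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(ec_code = cl, tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  list(per_code = per_code,
       macro_f1 = mean(per_code$f1),
       accuracy = mean(!is.na(preds) & preds == truth_vec),
       predictions = data.frame(reaction_id = sampled, truth = truth_vec,
                                predicted = preds, stringsAsFactors = FALSE))
}

#' Exact statistics for a 2x2 contingency table
#'
#' Sample odds ratio (ad/bc; `Inf` with `or_infinite = TRUE` when bc = 0)
#' and the two-sided Fisher exact p-value obtained by summing, over all
#' tables with the observed margins, the hypergeometric probabilities not
#' exceeding that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = predicted
#'   yes/no, columns = observed yes/no.
#' @return list with `odds_ratio`, `or_infinite`, `p_value`.
#' @examples
#' contingency_stats(matrix(c(6, 4, 7, 25), 2))  # OR 5.36, p 0.046
#' @export
contingency_stats <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or_inf <- (b * c_ == 0) && (a * d > 0)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  # hypergeometric enumeration over the first cell given fixed margins
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, or_infinite = or_inf, p_value = min(p, 1))
}
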