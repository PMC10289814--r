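#' Build the pairwise Tanimoto chemical space of a reaction database
#'
#' Fingerprints every reaction with the chosen method and computes the N x N
#' matrix of pairwise count-vector Tanimoto coefficients.  Each reaction's
#' row is its coordinate vector in the latent chemical space; queries are
#' later ranked by Euclidean distance between their similarity vector and
#' these rows.  Reactions that cannot be fingerprinted (unparsable
#' molecules) are excluded and reported, mirroring real reference databases
#' where a fraction of entries resists fingerprinting.
#'
#' @param reactions list of `reaction_record` objects.
#' @param method fingerprint method, see [mol_fingerprint()].
#' @return object of class `chemical_space`: `reaction_ids`, `matrix`
#'   (symmetric, unit diagonal), `method`, `fingerprints` (list of
#'   `diff_fp` keyed by reaction id), `annotations` (list with per-reaction
#'   `ec_codes` and `enzyme_seq_ids`), `excluded` (character vector of ids
#'   that failed), `reduced_basis` (NULL until [reduce_space()]).
#' @export
build_chemical_space <- function(reactions, method = "atompair") {
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate reaction ids in database", call. = FALSE)
  fps <- vector("list", length(reactions)); names(fps) <- ids
  failed <- character(0)
  for (i in seq_along(reactions)) {
    fp <- tryCatch(fingerprint_reaction(reactions[[i]], method),
                   error = function(e) NULL)
    if (is.null(fp)) failed <- c(failed, ids[i]) else fps[[ids[i]]] <- fp
  }
  keep <- setdiff(ids, failed)
  if (length(failed))
    warning(sprintf("%d reaction(s) could not be fingerprinted: %s",
                    length(failed), paste(failed, collapse = ", ")),
            call. = FALSE)
  if (length(keep) < 2L)
    stop("fewer than 2 fingerprintable reactions; cannot build a space",
         call. = FALSE)
  fps <- fps[keep]
  n <- length(keep)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- tanimoto(fps[[i]], fps[[j]])
      m[i, j] <- s; m[j, i] <- s
    }
  }
  dimnames(m) <- list(keep, keep)
  rx <- reactions[match(keep, ids)]
  ann <- list(
    ec_codes = stats::setNames(lapply(rx, function(r) r$ec_codes), keep),
    enzyme_seq_ids = stats::setNames(lapply(rx, function(r) r$enzyme_seq_ids),
                                     keep))
  structure(list(reaction_ids = keep, matrix = m, method = method,
                 fingerprints = fps, annotations = ann, excluded = failed,
                 reduced_basis = NULL,
                 metadata = list(method = method, n = n,
                                 built = format(Sys.time(), "%Y-%m-%d"))),
            class = "chemical_space")
}

#' @export
print.chemical_space <- function(x, ...) {
  cat(sprintf("<chemical space: %d reactions, %s fingerprints%s>\n",
              length(x$reaction_ids), x$method,
              if (!is.null(x$reduced_basis))
                sprintf(", PCA-reduced to %d components",
                        ncol(x$reduced_basis$rotation)) else ""))
  invisible(x)
}

#' Embed a query fingerprint into a chemical space
#'
#' Returns the query's similarity vector: its Tanimoto coefficient to every
#' database reaction, in database order.  This vector is the query's
#' coordinate in the latent chemical space.
#'
#' @param space a `chemical_space`.
#' @param fp a `diff_fp` with the same fingerprint method as the space.
#' @return named numeric vector of length N.
#' @export
embed_query <- function(space, fp) {
  stopifnot(inherits(space, "chemical_space"), inherits(fp, "diff_fp"))
  if (fp$method != space$method)
    stop(sprintf("fingerprint method mismatch: query '%s' vs space '%s'",
                 fp$method, space$method), call. = FALSE)
  vapply(space$fingerprints, function(g) tanimoto(fp, g), numeric(1))
}

#' Rank database reactions by Euclidean distance to a query vector
#'
#' Sorts database reactions by ascending L2 distance between the query's
#' Tanimoto similarity vector and each reaction's row of the similarity
#' matrix (or, when the space carries a PCA basis, between the projected
#' coordinates).  Ties are broken by lexicographic reaction id so rankings
#' are deterministic.  The normalised distance (raw distance divided by
#' sqrt(N)) is reported alongside, as a scale-free convenience.
#'
#' @param space a `chemical_space`.
#' @param qvec query similarity vector from [embed_query()], length N.
#' @param query_id identifier recorded in the ranking.
#' @return object of class `query_ranking`: data frame with columns `rank`,
#'   `reaction_id`, `euclidean_distance`, `normalized_distance`,
#'   `direct_tanimoto`, `ec_codes`; plus attribute `query_id`.
#' @export
rank_reactions <- function(space, qvec, query_id = "query") {
  stopifnot(inherits(space, "chemical_space"))
  n <- length(space$reaction_ids)
  if (length(qvec) != n)
    stop(sprintf("query vector length %d != database size %d",
                 length(qvec), n), call. = FALSE)
  if (is.null(space$reduced_basis)) {
    rows <- space$matrix
    q <- qvec
  } else {
    rb <- space$reduced_basis
    rows <- rb$scores
    q <- as.numeric((qvec[rb$cols] - rb$center) / rb$scale) %*% rb$rotation
  }
  d <- sqrt(rowSums(sweep(rows, 2L, as.numeric(q))^2))
  ord <- order(d, space$reaction_ids, method = "radix")
  ec <- vapply(space$annotations$ec_codes[space$reaction_ids[ord]],
               paste, character(1), collapse = ";")
  out <- data.frame(
    rank = seq_len(n),
    reaction_id = space$reaction_ids[ord],
    euclidean_distance = d[ord],
    normalized_distance = d[ord] / sqrt(n),
    direct_tanimoto = as.numeric(qvec[ord]),
    ec_codes = as.character(ec),
    stringsAsFactors = FALSE)
  attr(out, "query_id") <- query_id
  class(out) <- c("query_ranking", "data.frame")
  out
}

#' Reduce a chemical space by PCA under the Kaiser criterion
#'
#' Treats the similarity matrix rows as observations and its columns as
#' features, standardises the columns, and keeps the principal components
#' with eigenvalue greater than one (the Kaiser criterion on unit-variance
#' features).  Zero-variance columns are excluded with a message.  Ranking
#' then operates on the projected coordinates for both database rows and
#' queries.  Reduction is a performance convenience and is opt-in; the
#' default pipeline uses the full similarity matrix.
#'
#' @param space a `chemical_space`.
#' @return the space with `reduced_basis` filled in.
#' @export
reduce_space <- function(space) {
  stopifnot(inherits(space, "chemical_space"))
  n <- length(space$reaction_ids)
  if (n < 3L) stop("need at least 3 reactions to reduce", call. = FALSE)
  v <- apply(space$matrix, 2L, stats::sd)
  cols <- which(v > 0)
  if (length(cols) < length(v))
    message(sprintf("excluding %d zero-variance column(s) before PCA",
                    length(v) - length(cols)))
  if (length(cols) < 2L)
    stop("reduction refused: matrix columns carry no variance", call. = FALSE)
  p <- stats::prcomp(space$matrix[, cols, drop = FALSE],
                     center = TRUE, scale. = TRUE)
  keep <- which(p$sdev^2 > 1)
  if (!length(keep))
    stop("reduction refused: no component has eigenvalue > 1", call. = FALSE)
  space$reduced_basis <- list(
    rotation = p$rotation[, keep, drop = FALSE],
    center = p$center, scale = p$scale, cols = cols,
    scores = p$x[, keep, drop = FALSE],
    eigenvalues = p$sdev^2)
  space
}

#' Report candidate enzymes for the top-ranked reactions of a query
#'
#' Joins the top-k ranked reactions to a profile-search hit store and
#' returns the union of their hit rows, annotated with the source reaction
#' and its rank, deduplicated by (target id, source reaction).  The default
#' k = 1 reports enzymes of the single most similar reaction; k = 20 is the
#' conventional cutoff used when evaluating recovery of known enzymes.
#'
#' @param ranking a `query_ranking`.
#' @param hits a data frame of profile-search hits with at least columns
#'   `source_reaction_id` and `target_id` (see [read_hit_table()]), or a
#'   named list of per-reaction hit data frames.
#' @param k number of top-ranked reactions to draw enzymes from.
#' @return data frame of hits with `source_rank` and `source_reaction_id`
#'   columns prepended; zero rows if no top-k reaction has hits.
#' @export
enzymes_for_query <- function(ranking, hits, k = 1L) {
  stopifnot(inherits(ranking, "query_ranking"), k >= 1L)
  top <- utils::head(ranking, k)
  if (is.data.frame(hits)) {
    stopifnot(all(c("source_reaction_id", "target_id") %in% names(hits)))
    store <- split(hits, hits$source_reaction_id)
  } else store <- hits
  pieces <- list()
  for (i in seq_len(nrow(top))) {
    rid <- top$reaction_id[i]
    h <- store[[rid]]
    if (is.null(h) || nrow(h) == 0L) {
      warning(sprintf("no hit table for reaction '%s'", rid), call. = FALSE)
      next
    }
    h$source_reaction_id <- rid
    h$source_rank <- top$rank[i]
    pieces[[length(pieces) + 1L]] <- h
  }
  if (!length(pieces))
    return(data.frame(target_id = character(0),
                      source_reaction_id = character(0),
                      source_rank = integer(0)))
  out <- do.call(rbind, lapply(pieces, function(p)
    p[, union(c("source_rank", "source_reaction_id"), names(p)),
      drop = FALSE]))
  out[!duplicated(out[, c("target_id", "source_reaction_id")]), ,
      drop = FALSE]
}
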