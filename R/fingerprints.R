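#' @title Reaction difference fingerprints
#' @description Functions turning reactions into sparse signed count vectors
#'   and comparing them with a count-vector Tanimoto coefficient.
#' @name fingerprints
NULL

FP_METHODS <- c("atompair", "torsion", "pattern", "path")

# ---- per-molecule fingerprints -------------------------------------------

# Carhart-style atom invariant used by the torsion fingerprint: element,
# number of heavy-atom neighbours, number of pi electrons (bond order above
# one; aromatic SDF order 4 counts as one).
.atom_invariants <- function(g) {
  n <- length(g$elements)
  nb <- integer(n); pi_e <- integer(n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]; o <- g$bonds$order[i]
      nb[a] <- nb[a] + 1L; nb[b] <- nb[b] + 1L
      extra <- if (o == 4L) 1L else max(o - 1L, 0L)
      pi_e[a] <- pi_e[a] + extra; pi_e[b] <- pi_e[b] + extra
    }
  }
  paste0(g$elements, ".", nb, ".", pi_e)
}

# Topological torsion: every linear path of four distinct atoms, keyed by
# the invariant sequence in its canonical (lexicographically smaller)
# orientation, with counts.
.fp_torsion <- function(g) {
  n <- length(g$elements)
  if (n < 4L || nrow(g$bonds) < 3L) return(integer(0))
  inv <- .atom_invariants(g)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  keys <- character(0)
  for (i in seq_len(nrow(g$bonds))) {
    j <- g$bonds$a1[i]; k <- g$bonds$a2[i]
    for (a in setdiff(adj[[j]], k)) {
      for (b in setdiff(adj[[k]], c(j, a))) {
        fwd <- c(inv[a], inv[j], inv[k], inv[b])
        rev <- base::rev(fwd)
        key <- paste(if (paste(fwd, collapse = "|") <=
                         paste(rev, collapse = "|")) fwd else rev,
                     collapse = "|")
        keys <- c(keys, key)
      }
    }
  }
  if (!length(keys)) return(integer(0))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# Carhart atom pairs with counts, via ChemmineR (descriptor list retains one
# entry per pair of heavy atoms, so tabulating recovers counts).
.fp_atompair <- function(g) {
  if (length(g$elements) < 2L || nrow(g$bonds) < 1L) return(integer(0))
  ap <- suppressWarnings(tryCatch(ChemmineR::sdf2ap(g$sdfset),
                                  error = function(e) NULL))
  if (is.null(ap)) return(integer(0))
  descs <- methods::as(ap, "list")[[1]]
  if (length(descs) <= 1L && (length(descs) == 0L || descs[1] == 0))
    return(integer(0))
  tab <- table(descs)
  stats::setNames(as.integer(tab), names(tab))
}

# OpenBabel binary fingerprints exposed as 0/1 counts keyed by bit index.
.fp_openbabel <- function(g, fpname) {
  mol <- ChemmineOB::forEachMol("SMILES", g$smiles, identity)
  bits <- ChemmineOB::fingerprint_OB(mol, fpname)
  on <- which(as.numeric(bits) != 0)
  stats::setNames(rep(1L, length(on)), as.character(on))
}

#' Fingerprint a single molecule
#'
#' @param smiles valid SMILES of one molecule.
#' @param method one of `"atompair"` (Carhart atom pairs with counts,
#'   default), `"torsion"` (4-atom topological torsions with counts),
#'   `"pattern"` (SMARTS functional-group keys, binary), `"path"` (linear
#'   fragment paths, binary).
#' @return named integer vector of feature counts (possibly empty, e.g. for
#'   water, which has a single heavy atom and hence no atom pairs).
#' @export
mol_fingerprint <- function(smiles, method = "atompair") {
  if (!method %in% FP_METHODS)
    stop(sprintf("unsupported fingerprint method '%s' (use one of: %s)",
                 method, paste(FP_METHODS, collapse = ", ")), call. = FALSE)
  g <- mol_graph(smiles)
  if (is.null(g))
    stop(sprintf("invalid SMILES: '%s'", smiles), call. = FALSE)
  key <- paste0(method, "\r", smiles)
  hit <- .fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- switch(method,
              atompair = .fp_atompair(g),
              torsion  = .fp_torsion(g),
              pattern  = .fp_openbabel(g, "FP4"),
              path     = .fp_openbabel(g, "FP2"))
  storage.mode(v) <- "integer"
  .fp_cache[[key]] <- v
  v
}
.fp_cache <- new.env(parent = emptyenv())

# ---- difference fingerprints ---------------------------------------------

.sum_counts <- function(vectors) {
  all <- unlist(vectors)
  if (is.null(all) || !length(all)) return(integer(0))
  out <- tapply(all, names(all), sum)
  stats::setNames(as.integer(out), names(out))
}

#' Compute the difference fingerprint of a reaction
#'
#' The reaction is encoded as the sum of its product-molecule fingerprints
#' minus the sum of its reactant-side fingerprints (substrates and
#' cofactors).  The result is a sparse signed count vector describing what
#' the reaction changes; features present identically on both sides cancel.
#'
#' @param reaction a `reaction_record` (see [parse_reaction()]).
#' @param method fingerprint method, see [mol_fingerprint()].
#' @return object of class `diff_fp`: list with `counts` (named integer
#'   vector, no zeros) and `method`.
#' @export
fingerprint_reaction <- function(reaction, method = "atompair") {
  stopifnot(inherits(reaction, "reaction_record"))
  if (!method %in% FP_METHODS)
    stop(sprintf("unsupported fingerprint method '%s'", method),
         call. = FALSE)
  fps_p <- lapply(reaction$product_side$smiles, mol_fingerprint, method)
  fps_r <- lapply(reaction$reactant_side$smiles, mol_fingerprint, method)
  p <- .sum_counts(fps_p); r <- .sum_counts(fps_r)
  keys <- union(names(p), names(r))
  pv <- stats::setNames(integer(length(keys)), keys); pv[names(p)] <- p
  rv <- stats::setNames(integer(length(keys)), keys); rv[names(r)] <- r
  d <- pv - rv
  d <- d[d != 0L]
  structure(list(counts = d, method = method), class = "diff_fp")
}

#' @export
print.diff_fp <- function(x, ...) {
  cat(sprintf("<difference fingerprint: %s, %d features, L1 = %d>\n",
              x$method, length(x$counts), sum(abs(x$counts))))
  invisible(x)
}

#' Count-vector Tanimoto coefficient between two difference fingerprints
#'
#' Each signed vector is split into its positive and negative magnitude
#' parts (gains and losses live in disjoint key ranges), then
#' \eqn{T(a,b) = \sum_k \min(a_k, b_k) / \sum_k \max(a_k, b_k)} over the
#' union of keys.  This keeps T in \[0,1\], reduces to the Jaccard index for
#' binary vectors, and gives T(x,x) = 1.  Two empty fingerprints are
#' maximally similar (T = 1); empty versus non-empty gives 0.
#'
#' @param a,b `diff_fp` objects with the same method.
#' @return numeric scalar in \[0,1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "diff_fp"), inherits(b, "diff_fp"))
  if (a$method != b$method)
    stop(sprintf("fingerprint method mismatch: '%s' vs '%s'",
                 a$method, b$method), call. = FALSE)
  .tanimoto_counts(a$counts, b$counts)
}

.tanimoto_counts <- function(ac, bc) {
  if (!length(ac) && !length(bc)) return(1)
  keys <- union(names(ac), names(bc))
  av <- stats::setNames(numeric(length(keys)), keys); av[names(ac)] <- ac
  bv <- stats::setNames(numeric(length(keys)), keys); bv[names(bc)] <- bc
  num <- sum(pmin(pmax(av, 0), pmax(bv, 0))) +
         sum(pmin(pmax(-av, 0), pmax(-bv, 0)))
  den <- sum(pmax(pmax(av, 0), pmax(bv, 0))) +
         sum(pmax(pmax(-av, 0), pmax(-bv, 0)))
  if (den == 0) return(1)
  num / den
}
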