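#' @importFrom methods as is
#' @importFrom stats median prcomp sd ks.test dhyper setNames runif
#' @importFrom utils read.delim write.table head combn
NULL

# Characters permitted in a SMILES token.  OpenBabel is forgiving with some
# malformed strings, so a syntactic screen runs before the real parse.
.smiles_charset <- "^[A-Za-z0-9@+\\[\\]()=#$%./\\\\:*-]+$"

#' Check a SMILES string for syntactic sanity
#'
#' Verifies character set, balanced parentheses and brackets, paired
#' ring-closure digits, and absence of reaction arrows.  This is a screen,
#' not a grammar: strings passing it are then parsed chemically.
#'
#' @param smiles character scalar.
#' @return `TRUE` invisibly, or a character scalar describing the defect.
#' @keywords internal
smiles_syntax_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    return("empty SMILES token")
  if (grepl(">", smiles, fixed = TRUE))
    return("reaction arrow '>' inside a molecule token")
  if (!grepl(.smiles_charset, smiles, perl = TRUE))
    return("illegal character in SMILES")
  chars <- strsplit(smiles, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")"))
    return("unbalanced parentheses")
  if (sum(chars == "[") != sum(chars == "]"))
    return("unbalanced brackets")
  # ring closure digits must occur an even number of times (outside brackets)
  outside <- character(0)
  depth <- 0L
  for (ch in chars) {
    if (ch == "[") depth <- depth + 1L
    else if (ch == "]") depth <- depth - 1L
    else if (depth == 0L) outside <- c(outside, ch)
  }
  digs <- outside[grepl("[0-9]", outside)]
  if (length(digs) > 0L) {
    tab <- table(digs)
    if (any(tab %% 2L != 0L))
      return("unpaired ring-closure digit")
  }
  invisible(TRUE)
}

# Parse one SMILES through OpenBabel into a minimal molecular graph:
# list(elements = character, bonds = data.frame(a1, a2, order)).
# Hydrogens are implicit and never appear in the graph.
# Returns NULL when the string does not describe a molecule.
.mol_graph_cache <- new.env(parent = emptyenv())

mol_graph <- function(smiles) {
  key <- smiles
  hit <- .mol_graph_cache[[key]]
  if (!is.null(hit)) return(hit)
  chk <- smiles_syntax_ok(smiles)
  if (is.character(chk)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) != 1L) return(NULL)
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  elements <- sub("_.*$", "", rownames(ab))
  if (any(!grepl("^[A-Z][a-z]?$", elements))) {
    # single-atom molfiles are misread by the SDF reader; recover the
    # element from OpenBabel's canonical properties
    pr <- tryCatch(
      ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles,
                                                 identity)),
      error = function(e) NULL)
    if (is.null(pr) || !nzchar(pr$formula)) return(NULL)
    heavy <- regmatches(pr$formula,
                        gregexpr("[A-Z][a-z]?", pr$formula))[[1]]
    heavy <- setdiff(heavy, "H")
    if (length(heavy) != 1L) return(NULL)
    elements <- heavy
    ab <- ab[1, , drop = FALSE]
  }
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  heavy <- elements != "H"
  if (!all(heavy)) {
    # strip explicit hydrogens, reindex
    idx <- cumsum(heavy)
    keep <- bonds$a1 <= length(elements) & bonds$a2 <= length(elements) &
      heavy[bonds$a1] & heavy[bonds$a2]
    bonds <- bonds[keep, , drop = FALSE]
    bonds$a1 <- idx[bonds$a1]; bonds$a2 <- idx[bonds$a2]
    elements <- elements[heavy]
  }
  if (length(elements) == 0L) return(NULL)
  ChemmineR::cid(sdf) <- "m"
  g <- list(smiles = smiles, elements = elements, bonds = bonds,
            sdfset = sdf)
  .mol_graph_cache[[key]] <- g
  g
}

#' Is a SMILES string a valid molecule?
#'
#' @param smiles character scalar.
#' @return logical scalar.
#' @examples
#' valid_smiles("CCO")    # TRUE
#' valid_smiles("C(C")    # FALSE
#' @export
valid_smiles <- function(smiles) {
  !is.null(mol_graph(smiles))
}

#' Parse a reaction from dot-separated SMILES sides
#'
#' Builds a reaction record from a reactant side (substrates plus any
#' cofactors, e.g. water for a hydrolysis) and a product side.  Each side is
#' a dot-separated list of SMILES tokens; every token must parse to a valid
#' molecule.
#'
#' @param reaction_id character scalar identifying the reaction.
#' @param reactant_smiles dot-separated SMILES of substrates and cofactors.
#' @param product_smiles dot-separated SMILES of products.
#' @param ec_codes character vector of EC annotations (may be empty).
#' @param enzyme_seq_ids character vector of annotated enzyme sequence ids.
#' @param roles optional character vector of roles for the reactant-side
#'   tokens (`"substrate"` or `"cofactor"`); defaults to all `"substrate"`.
#' @return an object of class `reaction_record` with elements
#'   `reaction_id`, `reactant_side`, `product_side` (data frames with
#'   `smiles` and `role` columns), `ec_codes`, `enzyme_seq_ids`.
#' @examples
#' r <- parse_reaction("r1", "CCOC(C)=O.O", "CCO.CC(=O)O")
#' nrow(r$reactant_side)  # 2
#' @export
parse_reaction <- function(reaction_id, reactant_smiles, product_smiles,
                           ec_codes = character(0),
                           enzyme_seq_ids = character(0),
                           roles = NULL) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L,
            nzchar(reaction_id))
  side <- function(s, side_name, roles = NULL) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
      stop(sprintf("reaction '%s': empty %s side", reaction_id, side_name),
           call. = FALSE)
    toks <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(toks) == 0L || any(!nzchar(toks)) ||
        grepl("^\\.|\\.$|\\.\\.", s))
      stop(sprintf("reaction '%s': empty token on %s side", reaction_id,
                   side_name), call. = FALSE)
    for (i in seq_along(toks)) {
      chk <- smiles_syntax_ok(toks[i])
      if (is.character(chk))
        stop(sprintf("reaction '%s': %s token %d ('%s'): %s", reaction_id,
                     side_name, i, toks[i], chk), call. = FALSE)
      if (is.null(mol_graph(toks[i])))
        stop(sprintf("reaction '%s': %s token %d ('%s') is not a valid molecule",
                     reaction_id, side_name, i, toks[i]), call. = FALSE)
    }
    r <- if (is.null(roles)) rep("substrate", length(toks)) else roles
    if (length(r) != length(toks))
      stop("roles length must match the number of reactant tokens",
           call. = FALSE)
    stopifnot(all(r %in% c("substrate", "cofactor", "product")))
    data.frame(smiles = toks, role = r, stringsAsFactors = FALSE)
  }
  rs <- side(reactant_smiles, "reactant", roles)
  ps <- side(product_smiles, "product")
  ps$role <- "product"
  structure(list(reaction_id = reaction_id,
                 reactant_side = rs, product_side = ps,
                 ec_codes = as.character(ec_codes),
                 enzyme_seq_ids = as.character(enzyme_seq_ids)),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction %s> %s >> %s\n", x$reaction_id,
              paste(x$reactant_side$smiles, collapse = " . "),
              paste(x$product_side$smiles, collapse = " . ")))
  if (length(x$ec_codes))
    cat("  EC:", paste(x$ec_codes, collapse = "; "), "\n")
  invisible(x)
}

#' Adjust a SMILES to its major microspecies at a pH (pluggable hook)
#'
#' The default hook (`method = "none"`) is the identity transform: molecules
#' are used as drawn.  The `"rules"` hook applies a single documented rule:
#' carboxylic acids (pKa ~ 4.25) are deprotonated when `pH` exceeds that
#' pKa.  User-supplied hooks are functions `f(smiles, pH)` returning a
#' SMILES string.
#'
#' @param smiles character scalar, valid SMILES.
#' @param pH numeric scalar; default 7.4 (physiological).
#' @param method `"none"`, `"rules"`, or a function.
#' @return a SMILES character scalar.
#' @examples
#' protonate("CC(=O)O", 7.4, method = "rules")  # "CC(=O)[O-]"
#' protonate("O", 7.4)                          # "O"
#' @export
protonate <- function(smiles, pH = 7.4, method = c("none", "rules")) {
  if (is.function(method)) {
    out <- method(smiles, pH)
    stopifnot(is.character(out), length(out) == 1L)
    return(out)
  }
  method <- match.arg(method)
  if (is.null(mol_graph(smiles)))
    stop(sprintf("invalid SMILES: '%s'", smiles), call. = FALSE)
  if (method == "none") return(smiles)
  # rules: deprotonate -C(=O)OH when pH > 4.25.  The hydroxyl oxygen of a
  # carboxyl group is an O not followed by another atom token, in either of
  # the two common spellings.
  if (pH > 4.25) {
    out <- gsub("C\\(=O\\)O(?=[).]|$)", "C(=O)[O-]", smiles, perl = TRUE)
    out <- gsub("C\\(O\\)=O", "C([O-])=O", out, perl = TRUE)
    return(out)
  }
  smiles
}
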