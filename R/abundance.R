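#' @title Species presence and gene copy number from alignment summaries
#' @description Presence of a predicted species in a metagenomic sample is
#'   called from read coverage of 15 single-copy universal marker genes;
#'   per-cell copy number of a predicted gene is its read depth normalised
#'   by the marker coverage.
#' @name abundance_metrics
NULL

#' Default number of single-copy universal marker genes expected per species
#' @export
N_UNIVERSAL_GENES <- 15L

#' Call species presence from single-copy marker coverage
#'
#' A species is present in a sample when every one of its single-copy
#' universal genes is covered over at least 75% of its length.
#'
#' @param scg data frame with columns `scg_id` and
#'   `alignment_coverage_fraction` (in \[0,1\]), one row per marker gene.
#' @param expected_ids character vector of the marker ids that must be
#'   reported (default `scg15_1` ... `scg15_15`).
#' @param min_coverage minimum alignment coverage fraction (default 0.75,
#'   inclusive).
#' @return logical scalar.
#' @export
species_present <- function(scg,
                            expected_ids = paste0("scg15_",
                                                  seq_len(N_UNIVERSAL_GENES)),
                            min_coverage = 0.75) {
  stopifnot(is.data.frame(scg),
            all(c("scg_id", "alignment_coverage_fraction") %in% names(scg)))
  missing <- setdiff(expected_ids, scg$scg_id)
  if (length(missing))
    stop(sprintf("missing universal-gene rows: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  rows <- scg[match(expected_ids, scg$scg_id), , drop = FALSE]
  all(rows$alignment_coverage_fraction >= min_coverage)
}

#' Per-cell copy number of a gene
#'
#' Gene read depth (aligned reads over gene length) normalised by the median
#' read coverage of the 15 single-copy universal genes in the same sample.
#' A single-copy gene at typical coverage therefore scores 1 copy per cell.
#'
#' @param gene_reads aligned read count for the gene.
#' @param gene_length gene length in bp (> 0).
#' @param scg_coverages numeric vector of marker coverages (reads per bp);
#'   at least one must be positive.
#' @return numeric copies per cell.
#' @examples
#' gene_copy_number(30, 1500, rep(0.04, 15))  # 0.5
#' @export
gene_copy_number <- function(gene_reads, gene_length, scg_coverages) {
  stopifnot(gene_length > 0, gene_reads >= 0, length(scg_coverages) >= 1L)
  denom <- stats::median(scg_coverages)
  if (denom <= 0 || all(scg_coverages == 0))
    stop("all single-copy gene coverages are zero; copy number undefined",
         call. = FALSE)
  (gene_reads / gene_length) / denom
}

#' Call gene presence from copy number
#'
#' @param copies copies per cell (>= 0).
#' @param min_copies presence threshold (default 0.35, inclusive).
#' @return logical.
#' @export
gene_present <- function(copies, min_copies = 0.35) {
  stopifnot(all(copies >= 0))
  copies >= min_copies
}
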