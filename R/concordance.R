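# Protein-flux vs mRNA concordance: match protein FSR fold changes to a
# differential-expression table and test whether directions agree more
# often than a fair coin would allow.

#' Match protein flux changes to gene-expression changes
#'
#' Inner-joins a protein FSR comparison table with a gene-level
#' differential-expression table (log2 fold changes computed externally,
#' e.g. by DESeq2) and orients each pair: the mRNA direction is the sign
#' of its log2FC. Records with a zero fold change on either side are
#' excluded, as are genes or proteins involved in ambiguous many-to-many
#' mappings; join losses are recorded in attributes.
#'
#' @param comparisons Protein comparison table ([paired_log2fc()]), with
#'   `protein_id` and `log2fc`.
#' @param de_table Data frame with `gene_id` and `log2fc`.
#' @param mapping Optional two-column data frame `gene_id`, `protein_id`.
#'   When `NULL`, identifiers are assumed shared (`gene_id == protein_id`).
#' @return Data frame `gene_id`, `protein_id`, `fsr_log2fc`, `mrna_log2fc`,
#'   `fsr_direction`, `mrna_direction`, `concordant`; attributes
#'   `n_unmatched`, `n_zero_fc`, `n_ambiguous`.
#' @export
match_and_orient <- function(comparisons, de_table, mapping = NULL) {
  .check_columns(comparisons, c("protein_id", "log2fc"), "comparison table")
  .check_columns(de_table, c("gene_id", "log2fc"), "DE table")
  if (nrow(comparisons) == 0L || nrow(de_table) == 0L) {
    stop("both the comparison and DE tables must be non-empty")
  }
  if (is.null(mapping)) {
    mapping <- data.frame(gene_id = de_table$gene_id,
                          protein_id = de_table$gene_id,
                          stringsAsFactors = FALSE)
  }
  .check_columns(mapping, c("gene_id", "protein_id"), "mapping")
  dup_g <- mapping$gene_id %in% mapping$gene_id[duplicated(mapping$gene_id)]
  dup_p <- mapping$protein_id %in%
    mapping$protein_id[duplicated(mapping$protein_id)]
  ambiguous <- dup_g | dup_p
  n_ambiguous <- sum(ambiguous)
  mapping <- mapping[!ambiguous, , drop = FALSE]

  d <- merge(mapping, de_table[c("gene_id", "log2fc")], by = "gene_id")
  names(d)[names(d) == "log2fc"] <- "mrna_log2fc"
  d <- merge(d, comparisons[c("protein_id", "log2fc")], by = "protein_id")
  names(d)[names(d) == "log2fc"] <- "fsr_log2fc"
  n_unmatched <- nrow(comparisons) + nrow(de_table) - 2L * nrow(d)

  nonzero <- d$fsr_log2fc != 0 & d$mrna_log2fc != 0
  n_zero <- sum(!nonzero)
  d <- d[nonzero, , drop = FALSE]
  out <- data.frame(
    gene_id = d$gene_id,
    protein_id = d$protein_id,
    fsr_log2fc = d$fsr_log2fc,
    mrna_log2fc = d$mrna_log2fc,
    fsr_direction = ifelse(d$fsr_log2fc > 0, "Up", "Down"),
    mrna_direction = ifelse(d$mrna_log2fc > 0, "Up", "Down"),
    stringsAsFactors = FALSE
  )
  out$concordant <- out$fsr_direction == out$mrna_direction
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "n_zero_fc") <- n_zero
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Concordance counts and binomial significance
#'
#' Counts concordant vs discordant protein-flux/mRNA pairs and tests the
#' split against a fair coin with the exact two-tailed binomial test.
#'
#' @param records Output of [match_and_orient()].
#' @param method Binomial convention, see [binomial_two_tailed()].
#' @return List with `n_concordant`, `n_discordant`, `n_total`,
#'   `pct_concordant`, `p_binomial`.
#' @export
concordance_test <- function(records, method = c("double", "minlik")) {
  method <- match.arg(method)
  .check_columns(records, "concordant", "concordance records")
  if (nrow(records) == 0L) stop("no concordance records to test")
  n_con <- sum(records$concordant)
  n_total <- nrow(records)
  list(
    n_concordant = n_con,
    n_discordant = n_total - n_con,
    n_total = n_total,
    pct_concordant = 100 * n_con / n_total,
    p_binomial = binomial_two_tailed(n_con, n_total, method = method)
  )
}
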