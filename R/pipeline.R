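# Peptide-table -> peptide-level kinetics. The per-sample body-water
# enrichment comes from the metadata, so each sample gets its own asymptote.

#' Compute peptide-level fractional synthesis for a measurement table
#'
#' For every row of a peptide measurement table, computes the theoretical
#' baseline and asymptote envelopes of the sequence at the sample's
#' body-water enrichment, then the excess-M0 fractional synthesis
#' `f = EM0 / EM0max`. Envelopes are cached per (sequence, enrichment), so
#' cohorts with many samples of the same peptide are cheap.
#'
#' @param peptides Data frame with columns `sequence`, `protein_id`,
#'   `sample_id`, `M0`..`M3`, `spectral_count` (see [read_peptide_table()]).
#' @param metadata Data frame with columns `sample_id`, `arm`, `day`,
#'   `animal`, `p_body` (see [read_metadata()]).
#' @param sites Exchangeable-site table.
#' @param p_natural Natural deuterium abundance.
#' @param k_max Envelope truncation (default 3, the M0-M3 window).
#' @param carbamidomethyl_cys Treat every cysteine as carbamidomethylated.
#' @return The input table with added columns `em0`, `em0_max`, `f`,
#'   `qc_flag`.
#' @export
compute_peptide_fsr <- function(peptides, metadata,
                                sites = default_site_table(),
                                p_natural = 0.000115, k_max = 3L,
                                carbamidomethyl_cys = FALSE) {
  .check_columns(peptides, c("sequence", "protein_id", "sample_id",
                             paste0("M", 0:k_max), "spectral_count"),
                 "peptide table")
  .check_columns(metadata, c("sample_id", "p_body"), "metadata")
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata has duplicate sample_id values")
  }
  unmapped <- setdiff(unique(peptides$sample_id), metadata$sample_id)
  if (length(unmapped)) {
    stop("samples present in the peptide table but not in the metadata: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  p_body <- metadata$p_body[match(peptides$sample_id, metadata$sample_id)]

  mcols <- paste0("M", seq_len(k_max + 1L) - 1L)
  meas <- as.matrix(peptides[mcols])
  meas <- meas / rowSums(meas)

  # Envelope cache keyed by sequence x p_body.
  key <- paste(peptides$sequence, format(p_body, digits = 15L), sep = "|")
  uk <- !duplicated(key)
  base_m0 <- asym_m0 <- numeric(sum(uk))
  useq <- peptides$sequence[uk]
  up <- p_body[uk]
  comp_cache <- new.env(parent = emptyenv())
  for (i in seq_along(useq)) {
    sq <- useq[i]
    if (is.null(comp_cache[[sq]])) {
      comp_cache[[sq]] <- list(
        comp = composition_from_sequence(sq, carbamidomethyl_cys),
        n = exchangeable_site_count(sq, sites)
      )
    }
    cc <- comp_cache[[sq]]
    base_m0[i] <- theoretical_envelope(cc$comp, cc$n, p_natural,
                                       p_natural = p_natural,
                                       k_max = k_max)[[1L]]
    asym_m0[i] <- theoretical_envelope(cc$comp, cc$n, up[i],
                                       p_natural = p_natural,
                                       k_max = k_max)[[1L]]
  }
  idx <- match(key, key[uk])
  em0 <- meas[, 1L] - base_m0[idx]
  em0_max <- asym_m0[idx] - base_m0[idx]
  if (any(em0_max == 0)) {
    stop("no kinetic information for some peptides (EM0max = 0); ",
         "check p_body and the site table")
  }
  f <- em0 / em0_max
  qc_flag <- ifelse(f >= 0 & f <= 1, "ok",
                    ifelse(f >= -0.05 & f <= 1.2, "minor_excursion",
                           "out_of_bounds"))
  out <- peptides
  out$em0 <- unname(em0)
  out$em0_max <- unname(em0_max)
  out$f <- unname(f)
  out$qc_flag <- qc_flag
  out
}

.check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data frame")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
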