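# Protein-level roll-up: peptide kinetics -> per-animal protein FSRs,
# the minimum-spectra inclusion filter, per-group summaries, and WPASR.

#' Aggregate peptide kinetics to protein-level FSRs
#'
#' Collapses peptide-level fractional synthesis values to one FSR per
#' protein per sample. The default is a spectral-count-weighted mean, so
#' better-sampled peptides carry more weight; unweighted mean and median
#' are available. Peptides flagged `out_of_bounds` are dropped first;
#' proteins whose peptides are all flagged are returned with `fsr = NA`
#' and `qc_flag = "all_flagged"`.
#'
#' @param peptide_fsr Output of [compute_peptide_fsr()].
#' @param method `"weighted"` (default), `"mean"`, or `"median"`.
#' @return Data frame with columns `protein_id`, `sample_id`, `fsr`,
#'   `n_peptides`, `n_spectra`, `qc_flag`.
#' @export
protein_fsr <- function(peptide_fsr, method = c("weighted", "mean", "median")) {
  method <- match.arg(method)
  .check_columns(peptide_fsr, c("protein_id", "sample_id", "f",
                                "spectral_count", "qc_flag"),
                 "peptide kinetics table")
  key <- interaction(peptide_fsr$protein_id, peptide_fsr$sample_id,
                     drop = TRUE, sep = "\r")
  rows <- split(seq_len(nrow(peptide_fsr)), key)
  out <- lapply(rows, function(i) {
    d <- peptide_fsr[i, ]
    ok <- d$qc_flag != "out_of_bounds"
    ns <- sum(d$spectral_count)
    if (!any(ok)) {
      return(data.frame(protein_id = d$protein_id[1L],
                        sample_id = d$sample_id[1L],
                        fsr = NA_real_, n_peptides = nrow(d), n_spectra = ns,
                        qc_flag = "all_flagged"))
    }
    d <- d[ok, ]
    fsr <- switch(method,
                  weighted = sum(d$f * d$spectral_count) / sum(d$spectral_count),
                  mean = mean(d$f),
                  median = stats::median(d$f))
    data.frame(protein_id = d$protein_id[1L], sample_id = d$sample_id[1L],
               fsr = fsr, n_peptides = nrow(d), n_spectra = ns,
               qc_flag = "ok")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exclude proteins with too few peptide spectra
#'
#' Applies the inclusion rule that a protein measurement must rest on at
#' least `min_spectra` peptide spectra (default 2): sparser measurements
#' are removed. With `scope = "sample"` the rule is applied within each
#' sample; with `scope = "study"` a protein is kept everywhere if its
#' total spectra across samples pass.
#'
#' @param records Protein-level table with `protein_id`, `sample_id`,
#'   `n_spectra`.
#' @param min_spectra Minimum spectra required (default 2).
#' @param scope `"sample"` (default) or `"study"`.
#' @param quiet Suppress the removal-count message.
#' @return Filtered table, original row order preserved.
#' @export
filter_min_spectra <- function(records, min_spectra = 2L,
                               scope = c("sample", "study"), quiet = FALSE) {
  scope <- match.arg(scope)
  .check_columns(records, c("protein_id", "n_spectra"), "protein table")
  if (nrow(records) == 0L) return(records)
  keep <- if (scope == "sample") {
    records$n_spectra >= min_spectra
  } else {
    tot <- tapply(records$n_spectra, records$protein_id, sum)
    tot[records$protein_id] >= min_spectra
  }
  removed <- sum(!keep)
  if (!quiet && removed > 0L) {
    message(removed, " protein measurement(s) removed (fewer than ",
            min_spectra, " peptide spectra)")
  }
  records[keep, , drop = FALSE]
}

#' Per-protein group summaries (mean, SD, CV)
#'
#' Summarizes protein FSRs across replicate animals within each group
#' (arm, and day if present in the metadata): mean, sample SD (n - 1
#' denominator), and the coefficient of variation in percent,
#' `cv = 100 * sd / mean`. The CV is undefined (flagged `NA`) when fewer
#' than two animals contribute or the mean is not positive.
#'
#' @param protein_records Output of [protein_fsr()] (after filtering).
#' @param metadata Sample metadata with `sample_id`, `arm`, and optionally
#'   `day`.
#' @return Data frame with `protein_id`, `arm`, (`day`,) `mean_fsr`,
#'   `sd_fsr`, `cv`, `n_animals`.
#' @export
group_summary <- function(protein_records, metadata) {
  .check_columns(protein_records, c("protein_id", "sample_id", "fsr"),
                 "protein table")
  .check_columns(metadata, c("sample_id", "arm"), "metadata")
  m <- match(protein_records$sample_id, metadata$sample_id)
  if (anyNA(m)) stop("protein table contains samples absent from metadata")
  d <- protein_records
  d$arm <- metadata$arm[m]
  has_day <- "day" %in% names(metadata)
  if (has_day) d$day <- metadata$day[m]
  d <- d[!is.na(d$fsr), , drop = FALSE]

  keys <- if (has_day) list(d$protein_id, d$arm, d$day) else
    list(d$protein_id, d$arm)
  key <- do.call(paste, c(keys, sep = "\r"))
  rows <- split(seq_len(nrow(d)), key)
  out <- lapply(rows, function(i) {
    x <- d$fsr[i]
    n <- length(x)
    mu <- mean(x)
    sdv <- if (n >= 2L) stats::sd(x) else NA_real_
    cv <- if (n >= 2L && mu > 0) 100 * sdv / mu else NA_real_
    rec <- data.frame(protein_id = d$protein_id[i[1L]], arm = d$arm[i[1L]],
                      mean_fsr = mu, sd_fsr = sdv, cv = cv, n_animals = n)
    if (has_day) rec$day <- d$day[i[1L]]
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (has_day) out <- out[c("protein_id", "arm", "day", "mean_fsr",
                            "sd_fsr", "cv", "n_animals")]
  out
}

#' Normalized signal intensity quotient Q
#'
#' Within one sample, each protein's share of the total label-free signal:
#' `q_i = intensity_i / sum(intensity)`. The quotients sum to 1 by
#' construction. Zero or negative intensities are masked to `NA` rather
#' than imputed.
#'
#' @param intensity Numeric vector of protein intensities within a sample.
#' @return Numeric vector of quotients (NA where masked).
#' @export
#' @examples
#' intensity_quotient(c(2, 3, 5))
intensity_quotient <- function(intensity) {
  stopifnot(is.numeric(intensity))
  masked <- !is.finite(intensity) | intensity <= 0
  if (all(masked)) stop("all intensities are zero, negative or missing")
  q <- ifelse(masked, NA_real_, intensity)
  q / sum(q, na.rm = TRUE)
}

#' Within-proteome absolute synthesis rate (WPASR)
#'
#' Multiplies each protein's FSR by its normalized signal intensity
#' quotient within the same sample, giving an abundance-weighted absolute
#' synthesis contribution.
#'
#' @param protein_records Protein FSR table (`protein_id`, `sample_id`,
#'   `fsr`).
#' @param intensities Data frame with `protein_id`, `sample_id`,
#'   `intensity`.
#' @return The joined table with added `q` and `wpasr` columns.
#' @export
wpasr <- function(protein_records, intensities) {
  .check_columns(protein_records, c("protein_id", "sample_id", "fsr"),
                 "protein table")
  .check_columns(intensities, c("protein_id", "sample_id", "intensity"),
                 "intensity table")
  d <- merge(protein_records, intensities, by = c("protein_id", "sample_id"))
  if (nrow(d) == 0L) stop("no proteins shared between FSR and intensity tables")
  d$q <- NA_real_
  for (s in unique(d$sample_id)) {
    i <- d$sample_id == s
    d$q[i] <- intensity_quotient(d$intensity[i])
  }
  d$wpasr <- d$fsr * d$q
  d
}

#' Normalize a WPASR matrix for cross-sample comparison
#'
#' Applies the standard normalization cascade: divide each sample (column)
#' by its median to remove systemic differences, take log10 of the
#' individual values, then center each protein (row) to mean zero.
#' Non-positive entries are masked (`NA`) before the log step.
#'
#' @param mat Numeric matrix, proteins in rows, samples in columns.
#' @return Matrix of the same shape; every row has mean 0 over its
#'   non-missing entries.
#' @export
normalize_wpasr_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  mat[!is.finite(mat) | mat <= 0] <- NA_real_
  med <- apply(mat, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med <= 0)) {
    stop("a sample has no positive WPASR values; cannot median-adjust")
  }
  mat <- sweep(mat, 2L, med, "/")
  mat <- log10(mat)
  sweep(mat, 1L, rowMeans(mat, na.rm = TRUE), "-")
}
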