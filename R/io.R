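# Readers and writers. All tables are UTF-8, tab-separated, with a
# mandatory header row; missing values are empty fields. Malformed rows
# are rejected with their line numbers so upstream exports can be fixed.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8")
}

#' Write a tab-separated table
#'
#' Deterministic column order and full-precision numerics, so written
#' tables round-trip exactly through [read_peptide_table()] and friends.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17L, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peptide measurement table
#'
#' Expects columns `sequence`, `protein_id`, `sample_id`, `M0`..`M3`,
#' `spectral_count` (and optionally `charge`). Envelopes are renormalized
#' on read; rows with negative abundances, an all-zero envelope, an empty
#' or non-standard sequence, or a non-positive spectral count are dropped
#' with a message naming their line numbers.
#'
#' @param path Path to a tab-separated file.
#' @param quiet Suppress the rejected-row message.
#' @return Validated peptide measurement data frame.
#' @export
read_peptide_table <- function(path, quiet = FALSE) {
  d <- .read_tsv(path)
  required <- c("sequence", "protein_id", "sample_id",
                paste0("M", 0:3), "spectral_count")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("peptide table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  mcols <- paste0("M", 0:3)
  env <- as.matrix(d[mcols])
  seq_ok <- !is.na(d$sequence) & nchar(d$sequence) > 0 &
    !grepl(sprintf("[^%s]", paste(rownames(.RESIDUE_COMPOSITION),
                                  collapse = "")), d$sequence)
  env_ok <- apply(env, 1L, function(x) all(is.finite(x)) && all(x >= 0) &&
                    sum(x) > 0)
  sc_ok <- is.finite(d$spectral_count) & d$spectral_count >= 1
  ok <- seq_ok & env_ok & sc_ok
  if (!all(ok) && !quiet) {
    message(sum(!ok), " malformed row(s) rejected (file lines ",
            paste(utils::head(which(!ok) + 1L, 10L), collapse = ", "), ")")
  }
  d <- d[ok, , drop = FALSE]
  if (nrow(d)) {
    env <- as.matrix(d[mcols])
    d[mcols] <- env / rowSums(env)
  }
  if (!"charge" %in% names(d)) d$charge <- NA_integer_
  rownames(d) <- NULL
  d
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `arm`, `day`, `animal`, `p_body`.
#' Duplicate sample ids are an error, as is a labeled sample with no
#' body-water enrichment (`p_body <= 0` carries no kinetic information).
#'
#' @param path Path to a tab-separated file.
#' @return Metadata data frame.
#' @export
read_metadata <- function(path) {
  d <- .read_tsv(path)
  required <- c("sample_id", "arm", "day", "animal", "p_body")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         d$sample_id[duplicated(d$sample_id)][1L])
  }
  if (any(!is.finite(d$p_body) | d$p_body <= 0 | d$p_body >= 1)) {
    stop("every labeled sample needs p_body in (0, 1)")
  }
  d
}

#' Read an exchangeable-site table
#'
#' Two-column tab-separated file `residue`, `n_sites` covering the 20
#' standard residues.
#'
#' @param path Path to a tab-separated file.
#' @return Named numeric vector usable as the `sites` argument elsewhere.
#' @export
read_site_table <- function(path) {
  d <- .read_tsv(path)
  .check_columns(d, c("residue", "n_sites"), "site table")
  tbl <- stats::setNames(as.numeric(d$n_sites), d$residue)
  missing <- setdiff(rownames(.RESIDUE_COMPOSITION), names(tbl))
  if (length(missing)) {
    stop("site table must cover all 20 standard residues; missing: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tbl) | tbl < 0)) stop("site counts must be >= 0")
  tbl
}

#' Read a differential-expression table
#'
#' Expects `gene_id` and `log2fc` (optionally `padj`), as exported by the
#' usual RNA-Seq differential-expression tools.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  d <- .read_tsv(path)
  .check_columns(d, c("gene_id", "log2fc"), "DE table")
  d
}

#' Read a protein intensity table
#'
#' Expects `protein_id`, `sample_id`, `intensity`.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame.
#' @export
read_intensity_table <- function(path) {
  d <- .read_tsv(path)
  .check_columns(d, c("protein_id", "sample_id", "intensity"),
                 "intensity table")
  d
}

#' Write analysis reports
#'
#' Writes every data frame in `tables` as a tab-separated file and
#' `summary` as a machine-readable JSON run summary (counts Up/Down,
#' above-CV counts, binomial and Fisher p-values per contrast, seed,
#' config). Refuses to overwrite existing outputs unless `overwrite =
#' TRUE`.
#'
#' @param tables Named list of data frames.
#' @param summary Named list serialized to `run_summary.json`.
#' @param outdir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(tables = list(), summary = list(), outdir,
                          overwrite = FALSE) {
  stopifnot(is.list(tables), is.list(summary))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  files <- c(if (length(tables)) file.path(outdir,
                                           paste0(names(tables), ".tsv")),
             file.path(outdir, "run_summary.json"))
  existing <- files[file.exists(files)]
  if (length(existing) && !overwrite) {
    stop("refusing to overwrite existing output (use overwrite = TRUE): ",
         paste(basename(existing), collapse = ", "))
  }
  for (nm in names(tables)) {
    write_tsv(tables[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(files)
}
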