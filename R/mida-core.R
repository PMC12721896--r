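# MIDA core: from peptide sequence and labeling conditions to theoretical
# isotope envelopes, and from measured envelopes to fractional synthesis.
#
# All envelope arithmetic is done on the leading k+1 terms of the
# mass-shift distribution. Convolution is causal (term j depends only on
# terms <= j), so truncated vectors carry the exact M0..Mk values.

#' Labeling context for a heavy-water study
#'
#' Bundles the precursor model: body-water deuterium enrichment `p_body`
#' (the fraction of body water that is 2H2O during the labeling window,
#' about 0.05 in typical protocols), the natural deuterium abundance
#' `p_natural`, and the labeling duration in days.
#'
#' @param p_body Body-water 2H enrichment, a fraction in (0, 1).
#' @param p_natural Natural 2H abundance (default 0.000115).
#' @param t_label Labeling duration in days (> 0).
#' @return An object of class `labeling_context`.
#' @export
#' @examples
#' labeling_context(p_body = 0.05, t_label = 4)
labeling_context <- function(p_body = 0.05, p_natural = 0.000115, t_label = 4) {
  stopifnot(is.numeric(p_body), length(p_body) == 1L,
            is.numeric(p_natural), length(p_natural) == 1L,
            is.numeric(t_label), length(t_label) == 1L)
  if (!(p_natural >= 0 && p_natural < p_body && p_body < 1)) {
    stop("labeling_context requires 0 <= p_natural < p_body < 1 (got p_natural = ",
         p_natural, ", p_body = ", p_body, ")")
  }
  if (t_label <= 0) stop("t_label must be > 0 days")
  structure(list(p_body = p_body, p_natural = p_natural, t_label = t_label),
            class = "labeling_context")
}

#' @export
print.labeling_context <- function(x, ...) {
  cat(sprintf("labeling context: p_body = %.4g, p_natural = %.4g, t_label = %g d\n",
              x$p_body, x$p_natural, x$t_label))
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions over the sequence and adds one water, giving
#' the neutral-molecule formula in C, H, N, O, S counts. Optionally applies
#' fixed carbamidomethylation to every cysteine (+C2H3NO).
#'
#' @param sequence Peptide sequence, uppercase one-letter codes.
#' @param carbamidomethyl_cys If `TRUE`, add the carbamidomethyl offset per C.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
#' @examples
#' composition_from_sequence("G")   # glycine free amino acid: C2 H5 N O2
#' composition_from_sequence("GG")  # C4 H8 N2 O3
composition_from_sequence <- function(sequence, carbamidomethyl_cys = FALSE) {
  res <- .split_residues(sequence)
  comp <- colSums(.RESIDUE_COMPOSITION[res, , drop = FALSE])
  comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # one water
  if (carbamidomethyl_cys) {
    comp <- comp + sum(res == "C") * .CARBAMIDOMETHYL
  }
  storage.mode(comp) <- "double"
  comp
}

# Split and validate a peptide sequence, naming the first offending
# character and its position on failure.
.split_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty character string")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% rownames(.RESIDUE_COMPOSITION))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 res[bad[1L]], bad[1L], sequence))
  }
  res
}

#' Number of deuterium-accessible sites in a peptide
#'
#' Sums the per-residue effective C-H site counts over the sequence. The
#' result is real-valued because the table entries are empirical averages.
#'
#' @param sequence Peptide sequence.
#' @param table Named numeric vector mapping residue to site count;
#'   defaults to [default_site_table()].
#' @return Total effective site count `n` (>= 0).
#' @export
#' @examples
#' exchangeable_site_count("GG")  # 2 * 2.06
exchangeable_site_count <- function(sequence, table = default_site_table()) {
  res <- .split_residues(sequence)
  missing <- setdiff(unique(res), names(table))
  if (length(missing)) {
    stop("site table has no entry for residue(s): ",
         paste(missing, collapse = ", "))
  }
  n <- table[res]
  if (any(n < 0)) stop("site table entries must be >= 0")
  sum(n)
}

# ---- envelope arithmetic -------------------------------------------------

# Truncated convolution of two mass-shift distributions, keeping `len` terms.
.conv_trunc <- function(a, b, len) {
  la <- length(a); lb <- length(b)
  out <- numeric(len)
  for (j in seq_len(len)) {
    i <- seq_len(min(j, la))
    bj <- j - i + 1L
    keep <- bj <= lb
    out[j] <- sum(a[i[keep]] * b[bj[keep]])
  }
  out
}

# dist^m under convolution, truncated to `len` terms (binary exponentiation).
.conv_pow <- function(dist, m, len) {
  out <- c(1, numeric(len - 1L))
  base <- dist[seq_len(min(len, length(dist)))]
  while (m > 0) {
    if (m %% 2 == 1) out <- .conv_trunc(out, base, len)
    base <- .conv_trunc(base, base, len)
    m <- m %/% 2
  }
  out
}

# Envelope (first `len` terms, unnormalized) for a composition with exactly
# `n_int` hydrogen sites labeled at probability p_sites, remaining H natural.
.envelope_integer_n <- function(composition, n_int, p_sites, p_natural,
                                abundances, len) {
  h_total <- composition[["H"]]
  env <- c(1, numeric(len - 1L))
  for (el in .ELEMENTS) {
    m <- composition[[el]]
    if (el == "H" || m == 0) next
    env <- .conv_trunc(env, .conv_pow(abundances[[el]], m, len), len)
  }
  nat_dist <- c(1 - p_natural, p_natural)
  if (h_total - n_int > 0) {
    env <- .conv_trunc(env, .conv_pow(nat_dist, h_total - n_int, len), len)
  }
  if (n_int > 0) {
    env <- .conv_trunc(env, .conv_pow(c(1 - p_sites, p_sites), n_int, len), len)
  }
  env
}

#' Theoretical isotope envelope of a labeled peptide
#'
#' Predicts the relative abundances of mass isotopomers M0..Mk for a molecule
#' whose `n_sites` designated hydrogen positions carry deuterium with
#' probability `p_sites` while every other atom carries natural isotope
#' abundances. With `p_sites = p_natural` this is the unlabeled baseline; at
#' the body-water enrichment it is the fully labeled (100% newly synthesized)
#' asymptote. Non-integer `n_sites` is handled by linear interpolation
#' between the envelopes at `floor(n)` and `ceiling(n)`.
#'
#' @param composition Named numeric vector (C, H, N, O, S), e.g. from
#'   [composition_from_sequence()].
#' @param n_sites Effective number of deuterium-accessible H positions
#'   (0 <= n_sites <= H count); may be non-integer.
#' @param p_sites Deuterium probability at the labeled sites, in `[0, 1)`.
#' @param p_natural Natural deuterium abundance used for the remaining H.
#' @param k_max Highest mass isotopomer retained (default 3, i.e. M0-M3).
#' @param renormalize If `TRUE` (default) the truncated envelope is rescaled
#'   to sum to 1; if `FALSE` the absolute M0..Mk abundances are returned.
#' @param abundances Natural-abundance table, see
#'   [natural_isotope_abundances()].
#' @return Numeric vector of length `k_max + 1`, names `M0..Mk`.
#' @export
#' @examples
#' gg <- composition_from_sequence("GG")
#' theoretical_envelope(gg, n_sites = 0, p_sites = 0, renormalize = FALSE)
theoretical_envelope <- function(composition, n_sites, p_sites,
                                 p_natural = 0.000115, k_max = 3L,
                                 renormalize = TRUE,
                                 abundances = natural_isotope_abundances()) {
  stopifnot(is.numeric(composition), all(.ELEMENTS %in% names(composition)),
            all(composition >= 0), length(n_sites) == 1L, length(p_sites) == 1L)
  if (n_sites < 0) stop("n_sites must be >= 0")
  if (n_sites > composition[["H"]]) {
    stop(sprintf("n_sites (%.3g) exceeds the hydrogen count (%d)",
                 n_sites, as.integer(composition[["H"]])))
  }
  if (p_sites < 0 || p_sites >= 1) stop("p_sites must lie in [0, 1)")
  if (k_max < 1) stop("k_max must be >= 1")
  len <- as.integer(k_max) + 1L

  lo <- floor(n_sites); hi <- ceiling(n_sites)
  env <- .envelope_integer_n(composition, lo, p_sites, p_natural, abundances, len)
  if (hi > lo) {
    env_hi <- .envelope_integer_n(composition, hi, p_sites, p_natural,
                                  abundances, len)
    w <- n_sites - lo
    env <- (1 - w) * env + w * env_hi
  }
  if (renormalize) env <- env / sum(env)
  names(env) <- paste0("M", seq_len(len) - 1L)
  env
}

#' Truncate an envelope to M0..Mk and renormalize
#'
#' Keeps the first `k + 1` abundances and rescales them to sum to 1.
#' Idempotent for an already truncated, normalized envelope.
#'
#' @param envelope Numeric vector of relative abundances M0, M1, ...
#' @param k Highest isotopomer kept (default 3).
#' @return Numeric vector of length `k + 1` summing to 1.
#' @export
truncate_and_renormalize <- function(envelope, k = 3L) {
  stopifnot(is.numeric(envelope))
  if (length(envelope) < k + 1L) {
    stop("envelope has fewer than k + 1 abundances")
  }
  if (any(envelope < 0, na.rm = TRUE) || anyNA(envelope)) {
    stop("envelope abundances must be non-negative and non-missing")
  }
  env <- envelope[seq_len(k + 1L)]
  s <- sum(env)
  if (s <= 0) stop("degenerate envelope: truncated abundances sum to zero")
  env <- env / s
  names(env) <- paste0("M", seq_len(k + 1L) - 1L)
  env
}

#' Excess M0 and its asymptotic maximum
#'
#' The measured envelope of a partially renewed protein pool is a linear
#' mixture of the unlabeled baseline and the fully labeled asymptote, so the
#' excess M0 fraction `EM0 = measured M0 - baseline M0` scales linearly with
#' the fraction newly synthesized, reaching `EM0max = asymptote M0 -
#' baseline M0` for a 100% new pool. Both are negative whenever label is
#' incorporated (M0 can only be depleted).
#'
#' @param measured,baseline,asymptote Envelopes truncated/renormalized to the
#'   same k (see [truncate_and_renormalize()]).
#' @return List with `em0` and `em0_max`.
#' @export
em0_excess_and_max <- function(measured, baseline, asymptote) {
  if (length(measured) != length(baseline) ||
      length(baseline) != length(asymptote)) {
    stop("measured, baseline and asymptote envelopes must share one length")
  }
  em0 <- measured[[1L]] - baseline[[1L]]
  em0_max <- asymptote[[1L]] - baseline[[1L]]
  if (em0_max == 0) {
    stop("no kinetic information: asymptote M0 equals baseline M0 ",
         "(n_sites = 0 or p_body = p_natural)")
  }
  list(em0 = em0, em0_max = em0_max)
}

#' Fractional synthesis from excess M0
#'
#' The fraction `f` of the pool newly synthesized over the labeling window is
#' the ratio of the observed excess M0 to its theoretical maximum,
#' `f = EM0 / EM0max`. `f` is exact for noise-free mixtures and is reported
#' cumulatively (fraction renewed over the window). Optionally converts to a
#' first-order replacement rate constant `k = -ln(1 - f) / t` per day.
#'
#' Estimates outside `[0, 1]` are retained, not clipped: values within the
#' tolerance band `[-0.05, 1.2]` are flagged `"minor_excursion"`, values
#' beyond it `"out_of_bounds"` (excluded from protein roll-up).
#'
#' @param em0 Excess M0 (measured minus baseline), typically <= 0.
#' @param em0_max Maximal excess M0 (asymptote minus baseline), non-zero.
#' @param t_label Labeling duration in days (needed for `compute_rate`).
#' @param compute_rate If `TRUE`, also return `k_turnover`.
#' @return List with `f`, `qc_flag`, and (optionally) `k_turnover`
#'   (`NA` and flagged when `f >= 1` makes the rate unresolvable).
#' @export
#' @examples
#' fractional_synthesis(-0.10, -0.20)            # f = 0.5
#' fractional_synthesis(-0.10, -0.20, 4, TRUE)   # k = log(2)/4 per day
fractional_synthesis <- function(em0, em0_max, t_label = NULL,
                                 compute_rate = FALSE) {
  stopifnot(is.numeric(em0), is.numeric(em0_max),
            length(em0) == 1L, length(em0_max) == 1L)
  if (em0_max == 0) stop("em0_max must be non-zero")
  f <- em0 / em0_max
  qc_flag <- if (f >= 0 && f <= 1) {
    "ok"
  } else if (f >= -0.05 && f <= 1.2) {
    "minor_excursion"
  } else {
    "out_of_bounds"
  }
  out <- list(f = f, qc_flag = qc_flag)
  if (compute_rate) {
    if (is.null(t_label)) stop("t_label is required when compute_rate = TRUE")
    if (f >= 0 && f < 1) {
      out$k_turnover <- -log(1 - f) / t_label
    } else {
      out$k_turnover <- NA_real_
      out$rate_flag <- "unresolvable"
    }
  }
  out
}

#' Baseline and asymptote envelopes for a peptide
#'
#' Convenience wrapper computing, for one sequence under one labeling
#' context, the unlabeled baseline envelope (sites at natural abundance)
#' and the fully labeled asymptote (sites at body-water enrichment), both
#' truncated to M0..Mk and renormalized.
#'
#' @param sequence Peptide sequence.
#' @param context A [labeling_context()].
#' @param sites Exchangeable-site table.
#' @param k_max Envelope truncation (default 3).
#' @param carbamidomethyl_cys Passed to [composition_from_sequence()].
#' @return List with `baseline`, `asymptote`, `n_sites`, `composition`.
#' @export
peptide_envelopes <- function(sequence, context, sites = default_site_table(),
                              k_max = 3L, carbamidomethyl_cys = FALSE) {
  stopifnot(inherits(context, "labeling_context"))
  comp <- composition_from_sequence(sequence, carbamidomethyl_cys)
  n <- exchangeable_site_count(sequence, sites)
  baseline <- theoretical_envelope(comp, n, context$p_natural,
                                   p_natural = context$p_natural, k_max = k_max)
  asymptote <- theoretical_envelope(comp, n, context$p_body,
                                    p_natural = context$p_natural, k_max = k_max)
  list(baseline = baseline, asymptote = asymptote, n_sites = n,
       composition = comp)
}
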