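# Proteome-wide comparison machinery: paired log2 fold changes, the
# averaged-CV stringency cutoff, exact binomial and Fisher tests, z-score
# standardization, and the time-course transition summary.

#' Paired per-protein log2 fold change between two arms
#'
#' Pairs every protein present in both group summaries and computes
#' `log2fc = log2(mean_b / mean_a)` (conventionally treatment over
#' control), the Up/Down/Tie direction, and the equivalent percent change
#' `(2^log2fc - 1) * 100`. Proteins absent from either arm, or with a
#' non-positive mean in either, are excluded and counted in the attributes.
#'
#' @param summary_a Reference-arm summary (e.g. Con), columns `protein_id`,
#'   `mean_fsr`, optionally `cv`.
#' @param summary_b Comparison-arm summary (e.g. CR), same columns.
#' @return Data frame `protein_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `percent_change`, `direction`; attributes `n_unpaired`,
#'   `n_nonpositive`.
#' @export
paired_log2fc <- function(summary_a, summary_b) {
  .check_columns(summary_a, c("protein_id", "mean_fsr"), "arm A summary")
  .check_columns(summary_b, c("protein_id", "mean_fsr"), "arm B summary")
  d <- merge(summary_a[c("protein_id", "mean_fsr")],
             summary_b[c("protein_id", "mean_fsr")],
             by = "protein_id", suffixes = c("_a", "_b"))
  n_unpaired <- nrow(summary_a) + nrow(summary_b) - 2L * nrow(d)
  pos <- d$mean_fsr_a > 0 & d$mean_fsr_b > 0
  n_nonpositive <- sum(!pos)
  d <- d[pos, , drop = FALSE]
  log2fc <- log2(d$mean_fsr_b / d$mean_fsr_a)
  out <- data.frame(
    protein_id = d$protein_id,
    mean_a = d$mean_fsr_a,
    mean_b = d$mean_fsr_b,
    log2fc = log2fc,
    percent_change = (2^log2fc - 1) * 100,
    direction = ifelse(log2fc > 0, "Up", ifelse(log2fc < 0, "Down", "Tie")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_unpaired") <- n_unpaired
  attr(out, "n_nonpositive") <- n_nonpositive
  out
}

#' Averaged-CV variability cutoff
#'
#' The stringency threshold used for flux classification: the unweighted
#' mean of all defined per-protein CVs pooled across the compared arms.
#' A fold change counts as "above cutoff" only if its absolute percent
#' change exceeds this average CV.
#'
#' @param ... Numeric vectors of per-protein CVs (percent); `NA`s dropped.
#' @return The pooled mean CV in percent.
#' @export
#' @examples
#' average_cv_threshold(c(10, 20))  # 15
average_cv_threshold <- function(...) {
  cvs <- unlist(list(...), use.names = FALSE)
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) == 0L) stop("no defined CVs to average")
  if (any(cvs < 0)) stop("CVs must be >= 0")
  mean(cvs)
}

#' Flag fold changes above the CV cutoff
#'
#' @param comparisons Output of [paired_log2fc()].
#' @param threshold CV threshold in percent (see
#'   [average_cv_threshold()]).
#' @return `comparisons` with a logical `above_cv` column
#'   (`|percent_change| > threshold`).
#' @export
classify_flux_change <- function(comparisons, threshold) {
  .check_columns(comparisons, "percent_change", "comparison table")
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  comparisons$above_cv <- abs(comparisons$percent_change) > threshold
  comparisons
}

#' Exact two-tailed binomial test
#'
#' The probability that `n_total` fair coin tosses would produce a split at
#' least as lopsided as `n_down` successes. The default two-tailed
#' convention doubles the smaller tail and caps at 1; `method = "minlik"`
#' instead sums all outcomes whose point probability does not exceed the
#' observed one (the convention of [stats::binom.test()]).
#'
#' @param n_down Number of successes (e.g. proteins classified Down).
#' @param n_total Number of classified proteins (ties excluded upstream).
#' @param p0 Null success probability (default 0.5).
#' @param method `"double"` (default) or `"minlik"`.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' binomial_two_tailed(6, 10)   # 0.75390625
#' binomial_two_tailed(10, 10)  # 2 / 1024
binomial_two_tailed <- function(n_down, n_total, p0 = 0.5,
                                method = c("double", "minlik")) {
  method <- match.arg(method)
  stopifnot(length(n_down) == 1L, length(n_total) == 1L)
  if (n_total <= 0L) stop("n_total must be positive")
  stopifnot(n_down >= 0, n_down <= n_total, p0 > 0, p0 < 1)
  if (method == "double") {
    lower <- stats::pbinom(n_down, n_total, p0)
    upper <- stats::pbinom(n_down - 1L, n_total, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    dens <- stats::dbinom(0:n_total, n_total, p0)
    min(1, sum(dens[dens <= dens[n_down + 1L] * (1 + 1e-7)]))
  }
}

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric point
#' probabilities of every table (with the observed margins) that is no
#' more probable than the observed one.
#'
#' @param table 2x2 numeric matrix of counts; rows are outcome classes
#'   (e.g. Down vs not-Down), columns are arms.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_two_tailed(matrix(c(10, 0, 0, 10), 2))  # 2 / choose(20, 10)
fisher_exact_two_tailed <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop("table must be a 2x2 matrix of non-negative counts")
  }
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ])
  c1 <- sum(table[, 1L]); c2 <- sum(table[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("degenerate 2x2 table: all margins must be positive")
  }
  n <- r1 + r2
  a_range <- max(0L, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(a_range, r1, r2, c1)
  obs <- stats::dhyper(table[1L, 1L], r1, r2, c1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Proportion of Up vs Down flux changes with binomial significance
#'
#' Tallies a comparison table into the counts reported alongside the
#' proteome-wide fold-change plots: proteins Down vs Up (ties excluded from
#' the test but reported), the same counts restricted to changes above the
#' CV cutoff, and the exact two-tailed binomial p-value for the Down/Up
#' split.
#'
#' @param comparisons Output of [paired_log2fc()], optionally after
#'   [classify_flux_change()].
#' @param method Binomial convention, see [binomial_two_tailed()].
#' @return List with `n_down`, `n_up`, `n_tie`, `n_total`, `pct_down`,
#'   `pct_up`, `p_binomial`, and (when `above_cv` is present)
#'   `n_down_above_cv`, `n_up_above_cv`, `pct_down_above_cv`,
#'   `pct_up_above_cv`.
#' @export
flux_proportions <- function(comparisons, method = c("double", "minlik")) {
  method <- match.arg(method)
  .check_columns(comparisons, "direction", "comparison table")
  n_down <- sum(comparisons$direction == "Down")
  n_up <- sum(comparisons$direction == "Up")
  n_tie <- sum(comparisons$direction == "Tie")
  n_total <- n_down + n_up
  out <- list(
    n_down = n_down, n_up = n_up, n_tie = n_tie, n_total = n_total,
    pct_down = if (n_total > 0) 100 * n_down / n_total else NA_real_,
    pct_up = if (n_total > 0) 100 * n_up / n_total else NA_real_,
    p_binomial = if (n_total > 0)
      binomial_two_tailed(n_down, n_total, method = method) else NA_real_
  )
  if ("above_cv" %in% names(comparisons)) {
    out$n_down_above_cv <- sum(comparisons$direction == "Down" &
                                 comparisons$above_cv)
    out$n_up_above_cv <- sum(comparisons$direction == "Up" &
                               comparisons$above_cv)
    out$pct_down_above_cv <- if (n_total > 0)
      100 * out$n_down_above_cv / n_total else NA_real_
    out$pct_up_above_cv <- if (n_total > 0)
      100 * out$n_up_above_cv / n_total else NA_real_
  }
  out
}

#' Fisher contrast of Down proportions between two arms
#'
#' Builds the 2x2 table (Down, not-Down) x (arm A, arm B) from two
#' comparison tables (each already expressed against the common control)
#' and returns the exact two-tailed Fisher p-value. Ties are excluded, so
#' "not-Down" means Up.
#'
#' @param comparisons_a,comparisons_b Outputs of [paired_log2fc()] for the
#'   two arms under contrast (e.g. CR and NO-CR, both vs Con).
#' @return List with the 2x2 `table` (dimnames kept) and `p_fisher`.
#' @export
arm_contrast <- function(comparisons_a, comparisons_b) {
  counts <- function(cmp) {
    c(down = sum(cmp$direction == "Down"), up = sum(cmp$direction == "Up"))
  }
  a <- counts(comparisons_a); b <- counts(comparisons_b)
  tab <- matrix(c(a["down"], a["up"], b["down"], b["up"]), nrow = 2L,
                dimnames = list(c("Down", "NotDown"), c("armA", "armB")))
  list(table = tab, p_fisher = fisher_exact_two_tailed(tab))
}

#' Standard scores within a time point
#'
#' Positions each FSR relative to the mean of the values supplied (by
#' default the pooled Con + CR values at one time point):
#' `z = (x - mean) / sd` with the sample SD.
#'
#' @param x Numeric vector of FSRs (>= 2 distinct values).
#' @return Vector of z-scores with mean 0 and SD 1.
#' @export
zscore_by_timepoint <- function(x) {
  stopifnot(is.numeric(x))
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two values to standardize")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: z-scores undefined")
  (x - mean(x)) / s
}

#' Time-course summary and transition detection
#'
#' Takes per-day Down-proportion results and expresses each day relative
#' to the reference day on the log2 scale (both signs are emitted, since
#' either orientation is used in practice). A transition is estimated two
#' ways: the midpoint of a 4-parameter logistic fitted to `pct_down`
#' versus day (Levenberg-Marquardt), and the first day whose `pct_down`
#' exceeds `threshold`.
#'
#' @param points Data frame with columns `day`, `pct_down`, optionally
#'   `pct_down_above_cv`.
#' @param reference_day Day used as the log2 reference (default 0; must be
#'   present).
#' @param threshold Percent-down level defining the crossing day
#'   (default 70).
#' @return List with `points` (input plus `log2_rel_ref`,
#'   `neg_log2_rel_ref`) and `transition` (`logistic_midpoint`,
#'   `first_day_above_threshold`, `fit`). A flat series yields `NA`
#'   transition estimates.
#' @export
timecourse_summary <- function(points, reference_day = 0, threshold = 70) {
  .check_columns(points, c("day", "pct_down"), "time-course table")
  if (nrow(points) < 3L) stop("need at least three time points")
  if (!reference_day %in% points$day) {
    stop("reference day ", reference_day, " is missing from the series")
  }
  points <- points[order(points$day), , drop = FALSE]
  ref <- points$pct_down[points$day == reference_day][1L]
  if (!is.finite(ref) || ref <= 0) stop("reference-day pct_down must be > 0")
  points$log2_rel_ref <- log2(points$pct_down / ref)
  points$neg_log2_rel_ref <- -points$log2_rel_ref

  transition <- list(logistic_midpoint = NA_real_,
                     first_day_above_threshold = NA_real_, fit = NULL)
  above <- points$day[points$pct_down > threshold]
  if (length(above)) transition$first_day_above_threshold <- min(above)

  if (diff(range(points$pct_down)) > 1e-8) {
    fit <- .fit_logistic4(points$day, points$pct_down)
    if (!is.null(fit)) {
      transition$logistic_midpoint <- unname(stats::coef(fit)[["xmid"]])
      transition$fit <- fit
    }
  }
  list(points = points, transition = transition)
}

# 4-parameter logistic y = A + (B - A) / (1 + exp(-(x - xmid)/scal)),
# fitted by Levenberg-Marquardt on the raw residuals (robust to nearly
# step-like series where a formula-interface start is singular).
.fit_logistic4 <- function(x, y) {
  if (length(x) < 5L) return(NULL)  # 4 parameters need >= 5 points
  pred <- function(p) {
    p["A"] + (p["B"] - p["A"]) / (1 + exp(-(x - p["xmid"]) / p["scal"]))
  }
  lo <- min(y); hi <- max(y)
  half <- (lo + hi) / 2
  crossing <- x[which(y >= half)[1L]]
  if (!is.finite(crossing)) crossing <- stats::median(x)
  span <- diff(range(x))
  best <- NULL
  for (scal0 in c(span / 10, 1, 3)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(A = lo, B = hi, xmid = crossing, scal = scal0),
        fn = function(p) y - pred(p),
        lower = c(A = 0, B = 0, xmid = min(x) - span, scal = 0.05),
        upper = c(A = 100, B = 100, xmid = max(x) + span, scal = span),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NULL)
  structure(list(coefficients = best$par, deviance = best$deviance,
                 fitted = pred(best$par), nls_lm = best),
            class = "logistic4_fit")
}

#' @export
coef.logistic4_fit <- function(object, ...) object$coefficients

#' @export
print.logistic4_fit <- function(x, ...) {
  cat("4-parameter logistic fit\n")
  print(x$coefficients)
  invisible(x)
}
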