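# Synthetic-study generator. Emulates the statistical structure the
# analysis assumes: protein-specific baseline FSRs, a logistic
# calorie-restriction slowdown centered near day 27.5, arm effect
# multipliers, replicate animals, and multinomial counting noise on
# peptide isotopomer envelopes. Everything flows from a single seed via
# named streams, so fixtures are bitwise reproducible.

# Derive a component-specific 31-bit seed from the master seed.
.stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr under a named RNG stream, restoring the caller's RNG state.
.with_stream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.stream_seed(seed, name))
  expr
}

#' Design of a synthetic labeling study
#'
#' Fixes the cohort layout and measurement depth of a simulated
#' heavy-water study: number of proteins, peptides per protein, replicate
#' animals per arm (default 4, within the usual n = 3-5 per group), study
#' arms and days, body-water enrichment, labeling window, and the
#' multinomial ion-count depth of each envelope.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range (e.g. `2:4`) sampled per
#'   protein.
#' @param n_animals Animals per arm per day.
#' @param arms Character vector from `{"Con", "CR", "NO-", "NO-CR"}`.
#' @param days Study days sampled.
#' @param p_body Body-water 2H enrichment (default 0.05).
#' @param t_label Labeling window in days (default 4).
#' @param ion_counts Multinomial draws per envelope (default 10000).
#' @param dropout_rate Bernoulli peptide-measurement dropout (default 0).
#' @param seed Master seed (mandatory).
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_proteins = 200L,
                              peptides_per_protein = 2:4,
                              n_animals = 4L,
                              arms = c("Con", "CR"),
                              days = c(0, 9, 14, 20, 25, 27, 28, 29, 30, 31, 40),
                              p_body = 0.05, t_label = 4,
                              ion_counts = 10000L,
                              dropout_rate = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_proteins >= 1, all(peptides_per_protein >= 1), n_animals >= 1,
            length(arms) >= 1, length(days) >= 1, ion_counts >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  allowed <- c("Con", "CR", "NO-", "NO-CR")
  if (!all(arms %in% allowed)) {
    stop("arms must be a subset of: ", paste(allowed, collapse = ", "))
  }
  ctx <- labeling_context(p_body = p_body, t_label = t_label)
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 n_animals = as.integer(n_animals),
                 arms = arms, days = days,
                 p_body = p_body, p_natural = ctx$p_natural,
                 t_label = t_label,
                 ion_counts = as.integer(ion_counts),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Effect model of a synthetic study
#'
#' Describes the true biology the simulator injects. Baseline FSRs
#' (fraction of the pool renewed over the labeling window) are log-normal
#' across proteins. The calorie-restriction effect is a logistic slowdown
#' in study day: the CR/Con multiplier moves from 1 to
#' `cr_multiplier_late` with midpoint `transition_day` and time scale
#' `transition_steepness`. iNOS-deficient (NO-) animals run faster than
#' control by `no_multiplier`; NO-CR animals largely lose the CR slowing
#' (`no_cr_multiplier`). Animal-level biological variation is log-normal
#' jitter around the group truth.
#'
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-protein baseline FSR (defaults log(0.35), 0.5; clamped to
#'   (0.005, 0.95)).
#' @param cr_multiplier_late Late-CR FSR multiplier (default 0.7).
#' @param transition_day Logistic midpoint in days (default 27.5).
#' @param transition_steepness Logistic time scale in days (default 1).
#' @param no_multiplier NO- arm multiplier (> 1, default 1.3).
#' @param no_cr_multiplier NO-CR arm multiplier (default 0.95).
#' @param animal_jitter_sdlog SD of per-animal log-normal jitter
#'   (default 0.1; the jitter is mean-one).
#' @return Object of class `effect_model`.
#' @export
effect_model <- function(baseline_meanlog = log(0.35), baseline_sdlog = 0.5,
                         cr_multiplier_late = 0.7, transition_day = 27.5,
                         transition_steepness = 1, no_multiplier = 1.3,
                         no_cr_multiplier = 0.95,
                         animal_jitter_sdlog = 0.1) {
  stopifnot(cr_multiplier_late > 0, cr_multiplier_late <= 1,
            transition_steepness > 0, no_multiplier > 1,
            no_cr_multiplier > 0, animal_jitter_sdlog >= 0)
  structure(list(baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 cr_multiplier_late = cr_multiplier_late,
                 transition_day = transition_day,
                 transition_steepness = transition_steepness,
                 no_multiplier = no_multiplier,
                 no_cr_multiplier = no_cr_multiplier,
                 animal_jitter_sdlog = animal_jitter_sdlog),
            class = "effect_model")
}

#' Arm-and-day FSR multiplier
#'
#' The true group-level multiplier applied to each protein's baseline FSR:
#' Con is exactly 1; CR follows the logistic transition
#' `1 - (1 - cr_multiplier_late) * plogis((day - transition_day) /
#' transition_steepness)`; NO- and NO-CR are day-constant.
#'
#' @param arm Arm label(s).
#' @param day Study day(s).
#' @param effects An [effect_model()].
#' @return Numeric multiplier vector.
#' @export
arm_multiplier <- function(arm, day, effects) {
  stopifnot(inherits(effects, "effect_model"))
  cr <- 1 - (1 - effects$cr_multiplier_late) *
    stats::plogis((day - effects$transition_day) /
                    effects$transition_steepness)
  out <- rep(1, length(arm))
  out[arm == "CR"] <- cr[arm == "CR"]
  out[arm == "NO-"] <- effects$no_multiplier
  out[arm == "NO-CR"] <- effects$no_cr_multiplier
  out
}

#' Sample metadata implied by a design
#'
#' @param design A [simulation_design()].
#' @return Data frame `sample_id`, `animal`, `arm`, `day`, `p_body`.
#' @export
design_metadata <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  g <- expand.grid(animal = seq_len(design$n_animals), day = design$days,
                   arm = design$arms, stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_d%g_a%d", g$arm, g$day, g$animal),
    animal = sprintf("%s_a%d", g$arm, g$animal),
    arm = g$arm, day = g$day, p_body = design$p_body,
    stringsAsFactors = FALSE
  )
}

#' True protein FSR table
#'
#' Draws per-protein baseline FSRs, applies the arm-and-day multiplier and
#' per-animal jitter, and returns the ground truth for every sample.
#' Deterministic given the design seed.
#'
#' @param design A [simulation_design()].
#' @param effects An [effect_model()].
#' @return Data frame `protein_id`, `sample_id`, `arm`, `day`, `animal`,
#'   `fsr_true`, plus attribute `baseline` (named per-protein vector).
#' @export
true_fsr_model <- function(design, effects = effect_model()) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(effects, "effect_model"))
  meta <- design_metadata(design)
  proteins <- sprintf("P%04d", seq_len(design$n_proteins))
  baseline <- .with_stream(design$seed, "baseline", {
    b <- stats::rlnorm(design$n_proteins, effects$baseline_meanlog,
                       effects$baseline_sdlog)
    pmin(pmax(b, 0.005), 0.95)
  })
  names(baseline) <- proteins
  grid <- expand.grid(protein_id = proteins, sample_id = meta$sample_id,
                      stringsAsFactors = FALSE)
  m <- match(grid$sample_id, meta$sample_id)
  grid$arm <- meta$arm[m]; grid$day <- meta$day[m]
  grid$animal <- meta$animal[m]
  mult <- arm_multiplier(grid$arm, grid$day, effects)
  jitter <- .with_stream(design$seed, "jitter", {
    s <- effects$animal_jitter_sdlog
    stats::rlnorm(nrow(grid), -s^2 / 2, s)  # mean-one
  })
  grid$fsr_true <- pmin(baseline[grid$protein_id] * mult * jitter, 0.995)
  rownames(grid) <- NULL
  attr(grid, "baseline") <- baseline
  grid
}

# Tryptic-looking random peptides: 8-18 residues, C-terminal K/R.
.simulate_sequences <- function(n_proteins, peptides_per_protein, seed) {
  freqs <- c(A = 8.3, R = 5.6, N = 4.0, D = 5.5, C = 1.4, E = 6.7, Q = 3.9,
             G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  .with_stream(seed, "sequences", {
    npep <- sample(peptides_per_protein, n_proteins, replace = TRUE)
    total <- sum(npep)
    lens <- sample(8:18, total, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      body <- sample(names(freqs), L - 1L, replace = TRUE, prob = freqs)
      paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
    }, character(1L))
    data.frame(
      protein_id = rep(sprintf("P%04d", seq_len(n_proteins)), npep),
      sequence = seqs, stringsAsFactors = FALSE
    )
  })
}

#' Simulate peptide isotopomer envelopes for a truth table
#'
#' For each peptide of each protein in each sample, forms the exact
#' baseline/asymptote mixture envelope at the sample's true fractional
#' synthesis and, unless `analytic = TRUE`, adds multinomial counting
#' noise at the design's ion-count depth. Spectral counts are geometric
#' (shifted to a minimum of 1).
#'
#' @param truth Truth table ([true_fsr_model()] or any data frame with
#'   `protein_id`, `sample_id`, `fsr_true`).
#' @param design A [simulation_design()].
#' @param analytic If `TRUE`, emit noise-free mixture envelopes (closed
#'   loop for pipeline identities).
#' @param sequences Optional data frame `protein_id`, `sequence`
#'   overriding the generated peptides.
#' @param sites Exchangeable-site table used to build the envelopes.
#' @return Peptide measurement table: `sequence`, `protein_id`,
#'   `sample_id`, `charge`, `M0`..`M3`, `spectral_count`.
#' @export
simulate_peptide_envelopes <- function(truth, design, analytic = FALSE,
                                       sequences = NULL,
                                       sites = default_site_table()) {
  stopifnot(inherits(design, "simulation_design"))
  .check_columns(truth, c("protein_id", "sample_id", "fsr_true"),
                 "truth table")
  if (is.null(sequences)) {
    sequences <- .simulate_sequences(
      length(unique(truth$protein_id)),
      design$peptides_per_protein, design$seed)
    sequences$protein_id <-
      sort(unique(truth$protein_id))[match(sequences$protein_id,
                                           sort(unique(sequences$protein_id)))]
  }
  useq <- unique(sequences$sequence)
  ctx <- labeling_context(design$p_body, design$p_natural, design$t_label)
  base <- asym <- matrix(0, length(useq), 4L)
  for (i in seq_along(useq)) {
    env <- peptide_envelopes(useq[i], ctx, sites = sites, k_max = 3L)
    base[i, ] <- env$baseline
    asym[i, ] <- env$asymptote
  }

  rows <- merge(sequences, truth[c("protein_id", "sample_id", "fsr_true")],
                by = "protein_id")
  si <- match(rows$sequence, useq)
  f <- rows$fsr_true
  mix <- base[si, , drop = FALSE] * (1 - f) + asym[si, , drop = FALSE] * f

  meas <- mix
  counts <- NULL
  if (!analytic) {
    meas <- .with_stream(design$seed, "envelope_noise", {
      t(vapply(seq_len(nrow(mix)), function(i) {
        as.numeric(stats::rmultinom(1L, design$ion_counts, mix[i, ]))
      }, numeric(4L))) / design$ion_counts
    })
  }
  spectra <- .with_stream(design$seed, "spectral_counts",
                          stats::rgeom(nrow(rows), 0.4) + 1L)
  charge <- .with_stream(design$seed, "charge",
                         sample(2:3, nrow(rows), replace = TRUE))
  out <- data.frame(
    sequence = rows$sequence, protein_id = rows$protein_id,
    sample_id = rows$sample_id, charge = charge,
    M0 = meas[, 1L], M1 = meas[, 2L], M2 = meas[, 3L], M3 = meas[, 4L],
    spectral_count = spectra, stringsAsFactors = FALSE
  )
  if (design$dropout_rate > 0) {
    keep <- .with_stream(design$seed, "dropout",
                         stats::runif(nrow(out)) >= design$dropout_rate)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Simulate a gene-level differential-expression table
#'
#' Emits a DESeq2-style table whose per-gene direction matches the
#' protein's FSR direction with probability `concordance_prob` (else
#' flipped); log2FC magnitudes are half-normal with SD `fc_sd`.
#'
#' @param comparisons Protein comparison table with `protein_id`, `log2fc`.
#' @param concordance_prob Probability a gene agrees in direction.
#' @param seed Seed for this table.
#' @param fc_sd SD of the mRNA log2FC magnitude (default 1).
#' @return Data frame `gene_id`, `log2fc`.
#' @export
simulate_transcript_table <- function(comparisons, concordance_prob,
                                      seed, fc_sd = 1) {
  .check_columns(comparisons, c("protein_id", "log2fc"), "comparison table")
  stopifnot(concordance_prob >= 0, concordance_prob <= 1)
  n <- nrow(comparisons)
  .with_stream(seed, "transcripts", {
    agree <- stats::runif(n) < concordance_prob
    mag <- abs(stats::rnorm(n, 0, fc_sd))
    sign_fsr <- sign(comparisons$log2fc)
    sign_fsr[sign_fsr == 0] <- 1
    data.frame(gene_id = comparisons$protein_id,
               log2fc = ifelse(agree, sign_fsr, -sign_fsr) * mag,
               stringsAsFactors = FALSE)
  })
}

#' Simulate palmitate isotopomer envelopes
#'
#' Per-sample palmitate envelopes at arm-specific true DNL fractions,
#' using the same mixture-plus-multinomial mechanism as the peptide
#' simulator.
#'
#' @param design A [simulation_design()].
#' @param f_dnl_true Named numeric vector of true DNL fractions per arm.
#' @param species A [lipid_species()] (default [palmitate()]).
#' @param analytic If `TRUE`, noise-free envelopes.
#' @return Data frame `sample_id`, `arm`, `day`, `f_true`, `M0`..`M3`.
#' @export
simulate_palmitate <- function(design, f_dnl_true, species = palmitate(),
                               analytic = FALSE) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(species, "lipid_species"))
  meta <- design_metadata(design)
  if (!all(meta$arm %in% names(f_dnl_true))) {
    stop("f_dnl_true must name every arm in the design")
  }
  ctx <- labeling_context(design$p_body, design$p_natural, design$t_label)
  baseline <- theoretical_envelope(species$composition, species$n_sites,
                                   ctx$p_natural, p_natural = ctx$p_natural)
  asymptote <- theoretical_envelope(species$composition, species$n_sites,
                                    ctx$p_body, p_natural = ctx$p_natural)
  f <- unname(f_dnl_true[meta$arm])
  mix <- outer(1 - f, baseline) + outer(f, asymptote)
  meas <- mix
  if (!analytic) {
    meas <- .with_stream(design$seed, "palmitate_noise", {
      t(vapply(seq_len(nrow(mix)), function(i) {
        as.numeric(stats::rmultinom(1L, design$ion_counts, mix[i, ]))
      }, numeric(4L))) / design$ion_counts
    })
  }
  data.frame(sample_id = meta$sample_id, arm = meta$arm, day = meta$day,
             f_true = f, M0 = meas[, 1L], M1 = meas[, 2L], M2 = meas[, 3L],
             M3 = meas[, 4L], stringsAsFactors = FALSE)
}

#' Simulate protein label-free intensities
#'
#' Log-normal protein abundances with per-sample noise, for WPASR
#' exercises.
#'
#' @param truth Truth table with `protein_id`, `sample_id`.
#' @param seed Seed.
#' @param meanlog,sdlog Protein-level abundance distribution.
#' @param noise_sdlog Per-sample measurement jitter.
#' @return Data frame `protein_id`, `sample_id`, `intensity`.
#' @export
simulate_intensities <- function(truth, seed, meanlog = log(1e6),
                                 sdlog = 1, noise_sdlog = 0.2) {
  .check_columns(truth, c("protein_id", "sample_id"), "truth table")
  prot <- unique(truth$protein_id)
  .with_stream(seed, "intensities", {
    base <- stats::rlnorm(length(prot), meanlog, sdlog)
    names(base) <- prot
    data.frame(
      protein_id = truth$protein_id, sample_id = truth$sample_id,
      intensity = base[truth$protein_id] *
        stats::rlnorm(nrow(truth), 0, noise_sdlog),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete study
#'
#' One-call wrapper: truth table, sample metadata, peptide envelope table
#' and protein intensities for a design and effect model.
#'
#' @param design A [simulation_design()].
#' @param effects An [effect_model()].
#' @param analytic Noise-free envelopes if `TRUE`.
#' @return List with `peptides`, `metadata`, `truth`, `intensities`,
#'   `design`, `effects`.
#' @export
simulate_study <- function(design, effects = effect_model(),
                           analytic = FALSE) {
  truth <- true_fsr_model(design, effects)
  list(
    peptides = simulate_peptide_envelopes(truth, design, analytic = analytic),
    metadata = design_metadata(design),
    truth = truth,
    intensities = simulate_intensities(truth, design$seed),
    design = design,
    effects = effects
  )
}
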