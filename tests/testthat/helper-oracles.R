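# Independent oracles used across tests. These deliberately avoid the
# package's computational paths: envelopes are built atom by atom with a
# naive full-length convolution, and the exact tests are checked against
# direct enumeration of the outcome space.

# Atom-by-atom envelope: convolve one atom's isotope distribution at a
# time over the full (untruncated) mass-shift axis.
oracle_envelope <- function(composition, n_sites_int, p_sites,
                            p_natural = 0.000115) {
  abund <- natural_isotope_abundances()
  dists <- list()
  for (el in c("C", "N", "O", "S")) {
    dists <- c(dists, rep(list(abund[[el]]), composition[[el]]))
  }
  h_nat <- composition[["H"]] - n_sites_int
  dists <- c(dists,
             rep(list(c(1 - p_natural, p_natural)), h_nat),
             rep(list(c(1 - p_sites, p_sites)), n_sites_int))
  env <- 1
  for (d in dists) {
    new <- numeric(length(env) + length(d) - 1L)
    for (i in seq_along(env)) {
      for (j in seq_along(d)) {
        new[i + j - 1L] <- new[i + j - 1L] + env[i] * d[j]
      }
    }
    env <- new
  }
  env
}

# Two-tailed binomial by exhaustive enumeration of all 2^n coin-toss
# outcomes (double the smaller tail, capped at 1).
oracle_binomial <- function(k, n) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  heads <- rowSums(outcomes)
  pmf <- vapply(0:n, function(h) mean(heads == h), numeric(1L))
  lower <- sum(pmf[seq_len(k + 1L)])
  upper <- sum(pmf[seq(k + 1L, n + 1L)])
  min(1, 2 * min(lower, upper))
}

# Two-sided Fisher by full enumeration over all tables with the observed
# margins, counting arrangements with choose() directly.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_all <- max(0, c1 - r2):min(r1, c1)
  counts <- choose(r1, a_all) * choose(r2, c1 - a_all)
  probs <- counts / choose(n, c1)
  obs <- probs[a_all == tab[1, 1]]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

random_peptide <- function(len) {
  paste(sample(rownames(residue_compositions()), len, replace = TRUE),
        collapse = "")
}

# Small analytic cohort helper: truth table with prescribed f values,
# one protein per f, rendered through the analytic envelope simulator.
analytic_cohort <- function(f_values, seed = 7L) {
  design <- simulation_design(n_proteins = length(f_values),
                              peptides_per_protein = 2L,
                              n_animals = 1L, arms = "Con", days = 0,
                              seed = seed)
  meta <- design_metadata(design)
  truth <- data.frame(
    protein_id = sprintf("P%04d", seq_along(f_values)),
    sample_id = meta$sample_id[1L],
    fsr_true = f_values, stringsAsFactors = FALSE
  )
  peptides <- simulate_peptide_envelopes(truth, design, analytic = TRUE)
  list(design = design, metadata = meta, truth = truth, peptides = peptides)
}
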