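# Core MIDA machinery: compositions, site counts, theoretical envelopes,
# and the excess-M0 mixture model.

test_that("peptide compositions follow residue sums plus one water", {
  expect_equal(composition_from_sequence("G"),
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  expect_equal(composition_from_sequence("GG"),
               c(C = 4, H = 8, N = 2, O = 3, S = 0))
  # order invariance
  expect_equal(composition_from_sequence("AG"),
               composition_from_sequence("GA"))
  # additivity over concatenation minus the shared water
  water <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  expect_equal(composition_from_sequence("ACDK"),
               composition_from_sequence("AC") +
                 composition_from_sequence("DK") - water)
  # carbamidomethyl adds C2H3NO per cysteine
  expect_equal(composition_from_sequence("CC", carbamidomethyl_cys = TRUE) -
                 composition_from_sequence("CC"),
               c(C = 4, H = 6, N = 2, O = 2, S = 0))
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(composition_from_sequence("AXG"), "'X' at position 2")
  expect_error(composition_from_sequence(""), "non-empty")
  expect_error(composition_from_sequence("agk"), "position 1")
})

test_that("exchangeable site counts sum the residue table", {
  expect_equal(exchangeable_site_count("GG", c(G = 2.06)), 4.12)
  expect_equal(exchangeable_site_count("AG", c(A = 0, G = 0)), 0)
  expect_equal(exchangeable_site_count("GAK"),
               sum(default_site_table()[c("G", "A", "K")]))
  expect_error(exchangeable_site_count(""), "non-empty")
  expect_error(exchangeable_site_count("W", c(G = 2.06)), "W")
})

test_that("theoretical envelopes match the atom-by-atom oracle", {
  set.seed(11)
  for (i in 1:8) {
    sq <- random_peptide(sample(2:8, 1))
    comp <- composition_from_sequence(sq)
    n <- sample(0:min(6, comp[["H"]]), 1)
    p <- runif(1, 0.01, 0.1)
    env <- theoretical_envelope(comp, n, p, k_max = 3, renormalize = FALSE)
    orc <- oracle_envelope(comp, n, p)[1:4]
    expect_lt(max(abs(env - orc)), 1e-12)
  }
})

test_that("unlabeled GG envelope has the expected M0 and sites at natural
           abundance are indistinguishable from background", {
  gg <- composition_from_sequence("GG")
  env0 <- theoretical_envelope(gg, 0, 0, renormalize = FALSE)
  expect_equal(unname(env0[1]), 0.9431, tolerance = 1e-3)
  env_nat <- theoretical_envelope(gg, 5, 0.000115, renormalize = FALSE)
  expect_equal(env_nat, env0, tolerance = 1e-14)
})

test_that("labeled/baseline M0 ratio follows the closed form at integer n", {
  comp <- composition_from_sequence("LVNELTEFAK")
  for (n in c(1, 7, 20)) {
    for (p in c(0.02, 0.05)) {
      lab <- theoretical_envelope(comp, n, p, renormalize = FALSE)
      base <- theoretical_envelope(comp, n, 0.000115, renormalize = FALSE)
      expect_equal(unname(lab[1] / base[1]),
                   ((1 - p) / (1 - 0.000115))^n, tolerance = 1e-12)
    }
  }
})

test_that("envelopes are normalized, monotone in p_body, and interpolate
           consistently in n", {
  comp <- composition_from_sequence("SAMPLER")
  expect_equal(sum(theoretical_envelope(comp, 10, 0.05)), 1,
               tolerance = 1e-12)
  # asymptote M0 strictly decreasing in p_body for n > 0
  m0 <- vapply(c(0.01, 0.03, 0.05, 0.08),
               function(p) theoretical_envelope(comp, 10, p)[[1]],
               numeric(1))
  expect_true(all(diff(m0) < 0))
  # integer n equals the degenerate interpolation
  e_int <- theoretical_envelope(comp, 4, 0.05, renormalize = FALSE)
  e_eps <- theoretical_envelope(comp, 4 + 1e-12, 0.05, renormalize = FALSE)
  expect_equal(e_int, e_eps, tolerance = 1e-10)
  # midpoint n is the average of the flanking integer envelopes
  e_mid <- theoretical_envelope(comp, 4.5, 0.05, renormalize = FALSE)
  e5 <- theoretical_envelope(comp, 5, 0.05, renormalize = FALSE)
  expect_equal(e_mid, (e_int + e5) / 2, tolerance = 1e-14)
})

test_that("envelope preconditions are enforced", {
  gg <- composition_from_sequence("GG")
  expect_error(theoretical_envelope(gg, 9, 0.05), "exceeds the hydrogen")
  expect_error(theoretical_envelope(gg, 2, 1), "p_sites")
  expect_error(theoretical_envelope(gg, -1, 0.05), ">= 0")
})

test_that("truncate_and_renormalize keeps M0..Mk and rescales to 1", {
  out <- truncate_and_renormalize(c(0.5, 0.3, 0.1, 0.05, 0.05), k = 3)
  expect_equal(unname(out), c(0.5, 0.3, 0.1, 0.05) / 0.95)
  expect_equal(truncate_and_renormalize(out), out)  # idempotent
  expect_error(truncate_and_renormalize(rep(0, 5)), "degenerate")
  expect_error(truncate_and_renormalize(c(0.9, 0.1), k = 3), "fewer")
})

test_that("excess M0 arithmetic and its degenerate case behave", {
  em <- em0_excess_and_max(c(0.50, 0.5), c(0.60, 0.4), c(0.40, 0.6))
  expect_equal(em$em0, -0.10)
  expect_equal(em$em0_max, -0.20)
  # measured = baseline -> no label incorporated
  expect_equal(em0_excess_and_max(c(0.6, 0.4), c(0.6, 0.4),
                                  c(0.4, 0.6))$em0, 0)
  expect_error(em0_excess_and_max(c(0.6, 0.4), c(0.6, 0.4), c(0.6, 0.4)),
               "no kinetic information")
})

test_that("fractional synthesis is the EM0 ratio with first-order rate", {
  fs <- fractional_synthesis(-0.10, -0.20, t_label = 4, compute_rate = TRUE)
  expect_equal(fs$f, 0.5)
  expect_equal(fs$k_turnover, log(2) / 4)
  expect_identical(fs$qc_flag, "ok")
  # QC flags: retained, never clipped
  expect_identical(fractional_synthesis(-0.21, -0.20)$qc_flag,
                   "minor_excursion")
  expect_identical(fractional_synthesis(0.5, -0.20)$qc_flag,
                   "out_of_bounds")
  expect_equal(fractional_synthesis(0.5, -0.20)$f, -2.5)
  expect_error(fractional_synthesis(-0.1, 0), "non-zero")
  expect_true(is.na(
    fractional_synthesis(-0.2, -0.2, 4, compute_rate = TRUE)$k_turnover))
})

test_that("noise-free mixtures are recovered exactly", {
  ctx <- labeling_context(p_body = 0.05, t_label = 4)
  env <- peptide_envelopes("GLSDGEWQLVLNVWGK", ctx)
  for (f_true in seq(0, 1, by = 0.1)) {
    mixed <- (1 - f_true) * env$baseline + f_true * env$asymptote
    em <- em0_excess_and_max(mixed, env$baseline, env$asymptote)
    expect_equal(fractional_synthesis(em$em0, em$em0_max)$f, f_true,
                 tolerance = 1e-12)
  }
})

test_that("labeling context validates its precursor model", {
  ctx <- labeling_context(0.05, t_label = 4)
  expect_s3_class(ctx, "labeling_context")
  expect_error(labeling_context(p_body = 0.00005), "p_natural < p_body")
  expect_error(labeling_context(p_body = 1.2), "p_body")
  expect_error(labeling_context(0.05, t_label = 0), "t_label")
})
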