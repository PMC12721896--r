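# Protein-level roll-up: inclusion filter, aggregation, group summaries,
# intensity quotients and WPASR normalization.

make_protein_records <- function(n_spectra) {
  data.frame(protein_id = sprintf("P%02d", seq_along(n_spectra)),
             sample_id = "s1", fsr = 0.3, n_peptides = 1,
             n_spectra = n_spectra, stringsAsFactors = FALSE)
}

test_that("the minimum-spectra filter removes sparse proteins at the
           stated boundary and is idempotent", {
  rec <- make_protein_records(c(1, 2, 3, 5))
  out <- suppressMessages(filter_min_spectra(rec))
  expect_equal(out$protein_id, c("P02", "P03", "P04"))  # 1 removed, 2 kept
  expect_equal(suppressMessages(filter_min_spectra(out)), out)
  expect_equal(nrow(filter_min_spectra(rec[0, ])), 0L)
  expect_message(filter_min_spectra(rec), "1 protein measurement")
})

test_that("study-scope filtering pools spectra across samples", {
  rec <- rbind(make_protein_records(1), make_protein_records(1))
  rec$sample_id <- rep(c("s1", "s2"), each = nrow(rec) / 2)
  expect_equal(nrow(suppressMessages(filter_min_spectra(rec))), 0L)
  expect_equal(nrow(filter_min_spectra(rec, scope = "study", quiet = TRUE)),
               nrow(rec))
})

test_that("protein FSR aggregation honors the chosen method", {
  pk <- data.frame(protein_id = "P1", sample_id = "s1",
                   f = c(0.2, 0.4), spectral_count = c(1, 1),
                   qc_flag = "ok", stringsAsFactors = FALSE)
  expect_equal(protein_fsr(pk)$fsr, 0.3)
  pk$spectral_count <- c(3, 1)
  expect_equal(protein_fsr(pk)$fsr, 0.25)            # weighted mean
  expect_equal(protein_fsr(pk, "mean")$fsr, 0.3)
  expect_equal(protein_fsr(pk, "median")$fsr, 0.3)
  expect_equal(protein_fsr(pk[1, ])$fsr, 0.2)        # single peptide
  # weighted reduces to unweighted when counts are equal
  pk$spectral_count <- c(2, 2)
  expect_equal(protein_fsr(pk)$fsr, protein_fsr(pk, "mean")$fsr)
})

test_that("flagged peptides are excluded and fully flagged proteins
           propagate their flag", {
  pk <- data.frame(protein_id = "P1", sample_id = "s1",
                   f = c(0.2, 5), spectral_count = c(1, 9),
                   qc_flag = c("ok", "out_of_bounds"),
                   stringsAsFactors = FALSE)
  out <- protein_fsr(pk)
  expect_equal(out$fsr, 0.2)
  expect_equal(out$n_spectra, 10)  # spectra counted before exclusion
  pk$qc_flag <- "out_of_bounds"
  out <- protein_fsr(pk)
  expect_true(is.na(out$fsr))
  expect_identical(out$qc_flag, "all_flagged")
})

test_that("group summaries give sample SD and percent CV per arm", {
  rec <- data.frame(protein_id = "P1",
                    sample_id = c("a1", "a2", "a3"),
                    fsr = c(0.045, 0.05, 0.055), stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("a1", "a2", "a3"), arm = "Con",
                     stringsAsFactors = FALSE)
  gs <- group_summary(rec, meta)
  expect_equal(gs$mean_fsr, 0.05)
  expect_equal(gs$cv, 100 * sd(c(0.045, 0.05, 0.055)) / 0.05)
  expect_equal(gs$n_animals, 3)
  # identical values -> zero CV
  rec$fsr <- 0.05
  expect_equal(group_summary(rec, meta)$cv, 0)
  # single animal -> CV undefined (flagged NA)
  gs1 <- group_summary(rec[1, ], meta[1, ])
  expect_true(is.na(gs1$cv))
  expect_equal(gs1$n_animals, 1)
})

test_that("intensity quotients partition the sample signal", {
  expect_equal(intensity_quotient(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(intensity_quotient(7), 1)
  q <- intensity_quotient(c(0, 2, 3))   # zero masked, not imputed
  expect_true(is.na(q[1]))
  expect_equal(sum(q, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(intensity_quotient(c(0, 0)), "all intensities")
})

test_that("WPASR is the FSR-quotient product", {
  prot <- data.frame(protein_id = c("P1", "P2"), sample_id = "s1",
                     fsr = c(0.5, 0.1), stringsAsFactors = FALSE)
  intens <- data.frame(protein_id = c("P1", "P2"), sample_id = "s1",
                       intensity = c(2, 8), stringsAsFactors = FALSE)
  w <- wpasr(prot, intens)
  expect_equal(sum(w$q), 1, tolerance = 1e-12)
  expect_equal(w$wpasr[w$protein_id == "P1"], 0.5 * 0.2)
})

test_that("WPASR normalization is median-adjust, log10, row-center", {
  m <- matrix(1, 3, 4)
  expect_true(all(normalize_wpasr_matrix(m) == 0))
  # columns already have median 1, so the log/center steps act alone
  m2 <- rbind(c(0.1, 10), c(1, 1), c(10, 0.1))
  out <- normalize_wpasr_matrix(m2)
  expect_equal(rowMeans(out, na.rm = TRUE), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(out[1, ], c(-1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(normalize_wpasr_matrix(matrix(0, 2, 2)), "no positive")
})
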