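intro_cfg <- function(seed, n_sl = 40) {
  ScenarioConfig(n_chrom = 4, sex_chrom = "chr2", chrom_length = 2000,
                 n_snp_autosomal = 60, n_snp_sexlinked = n_sl,
                 n_pa_autosomal = 10, n_pa_sexlinked = 0,
                 error_rate = 0, missing_rate = 0, recomb_fraction = 0,
                 seed = seed)
}

test_that("introgression copies the donor Y haplotype into the recipient", {
  trio <- simulateIntrogression(intro_cfg(1), intro_cfg(2), intro_cfg(3),
                                seed = 5)
  expect_equal(sharedYAlleleFraction(trio$donor, trio$recipient), 1)
  expect_equal(sharedYAlleleFraction(trio$donor, trio$donor), 1)

  # the control draws labels independently: sharing ~ Binomial(n, 0.5)
  ctrl <- sharedYAlleleFraction(trio$donor, trio$control)
  lo <- qbinom(0.005, 40, 0.5) / 40
  hi <- qbinom(0.995, 40, 0.5) / 40
  expect_gte(ctrl, lo)
  expect_lte(ctrl, hi)

  # donor and recipient autosomal frequencies are independent draws
  q <- function(ds) {
    calls <- genotypeCalls(snpGenotypes(ds))
    auto <- grepl("^snpA", rownames(calls))
    rowMeans(calls[auto, , drop = FALSE], na.rm = TRUE) / 2
  }
  expect_gt(mean(abs(q(trio$donor) - q(trio$recipient))), 0.02)
})

test_that("inferred allele sharing agrees with truth on noise-free data", {
  trio <- simulateIntrogression(intro_cfg(11), intro_cfg(12), intro_cfg(13),
                                seed = 17)
  expect_equal(
    suppressMessages(sharedYAlleleFraction(trio$donor, trio$recipient,
                                           use = "inferred")), 1)
  expect_equal(
    suppressMessages(sharedYAlleleFraction(trio$donor, trio$control,
                                           use = "inferred")),
    sharedYAlleleFraction(trio$donor, trio$control, use = "truth"))
})

test_that("introgression preconditions are enforced", {
  expect_error(
    simulateIntrogression(intro_cfg(1), intro_cfg(2, n_sl = 10), intro_cfg(3)),
    "n_snp_sexlinked")
  none <- ScenarioConfig(n_chrom = 4, sex_chrom = "chr2", chrom_length = 2000,
                         n_snp_autosomal = 20, n_snp_sexlinked = 0,
                         n_pa_autosomal = 0, n_pa_sexlinked = 0, seed = 9)
  a <- simulatePopulation(none, generateReference(none))
  expect_error(sharedYAlleleFraction(a, a), "in common")
})
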