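small_cfg <- function(...) {
  ScenarioConfig(n_chrom = 4, sex_chrom = "chr2", chrom_length = 2000,
                 n_snp_autosomal = 60, n_snp_sexlinked = 20,
                 n_pa_autosomal = 20, n_pa_sexlinked = 6, ...)
}

test_that("generation is deterministic under (config, seed)", {
  cfg <- small_cfg(seed = 21)
  r1 <- generateReference(cfg)
  r2 <- generateReference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(length(r1), 4L)
  expect_true(all(Biostrings::width(r1) == 2000))
  r3 <- generateReference(cfg, seed = 22)
  expect_true(as.character(r1[[1]]) != as.character(r3[[1]]))

  d1 <- simulatePopulation(cfg, r1)
  d2 <- simulatePopulation(cfg, r2)
  expect_identical(genotypeCalls(snpGenotypes(d1)), genotypeCalls(snpGenotypes(d2)))
  expect_identical(genotypeCalls(paGenotypes(d1)), genotypeCalls(paGenotypes(d2)))
  expect_identical(as.data.frame(truthTable(d1)), as.data.frame(truthTable(d2)))
  expect_identical(tagSequences(snpGenotypes(d1)), tagSequences(snpGenotypes(d2)))

  # serialization round-trips byte-identically for identical inputs
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  writeSimulatedDataset(d1, dir1)
  writeSimulatedDataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("truth-table class counts match the configuration exactly", {
  cfg <- small_cfg(seed = 31, recomb_fraction = 0.25)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  tt <- truthTable(ds)
  expect_identical(sum(tt$marker_class == "SNP"), 80L)
  expect_identical(sum(tt$marker_class == "PA"), 26L)
  # recombining: round(0.25 * 20) = 5 SNPs, round(0.25 * 6) = 2 PA
  expect_identical(sum(tt$truth_class == "sexlinked_recombining" &
                         tt$marker_class == "SNP"), 5L)
  expect_identical(sum(tt$truth_class == "sexlinked_recombining" &
                         tt$marker_class == "PA"), 2L)
  expect_identical(sum(tt$truth_class == "autosomal"), 80L)
  expect_true(all(tt$chromosome[tt$truth_class != "autosomal"] == "chr2"))
  expect_true(all(tt$chromosome[tt$truth_class == "autosomal"] != "chr2"))
})

test_that("tags are copied verbatim from the recorded reference positions", {
  cfg <- small_cfg(seed = 41)
  ref <- generateReference(cfg)
  ds <- simulatePopulation(cfg, ref)
  tt <- truthTable(ds)
  tags <- c(tagSequences(snpGenotypes(ds)), tagSequences(paGenotypes(ds)))
  pick <- sample(nrow(tt), 12)
  for (i in pick) {
    expect_identical(
      unname(tags[tt$locus_id[i]]),
      substring(as.character(ref[[tt$chromosome[i]]]), tt$tag_start[i],
                tt$tag_start[i] + cfg@tag_length - 1L))
  }
})

test_that("missingness is injected at the configured binomial rate", {
  cfg <- ScenarioConfig(n_snp_autosomal = 1500, n_snp_sexlinked = 0,
                        n_pa_autosomal = 0, n_pa_sexlinked = 0,
                        error_rate = 0, missing_rate = 0.2, seed = 51)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  calls <- genotypeCalls(snpGenotypes(ds))
  n <- length(calls)
  frac <- mean(is.na(calls))
  tol <- 3 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), tol)
})

test_that("noise-free sex-linked loci carry the fixed-difference signature", {
  cfg <- small_cfg(seed = 61, error_rate = 0, missing_rate = 0,
                   recomb_fraction = 0, sex_reversal = 0)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  calls <- genotypeCalls(snpGenotypes(ds))
  tt <- truthTable(ds)
  males <- sexes(snpGenotypes(ds)) == "male"
  sl <- tt$locus_id[tt$marker_class == "SNP" & tt$truth_class != "autosomal"]
  labels <- tt$y_allele_label[match(sl, tt$locus_id)]
  for (k in seq_along(sl)) {
    row <- calls[sl[k], ]
    expect_true(all(row[males] == 1L))
    expect_true(all(row[!males] == (if (labels[k] == "b1") 0L else 2L)))
  }
  # PA: present exactly in the heterogametic sex
  pa_calls <- genotypeCalls(paGenotypes(ds))
  pa_sl <- tt$locus_id[tt$marker_class == "PA" & tt$truth_class != "autosomal"]
  expect_true(all(pa_calls[pa_sl, males] == 1L))
  expect_true(all(pa_calls[pa_sl, !males] == 0L))
})

test_that("a ZW scenario mirrors the XY construction", {
  cfg <- small_cfg(seed = 71, system = "ZW", error_rate = 0, missing_rate = 0,
                   recomb_fraction = 0)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  set <- suppressMessages(classifySexLinked(snpGenotypes(ds), paGenotypes(ds)))
  tb <- markerTable(set)
  tt <- truthTable(ds)
  sl <- tt$locus_id[tt$truth_class == "sexlinked_nonrecombining"]
  got <- tb$category[match(sl, tb$locus_id)]
  expect_true(all(got %in% c("female_het_snp", "female_present_pa")))
  expect_identical(sum(!is.na(got)), length(sl))
})

test_that("pervasive sex reversal destroys the sex-linkage signal", {
  cfg <- ScenarioConfig(n_males = 25, n_females = 25, n_snp_autosomal = 0,
                        n_snp_sexlinked = 40, n_pa_autosomal = 0,
                        n_pa_sexlinked = 0, error_rate = 0, missing_rate = 0,
                        recomb_fraction = 0, sex_reversal = 0.5, seed = 81)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  # phenotypic labels actually flipped for a sizeable minority
  cd <- SummarizedExperiment::colData(snpGenotypes(ds))
  expect_gt(sum(cd$sex != cd$genotypic_sex), 5)
  set <- suppressMessages(classifySexLinked(snpGenotypes(ds)))
  expect_lt(length(set), 0.1 * 40)
})
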