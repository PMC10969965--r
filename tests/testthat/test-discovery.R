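# sexes used throughout: 3M/3F unless stated otherwise
SEX6 <- c(rep("male", 3), rep("female", 3))

test_that("locusCallStats counts by sex and computes the call ratio", {
  sex <- c(rep("male", 10), rep("female", 10))
  snp <- makeSnp(list(
    L1 = lv(rep(1L, 10), rep(0L, 10)),
    L2 = lv(c(rep(1L, 8), NA, NA), c(rep(0L, 8), NA, NA)),
    L3 = lv(rep(NA_integer_, 10), rep(NA_integer_, 10))
  ), sex)
  s1 <- locusCallStats(snp, "L1")
  expect_equal(s1$call_ratio, 1)
  expect_equal(unname(s1$males["het"]), 10)
  expect_equal(unname(s1$females["hom_ref"]), 10)
  expect_equal(locusCallStats(snp, "L2")$call_ratio, 0.8)  # 16/20 called
  s3 <- locusCallStats(snp, "L3")
  expect_equal(s3$call_ratio, 0)
  expect_equal(sum(s3$males) + sum(s3$females), 0)
  expect_error(locusCallStats(snp, "nope"), "unknown locus")
})

test_that("unknown-sex individuals are excluded from all statistics", {
  snp <- makeSnp(list(L1 = c(1L, 1L, 1L, 0L, 0L, 0L, 2L, NA)),
                 c(SEX6, "unknown", "unknown"))
  s <- locusCallStats(snp, "L1")
  expect_equal(s$n_male + s$n_female, 6)
  expect_equal(s$call_ratio, 1)  # the unknowns' calls don't enter
  r <- snpConcordance(s, "male")
  expect_equal(r$concordance, 1)
})

test_that("call-ratio filtering keeps the boundary and preserves order", {
  sex <- c(rep("male", 10), rep("female", 10))
  snp <- makeSnp(list(
    A = lv(rep(0L, 10), rep(0L, 10)),                              # 1.0
    B = lv(c(rep(0L, 8), NA, NA), c(rep(0L, 8), NA, NA)),          # 0.8
    C = lv(c(rep(0L, 7), NA, NA, NA), c(rep(0L, 8), NA, NA))       # 0.75
  ), sex)
  expect_message(kept <- filterCallRatio(snp, 0.8), "removed 1 of 3")
  expect_identical(lociIds(kept), c("A", "B"))
  # min_call_ratio = 1 on complete data is the identity
  complete <- makeSnp(list(A = lv(rep(0L, 10), rep(1L, 10))), sex)
  expect_identical(lociIds(suppressMessages(filterCallRatio(complete, 1))), "A")
})

test_that("snpConcordance matches hand enumeration under both systems", {
  snp <- makeSnp(list(L1 = lv(c(1L, 1L, 0L), c(0L, 0L, 1L))), SEX6)
  s <- locusCallStats(snp, "L1")
  xy <- snpConcordance(s, "male")
  expect_equal(xy$concordance, 4 / 6)   # 2 het males + 2 hom females
  expect_identical(xy$system, "XY")
  zw <- snpConcordance(s, "female")
  expect_equal(zw$concordance, 2 / 6)   # 1 het female + 1 hom male
  expect_identical(zw$system, "ZW")

  # perfect XY locus: 9 males het, 10 females hom_ref
  sex19 <- c(rep("male", 9), rep("female", 10))
  perf <- makeSnp(list(L1 = lv(rep(1L, 9), rep(0L, 10))), sex19)
  p <- snpConcordance(locusCallStats(perf, "L1"), "male")
  expect_equal(p$concordance, 1)
  expect_identical(p$sex_limited_allele, "alt")

  # mirrored perfect locus: females hom_alt -> sex-limited allele is ref
  mirr <- makeSnp(list(L1 = lv(rep(1L, 9), rep(2L, 10))), sex19)
  expect_identical(snpConcordance(locusCallStats(mirr, "L1"),
                                  "male")$sex_limited_allele, "ref")
})

test_that("paConcordance counts present-in-limited-sex plus absent-in-other", {
  sex16 <- c(rep("male", 8), rep("female", 8))
  pa <- makePa(list(
    perfect = lv(rep(1L, 8), rep(0L, 8)),
    noisy = lv(c(rep(1L, 6), 0L, 0L), c(rep(0L, 7), 1L)),
    everywhere = lv(rep(1L, 8), rep(1L, 8))
  ), sex16)
  expect_equal(paConcordance(locusCallStats(pa, "perfect"), "male")$concordance, 1)
  expect_equal(paConcordance(locusCallStats(pa, "noisy"), "male")$concordance,
               13 / 16)
  expect_equal(paConcordance(locusCallStats(pa, "everywhere"), "male")$concordance,
               0.5)
})

test_that("concordance equals brute-force enumeration on random matrices", {
  set.seed(42)
  for (rep_i in 1:25) {
    n_ind <- sample(4:8, 1)
    snp <- randomSnpMatrix(sample(2:6, 1), n_ind)
    sex <- unname(sexes(snp))
    for (locus in lociIds(snp)) {
      s <- locusCallStats(snp, locus)
      if (s$n_called_male < 1 || s$n_called_female < 1) next
      for (hs in c("male", "female")) {
        expect_equal(snpConcordance(s, hs)$concordance,
                     bruteConcordance(genotypeCalls(snp)[locus, ], sex, hs, "SNP"),
                     info = sprintf("rep %d locus %s %s", rep_i, locus, hs))
      }
    }
    pa <- randomPaMatrix(sample(2:6, 1), n_ind)
    sexp <- unname(sexes(pa))
    for (locus in lociIds(pa)) {
      s <- locusCallStats(pa, locus)
      if (s$n_called_male < 1 || s$n_called_female < 1) next
      for (hs in c("male", "female")) {
        expect_equal(paConcordance(s, hs)$concordance,
                     bruteConcordance(genotypeCalls(pa)[locus, ], sexp, hs, "PA"))
      }
    }
  }
})

test_that("concordance is symmetric under swapping sexes and systems", {
  set.seed(7)
  for (i in 1:10) {
    snp <- randomSnpMatrix(3, 6)
    swapped <- SnpGenotypes(genotypeCalls(snp),
                            ifelse(sexes(snp) == "male", "female", "male"))
    for (locus in lociIds(snp)) {
      s <- locusCallStats(snp, locus)
      s2 <- locusCallStats(swapped, locus)
      if (s$n_called_male < 1 || s$n_called_female < 1) next
      expect_equal(snpConcordance(s, "male")$concordance,
                   snpConcordance(s2, "female")$concordance)
    }
  }
})

test_that("classifySexLinked applies threshold, boundary, tie and eligibility rules", {
  sex20 <- c(rep("male", 10), rep("female", 10))
  snp <- makeSnp(list(
    perfect = lv(rep(1L, 10), rep(0L, 10)),
    boundary = lv(c(rep(1L, 8), 0L, 0L), c(rep(0L, 8), 1L, 1L)),  # 16/20 = 0.8
    allhet = lv(rep(1L, 10), rep(1L, 10)),                        # 0.5 both
    zw = lv(rep(0L, 10), rep(1L, 10))
  ), sex20)
  set <- classifySexLinked(snp, concordance_threshold = 0.8)
  tb <- markerTable(set)
  expect_setequal(tb$locus_id, c("perfect", "boundary", "zw"))
  expect_identical(tb$category[tb$locus_id == "perfect"], "male_het_snp")
  expect_identical(tb$category[tb$locus_id == "zw"], "female_het_snp")
  expect_equal(tb$concordance[tb$locus_id == "boundary"], 0.8)

  # an exact XY/ZW tie above threshold is dropped as ambiguous
  sex4 <- c("male", "male", "female", "female")
  tied <- makeSnp(list(T1 = c(1L, 0L, 1L, 0L)), sex4)
  expect_message(
    set_tie <- classifySexLinked(tied, concordance_threshold = 0.5,
                                 min_called_per_sex = 2),
    "tied")
  expect_length(set_tie, 0)

  # too few called individuals in one sex -> not eligible
  sparse <- makeSnp(list(S1 = lv(c(1L, 1L, rep(NA_integer_, 8)), rep(0L, 10))),
                    sex20)
  expect_length(classifySexLinked(sparse, min_called_per_sex = 3), 0)

  expect_error(classifySexLinked(snp, pa = makePa(list(perfect = rep(1L, 20)),
                                                  sex20)),
               "share no locus ids")
})

test_that("false-positive test flags homozygotes for the sex-limited allele", {
  sex20 <- c(rep("male", 10), rep("female", 10))
  snp <- makeSnp(list(
    clean = lv(rep(1L, 10), rep(0L, 10)),
    dirty = lv(c(rep(1L, 8), 2L, 2L), rep(0L, 10)),  # 2/20 hom for b = alt
    split = lv(rep(1L, 10), c(rep(0L, 5), rep(2L, 5)))
  ), sex20)
  set <- falsePositiveTest(classifySexLinked(snp), snp, fp_threshold = 0.05)
  tb <- markerTable(set)
  expect_equal(tb$fp_statistic[tb$locus_id == "clean"], 0)
  expect_false(tb$fp_flag[tb$locus_id == "clean"])
  expect_equal(tb$fp_statistic[tb$locus_id == "dirty"], 0.1)
  expect_true(tb$fp_flag[tb$locus_id == "dirty"])
  # 50/50 homozygote split leaves the sex-limited allele undefined -> flagged
  expect_true(is.na(tb$sex_limited_allele[tb$locus_id == "split"]))
  expect_true(tb$fp_flag[tb$locus_id == "split"])
})

test_that("PA candidates are exempt from the false-positive test", {
  sex16 <- c(rep("male", 8), rep("female", 8))
  pa <- makePa(list(Y = lv(rep(1L, 8), rep(0L, 8))), sex16)
  snp <- makeSnp(list(X = lv(rep(1L, 8), rep(0L, 8))), sex16)
  set <- falsePositiveTest(classifySexLinked(snp, pa), snp)
  tb <- markerTable(set)
  expect_true(is.na(tb$fp_statistic[tb$marker_class == "PA"]))
  expect_false(any(tb$fp_flag[tb$marker_class == "PA"]))
})

test_that("summarizeDiscovery obeys the bookkeeping identity", {
  expect_identical(trueTotal(summarizeDiscovery(
    sexLinkedSetFromCounts(c(0, 0, 0, 0)))), 0L)
  set.seed(1)
  for (i in 1:10) {
    n_initial <- sample(0:40, 4, replace = TRUE)
    n_fp <- c(vapply(n_initial[1:2], function(n) sample(0:n, 1), integer(1)),
              0L, 0L)
    summ <- summarizeDiscovery(sexLinkedSetFromCounts(n_initial, n_fp))
    ct <- discoveryCounts(summ)
    expect_identical(ct$n_true, ct$n_initial - ct$n_false_positive)
    expect_identical(trueTotal(summ), as.integer(sum(ct$n_true)))
    expect_true(all(ct$n_true >= 0))
  }
  expect_error(summarizeDiscovery(classifySexLinked(
    makeSnp(list(L1 = lv(rep(1L, 3), rep(0L, 3))), SEX6))),
    "falsePositiveTest")
})

test_that("raising thresholds never grows the candidate or flagged sets", {
  cfg <- ScenarioConfig(n_snp_autosomal = 300, n_snp_sexlinked = 30,
                        n_pa_autosomal = 50, n_pa_sexlinked = 5,
                        error_rate = 0.05, missing_rate = 0.1, seed = 99)
  ds <- simulatePopulation(cfg, generateReference(cfg))
  suppressMessages({
    sizes <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(thr)
      length(classifySexLinked(snpGenotypes(ds), paGenotypes(ds),
                               concordance_threshold = thr)),
      integer(1))
    base <- classifySexLinked(snpGenotypes(ds), paGenotypes(ds),
                              concordance_threshold = 0.6)
    flagged <- vapply(c(0, 0.05, 0.2, 0.5, 1), function(thr)
      sum(markerTable(falsePositiveTest(base, snpGenotypes(ds), thr))$fp_flag),
      integer(1))
  })
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(diff(flagged) <= 0))
})
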