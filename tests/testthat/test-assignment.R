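test_that("the mapper finds exact, reverse-complement and rejects sub-identity hits", {
  set.seed(5)
  ref <- generateReference(ScenarioConfig(n_chrom = 3, chrom_length = 2000,
                                          sex_chrom = "chr2", seed = 5))
  tag <- substring(as.character(ref[["chr3"]]), 1000, 1068)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))

  hits <- mapTags(c(fwd = tag, rev = rc), ref)
  fwd <- hits[hits$query_id == "fwd", ]
  expect_identical(fwd$chrom, "chr3")
  expect_identical(fwd$start, 1000L)
  expect_identical(fwd$end, 1068L)
  expect_identical(fwd$strand, "+")
  expect_equal(fwd$identity, 1)
  rev <- hits[hits$query_id == "rev", ]
  expect_identical(rev$strand, "-")
  expect_identical(rev$start, 1000L)

  # 8 mismatches over 69 bp: identity 61/69 = 0.884 < 0.90 -> no hit
  worn <- mutateSeq(tag, 8)
  expect_identical(nrow(mapTags(c(worn = worn), ref)), 0L)

  # tag shorter than seed_k is reported unaligned, with a log line
  expect_message(short <- mapTags(c(tiny = "ACGTACGT"), ref), "tiny")
  expect_identical(nrow(short), 0L)
})

test_that("a tag present on two chromosomes yields hits on both", {
  chr1 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  insert <- substring(chr1, 100, 168)
  chr2 <- paste0(paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                       collapse = ""), insert,
                 paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                       collapse = ""))
  ref <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  hits <- mapTags(c(dup = insert), ref)
  expect_setequal(unique(hits$chrom), c("chr1", "chr2"))
  parts <- uniqueChromosomeAssignments(hits, "dup")
  expect_identical(parts$multi_chrom, "dup")
  expect_length(parts$assigned, 0)
})

test_that("assignment partitions loci into assigned, multi and unaligned", {
  hits <- S4Vectors::DataFrame(
    query_id = c("A", "A", "B", "B", "C"),
    chrom = c("chr9", "chr9", "chr9", "chr2", "chr1"),
    start = c(10L, 400L, 7L, 9L, 1L), end = c(78L, 468L, 75L, 77L, 69L),
    strand = "+", identity = 1, aln_length = 69L
  )
  parts <- uniqueChromosomeAssignments(hits, c("A", "B", "C", "D"))
  expect_identical(parts$assigned, c(A = "chr9", C = "chr1"))
  expect_identical(parts$multi_chrom, "B")
  expect_identical(parts$unaligned, "D")

  # partition property over random hit lists
  set.seed(11)
  for (i in 1:20) {
    loci <- sprintf("L%02d", 1:12)
    n <- sample(0:30, 1)
    h <- S4Vectors::DataFrame(
      query_id = sample(loci, n, replace = TRUE),
      chrom = sample(paste0("chr", 1:4), n, replace = TRUE),
      start = rep(1L, n), end = rep(69L, n), strand = "+",
      identity = 1, aln_length = 69L)
    p <- uniqueChromosomeAssignments(h, loci)
    expect_identical(length(p$assigned) + length(p$multi_chrom) +
                       length(p$unaligned), length(loci))
  }
})

test_that("assignmentSummary computes modal chromosome with deterministic ties", {
  s <- assignmentSummary(c(chr9 = 78, chr2 = 10, chr12 = 8),
                         n_multi_chrom = 3, n_unaligned = 2)
  expect_identical(modalChrom(s), "chr9")
  expect_equal(modalFraction(s), 78 / 96)
  expect_equal(modalPercent(s), 81.3)
  expect_identical(s@n_multi_chrom, 3L)

  expect_message(tied <- assignmentSummary(c(chrB = 2, chrA = 2)), "tied")
  expect_identical(modalChrom(tied), "chrA")
  expect_true(tied@modal_tie)

  expect_message(none <- assignmentSummary(list(assigned = character(0),
                                                multi_chrom = character(0),
                                                unaligned = c("L1", "L2"))),
                 "no uniquely assigned")
  expect_true(is.na(modalChrom(none)))
  expect_error(callSexChromosome(none), "cannot call")
})

test_that("callSexChromosome translates through the map and gates confidence", {
  s <- assignmentSummary(c("9" = 57, "3" = 7))
  call <- callSexChromosome(s)
  expect_identical(call@reference_chrom, "9")
  expect_identical(call@species_chrom, "7")
  expect_true(call@confident)
  expect_equal(modalFraction(call), 57 / 64)

  low <- callSexChromosome(assignmentSummary(c("4" = 2, "1" = 1, "2" = 1,
                                               "3" = 1)))
  expect_identical(low@species_chrom, "3")
  expect_false(low@confident)  # fraction 0.4 < 0.5 and 2 markers < 3

  expect_message(ident <- callSexChromosome(assignmentSummary(c(chr7 = 5))),
                 "identity mapping")
  expect_identical(ident@species_chrom, "chr7")
})
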