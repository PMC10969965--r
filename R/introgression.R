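# Y-haplotype introgression scenario and the allele-sharing surrogate.
#
# A Y (or W) haplotype introduced from a donor into a recipient population
# carries the donor's sex-limited alleles; an unrelated control population
# draws its own. The fraction of sex-linked loci whose sex-limited allele is
# identical between two populations is therefore ~1 for donor vs recipient
# and ~0.5 (binomial over the two-label alphabet) for donor vs control --
# a desk-scale surrogate for shared Y clusters in a population-structure map.

#' Simulate a Y-haplotype introgression triple
#'
#' Generates three populations: a donor, a recipient whose sex-limited allele
#' labels are copied locus-by-locus from the donor (the introgressed Y
#' haplotype), and an independent control. Autosomal allele frequencies are
#' drawn independently in every population. The three configurations must
#' agree on `n_snp_sexlinked`, `system` and `sex_chrom`.
#'
#' @param donor_config,recipient_config,control_config [ScenarioConfig-class]
#'   objects.
#' @param seed RNG seed from which per-population sub-seeds are drawn.
#' @return named list of three [SimulatedDataset-class] objects
#'   (`donor`, `recipient`, `control`).
#' @export
simulateIntrogression <- function(donor_config, recipient_config,
                                  control_config, seed = donor_config@seed) {
  cfgs <- list(donor = donor_config, recipient = recipient_config,
               control = control_config)
  for (s in c("n_snp_sexlinked", "system", "sex_chrom")) {
    vals <- vapply(cfgs, function(cf) as.character(slot(cf, s)), character(1))
    if (length(unique(vals)) != 1L)
      stop(sprintf("configs must share '%s' (got %s)", s,
                   paste(vals, collapse = ", ")))
  }
  sub <- .withSeed(seed, sample.int(2147483646L, 6L))
  donor <- simulatePopulation(donor_config,
                              generateReference(donor_config, sub[1]), sub[2])
  donor_labels <- truthTable(donor)$y_allele_label[
    truthTable(donor)$marker_class == "SNP" &
      truthTable(donor)$truth_class != "autosomal"]
  recipient <- simulatePopulation(recipient_config,
                                  generateReference(recipient_config, sub[3]),
                                  sub[4], y_allele_labels = donor_labels)
  control <- simulatePopulation(control_config,
                                generateReference(control_config, sub[5]),
                                sub[6])
  list(donor = donor, recipient = recipient, control = control)
}

.truthYLabels <- function(dataset) {
  tt <- truthTable(dataset)
  sel <- tt$marker_class == "SNP" & tt$truth_class != "autosomal"
  stats::setNames(tt$y_allele_label[sel], tt$locus_id[sel])
}

# Inferred sex-limited allele (ref/alt) per discovered SNP candidate.
.inferredYAlleles <- function(dataset) {
  set <- classifySexLinked(snpGenotypes(dataset), paGenotypes(dataset))
  set <- falsePositiveTest(set, snpGenotypes(dataset))
  tb <- markerTable(set)
  sel <- tb$marker_class == "SNP" & !is.na(tb$sex_limited_allele)
  stats::setNames(tb$sex_limited_allele[sel], tb$locus_id[sel])
}

#' Fraction of shared sex-limited alleles between two populations
#'
#' Compares the sex-limited allele of sex-linked SNP loci matched by locus
#' index between two simulated datasets and returns the fraction that is
#' identical. With `use = "truth"` the comparison is over the generator's
#' `b1`/`b2` labels of all sex-linked SNP loci; with `use = "inferred"` the
#' alleles are re-discovered from the genotype matrices
#' ([classifySexLinked()] + [falsePositiveTest()]) and compared over loci
#' discovered in both datasets (`b1` corresponds to an alternate-allele call,
#' `b2` to a reference-allele call).
#'
#' @param a,b [SimulatedDataset-class] objects with the same sex-linked SNP
#'   locus layout.
#' @param use `"truth"` or `"inferred"`.
#' @return fraction in `[0, 1]`.
#' @export
sharedYAlleleFraction <- function(a, b, use = c("truth", "inferred")) {
  use <- match.arg(use)
  la <- if (use == "truth") .truthYLabels(a) else .inferredYAlleles(a)
  lb <- if (use == "truth") .truthYLabels(b) else .inferredYAlleles(b)
  common <- intersect(names(la), names(lb))
  if (!length(common))
    stop("no sex-linked SNP loci in common between the two datasets")
  mean(la[common] == lb[common])
}
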