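# Synthetic DArTseq-style data generator.
#
# The generator emulates called markers (not reads) for a sib-ship-scale
# sample under a chosen heterogamety system: autosomal SNPs segregate at
# Hardy-Weinberg proportions with a per-locus allele frequency drawn from
# maf_range; non-recombining sex-linked SNPs are fixed differences
# (homogametic sex a/a, heterogametic sex a/b, with the sex-limited allele b
# labelled b1 = alternate or b2 = reference per locus); presence/absence
# markers are fragment dominant (sex-linked: present exactly in the
# heterogametic genotypic sex; autosomal: per-locus presence probability).
# A fraction of sex-linked loci "recombine": they sit on the sex chromosome
# but segregate autosomally. Noise is layered on afterwards: per-call
# genotyping error, per-call missingness, and phenotypic sex reversal.
# Every locus receives a tag copied verbatim from its true chromosome, so the
# mapper can recover locations exactly.

#' Simulation scenario configuration
#'
#' Builds a validated [ScenarioConfig-class]. Defaults describe the package's
#' reference scenario: sib-ship-scale sampling (10 males, 10 females), an XY
#' system on chromosome 7 of a 13-chromosome genome (2n = 26), 2000 autosomal
#' and 50 sex-linked SNPs, 200 autosomal and 10 sex-linked presence/absence
#' markers, 2% genotyping error, 10% missingness, 10% of sex-linked loci
#' recombining, no sex reversal, and 69 bp tags.
#'
#' @param n_males,n_females sample sizes by phenotypic target sex.
#' @param system `"XY"` (male heterogametic) or `"ZW"` (female heterogametic).
#' @param sex_chrom sex chromosome id, one of `chr1..chr<n_chrom>`.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_snp_autosomal,n_snp_sexlinked,n_pa_autosomal,n_pa_sexlinked locus
#'   counts by marker class and linkage.
#' @param maf_range interval within (0, 0.5] for autosomal allele frequencies.
#' @param error_rate per-call probability of replacement by a uniformly chosen
#'   different non-missing state.
#' @param missing_rate per-call probability of a missing call.
#' @param recomb_fraction fraction of sex-linked loci behaving autosomally.
#' @param sex_reversal per-individual probability that phenotypic sex differs
#'   from genotypic sex.
#' @param tag_length tag length in bp.
#' @param seed default seed for the generator operations.
#' @return a [ScenarioConfig-class].
#' @export
ScenarioConfig <- function(n_males = 10, n_females = 10, system = "XY",
                           sex_chrom = "chr7", n_chrom = 13,
                           chrom_length = 10000,
                           n_snp_autosomal = 2000, n_snp_sexlinked = 50,
                           n_pa_autosomal = 200, n_pa_sexlinked = 10,
                           maf_range = c(0.05, 0.5), error_rate = 0.02,
                           missing_rate = 0.10, recomb_fraction = 0.10,
                           sex_reversal = 0, tag_length = 69, seed = 1) {
  new("ScenarioConfig",
      n_males = as.integer(n_males), n_females = as.integer(n_females),
      system = system, sex_chrom = sex_chrom, n_chrom = as.integer(n_chrom),
      chrom_length = as.integer(chrom_length),
      n_snp_autosomal = as.integer(n_snp_autosomal),
      n_snp_sexlinked = as.integer(n_snp_sexlinked),
      n_pa_autosomal = as.integer(n_pa_autosomal),
      n_pa_sexlinked = as.integer(n_pa_sexlinked),
      maf_range = as.numeric(maf_range), error_rate = error_rate,
      missing_rate = missing_rate, recomb_fraction = recomb_fraction,
      sex_reversal = sex_reversal, tag_length = as.integer(tag_length),
      seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %dM/%dF, %s on %s of %d x %d bp chromosomes\n",
              object@n_males, object@n_females, object@system,
              object@sex_chrom, object@n_chrom, object@chrom_length))
  cat(sprintf("  SNP %d autosomal + %d sex-linked; PA %d + %d\n",
              object@n_snp_autosomal, object@n_snp_sexlinked,
              object@n_pa_autosomal, object@n_pa_sexlinked))
  cat(sprintf("  e=%.3g m=%.3g r=%.3g s=%.3g, tags %d bp, seed %d\n",
              object@error_rate, object@missing_rate, object@recomb_fraction,
              object@sex_reversal, object@tag_length, object@seed))
})

# Echo a config as a plain named list (JSON-friendly).
.configAsList <- function(config) {
  sl <- methods::slotNames("ScenarioConfig")
  stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

#' Generate a synthetic reference genome
#'
#' `n_chrom` chromosomes of `chrom_length` i.i.d. uniform bases, named
#' `chr1..chr<n_chrom>`. Deterministic under `(config, seed)`.
#'
#' @param config a [ScenarioConfig-class].
#' @param seed RNG seed (defaults to the config's).
#' @return a named `DNAStringSet`.
#' @export
generateReference <- function(config, seed = config@seed) {
  validObject(config)
  .withSeed(seed, {
    seqs <- vapply(seq_len(config@n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), config@chrom_length,
                   replace = TRUE), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs,
                                             paste0("chr", seq_len(config@n_chrom))))
  })
}

# HWE genotype matrix for given per-locus alternate allele frequencies.
.hweGenotypes <- function(q, n_ind) {
  p0 <- (1 - q)^2
  p1 <- 2 * q * (1 - q)
  u <- matrix(stats::runif(length(q) * n_ind), nrow = length(q),
              ncol = n_ind)
  (u > p0) + (u > p0 + p1)
}

.applySnpNoise <- function(calls, e, m) {
  if (length(calls) && e > 0) {
    err <- stats::runif(length(calls)) < e
    shift <- sample(1:2, sum(err), replace = TRUE)
    calls[err] <- (calls[err] + shift) %% 3L
  }
  if (length(calls) && m > 0) calls[stats::runif(length(calls)) < m] <- NA
  calls
}

.applyPaNoise <- function(calls, e, m) {
  if (length(calls) && e > 0) {
    err <- stats::runif(length(calls)) < e
    calls[err] <- 1L - calls[err]
  }
  if (length(calls) && m > 0) calls[stats::runif(length(calls)) < m] <- NA
  calls
}

#' Simulate a population's genotype matrices
#'
#' Draws one simulated dataset under `config` against `reference` (see the
#' module description above for the generative model). Fully reproducible
#' under `(config, seed)`.
#'
#' @param config a [ScenarioConfig-class].
#' @param reference a `DNAStringSet` consistent with `config` (use
#'   [generateReference()]).
#' @param seed RNG seed (defaults to the config's).
#' @param y_allele_labels optional character vector (`"b1"`/`"b2"`, one per
#'   sex-linked SNP locus) overriding the random sex-limited-allele labels;
#'   used by [simulateIntrogression()] to copy a Y haplotype across
#'   populations.
#' @return a [SimulatedDataset-class].
#' @export
simulatePopulation <- function(config, reference, seed = config@seed,
                               y_allele_labels = NULL) {
  validObject(config)
  chroms <- paste0("chr", seq_len(config@n_chrom))
  if (!identical(names(reference), chroms) ||
      !all(Biostrings::width(reference) == config@chrom_length))
    stop("reference inconsistent with config (chromosome names or lengths)")
  nS <- config@n_snp_sexlinked
  if (!is.null(y_allele_labels)) {
    if (length(y_allele_labels) != nS || !all(y_allele_labels %in% c("b1", "b2")))
      stop("y_allele_labels must be 'b1'/'b2', one per sex-linked SNP locus")
  }
  .withSeed(seed, {
    nm <- config@n_males; nf <- config@n_females
    n <- nm + nf
    if (n < 1L) stop("at least one individual is required")
    geno_sex <- c(rep("male", nm), rep("female", nf))
    ids <- c(sprintf("M%03d", seq_len(nm)), sprintf("F%03d", seq_len(nf)))
    flip <- stats::runif(n) < config@sex_reversal
    pheno_sex <- ifelse(flip, ifelse(geno_sex == "male", "female", "male"),
                        geno_sex)
    hetero_sex <- if (config@system == "XY") "male" else "female"
    is_het <- geno_sex == hetero_sex

    labels <- if (!is.null(y_allele_labels)) y_allele_labels
              else sample(c("b1", "b2"), nS, replace = TRUE)
    n_rec_snp <- round(config@recomb_fraction * nS)
    rec_snp <- rep(FALSE, nS)
    if (n_rec_snp > 0) rec_snp[sample(nS, n_rec_snp)] <- TRUE
    nPS <- config@n_pa_sexlinked
    n_rec_pa <- round(config@recomb_fraction * nPS)
    rec_pa <- rep(FALSE, nPS)
    if (n_rec_pa > 0) rec_pa[sample(nPS, n_rec_pa)] <- TRUE

    # --- SNP calls -------------------------------------------------------
    nA <- config@n_snp_autosomal
    q_auto <- stats::runif(nA, config@maf_range[1], config@maf_range[2])
    snp_auto <- .hweGenotypes(q_auto, n)
    snp_sex <- matrix(0L, nrow = nS, ncol = n)
    if (nS > 0) {
      hom_val <- ifelse(labels == "b1", 0L, 2L)
      snp_sex <- matrix(rep(hom_val, n), nrow = nS)
      snp_sex[, is_het] <- 1L
      if (any(rec_snp)) {
        q_rec <- stats::runif(sum(rec_snp), config@maf_range[1],
                              config@maf_range[2])
        snp_sex[rec_snp, ] <- .hweGenotypes(q_rec, n)
      }
    }
    snp_calls <- rbind(snp_auto, snp_sex)
    storage.mode(snp_calls) <- "integer"
    snp_calls <- .applySnpNoise(snp_calls, config@error_rate,
                                config@missing_rate)

    # --- PA calls --------------------------------------------------------
    nPA <- config@n_pa_autosomal
    pres_p <- stats::runif(nPA, 0.3, 0.9)
    pa_auto <- matrix(as.integer(stats::runif(nPA * n) <
                                   rep(pres_p, n)), nrow = nPA, ncol = n)
    pa_sex <- matrix(0L, nrow = nPS, ncol = n)
    if (nPS > 0) {
      pa_sex[, is_het] <- 1L
      if (any(rec_pa)) {
        p_rec <- stats::runif(sum(rec_pa), 0.3, 0.9)
        pa_sex[rec_pa, ] <- matrix(as.integer(
          stats::runif(sum(rec_pa) * n) < rep(p_rec, n)), nrow = sum(rec_pa))
      }
    }
    pa_calls <- rbind(pa_auto, pa_sex)
    storage.mode(pa_calls) <- "integer"
    pa_calls <- .applyPaNoise(pa_calls, config@error_rate,
                              config@missing_rate)

    # --- locus placement and tags ---------------------------------------
    autos <- setdiff(chroms, config@sex_chrom)
    snp_ids <- c(sprintf("snpA_%04d", seq_len(nA)),
                 sprintf("snpS_%04d", seq_len(nS)))
    pa_ids <- c(sprintf("paA_%04d", seq_len(nPA)),
                sprintf("paS_%04d", seq_len(nPS)))
    dimnames(snp_calls) <- list(snp_ids, ids)
    dimnames(pa_calls) <- list(pa_ids, ids)
    locus_chrom <- c(sample(autos, nA, replace = TRUE),
                     rep(config@sex_chrom, nS),
                     sample(autos, nPA, replace = TRUE),
                     rep(config@sex_chrom, nPS))
    n_loci <- nA + nS + nPA + nPS
    tag_start <- sample.int(config@chrom_length - config@tag_length + 1L,
                            n_loci, replace = TRUE)
    tags <- substring(as.character(reference)[locus_chrom], tag_start,
                      tag_start + config@tag_length - 1L)

    truth <- S4Vectors::DataFrame(
      locus_id = c(snp_ids, pa_ids),
      marker_class = rep(c("SNP", "PA"), c(nA + nS, nPA + nPS)),
      truth_class = c(rep("autosomal", nA),
                      ifelse(rec_snp, "sexlinked_recombining",
                             "sexlinked_nonrecombining"),
                      rep("autosomal", nPA),
                      ifelse(rec_pa, "sexlinked_recombining",
                             "sexlinked_nonrecombining")),
      chromosome = locus_chrom,
      tag_start = tag_start,
      y_allele_label = c(rep(NA_character_, nA), labels,
                         rep(NA_character_, nPA + nPS))
    )

    snp <- SnpGenotypes(snp_calls, pheno_sex, tags = tags[seq_len(nA + nS)])
    SummarizedExperiment::colData(snp)$genotypic_sex <- geno_sex
    pa <- PAGenotypes(pa_calls, pheno_sex,
                      tags = tags[nA + nS + seq_len(nPA + nPS)])
    SummarizedExperiment::colData(pa)$genotypic_sex <- geno_sex
    new("SimulatedDataset", snp = snp, pa = pa, reference = reference,
        truth = truth, config = config, seed = as.integer(seed))
  })
}

#' @rdname accessors
#' @export
setMethod("snpGenotypes", "SimulatedDataset", function(x) x@snp)

#' @rdname accessors
#' @export
setMethod("paGenotypes", "SimulatedDataset", function(x) x@pa)

#' @rdname accessors
#' @export
setMethod("referenceGenome", "SimulatedDataset", function(x) x@reference)

#' @rdname accessors
#' @export
setMethod("truthTable", "SimulatedDataset", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("scenarioConfig", "SimulatedDataset", function(x) x@config)

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (seed %d):\n", object@seed))
  show(object@snp)
  show(object@pa)
  cat(sprintf("  truth: %d sex-linked non-recombining, %d recombining, %d autosomal\n",
              sum(object@truth$truth_class == "sexlinked_nonrecombining"),
              sum(object@truth$truth_class == "sexlinked_recombining"),
              sum(object@truth$truth_class == "autosomal")))
})

#' Write a simulated dataset's files
#'
#' Writes the canonical genotype/PA/sex CSVs, tag and reference FASTA, the
#' truth-table CSV, and a JSON echo of the scenario configuration and seed.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeSimulatedDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    snp = file.path(dir, "snp_genotypes.csv"),
    pa = file.path(dir, "pa_genotypes.csv"),
    sex = file.path(dir, "sexes.csv"),
    tags = file.path(dir, "tags.fasta"),
    reference = file.path(dir, "reference.fasta"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "scenario_config.json")
  )
  writeGenotypeTables(dataset@snp, dataset@pa, snp_path = paths$snp,
                      pa_path = paths$pa, sex_path = paths$sex)
  tags <- c(tagSequences(dataset@snp), tagSequences(dataset@pa))
  writeFasta(tags, paths$tags)
  writeFasta(dataset@reference, paths$reference)
  utils::write.csv(as.data.frame(dataset@truth), paths$truth,
                   row.names = FALSE, quote = FALSE)
  cfg <- .configAsList(dataset@config)
  cfg$generator_seed <- dataset@seed
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
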