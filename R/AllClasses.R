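#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.SEX_LEVELS <- c("male", "female", "unknown")
.CATEGORIES <- c("male_het_snp", "female_het_snp",
                 "male_present_pa", "female_present_pa")

# ---------------------------------------------------------------------------
# Genotype containers
# ---------------------------------------------------------------------------

#' Genotype matrix containers
#'
#' `SnpGenotypes` holds co-dominant SNP calls (loci x individuals) and
#' `PAGenotypes` holds dominant presence/absence calls, both as thin
#' `SummarizedExperiment` subclasses. The single assay `"calls"` is an integer
#' matrix: SNP calls are coded `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (missing); presence/absence calls are
#' `1` (present), `0` (absent), `NA` (missing). Column metadata carries the
#' phenotypic sex of each individual (`"male"`, `"female"`, `"unknown"`);
#' row metadata optionally carries the marker tag sequence (A/C/G/T, typically
#' 69 bp for DArTseq-style data).
#'
#' Individuals of unknown sex are retained in the matrix but excluded from all
#' sex-conditional statistics (call ratios, concordance, the false-positive
#' test).
#'
#' @aliases SnpGenotypes-class PAGenotypes-class GenotypeExperiment-class
#' @name GenotypeExperiment
NULL

#' @rdname GenotypeExperiment
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment",
         contains = c("SummarizedExperiment", "VIRTUAL"))

#' @rdname GenotypeExperiment
#' @exportClass SnpGenotypes
setClass("SnpGenotypes", contains = "GenotypeExperiment")

#' @rdname GenotypeExperiment
#' @exportClass PAGenotypes
setClass("PAGenotypes", contains = "GenotypeExperiment")

.validGenotypeExperiment <- function(object, allowed) {
  msg <- character(0)
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'calls' is required")
  calls <- SummarizedExperiment::assay(object, "calls")
  if (!is.numeric(calls) && !is.integer(calls))
    msg <- c(msg, "assay 'calls' must be numeric")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% allowed))
    msg <- c(msg, sprintf("calls must be NA or one of {%s}",
                          paste(allowed, collapse = ",")))
  if (nrow(object) > 0 &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "locus ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!("sex" %in% colnames(cd))) {
    msg <- c(msg, "colData must contain a 'sex' column")
  } else if (!all(cd$sex %in% .SEX_LEVELS)) {
    msg <- c(msg, "sex must be 'male', 'female' or 'unknown'")
  }
  rd <- SummarizedExperiment::rowData(object)
  if ("tag" %in% colnames(rd)) {
    tags <- rd$tag
    ok <- is.na(tags) | (nzchar(tags) & !grepl("[^ACGT]", tags))
    if (!all(ok))
      msg <- c(msg, "tags must be nonempty strings over {A,C,G,T}")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SnpGenotypes", function(object)
  .validGenotypeExperiment(object, allowed = 0:2))

setValidity("PAGenotypes", function(object)
  .validGenotypeExperiment(object, allowed = 0:1))

# ---------------------------------------------------------------------------
# Discovery results
# ---------------------------------------------------------------------------

#' Classified sex-linked candidate loci
#'
#' One row per candidate locus passing the concordance threshold, with the
#' marker class (`SNP`/`PA`), winning heterogamety system (`XY`/`ZW`), category
#' (`male_het_snp`, `female_het_snp`, `male_present_pa`, `female_present_pa`),
#' concordance, the inferred sex-limited allele (`"ref"`/`"alt"`, SNP only),
#' and after [falsePositiveTest()] the false-positive statistic and flag.
#' The thresholds used at discovery are recorded alongside.
#'
#' @slot table a `DataFrame` with columns `locus_id`, `marker_class`, `system`,
#'   `category`, `concordance`, `sex_limited_allele`, `fp_statistic`,
#'   `fp_flag`.
#' @slot thresholds named list of the thresholds used.
#' @aliases SexLinkedSet-class
#' @export SexLinkedSet
#' @exportClass SexLinkedSet
SexLinkedSet <- setClass("SexLinkedSet",
                         representation(table = "DataFrame",
                                        thresholds = "list"))

setValidity("SexLinkedSet", function(object) {
  tb <- object@table
  need <- c("locus_id", "marker_class", "system", "category", "concordance",
            "sex_limited_allele", "fp_statistic", "fp_flag")
  if (!all(need %in% colnames(tb)))
    return(sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  msg <- character(0)
  if (anyDuplicated(tb$locus_id))
    msg <- c(msg, "categories are per-locus: locus_id must be unique")
  if (!all(tb$marker_class %in% c("SNP", "PA")))
    msg <- c(msg, "marker_class must be 'SNP' or 'PA'")
  if (!all(tb$system %in% c("XY", "ZW")))
    msg <- c(msg, "system must be 'XY' or 'ZW'")
  if (!all(tb$category %in% .CATEGORIES))
    msg <- c(msg, "invalid category")
  if (any(!is.na(tb$concordance) & (tb$concordance < 0 | tb$concordance > 1)))
    msg <- c(msg, "concordance must lie in [0, 1]")
  thr <- object@thresholds$concordance_threshold
  if (!is.null(thr) && any(tb$concordance < thr - 1e-12))
    msg <- c(msg, "every member's concordance must be >= the recorded threshold")
  if (any(!is.na(tb$fp_flag) & tb$fp_flag & tb$marker_class != "SNP"))
    msg <- c(msg, "fp_flag = TRUE is only defined for SNP markers")
  if (length(msg)) msg else TRUE
})

#' Table-1-style discovery bookkeeping
#'
#' Per category: initial members, false-positive-flagged members, and true
#' markers (initial minus false positive), plus the four-category grand total
#' of true markers.
#'
#' @slot counts data.frame with columns `category`, `n_initial`,
#'   `n_false_positive`, `n_true`.
#' @slot n_true_total integer grand total of true markers.
#' @aliases DiscoverySummary-class
#' @exportClass DiscoverySummary
setClass("DiscoverySummary",
         representation(counts = "data.frame", n_true_total = "integer"))

setValidity("DiscoverySummary", function(object) {
  ct <- object@counts
  msg <- character(0)
  if (!identical(ct$n_true, ct$n_initial - ct$n_false_positive))
    msg <- c(msg, "n_true must equal n_initial - n_false_positive")
  if (any(ct$n_initial < 0 | ct$n_false_positive < 0 | ct$n_true < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!identical(object@n_true_total, as.integer(sum(ct$n_true))))
    msg <- c(msg, "n_true_total must equal the sum of per-category n_true")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Chromosome assignment
# ---------------------------------------------------------------------------

#' Parameters of the built-in tag mapper
#'
#' The mapper reports an ungapped, full-length alignment of a marker tag to the
#' reference wherever (i) an exact `seed_k`-mer shared between tag and
#' reference anchors the placement, (ii) the whole tag fits on the chromosome,
#' and (iii) the identity over the tag is at least `min_identity`. Tags shorter
#' than `min_aln_length` (or `seed_k`) are reported unaligned. Externally
#' produced BLAST tabular hits can substitute for the mapper via
#' [readAlignmentTab()].
#'
#' @param seed_k exact-match seed length in bp.
#' @param min_identity minimum fraction of matching bases over the tag.
#' @param min_aln_length minimum tag length considered alignable, in bp.
#' @return a `MapperParams` object.
#' @aliases MapperParams-class
#' @exportClass MapperParams
setClass("MapperParams",
         representation(seed_k = "integer",
                        min_identity = "numeric",
                        min_aln_length = "integer"),
         prototype(seed_k = 21L, min_identity = 0.90,
                   min_aln_length = 50L))

#' @rdname MapperParams-class
#' @export
MapperParams <- function(seed_k = 21, min_identity = 0.90,
                         min_aln_length = 50) {
  new("MapperParams", seed_k = as.integer(seed_k),
      min_identity = as.numeric(min_identity),
      min_aln_length = as.integer(min_aln_length))
}

setValidity("MapperParams", function(object) {
  msg <- character(0)
  if (object@seed_k < 1L || object@seed_k > object@min_aln_length)
    msg <- c(msg, "need 1 <= seed_k <= min_aln_length")
  if (object@min_identity <= 0 || object@min_identity > 1)
    msg <- c(msg, "need 0 < min_identity <= 1")
  if (length(msg)) msg else TRUE
})

#' Per-chromosome summary of uniquely aligned markers
#'
#' @slot per_chrom_counts named integer vector, uniquely assigned markers per
#'   chromosome.
#' @slot n_assigned,n_multi_chrom,n_unaligned partition of the input loci.
#' @slot modal_chrom chromosome attracting the most markers (`NA` when
#'   nothing is assigned); ties broken towards the smaller chromosome id.
#' @slot modal_fraction fraction of assigned markers on the modal chromosome.
#' @slot modal_percent_1dp the fraction as a percentage, rounded half-up to
#'   one decimal.
#' @slot modal_tie whether the modal chromosome was tied.
#' @aliases AssignmentSummary-class
#' @exportClass AssignmentSummary
setClass("AssignmentSummary",
         representation(per_chrom_counts = "integer",
                        n_assigned = "integer",
                        n_multi_chrom = "integer",
                        n_unaligned = "integer",
                        modal_chrom = "character",
                        modal_fraction = "numeric",
                        modal_percent_1dp = "numeric",
                        modal_tie = "logical"))

setValidity("AssignmentSummary", function(object) {
  msg <- character(0)
  if (sum(object@per_chrom_counts) != object@n_assigned)
    msg <- c(msg, "per_chrom_counts must sum to n_assigned")
  if (object@n_assigned > 0L) {
    expect <- object@per_chrom_counts[[object@modal_chrom]] / object@n_assigned
    if (!isTRUE(all.equal(expect, object@modal_fraction)))
      msg <- c(msg, "modal_fraction inconsistent with per_chrom_counts")
  }
  if (length(msg)) msg else TRUE
})

#' Sex chromosome call
#'
#' @slot reference_chrom modal reference chromosome.
#' @slot species_chrom corresponding study-species chromosome via the
#'   chromosome correspondence map.
#' @slot modal_fraction,n_assigned as in [AssignmentSummary-class].
#' @slot confident TRUE when the modal fraction and modal marker count clear
#'   their minima.
#' @aliases SexChromosomeCall-class
#' @exportClass SexChromosomeCall
setClass("SexChromosomeCall",
         representation(reference_chrom = "character",
                        species_chrom = "character",
                        modal_fraction = "numeric",
                        n_assigned = "integer",
                        confident = "logical"))

# ---------------------------------------------------------------------------
# Simulation
# ---------------------------------------------------------------------------

#' Simulation scenario configuration
#'
#' Describes one simulated sib-ship-scale population: sample sizes, the
#' heterogamety system and sex chromosome, genome shape, locus counts by class,
#' and the noise processes (genotyping error, missingness, recombination
#' between the sex chromosomes, phenotypic sex reversal).
#'
#' @aliases ScenarioConfig-class
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
         representation(n_males = "integer", n_females = "integer",
                        system = "character", sex_chrom = "character",
                        n_chrom = "integer", chrom_length = "integer",
                        n_snp_autosomal = "integer", n_snp_sexlinked = "integer",
                        n_pa_autosomal = "integer", n_pa_sexlinked = "integer",
                        maf_range = "numeric", error_rate = "numeric",
                        missing_rate = "numeric", recomb_fraction = "numeric",
                        sex_reversal = "numeric", tag_length = "integer",
                        seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (object@n_males < 0L || object@n_females < 0L)
    msg <- c(msg, "sample sizes must be non-negative")
  if (!(object@system %in% c("XY", "ZW")))
    msg <- c(msg, "system must be 'XY' or 'ZW'")
  if (object@n_chrom < 2L)
    msg <- c(msg, "n_chrom must be >= 2")
  chroms <- paste0("chr", seq_len(object@n_chrom))
  if (!(object@sex_chrom %in% chroms))
    msg <- c(msg, sprintf("sex_chrom must be one of chr1..chr%d", object@n_chrom))
  if (length(object@maf_range) != 2L || object@maf_range[1] <= 0 ||
      object@maf_range[2] > 0.5 || diff(object@maf_range) < 0)
    msg <- c(msg, "maf_range must be an interval within (0, 0.5]")
  for (s in c("error_rate", "missing_rate", "recomb_fraction", "sex_reversal")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (object@tag_length < 1L || object@tag_length > object@chrom_length)
    msg <- c(msg, "need 1 <= tag_length <= chrom_length")
  if (length(msg)) msg else TRUE
})

#' A fully simulated dataset
#'
#' Bundles the genotype matrices, the synthetic reference they were drawn
#' from, the per-locus ground truth, and the scenario that produced them.
#'
#' @slot snp a [SnpGenotypes].
#' @slot pa a [PAGenotypes].
#' @slot reference a `DNAStringSet` of synthetic chromosomes.
#' @slot truth a `DataFrame` with per-locus `locus_id`, `marker_class`,
#'   `truth_class` (`autosomal`, `sexlinked_nonrecombining`,
#'   `sexlinked_recombining`), `chromosome`, `tag_start`, `y_allele_label`.
#' @slot config the [ScenarioConfig-class] used.
#' @slot seed the seed used.
#' @aliases SimulatedDataset-class
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
         representation(snp = "SnpGenotypes", pa = "PAGenotypes",
                        reference = "DNAStringSet", truth = "DataFrame",
                        config = "ScenarioConfig", seed = "integer"))

setValidity("SimulatedDataset", function(object) {
  cfg <- object@config
  msg <- character(0)
  if (nrow(object@snp) != cfg@n_snp_autosomal + cfg@n_snp_sexlinked)
    msg <- c(msg, "SNP locus count inconsistent with config")
  if (nrow(object@pa) != cfg@n_pa_autosomal + cfg@n_pa_sexlinked)
    msg <- c(msg, "PA locus count inconsistent with config")
  if (nrow(object@truth) != nrow(object@snp) + nrow(object@pa))
    msg <- c(msg, "truth table must cover every locus")
  sl <- object@truth$truth_class != "autosomal"
  if (any(object@truth$chromosome[sl] != cfg@sex_chrom))
    msg <- c(msg, "sex-linked loci must lie on the configured sex chromosome")
  if (length(msg)) msg else TRUE
})
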