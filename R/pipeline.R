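# Pipeline orchestration: the four stages (simulate / discover / assign /
# report) as one entry point over a structured run configuration, with a
# logged seed and filter counts, so a whole analysis is reproducible from a
# single YAML file. A thin command-line wrapper lives in
# inst/scripts/sexlinkr.R.

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    outdir = "sexlinkr_results",
    paths = list(snp = NULL, pa = NULL, sex = NULL, tags = NULL,
                 reference = NULL, alignments = NULL),
    thresholds = list(min_call_ratio = 0.8, concordance_threshold = 0.8,
                      min_called_per_sex = 3L, fp_threshold = 0.05,
                      min_fraction = 0.5, min_markers = 3L),
    mapper = list(seed_k = 21L, min_identity = 0.90, min_aln_length = 50L),
    chrom_map = as.list(defaultChromMap()),
    scenario = list()
  )
}

.mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Run configuration
#'
#' `runConfig()` builds a validated configuration list from the package
#' defaults with selective overrides; `readRunConfig()` reads one from a YAML
#' file. The configuration holds the output directory, input paths, all
#' thresholds (call ratio, concordance, per-sex call minimum, false-positive
#' threshold, mapper parameters, confidence minima), the chromosome
#' correspondence map, the seed, and the simulation scenario.
#'
#' @param ... named overrides of the default configuration (nested lists are
#'   merged; e.g. `thresholds = list(concordance_threshold = 0.9)`).
#' @param path a YAML file with the same structure.
#' @return a validated configuration list.
#' @export
runConfig <- function(...) {
  config <- .mergeConfig(.defaultRunConfig(), list(...))
  .validateRunConfig(config)
  config
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  config <- .mergeConfig(.defaultRunConfig(), yaml::read_yaml(path))
  .validateRunConfig(config)
  config
}

.validateRunConfig <- function(config) {
  th <- config$thresholds
  .checkFraction(th$min_call_ratio, "min_call_ratio", min_open = TRUE)
  .checkFraction(th$concordance_threshold, "concordance_threshold",
                 min_open = TRUE)
  .checkFraction(th$fp_threshold, "fp_threshold")
  .checkFraction(th$min_fraction, "min_fraction")
  if (th$min_called_per_sex < 0) stop("min_called_per_sex must be >= 0")
  if (th$min_markers < 0) stop("min_markers must be >= 0")
  validObject(MapperParams(
    seed_k = as.integer(config$mapper$seed_k),
    min_identity = config$mapper$min_identity,
    min_aln_length = as.integer(config$mapper$min_aln_length)))
  invisible(config)
}

.logRun <- function(config, subcommand) {
  .msg("SexLinkR %s | subcommand '%s' | seed %d",
       as.character(utils::packageVersion("SexLinkR")), subcommand,
       as.integer(config$seed))
}

.requireFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("missing input for %s: %s", what,
                 if (is.null(path)) "(no path configured)" else path))
  path
}

#' Run a pipeline stage
#'
#' Subcommands: `"simulate"` writes a [SimulatedDataset-class]'s files to the
#' output directory; `"discover"` reads the genotype tables, applies the
#' call-ratio filter, classifies sex-linked candidates and runs the
#' false-positive test, writing a per-locus discovery report and a
#' bookkeeping summary; `"assign"` maps the true markers' tags to the
#' reference (or ingests configured BLAST tabular hits), writes per-chromosome
#' counts and the sex chromosome call; `"report"` merges the stage outputs
#' into one JSON report. Every stage logs the package version, the seed, and
#' the counts at each filter, and stops with a named cause on missing inputs
#' or invalid thresholds.
#'
#' @param config a configuration list from [runConfig()] or
#'   [readRunConfig()].
#' @param subcommand one of `"simulate"`, `"discover"`, `"assign"`,
#'   `"report"`.
#' @return invisibly, a named list of the files written (plus the main result
#'   object of the stage).
#' @export
runPipeline <- function(config,
                        subcommand = c("simulate", "discover", "assign",
                                       "report")) {
  subcommand <- match.arg(subcommand)
  .validateRunConfig(config)
  .logRun(config, subcommand)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(subcommand,
                simulate = .stageSimulate(config),
                discover = .stageDiscover(config),
                assign = .stageAssign(config),
                report = .stageReport(config))
  invisible(out)
}

.inPath <- function(config, key, default_file) {
  p <- config$paths[[key]]
  if (is.null(p)) file.path(config$outdir, default_file) else p
}

.stageSimulate <- function(config) {
  scenario <- do.call(ScenarioConfig,
                      .mergeConfig(list(seed = config$seed), config$scenario))
  reference <- generateReference(scenario)
  dataset <- simulatePopulation(scenario, reference)
  paths <- writeSimulatedDataset(dataset, config$outdir)
  .msg("simulate: wrote %d SNP and %d PA loci for %d individuals to %s",
       nrow(snpGenotypes(dataset)), nrow(paGenotypes(dataset)),
       ncol(snpGenotypes(dataset)), config$outdir)
  c(paths, list(dataset = dataset))
}

.stageDiscover <- function(config) {
  th <- config$thresholds
  snp_path <- .requireFile(.inPath(config, "snp", "snp_genotypes.csv"), "discover")
  sex_path <- .requireFile(.inPath(config, "sex", "sexes.csv"), "discover")
  pa_path <- .inPath(config, "pa", "pa_genotypes.csv")
  if (!file.exists(pa_path)) pa_path <- NULL
  mats <- readGenotypeTables(snp_path, pa_path, sex_path)
  snp <- filterCallRatio(mats$snp, th$min_call_ratio)
  pa <- if (!is.null(mats$pa)) filterCallRatio(mats$pa, th$min_call_ratio)
  set <- classifySexLinked(snp, pa, th$concordance_threshold,
                           th$min_called_per_sex)
  set <- falsePositiveTest(set, snp, th$fp_threshold)
  summ <- summarizeDiscovery(set)
  report_path <- file.path(config$outdir, "discovery_report.csv")
  summary_path <- file.path(config$outdir, "discovery_summary.csv")
  utils::write.csv(as.data.frame(markerTable(set)), report_path,
                   row.names = FALSE, quote = FALSE)
  counts <- discoveryCounts(summ)
  counts$n_true_total <- c(trueTotal(summ), rep(NA, nrow(counts) - 1L))
  utils::write.csv(counts, summary_path, row.names = FALSE, quote = FALSE)
  .msg("discover: %d candidate(s), %d flagged, %d true",
       length(set), sum(markerTable(set)$fp_flag), trueTotal(summ))
  list(report = report_path, summary = summary_path, set = set,
       discovery_summary = summ)
}

.stageAssign <- function(config) {
  th <- config$thresholds
  report_path <- .requireFile(file.path(config$outdir, "discovery_report.csv"),
                              "assign (run 'discover' first)")
  report <- utils::read.csv(report_path, colClasses = "character")
  true_ids <- report$locus_id[report$fp_flag == "FALSE"]
  tags_path <- .requireFile(.inPath(config, "tags", "tags.fasta"), "assign")
  tags <- readTagsFasta(tags_path)
  tags <- tags[names(tags) %in% true_ids]
  if (!length(tags))
    stop("no true sex-linked markers with tags to assign")
  aln_path <- config$paths$alignments
  hits <- if (!is.null(aln_path)) {
    readAlignmentTab(.requireFile(aln_path, "assign"))
  } else {
    ref_path <- .requireFile(.inPath(config, "reference", "reference.fasta"),
                             "assign")
    params <- MapperParams(seed_k = as.integer(config$mapper$seed_k),
                           min_identity = config$mapper$min_identity,
                           min_aln_length = as.integer(config$mapper$min_aln_length))
    mapTags(tags, readReferenceFasta(ref_path), params)
  }
  parts <- uniqueChromosomeAssignments(hits, names(tags))
  summ <- assignmentSummary(parts)
  call <- callSexChromosome(summ, unlist(config$chrom_map),
                            th$min_fraction, th$min_markers)
  counts_path <- file.path(config$outdir, "per_chrom_counts.csv")
  call_path <- file.path(config$outdir, "sex_chromosome_call.json")
  utils::write.csv(data.frame(chrom = names(perChromCounts(summ)),
                              n_markers = as.integer(perChromCounts(summ))),
                   counts_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(reference_chrom = call@reference_chrom,
         species_chrom = call@species_chrom,
         modal_fraction = call@modal_fraction,
         modal_percent_1dp = modalPercent(summ),
         n_assigned = call@n_assigned,
         n_multi_chrom = summ@n_multi_chrom,
         n_unaligned = summ@n_unaligned,
         confident = call@confident),
    call_path, auto_unbox = TRUE, digits = NA)
  .msg("assign: %d assigned, modal %s (%.1f%%) -> species %s",
       summ@n_assigned, modalChrom(summ), modalPercent(summ),
       call@species_chrom)
  list(counts = counts_path, call_json = call_path, summary = summ,
       call = call)
}

.stageReport <- function(config) {
  summary_path <- .requireFile(file.path(config$outdir, "discovery_summary.csv"),
                               "report (run 'discover' first)")
  call_path <- .requireFile(file.path(config$outdir, "sex_chromosome_call.json"),
                            "report (run 'assign' first)")
  report <- list(
    seed = as.integer(config$seed),
    thresholds = config$thresholds,
    discovery = utils::read.csv(summary_path),
    sex_chromosome_call = jsonlite::read_json(call_path)
  )
  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  .msg("report: wrote %s", report_path)
  list(report_json = report_path, report = report)
}
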