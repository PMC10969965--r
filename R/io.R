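# Readers and writers for the pipeline's plain-text formats:
#   * genotype / presence-absence CSV (loci as rows, individuals as columns,
#     SNP codes 0/1/2/- and PA codes 1/0/-, optional 'tag' column),
#   * two-column sex CSV (individual_id,sex with M/F/U),
#   * FASTA (reference chromosomes, marker tags) via Biostrings,
#   * BLAST tabular (outfmt 6) alignments,
#   * STRUCTURE two-row genotype input (export only).

.SNP_FROM_CODE <- c("0" = 0L, "1" = 1L, "2" = 2L, "-" = NA_integer_)
.PA_FROM_CODE <- c("1" = 1L, "0" = 0L, "-" = NA_integer_)
.SEX_FROM_CODE <- c(M = "male", F = "female", U = "unknown")

.parseCallTable <- function(path, code_map, what) {
  tb <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!nrow(tb) && !ncol(tb))
    stop(sprintf("empty %s table: %s", what, path))
  if (colnames(tb)[1] != "locus_id")
    stop(sprintf("first column of %s table must be 'locus_id' (%s)", what, path))
  loci <- tb[[1]]
  if (anyDuplicated(loci))
    stop(sprintf("duplicate locus id '%s' in %s", loci[duplicated(loci)][1], path))
  tags <- NULL
  first_ind <- 2L
  if (ncol(tb) >= 2L && colnames(tb)[2] == "tag") {
    tags <- tb[[2]]
    first_ind <- 3L
  }
  inds <- colnames(tb)[seq(first_ind, length.out = ncol(tb) - first_ind + 1L)]
  if (anyDuplicated(inds))
    stop(sprintf("duplicate individual id '%s' in %s",
                 inds[duplicated(inds)][1], path))
  cells <- as.matrix(tb[, first_ind:ncol(tb), drop = FALSE])
  bad <- !(cells %in% names(code_map))
  dim(bad) <- dim(cells)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable %s code '%s' at locus '%s', individual '%s' in %s",
                 what, cells[w[1], w[2]], loci[w[1]], inds[w[2]], path))
  }
  calls <- matrix(code_map[cells], nrow = length(loci),
                  dimnames = list(loci, inds))
  list(calls = calls, tags = tags)
}

.readSexFile <- function(path) {
  tb <- utils::read.csv(path, colClasses = "character")
  if (!identical(colnames(tb)[1:2], c("individual_id", "sex")))
    stop(sprintf("sex file must have header 'individual_id,sex' (%s)", path))
  if (anyDuplicated(tb$individual_id))
    stop(sprintf("duplicate individual id '%s' in sex file",
                 tb$individual_id[duplicated(tb$individual_id)][1]))
  if (!all(tb$sex %in% names(.SEX_FROM_CODE)))
    stop(sprintf("sex codes must be M, F or U (%s)", path))
  stats::setNames(.SEX_FROM_CODE[tb$sex], tb$individual_id)
}

.lookupSexes <- function(inds, sex_map, path) {
  sex <- unname(sex_map[inds])
  miss <- is.na(sex)
  if (any(miss)) {
    warning(sprintf("%d individual(s) absent from sex file, set to unknown: %s",
                    sum(miss), paste(inds[miss], collapse = ", ")),
            call. = FALSE)
    sex[miss] <- "unknown"
  }
  sex
}

#' Read genotype and presence/absence tables
#'
#' Reads the canonical CSV dialect (loci as rows, individuals as columns;
#' SNP codes `0`/`1`/`2`/`-` for homozygous reference / heterozygous /
#' homozygous alternate / missing; PA codes `1`/`0`/`-` for present / absent /
#' missing; optional second column `tag` with the marker tag sequence)
#' together with a two-column sex file (`individual_id,sex`, sex in M/F/U).
#' Individuals missing from the sex file are retained with sex `unknown` and
#' a warning. When a PA table is given its individuals must match the SNP
#' table's; columns are reordered to the SNP table's order.
#'
#' @param snp_path path to the SNP genotype CSV.
#' @param pa_path optional path to the presence/absence CSV.
#' @param sex_path path to the sex CSV.
#' @return list with elements `snp` ([SnpGenotypes]) and `pa` ([PAGenotypes]
#'   or `NULL`).
#' @export
readGenotypeTables <- function(snp_path, pa_path = NULL, sex_path) {
  sex_map <- .readSexFile(sex_path)
  snp_raw <- .parseCallTable(snp_path, .SNP_FROM_CODE, "SNP")
  snp <- SnpGenotypes(snp_raw$calls,
                      .lookupSexes(colnames(snp_raw$calls), sex_map, snp_path),
                      tags = snp_raw$tags)
  pa <- NULL
  if (!is.null(pa_path)) {
    pa_raw <- .parseCallTable(pa_path, .PA_FROM_CODE, "PA")
    if (!setequal(colnames(pa_raw$calls), colnames(snp_raw$calls)))
      stop("PA table individuals differ from SNP table individuals")
    calls <- pa_raw$calls[, colnames(snp_raw$calls), drop = FALSE]
    pa <- PAGenotypes(calls,
                      .lookupSexes(colnames(calls), sex_map, pa_path),
                      tags = pa_raw$tags)
  }
  list(snp = snp, pa = pa)
}

#' Write genotype and presence/absence tables
#'
#' Inverse of [readGenotypeTables()]: writes the genotype CSV(s) and the sex
#' CSV in the canonical dialect, such that re-reading reproduces the matrices
#' exactly.
#'
#' @param snp a [SnpGenotypes] object.
#' @param pa optional [PAGenotypes] object.
#' @param snp_path,pa_path,sex_path output paths (`pa_path` used only when
#'   `pa` is given).
#' @return invisibly, the paths written.
#' @export
writeGenotypeTables <- function(snp, pa = NULL, snp_path, pa_path = NULL,
                                sex_path) {
  .writeCallTable <- function(x, path, to_code) {
    calls <- genotypeCalls(x)
    codes <- matrix(to_code[as.character(calls)], nrow = nrow(calls))
    codes[is.na(calls)] <- "-"
    df <- data.frame(locus_id = rownames(calls), check.names = FALSE)
    tg <- tagSequences(x)
    if (!is.null(tg)) df$tag <- unname(tg)
    df <- cbind(df, as.data.frame(codes, optional = TRUE))
    colnames(df)[(ncol(df) - ncol(calls) + 1L):ncol(df)] <- colnames(calls)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  .writeCallTable(snp, snp_path, c("0" = "0", "1" = "1", "2" = "2"))
  if (!is.null(pa)) .writeCallTable(pa, pa_path, c("0" = "0", "1" = "1"))
  sx <- sexes(snp)
  utils::write.csv(
    data.frame(individual_id = names(sx),
               sex = names(.SEX_FROM_CODE)[match(sx, .SEX_FROM_CODE)]),
    sex_path, row.names = FALSE, quote = FALSE)
  invisible(c(snp_path, if (!is.null(pa)) pa_path, sex_path))
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Parses the standard 12-column layout (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Strand is inferred from the subject coordinate order (sstart > send means
#' minus strand); subject coordinates are normalized so `start <= end` and
#' identity is `pident/100`. Coordinates are 1-based inclusive.
#'
#' @param path path to a tab- or whitespace-separated outfmt-6 file.
#' @return a `DataFrame` of alignment hits with columns `query_id`, `chrom`,
#'   `start`, `end`, `strand`, `identity`, `aln_length`.
#' @export
readAlignmentTab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.emptyHits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop(sprintf("expected 12 columns in BLAST tabular input, got %d at line %d of %s",
                 nf[nf != 12L][1], which(nf != 12L)[1], path))
  m <- do.call(rbind, fields)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  hits <- S4Vectors::DataFrame(
    query_id = m[, 1],
    chrom = m[, 2],
    start = pmin(sstart, send),
    end = pmax(sstart, send),
    strand = ifelse(sstart > send, "-", "+"),
    identity = as.numeric(m[, 3]) / 100,
    aln_length = as.integer(m[, 4])
  )
  if (any(hits$identity < 0 | hits$identity > 1) || any(hits$aln_length < 1))
    stop(sprintf("malformed identity or alignment length in %s", path))
  hits
}

.checkDNA <- function(seqs, what) {
  if (!length(seqs)) stop(sprintf("no records in %s", what))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop(sprintf("every record in %s must be named", what))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate header '%s' in %s",
                 names(seqs)[duplicated(names(seqs))][1], what))
  chr <- toupper(as.character(seqs))
  if (any(!nzchar(chr)))
    stop(sprintf("empty record '%s' in %s", names(seqs)[!nzchar(chr)][1], what))
  bad <- grepl("[^ACGT]", chr)
  if (any(bad))
    stop(sprintf("record '%s' in %s contains non-ACGT symbols",
                 names(seqs)[bad][1], what))
  Biostrings::DNAStringSet(stats::setNames(chr, names(seqs)))
}

#' FASTA input and output
#'
#' Thin validated wrappers around Biostrings FASTA I/O. Sequences are
#' uppercased on input; records with non-ACGT symbols (including `N`),
#' empty bodies, or duplicate headers are rejected. `readReferenceFasta()`
#' and `readTagsFasta()` are aliases with intent-revealing names.
#'
#' @param path a FASTA file path.
#' @param x a named `DNAStringSet` (or named character vector) of reference
#'   chromosomes or per-locus tags.
#' @return the readers return a `DNAStringSet`; the writer returns `path`
#'   invisibly. A written object re-reads identically (ids and sequences).
#' @export
readReferenceFasta <- function(path) {
  .checkDNA(Biostrings::readDNAStringSet(path), path)
}

#' @rdname readReferenceFasta
#' @export
readTagsFasta <- readReferenceFasta

#' @rdname readReferenceFasta
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  x <- .checkDNA(x, "input to writeFasta")
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write a STRUCTURE two-row genotype input file
#'
#' Exports co-dominant SNP genotypes in the two-row STRUCTURE format: two
#' rows per individual (one per allele), one column per locus after the
#' individual id, alleles coded 1/2 and missing as -9; homozygous reference
#' is (1,1), heterozygous (1,2), homozygous alternate (2,2). A header line of
#' locus ids is written first. Running STRUCTURE itself is out of scope.
#'
#' @param x a [SnpGenotypes] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeStructureInput <- function(x, path) {
  calls <- genotypeCalls(x)
  a1 <- ifelse(is.na(calls), -9L, ifelse(calls >= 2L, 2L, 1L))
  a2 <- ifelse(is.na(calls), -9L, ifelse(calls >= 1L, 2L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(calls), collapse = " "), con)
  for (j in seq_len(ncol(calls))) {
    writeLines(paste(c(colnames(calls)[j], a1[, j]), collapse = " "), con)
    writeLines(paste(c(colnames(calls)[j], a2[, j]), collapse = " "), con)
  }
  invisible(path)
}
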