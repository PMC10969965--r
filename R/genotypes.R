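#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

.newGenotypes <- function(class, calls, sex, tags) {
  if ((nrow(calls) > 0 && is.null(rownames(calls))) || is.null(colnames(calls)))
    stop("'calls' must have locus ids as rownames and individual ids as colnames")
  if (nrow(calls) == 0 && is.null(rownames(calls)))
    rownames(calls) <- character(0)
  storage.mode(calls) <- "integer"
  if (length(sex) != ncol(calls))
    stop("one sex per individual is required (|sexes| = |individual_ids|)")
  rd <- S4Vectors::DataFrame(row.names = rownames(calls))
  if (!is.null(tags)) {
    if (methods::is(tags, "XStringSet")) tags <- as.character(tags)
    if (length(tags) != nrow(calls))
      stop("one tag per locus is required")
    rd$tag <- toupper(unname(tags))
  }
  se <- SummarizedExperiment(
    assays = list(calls = calls),
    rowData = rd,
    colData = S4Vectors::DataFrame(sex = unname(as.character(sex)),
                                   row.names = colnames(calls))
  )
  new(class, se)
}

#' @param calls integer matrix (loci x individuals) with locus ids as rownames
#'   and individual ids as colnames; coding as described above.
#' @param sex character vector of phenotypic sexes
#'   (`"male"`/`"female"`/`"unknown"`), one per individual.
#' @param tags optional per-locus tag sequences (character or `DNAStringSet`).
#' @return `SnpGenotypes()` and `PAGenotypes()` return validated objects of the
#'   corresponding class.
#' @examples
#' calls <- matrix(c(0L, 1L, 1L, 0L, NA, 2L), nrow = 2,
#'                 dimnames = list(c("L1", "L2"), c("i1", "i2", "i3")))
#' gm <- SnpGenotypes(calls, sex = c("male", "female", "female"))
#' callRatio(gm)
#' @rdname GenotypeExperiment
#' @export
SnpGenotypes <- function(calls, sex, tags = NULL) {
  .newGenotypes("SnpGenotypes", calls, sex, tags)
}

#' @rdname GenotypeExperiment
#' @export
PAGenotypes <- function(calls, sex, tags = NULL) {
  .newGenotypes("PAGenotypes", calls, sex, tags)
}

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeExperiment", function(x)
  assay(x, "calls"))

#' @rdname accessors
#' @export
setMethod("sexes", "GenotypeExperiment", function(x)
  stats::setNames(colData(x)$sex, colnames(x)))

#' @rdname accessors
#' @export
setMethod("tagSequences", "GenotypeExperiment", function(x) {
  rd <- rowData(x)
  if (!("tag" %in% colnames(rd))) return(NULL)
  stats::setNames(rd$tag, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("lociIds", "GenotypeExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("individualIds", "GenotypeExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("markerClass", "SnpGenotypes", function(x) "SNP")

#' @rdname accessors
#' @export
setMethod("markerClass", "PAGenotypes", function(x) "PA")

setMethod("show", "GenotypeExperiment", function(object) {
  sx <- sexes(object)
  cat(sprintf("%s: %d loci x %d individuals (%d male, %d female, %d unknown)\n",
              class(object), nrow(object), ncol(object),
              sum(sx == "male"), sum(sx == "female"), sum(sx == "unknown")))
  if (!is.null(tagSequences(object)))
    cat(sprintf("  tags: %d bp (median)\n",
                stats::median(nchar(tagSequences(object)))))
})
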