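#' @importFrom methods setGeneric setClass setMethod setValidity new validObject is slot
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname accessors
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("markerClass", function(x) standardGeneric("markerClass"))

#' @rdname accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("discoveryThresholds", function(x) standardGeneric("discoveryThresholds"))

#' @rdname accessors
#' @export
setGeneric("discoveryCounts", function(x) standardGeneric("discoveryCounts"))

#' @rdname accessors
#' @export
setGeneric("trueTotal", function(x) standardGeneric("trueTotal"))

#' @rdname accessors
#' @export
setGeneric("perChromCounts", function(x) standardGeneric("perChromCounts"))

#' @rdname accessors
#' @export
setGeneric("modalChrom", function(x) standardGeneric("modalChrom"))

#' @rdname accessors
#' @export
setGeneric("modalFraction", function(x) standardGeneric("modalFraction"))

#' @rdname accessors
#' @export
setGeneric("modalPercent", function(x) standardGeneric("modalPercent"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("scenarioConfig", function(x) standardGeneric("scenarioConfig"))

#' @rdname accessors
#' @export
setGeneric("snpGenotypes", function(x) standardGeneric("snpGenotypes"))

#' @rdname accessors
#' @export
setGeneric("paGenotypes", function(x) standardGeneric("paGenotypes"))

#' @rdname accessors
#' @export
setGeneric("referenceGenome", function(x) standardGeneric("referenceGenome"))

#' Filter loci by call ratio
#'
#' @param x a [SnpGenotypes] or [PAGenotypes] object.
#' @param min_call_ratio minimum fraction of called (non-missing) genotypes
#'   among known-sex individuals; loci strictly below it are removed
#'   (the boundary passes).
#' @return `x` restricted to passing loci, input order preserved.
#' @export
setGeneric("filterCallRatio", function(x, min_call_ratio = 0.8)
  standardGeneric("filterCallRatio"))

#' Per-locus call ratio
#'
#' @param x a [SnpGenotypes] or [PAGenotypes] object.
#' @return named numeric vector, fraction of known-sex individuals with a
#'   non-missing call at each locus.
#' @export
setGeneric("callRatio", function(x) standardGeneric("callRatio"))
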