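# Sex chromosome assignment: align sex-linked marker tags to a reference
# genome, keep markers whose hits name a single chromosome, and call the sex
# chromosome as the modal chromosome among uniquely assigned markers,
# translated to the study species through a chromosome correspondence map.

# k-mer index of the reference: environment mapping each k-mer to encoded
# (chromosome, position) integers, plus the split character vectors used for
# ungapped identity scoring.
.referenceIndex <- function(reference, k) {
  seqs <- as.character(reference)
  lens <- nchar(seqs)
  if (any(lens < k))
    stop(sprintf("reference chromosome shorter than seed_k = %d", k))
  max_len <- max(lens)
  kmers <- vector("list", length(seqs))
  encs <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    n <- lens[ci] - k + 1L
    pos <- seq_len(n)
    kmers[[ci]] <- substring(seqs[ci], pos, pos + k - 1L)
    encs[[ci]] <- (ci - 1L) * max_len + pos
  }
  idx <- split(unlist(encs, use.names = FALSE),
               unlist(kmers, use.names = FALSE))
  list(env = list2env(idx, hash = TRUE, size = length(idx)),
       chars = strsplit(seqs, "", fixed = TRUE),
       chrom_ids = names(reference), lens = lens, max_len = max_len, k = k)
}

# Candidate full-tag placements for one oriented tag sequence against the
# index: all (chrom, start) pairs sharing an exact k-mer with the tag, with
# the whole tag on the chromosome.
.seedCandidates <- function(seq, idx) {
  tl <- nchar(seq)
  offs <- seq_len(tl - idx$k + 1L)
  kms <- substring(seq, offs, offs + idx$k - 1L)
  enc <- unlist(lapply(seq_along(kms), function(j) {
    hit <- get0(kms[j], envir = idx$env, ifnotfound = NULL)
    if (is.null(hit)) NULL else hit - (offs[j] - 1L)
  }), use.names = FALSE)
  if (is.null(enc)) return(NULL)
  # the seed's chromosome is recoverable from the seed encoding because the
  # offset shift never crosses a chromosome boundary for retained candidates
  enc <- unique(enc)
  chrom <- (enc - 1L) %/% idx$max_len + 1L
  start <- enc - (chrom - 1L) * idx$max_len
  keep <- start >= 1L & (start + tl - 1L) <= idx$lens[chrom]
  if (!any(keep)) return(NULL)
  data.frame(chrom = chrom[keep], start = start[keep])
}

#' Map marker tags to a reference genome
#'
#' The built-in stand-in for an external aligner: exact `seed_k`-mer seeding
#' against both strands followed by ungapped scoring of the full tag at each
#' seeded placement. A hit is reported when the whole tag fits on the
#' chromosome and its identity is at least `min_identity`; all qualifying
#' placements on all chromosomes are returned, ordered by query, chromosome
#' and start. Tags shorter than `seed_k` or `min_aln_length` are reported
#' unaligned (logged). Hits from an external BLAST run ingested with
#' [readAlignmentTab()] can substitute for this mapper everywhere downstream.
#'
#' @param tags a named `DNAStringSet` or named character vector of tag
#'   sequences (names are locus ids).
#' @param reference a named `DNAStringSet` of reference chromosomes (e.g. from
#'   [readReferenceFasta()] or [generateReference()]).
#' @param params a [MapperParams] object.
#' @return a `DataFrame` of hits with columns `query_id`, `chrom`, `start`,
#'   `end`, `strand`, `identity`, `aln_length` (1-based inclusive
#'   coordinates).
#' @export
mapTags <- function(tags, reference, params = MapperParams()) {
  validObject(params)
  if (is.character(tags)) tags <- Biostrings::DNAStringSet(tags)
  if (is.null(names(tags)) || anyDuplicated(names(tags)))
    stop("tags must carry unique locus ids as names")
  if (!length(tags)) return(.emptyHits())
  idx <- .referenceIndex(reference, params@seed_k)
  tag_chr <- unname(as.character(tags))
  rows <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    tl <- nchar(tag_chr[i])
    if (tl < params@seed_k || tl < params@min_aln_length) {
      .msg("mapTags: tag '%s' (%d bp) shorter than seed_k/min_aln_length; unaligned",
           names(tags)[i], tl)
      next
    }
    per_strand <- lapply(c("+", "-"), function(strand) {
      s <- if (strand == "+") tag_chr[i] else .reverseComplement(tag_chr[i])
      cand <- .seedCandidates(s, idx)
      if (is.null(cand)) return(NULL)
      schars <- strsplit(s, "", fixed = TRUE)[[1]]
      ident <- vapply(seq_len(nrow(cand)), function(r) {
        ref <- idx$chars[[cand$chrom[r]]]
        span <- cand$start[r]:(cand$start[r] + tl - 1L)
        sum(ref[span] == schars) / tl
      }, numeric(1))
      keep <- ident >= params@min_identity - 1e-12
      if (!any(keep)) return(NULL)
      data.frame(query_id = names(tags)[i],
                 chrom = idx$chrom_ids[cand$chrom[keep]],
                 start = cand$start[keep],
                 end = cand$start[keep] + tl - 1L,
                 strand = strand,
                 identity = ident[keep],
                 aln_length = tl,
                 stringsAsFactors = FALSE)
    })
    per_strand <- per_strand[!vapply(per_strand, is.null, logical(1))]
    if (length(per_strand)) rows[[i]] <- do.call(rbind, per_strand)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyHits())
  out <- do.call(rbind, rows)
  out <- out[order(match(out$query_id, names(tags)),
                   match(out$chrom, idx$chrom_ids),
                   out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}

#' Partition loci by chromosome uniqueness of their hits
#'
#' A locus is assigned to a chromosome only when all of its hits lie on
#' exactly one chromosome (multiple placements on that one chromosome still
#' count); loci hitting two or more chromosomes are set aside as
#' multi-chromosome, and loci without hits as unaligned.
#'
#' @param hits a hit `DataFrame` from [mapTags()] or [readAlignmentTab()].
#' @param locus_ids the full set of loci that were queried; defaults to the
#'   loci appearing in `hits` (in which case the unaligned set is empty).
#' @return list with `assigned` (named character vector, locus to chromosome),
#'   `multi_chrom` and `unaligned` (character vectors of locus ids).
#' @export
uniqueChromosomeAssignments <- function(hits, locus_ids = NULL) {
  if (is.null(locus_ids)) locus_ids <- unique(hits$query_id)
  chrom_by_locus <- split(hits$chrom, factor(hits$query_id, levels = locus_ids))
  n_chrom <- vapply(chrom_by_locus, function(ch) length(unique(ch)), integer(1))
  assigned_ids <- locus_ids[n_chrom == 1L]
  list(
    assigned = vapply(chrom_by_locus[assigned_ids], function(ch) ch[1],
                      character(1)),
    multi_chrom = locus_ids[n_chrom > 1L],
    unaligned = locus_ids[n_chrom == 0L]
  )
}

#' Summarize per-chromosome marker counts and the modal chromosome
#'
#' Accepts either the partition produced by [uniqueChromosomeAssignments()] or
#' a named vector of per-chromosome counts of uniquely assigned markers (as
#' printed in a per-chromosome bar chart). The modal chromosome is the one
#' attracting the most markers; ties are broken towards the smaller chromosome
#' id and flagged. The modal percentage is reported rounded half-up to one
#' decimal, the conventional printed style.
#'
#' @param assignments a list with an `assigned` element, or a named
#'   integer/numeric vector of per-chromosome counts.
#' @param n_multi_chrom,n_unaligned counts of multi-chromosome and unaligned
#'   markers; taken from `assignments` when it is a partition list.
#' @return an [AssignmentSummary-class].
#' @export
assignmentSummary <- function(assignments, n_multi_chrom = 0L,
                              n_unaligned = 0L) {
  if (is.list(assignments) && !is.null(assignments$assigned)) {
    counts_tb <- table(assignments$assigned)
    counts <- stats::setNames(as.integer(counts_tb), names(counts_tb))
    n_multi_chrom <- length(assignments$multi_chrom)
    n_unaligned <- length(assignments$unaligned)
  } else {
    if (is.null(names(assignments)) ||
        any(assignments < 0) || any(assignments != round(assignments)))
      stop("per-chromosome counts must be a named non-negative integer vector")
    counts <- stats::setNames(as.integer(assignments), names(assignments))
  }
  counts <- counts[.chromOrder(names(counts))]
  n_assigned <- sum(counts)
  if (n_assigned == 0L) {
    .msg("assignmentSummary: no uniquely assigned markers; modal fields undefined")
    return(new("AssignmentSummary",
               per_chrom_counts = counts, n_assigned = 0L,
               n_multi_chrom = as.integer(n_multi_chrom),
               n_unaligned = as.integer(n_unaligned),
               modal_chrom = NA_character_, modal_fraction = NA_real_,
               modal_percent_1dp = NA_real_, modal_tie = NA))
  }
  top <- which(counts == max(counts))
  tie <- length(top) > 1L
  if (tie)
    .msg("assignmentSummary: modal chromosome tied (%s); smallest id chosen",
         paste(names(counts)[top], collapse = ", "))
  modal <- names(counts)[top[1L]]
  frac <- counts[[modal]] / n_assigned
  new("AssignmentSummary",
      per_chrom_counts = counts, n_assigned = as.integer(n_assigned),
      n_multi_chrom = as.integer(n_multi_chrom),
      n_unaligned = as.integer(n_unaligned),
      modal_chrom = modal, modal_fraction = frac,
      modal_percent_1dp = roundHalfUp(100 * frac, 1), modal_tie = tie)
}

#' @rdname accessors
#' @export
setMethod("perChromCounts", "AssignmentSummary", function(x) x@per_chrom_counts)

#' @rdname accessors
#' @export
setMethod("modalChrom", "AssignmentSummary", function(x) x@modal_chrom)

#' @rdname accessors
#' @export
setMethod("modalFraction", "AssignmentSummary", function(x) x@modal_fraction)

#' @rdname accessors
#' @export
setMethod("modalPercent", "AssignmentSummary", function(x) x@modal_percent_1dp)

setMethod("show", "AssignmentSummary", function(object) {
  cat(sprintf("AssignmentSummary: %d uniquely assigned, %d multi-chromosome, %d unaligned\n",
              object@n_assigned, object@n_multi_chrom, object@n_unaligned))
  if (!is.na(object@modal_chrom))
    cat(sprintf("  modal chromosome %s: %d markers (%.1f%%)%s\n",
                object@modal_chrom,
                object@per_chrom_counts[[object@modal_chrom]],
                object@modal_percent_1dp,
                if (isTRUE(object@modal_tie)) " [tie]" else ""))
})

#' Default reference-to-species chromosome correspondence
#'
#' Correspondence between the *Rana temporaria* reference chromosomes carrying
#' the sex-linked markers and the chromosomes of the study species
#' (*R. tagoi* / *R. sakuraii*): reference chromosome 9 corresponds to species
#' chromosome 7, 4 to 3, and 13 to 13.
#'
#' @return named character vector mapping reference to species chromosome ids.
#' @export
defaultChromMap <- function() {
  c("9" = "7", "4" = "3", "13" = "13")
}

#' Call the sex chromosome from an assignment summary
#'
#' The sex chromosome is the modal reference chromosome, translated to the
#' study species through `chrom_map` (identity, logged, when the modal
#' chromosome has no entry). The call is confident when the modal fraction
#' reaches `min_fraction` and the modal chromosome carries at least
#' `min_markers` markers.
#'
#' @param summary an [AssignmentSummary-class] with defined modal fields.
#' @param chrom_map named character vector, reference id to species id.
#' @param min_fraction,min_markers confidence minima.
#' @return a [SexChromosomeCall-class].
#' @export
callSexChromosome <- function(summary, chrom_map = defaultChromMap(),
                              min_fraction = 0.5, min_markers = 3L) {
  .checkFraction(min_fraction, "min_fraction")
  if (is.na(summary@modal_chrom))
    stop("assignment summary has no assigned markers; cannot call a sex chromosome")
  ref <- summary@modal_chrom
  if (ref %in% names(chrom_map)) {
    species <- unname(chrom_map[[ref]])
  } else {
    species <- ref
    .msg("callSexChromosome: '%s' not in chromosome map; identity mapping used",
         ref)
  }
  confident <- summary@modal_fraction >= min_fraction &&
    summary@per_chrom_counts[[ref]] >= min_markers
  new("SexChromosomeCall",
      reference_chrom = ref, species_chrom = species,
      modal_fraction = summary@modal_fraction,
      n_assigned = summary@n_assigned, confident = confident)
}

#' @rdname accessors
#' @export
setMethod("modalFraction", "SexChromosomeCall", function(x) x@modal_fraction)

setMethod("show", "SexChromosomeCall", function(object) {
  cat(sprintf("SexChromosomeCall: reference %s -> species %s (%.1f%% of %d markers)%s\n",
              object@reference_chrom, object@species_chrom,
              100 * object@modal_fraction, object@n_assigned,
              if (object@confident) ", confident" else ", low confidence"))
})
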