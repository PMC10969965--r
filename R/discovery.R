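# Sex-linked marker discovery.
#
# A locus is a sex-linked candidate under a male-heterogametic (XY) system
# when males are heterozygous (SNP) or carry the fragment (PA) and females are
# homozygous (either class) or lack the fragment; under a female-heterogametic
# (ZW) system with the sexes swapped. Concordance is the fraction of called,
# known-sex individuals conforming to that expectation. Sub-100% thresholds
# absorb recombination between the sex chromosomes, phenotypic sex reversal,
# and genotyping error. The false-positive test exploits the fact that a truly
# Y- (or W-) limited allele is never observed homozygously: SNP candidates
# with too many homozygotes for the putative sex-limited allele are flagged.

# Vectorized per-locus, per-sex call counts for a genotype container.
.sexCallCounts <- function(x) {
  calls <- genotypeCalls(x)
  sx <- sexes(x)
  m <- sx == "male"
  f <- sx == "female"
  cm <- calls[, m, drop = FALSE]
  cf <- calls[, f, drop = FALSE]
  out <- list(
    locus_id = rownames(calls),
    n_male = sum(m), n_female = sum(f),
    called_m = rowSums(!is.na(cm)), called_f = rowSums(!is.na(cf))
  )
  if (markerClass(x) == "SNP") {
    for (g in 0:2) {
      out[[paste0("m", g)]] <- rowSums(cm == g, na.rm = TRUE)
      out[[paste0("f", g)]] <- rowSums(cf == g, na.rm = TRUE)
    }
  } else {
    out$m_pres <- rowSums(cm == 1L, na.rm = TRUE)
    out$f_pres <- rowSums(cf == 1L, na.rm = TRUE)
    out$m_abs <- out$called_m - out$m_pres
    out$f_abs <- out$called_f - out$f_pres
  }
  denom <- out$n_male + out$n_female
  out$call_ratio <- if (denom > 0) (out$called_m + out$called_f) / denom
                    else rep(NaN, nrow(calls))
  out
}

#' @rdname callRatio
#' @export
setMethod("callRatio", "GenotypeExperiment", function(x) {
  cc <- .sexCallCounts(x)
  stats::setNames(cc$call_ratio, cc$locus_id)
})

#' @rdname filterCallRatio
#' @export
setMethod("filterCallRatio", "GenotypeExperiment",
          function(x, min_call_ratio = 0.8) {
  .checkFraction(min_call_ratio, "min_call_ratio", min_open = TRUE)
  keep <- callRatio(x) >= min_call_ratio - 1e-12
  .msg("filterCallRatio: removed %d of %d %s loci below call ratio %.3g",
       sum(!keep), length(keep), markerClass(x), min_call_ratio)
  x[keep, ]
})

#' Per-locus call statistics
#'
#' Counts calls at one locus by sex (individuals of unknown sex excluded):
#' genotype counts per sex for SNP loci, presence/absence counts per sex for
#' PA loci, plus the call ratio over all known-sex individuals.
#'
#' @param x a [SnpGenotypes] or [PAGenotypes] object.
#' @param locus_id a locus identifier present in `x`.
#' @return a `LocusCallStats` list with elements `locus_id`, `marker_class`,
#'   `n_male`, `n_female`, `n_called_male`, `n_called_female`, `call_ratio`,
#'   and `males`/`females` named count vectors (`hom_ref`/`het`/`hom_alt` for
#'   SNP, `present`/`absent` for PA).
#' @export
locusCallStats <- function(x, locus_id) {
  i <- match(locus_id, lociIds(x))
  if (is.na(i)) stop(sprintf("unknown locus '%s'", locus_id))
  if (!any(sexes(x) %in% c("male", "female")))
    stop("at least one known-sex individual is required")
  cc <- .sexCallCounts(x)
  out <- list(locus_id = locus_id, marker_class = markerClass(x),
              n_male = cc$n_male, n_female = cc$n_female,
              n_called_male = unname(cc$called_m[i]),
              n_called_female = unname(cc$called_f[i]),
              call_ratio = unname(cc$call_ratio[i]))
  if (markerClass(x) == "SNP") {
    out$males <- c(hom_ref = unname(cc$m0[i]), het = unname(cc$m1[i]),
                   hom_alt = unname(cc$m2[i]))
    out$females <- c(hom_ref = unname(cc$f0[i]), het = unname(cc$f1[i]),
                     hom_alt = unname(cc$f2[i]))
  } else {
    out$males <- c(present = unname(cc$m_pres[i]), absent = unname(cc$m_abs[i]))
    out$females <- c(present = unname(cc$f_pres[i]), absent = unname(cc$f_abs[i]))
  }
  structure(out, class = "LocusCallStats")
}

#' @export
print.LocusCallStats <- function(x, ...) {
  cat(sprintf("LocusCallStats for %s (%s): call ratio %.3f\n",
              x$locus_id, x$marker_class, x$call_ratio))
  cat("  males:  ", paste(names(x$males), x$males, sep = "=", collapse = " "), "\n")
  cat("  females:", paste(names(x$females), x$females, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.concordanceResult <- function(stats, system, concordance, n_het, n_hom,
                               sex_limited_allele = NA_character_,
                               allele_tied = FALSE) {
  structure(list(locus_id = stats$locus_id, marker_class = stats$marker_class,
                 system = system, concordance = concordance,
                 n_conforming_heterogametic = n_het,
                 n_conforming_homogametic = n_hom,
                 sex_limited_allele = sex_limited_allele,
                 allele_tied = allele_tied),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("ConcordanceResult %s (%s, %s): %.4f (%d het-conforming + %d hom-conforming)\n",
              x$locus_id, x$marker_class, x$system, x$concordance,
              x$n_conforming_heterogametic, x$n_conforming_homogametic))
  if (x$marker_class == "SNP")
    cat(sprintf("  sex-limited allele: %s%s\n",
                ifelse(is.na(x$sex_limited_allele), "undefined",
                       x$sex_limited_allele),
                if (x$allele_tied) " (homozygote classes tied)" else ""))
  invisible(x)
}

.snpAlleleCall <- function(hom_ref_count, hom_alt_count) {
  # The sex-limited allele is the het allele NOT matching the majority
  # homozygote class of the homogametic sex; a tie leaves it undefined.
  if (hom_ref_count > hom_alt_count) list(allele = "alt", tied = FALSE)
  else if (hom_alt_count > hom_ref_count) list(allele = "ref", tied = FALSE)
  else list(allele = NA_character_, tied = TRUE)
}

#' SNP concordance under a hypothesized heterogamety system
#'
#' Conforming individuals are heterozygotes of the heterogametic sex and
#' homozygotes (either class) of the homogametic sex; concordance is their
#' count over all called, known-sex individuals. The sex-limited allele is the
#' heterozygote allele not matching the majority homozygote class of the
#' homogametic sex (undefined, and flagged, when the homozygote classes tie).
#'
#' @param stats a `LocusCallStats` for a SNP locus (see [locusCallStats()]).
#' @param heterogametic_sex `"male"` for XY, `"female"` for ZW.
#' @return a `ConcordanceResult` list.
#' @export
snpConcordance <- function(stats, heterogametic_sex = c("male", "female")) {
  heterogametic_sex <- match.arg(heterogametic_sex)
  stopifnot(inherits(stats, "LocusCallStats"), stats$marker_class == "SNP")
  if (stats$n_called_male < 1L || stats$n_called_female < 1L)
    stop(sprintf("locus '%s': both sexes need at least one called individual",
                 stats$locus_id))
  het <- if (heterogametic_sex == "male") stats$males else stats$females
  hom <- if (heterogametic_sex == "male") stats$females else stats$males
  n_het <- unname(het[["het"]])
  n_hom <- unname(hom[["hom_ref"]] + hom[["hom_alt"]])
  conc <- (n_het + n_hom) / (stats$n_called_male + stats$n_called_female)
  al <- .snpAlleleCall(hom[["hom_ref"]], hom[["hom_alt"]])
  .concordanceResult(stats,
                     system = if (heterogametic_sex == "male") "XY" else "ZW",
                     concordance = conc, n_het = n_het, n_hom = n_hom,
                     sex_limited_allele = al$allele, allele_tied = al$tied)
}

#' Presence/absence concordance for a sex-limited fragment
#'
#' For dominant markers the expectation under sex linkage is presence in the
#' heterogametic sex and absence in the homogametic sex. Conforming
#' individuals are those of `limited_to_sex` called present plus those of the
#' other sex called absent, over all called, known-sex individuals.
#'
#' @param stats a `LocusCallStats` for a PA locus.
#' @param limited_to_sex the sex hypothesized to carry the fragment
#'   (`"male"` for XY, `"female"` for ZW).
#' @return a `ConcordanceResult` list.
#' @export
paConcordance <- function(stats, limited_to_sex = c("male", "female")) {
  limited_to_sex <- match.arg(limited_to_sex)
  stopifnot(inherits(stats, "LocusCallStats"), stats$marker_class == "PA")
  if (stats$n_called_male < 1L || stats$n_called_female < 1L)
    stop(sprintf("locus '%s': both sexes need at least one called individual",
                 stats$locus_id))
  pres <- if (limited_to_sex == "male") stats$males else stats$females
  abs_ <- if (limited_to_sex == "male") stats$females else stats$males
  n_het <- unname(pres[["present"]])
  n_hom <- unname(abs_[["absent"]])
  conc <- (n_het + n_hom) / (stats$n_called_male + stats$n_called_female)
  .concordanceResult(stats,
                     system = if (limited_to_sex == "male") "XY" else "ZW",
                     concordance = conc, n_het = n_het, n_hom = n_hom)
}

# Vectorized classification of one matrix; returns a DataFrame of members.
.classifyMatrix <- function(x, threshold, min_called) {
  cc <- .sexCallCounts(x)
  n <- length(cc$locus_id)
  if (!n) return(NULL)
  called <- cc$called_m + cc$called_f
  scorable <- cc$called_m >= 1L & cc$called_f >= 1L
  if (any(!scorable))
    .msg("classifySexLinked: skipped %d %s locus/loci with a sex having zero calls",
         sum(!scorable), markerClass(x))
  if (markerClass(x) == "SNP") {
    c_xy <- (cc$m1 + cc$f0 + cc$f2) / called
    c_zw <- (cc$f1 + cc$m0 + cc$m2) / called
  } else {
    c_xy <- (cc$m_pres + cc$f_abs) / called
    c_zw <- (cc$f_pres + cc$m_abs) / called
  }
  eligible <- scorable & cc$called_m >= min_called & cc$called_f >= min_called
  best <- pmax(c_xy, c_zw)
  passes <- eligible & best >= threshold - 1e-12
  tied <- passes & abs(c_xy - c_zw) < 1e-12
  if (any(tied))
    .msg("classifySexLinked: dropped %d ambiguous locus/loci with tied XY/ZW concordance",
         sum(tied))
  member <- passes & !tied
  if (!any(member)) return(NULL)
  system <- unname(ifelse(c_xy[member] > c_zw[member], "XY", "ZW"))
  if (markerClass(x) == "SNP") {
    category <- ifelse(system == "XY", "male_het_snp", "female_het_snp")
    hom0 <- unname(ifelse(system == "XY", cc$f0[member], cc$m0[member]))
    hom2 <- unname(ifelse(system == "XY", cc$f2[member], cc$m2[member]))
    allele <- ifelse(hom0 > hom2, "alt", ifelse(hom2 > hom0, "ref",
                                                NA_character_))
  } else {
    category <- ifelse(system == "XY", "male_present_pa", "female_present_pa")
    allele <- NA_character_
  }
  S4Vectors::DataFrame(
    locus_id = cc$locus_id[member],
    marker_class = markerClass(x),
    system = system,
    category = category,
    concordance = unname(best[member]),
    sex_limited_allele = allele,
    fp_statistic = NA_real_,
    fp_flag = NA
  )
}

#' Classify sex-linked candidate loci
#'
#' Scores every locus under both the XY and ZW hypotheses and admits it to the
#' candidate set when the better concordance reaches `concordance_threshold`
#' (the boundary passes) and both sexes have at least `min_called_per_sex`
#' called individuals. The winning system and marker class set the category;
#' an exact XY/ZW tie drops the locus as ambiguous (logged). Run
#' [filterCallRatio()] beforehand to apply the call-ratio filter.
#'
#' @param snp a [SnpGenotypes] object (or `NULL`).
#' @param pa an optional [PAGenotypes] object; must share no locus ids with
#'   `snp`.
#' @param concordance_threshold minimum concordance for membership.
#' @param min_called_per_sex minimum called individuals per sex.
#' @return a [SexLinkedSet-class]; false-positive columns are `NA` until
#'   [falsePositiveTest()] is run.
#' @export
classifySexLinked <- function(snp, pa = NULL, concordance_threshold = 0.8,
                              min_called_per_sex = 3L) {
  .checkFraction(concordance_threshold, "concordance_threshold", min_open = TRUE)
  if (!is.null(snp) && !is.null(pa) &&
      length(intersect(lociIds(snp), lociIds(pa))))
    stop("SNP and PA matrices must share no locus ids")
  parts <- c(
    if (!is.null(snp)) list(.classifyMatrix(snp, concordance_threshold,
                                            min_called_per_sex)),
    if (!is.null(pa)) list(.classifyMatrix(pa, concordance_threshold,
                                           min_called_per_sex))
  )
  parts <- parts[!vapply(parts, is.null, logical(1))]
  tb <- if (length(parts)) do.call(rbind, parts) else
    S4Vectors::DataFrame(locus_id = character(0), marker_class = character(0),
                         system = character(0), category = character(0),
                         concordance = numeric(0),
                         sex_limited_allele = character(0),
                         fp_statistic = numeric(0), fp_flag = logical(0))
  new("SexLinkedSet", table = tb,
      thresholds = list(concordance_threshold = concordance_threshold,
                        min_called_per_sex = as.integer(min_called_per_sex),
                        fp_threshold = NA_real_))
}

#' @rdname accessors
#' @export
setMethod("markerTable", "SexLinkedSet", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("discoveryThresholds", "SexLinkedSet", function(x) x@thresholds)

#' @export
setMethod("length", "SexLinkedSet", function(x) nrow(x@table))

setMethod("show", "SexLinkedSet", function(object) {
  tb <- object@table
  cat(sprintf("SexLinkedSet: %d candidate locus/loci (threshold %.2f)\n",
              nrow(tb), object@thresholds$concordance_threshold))
  if (nrow(tb)) {
    counts <- table(factor(tb$category, levels = .CATEGORIES))
    for (k in names(counts)) cat(sprintf("  %-17s %d\n", k, counts[[k]]))
    if (!anyNA(tb$fp_flag))
      cat(sprintf("  false-positive flagged: %d\n", sum(tb$fp_flag)))
  }
})

#' Homozygosity-based false-positive test
#'
#' For each SNP candidate with a defined sex-limited allele `b`, the statistic
#' is the proportion of called, known-sex individuals (both sexes) homozygous
#' for `b`. Under true sex linkage `b` occurs only hemizygously on the Y (or
#' W), so the proportion is near zero; autosomal loci that slipped through the
#' concordance filter show `b/b` homozygotes. A locus is flagged when the
#' statistic exceeds `fp_threshold`, or when its sex-limited allele is
#' undefined. Dominant (PA) candidates are exempt: homozygosity is undefined
#' for them. Flagged loci remain in the set but are excluded from true-marker
#' counts.
#'
#' @param set a [SexLinkedSet-class] from [classifySexLinked()].
#' @param snp the [SnpGenotypes] matrix the set was built from.
#' @param fp_threshold flagging threshold on the homozygosity proportion.
#' @return the set with `fp_statistic` and `fp_flag` filled in.
#' @export
falsePositiveTest <- function(set, snp, fp_threshold = 0.05) {
  .checkFraction(fp_threshold, "fp_threshold")
  tb <- markerTable(set)
  is_snp <- tb$marker_class == "SNP"
  fp_stat <- rep(NA_real_, nrow(tb))
  fp_flag <- rep(FALSE, nrow(tb))
  if (any(is_snp)) {
    idx <- match(tb$locus_id[is_snp], lociIds(snp))
    if (anyNA(idx))
      stop("set contains SNP loci absent from the supplied matrix")
    calls <- genotypeCalls(snp)[idx, , drop = FALSE]
    known <- sexes(snp) %in% c("male", "female")
    calls <- calls[, known, drop = FALSE]
    n_called <- rowSums(!is.na(calls))
    b_state <- ifelse(tb$sex_limited_allele[is_snp] == "alt", 2L, 0L)
    n_bb <- rowSums(calls == matrix(b_state, nrow = length(idx),
                                    ncol = ncol(calls)), na.rm = TRUE)
    stat <- ifelse(n_called > 0, n_bb / n_called, NA_real_)
    undefined <- is.na(tb$sex_limited_allele[is_snp])
    stat[undefined] <- NA_real_
    fp_stat[is_snp] <- stat
    fp_flag[is_snp] <- undefined | (!is.na(stat) & stat > fp_threshold + 1e-12)
  }
  tb$fp_statistic <- fp_stat
  tb$fp_flag <- fp_flag
  thr <- set@thresholds
  thr$fp_threshold <- fp_threshold
  new("SexLinkedSet", table = tb, thresholds = thr)
}

#' Table-style discovery bookkeeping
#'
#' Summarizes a flagged [SexLinkedSet-class] into per-category counts of
#' initial members, false positives, and true markers (initial minus false
#' positive), plus the four-category grand total of true markers.
#'
#' @param set a [SexLinkedSet-class] with false-positive flags assigned.
#' @return a [DiscoverySummary-class].
#' @export
summarizeDiscovery <- function(set) {
  tb <- markerTable(set)
  if (anyNA(tb$fp_flag))
    stop("run falsePositiveTest() before summarizeDiscovery()")
  cat_f <- factor(tb$category, levels = .CATEGORIES)
  n_initial <- as.integer(table(cat_f))
  n_fp <- as.integer(table(cat_f[tb$fp_flag]))
  counts <- data.frame(category = .CATEGORIES,
                       n_initial = n_initial,
                       n_false_positive = n_fp,
                       n_true = n_initial - n_fp)
  new("DiscoverySummary", counts = counts,
      n_true_total = as.integer(sum(counts$n_true)))
}

#' Build a candidate set from per-category counts
#'
#' Constructs a [SexLinkedSet-class] containing `n_initial[k]` members of each
#' category, of which the first `n_false_positive[k]` are flagged. Useful for
#' redoing published-style bookkeeping when only the per-category counts of a
#' study are available, and for testing [summarizeDiscovery()].
#'
#' @param n_initial,n_false_positive integer vectors of length 4 in category
#'   order `male_het_snp`, `female_het_snp`, `male_present_pa`,
#'   `female_present_pa`. False positives are only defined for the two SNP
#'   categories.
#' @return a [SexLinkedSet-class] with flags assigned.
#' @export
sexLinkedSetFromCounts <- function(n_initial, n_false_positive = c(0, 0, 0, 0)) {
  stopifnot(length(n_initial) == 4L, length(n_false_positive) == 4L,
            all(n_false_positive <= n_initial))
  if (any(n_false_positive[3:4] > 0))
    stop("false positives are only defined for SNP categories")
  cat_rep <- rep(.CATEGORIES, times = n_initial)
  flagged <- unlist(lapply(1:4, function(k)
    seq_len(n_initial[k]) <= n_false_positive[k]), use.names = FALSE)
  if (!length(cat_rep)) flagged <- logical(0)
  is_snp <- cat_rep %in% .CATEGORIES[1:2]
  tb <- S4Vectors::DataFrame(
    locus_id = sprintf("locus_%04d", seq_along(cat_rep)),
    marker_class = ifelse(is_snp, "SNP", "PA"),
    system = ifelse(cat_rep %in% c("male_het_snp", "male_present_pa"),
                    "XY", "ZW"),
    category = cat_rep,
    concordance = rep(1, length(cat_rep)),
    sex_limited_allele = ifelse(is_snp, "alt", NA_character_),
    fp_statistic = ifelse(is_snp, ifelse(flagged, 1, 0), NA_real_),
    fp_flag = flagged
  )
  new("SexLinkedSet", table = tb,
      thresholds = list(concordance_threshold = 1, min_called_per_sex = NA,
                        fp_threshold = 0.05))
}

#' @rdname accessors
#' @export
setMethod("discoveryCounts", "DiscoverySummary", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("trueTotal", "DiscoverySummary", function(x) x@n_true_total)

setMethod("show", "DiscoverySummary", function(object) {
  cat("DiscoverySummary (initial - false positive = true):\n")
  print(object@counts, row.names = FALSE)
  cat(sprintf("  total true sex-linked markers: %d\n", object@n_true_total))
})
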