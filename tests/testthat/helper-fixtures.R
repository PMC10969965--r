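# Fixture builders and independent oracles shared across test files.
# All fixtures are generated in code; nothing is read from disk.

# SNP matrix from a compact spec: list of per-locus call vectors
# (0/1/2/NA), plus a sex vector.
makeSnp <- function(rows, sex, tags = NULL) {
  calls <- do.call(rbind, rows)
  rownames(calls) <- if (is.null(names(rows)))
    sprintf("L%02d", seq_along(rows)) else names(rows)
  colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  SnpGenotypes(calls, sex, tags = tags)
}

makePa <- function(rows, sex, tags = NULL) {
  calls <- do.call(rbind, rows)
  rownames(calls) <- if (is.null(names(rows)))
    sprintf("P%02d", seq_along(rows)) else names(rows)
  colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  PAGenotypes(calls, sex, tags = tags)
}

# A locus vector with the given per-sex genotypes, males first.
lv <- function(males, females) c(males, females)

randomSnpMatrix <- function(n_loci, n_ind, missing_p = 0.15) {
  calls <- matrix(sample(c(0:2, NA), n_loci * n_ind, replace = TRUE,
                         prob = c(rep((1 - missing_p) / 3, 3), missing_p)),
                  nrow = n_loci,
                  dimnames = list(sprintf("L%02d", seq_len(n_loci)),
                                  sprintf("i%02d", seq_len(n_ind))))
  sex <- sample(c("male", "female"), n_ind, replace = TRUE)
  # guarantee both sexes
  sex[1] <- "male"; sex[n_ind] <- "female"
  SnpGenotypes(calls, sex)
}

randomPaMatrix <- function(n_loci, n_ind, missing_p = 0.15) {
  calls <- matrix(sample(c(0:1, NA), n_loci * n_ind, replace = TRUE,
                         prob = c(rep((1 - missing_p) / 2, 2), missing_p)),
                  nrow = n_loci,
                  dimnames = list(sprintf("P%02d", seq_len(n_loci)),
                                  sprintf("i%02d", seq_len(n_ind))))
  sex <- sample(c("male", "female"), n_ind, replace = TRUE)
  sex[1] <- "male"; sex[n_ind] <- "female"
  PAGenotypes(calls, sex)
}

# --- independent concordance oracle: explicit loop over individuals --------
# Counts conforming individuals one by one, with no shared code with the
# package's vectorized implementation.
bruteConcordance <- function(calls_row, sex, heterogametic_sex, marker_class) {
  conforming <- 0L
  called <- 0L
  for (j in seq_along(calls_row)) {
    if (!(sex[j] %in% c("male", "female"))) next
    g <- calls_row[j]
    if (is.na(g)) next
    called <- called + 1L
    is_het_sex <- sex[j] == heterogametic_sex
    ok <- if (marker_class == "SNP") {
      if (is_het_sex) g == 1L else g %in% c(0L, 2L)
    } else {
      if (is_het_sex) g == 1L else g == 0L
    }
    if (ok) conforming <- conforming + 1L
  }
  conforming / called
}

# --- independent mapper oracle: exhaustive position/strand scan ------------
# A hit is expected wherever the full tag fits, identity >= min_identity,
# and the alignment contains an exact run of >= seed_k matches (the mapper's
# documented seeding guarantee). Run length is computed with rle(), not the
# mapper's k-mer index.
bruteMapScan <- function(tag, reference, seed_k, min_identity) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- list()
  tl <- nchar(tag)
  for (ci in seq_along(reference)) {
    ref <- as.character(reference[[ci]])
    rchars <- strsplit(ref, "")[[1]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") tag else revcomp(tag)
      schars <- strsplit(s, "")[[1]]
      for (start in seq_len(max(0L, nchar(ref) - tl + 1L))) {
        eq <- rchars[start:(start + tl - 1L)] == schars
        ident <- mean(eq)
        runs <- rle(eq)
        max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
        if (ident >= min_identity - 1e-12 && max_run >= seed_k) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = names(reference)[ci], start = start,
            end = start + tl - 1L, strand = strand, identity = ident)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Mutate a sequence at n_mut distinct positions (to a different base).
mutateSeq <- function(seq, n_mut) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
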