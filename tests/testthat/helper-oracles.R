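# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use naive algorithms (iterative string splicing,
# per-marker loops, exhaustive enumeration) so they share no code path
# with the implementation they check.

random_genome <- function(n, contigs = 1, prefix = "chr") {
  seqs <- vapply(seq_len(contigs), function(i)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0(prefix, seq_len(contigs))
  seqs
}

# apply trimmed edits one at a time, right to left, by plain substring
# surgery
oracle_splice <- function(seq, edits) {
  for (i in order(edits$start0, decreasing = TRUE)) {
    s <- edits$start0[i]
    seq <- paste0(substr(seq, 1, s), edits$replacement[i],
                  substr(seq, s + edits$oldLen[i] + 1, nchar(seq)))
  }
  seq
}

# brute-force old->new position map: tag every old base with its index,
# replay the edits on the tag vector (same-length edits keep tags, as a
# replaced base is still an aligned position), then look indices up
oracle_position_map <- function(L, edits) {
  tags <- as.list(seq_len(L))
  for (i in order(edits$start0, decreasing = TRUE)) {
    s <- edits$start0[i]; ol <- edits$oldLen[i]
    nl <- nchar(edits$replacement[i])
    insert <- if (ol == nl) tags[seq(s + 1, length.out = ol)]
              else as.list(rep(NA_integer_, nl))
    tags <- c(tags[seq_len(s)], insert,
              if (s + ol < length(tags)) tags[seq(s + ol + 1, length(tags))])
  }
  flat <- unlist(tags)
  map <- rep(NA_integer_, L)
  ok <- !is.na(flat)
  map[flat[ok]] <- which(ok)
  map      # map[oldPos] = newPos or NA
}

# random non-overlapping substitution records (VCF-style, untrimmed) on a
# genome; returns a SubstitutionSet
random_substitutions <- function(seqs, nPerContig = 10, indelProb = 0.4,
                                 maxIndel = 6) {
  rows <- list()
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    gap <- maxIndel + 2
    cand <- seq(gap, L - gap, by = gap)
    pos <- sort(sample(cand, min(nPerContig, length(cand))))
    for (p in pos) {
      base <- substr(seqs[[ch]], p, p)
      if (runif(1) < indelProb) {
        len <- sample(maxIndel, 1)
        if (runif(1) < 0.5) {
          ref <- substr(seqs[[ch]], p, p + len); alt <- base
        } else {
          ref <- base
          alt <- paste0(base, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
        }
      } else {
        ref <- base
        alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = p, ref = ref, alt = alt,
        AC = 3L, AN = 4L, AF = 0.75, stringsAsFactors = FALSE)
    }
  }
  e <- do.call(rbind, rows)
  e <- e[order(e$chrom, e$pos), ]
  rownames(e) <- NULL
  new("SubstitutionSet", edits = e, threshold = 0.5)
}

# per-genotype-string allele recount, independent of gt_alleles()
oracle_af <- function(gtRow) {
  alleles <- unlist(strsplit(gtRow, "[/|]"))
  alleles <- sub(":.*", "", alleles)
  called <- alleles != "."
  c(AC = sum(alleles[called] == "1"), AN = sum(called))
}

# per-pair per-marker IBS loop
oracle_ibs <- function(gm) {
  n <- nrow(gm)
  d <- matrix(0, n, n, dimnames = list(rownames(gm), rownames(gm)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shared <- 0; valid <- 0
    for (m in seq_len(ncol(gm))) {
      a <- gm[i, m]; b <- gm[j, m]
      if (is.na(a) || is.na(b)) next
      valid <- valid + 1
      shared <- shared + (2 - abs(a - b))
    }
    d[i, j] <- d[j, i] <- 1 - shared / (2 * valid)
  }
  d
}

# enumerate every (pos, ref, alt) representation of a variant that yields
# the same applied haplotype on a window, and return the unique
# irreducible (left-aligned, minimal) one
oracle_normalize <- function(win, pos, ref, alt, maxLen = 12) {
  H <- paste0(substr(win, 1, pos - 1), alt,
              substr(win, pos + nchar(ref), nchar(win)))
  out <- NULL
  for (p in seq_len(nchar(win))) {
    for (lr in seq_len(min(maxLen, nchar(win) - p + 1))) {
      r <- substr(win, p, p + lr - 1)
      la <- nchar(H) - (p - 1) - (nchar(win) - (p + lr - 1))
      if (la < 1 || la > maxLen) next
      a <- substr(H, p, p + la - 1)
      cand <- paste0(substr(win, 1, p - 1), a,
                     substr(win, p + lr, nchar(win)))
      if (cand != H) next
      lastEq <- substr(r, lr, lr) == substr(a, la, la)
      firstEq <- substr(r, 1, 1) == substr(a, 1, 1)
      redTrail <- lastEq && (min(lr, la) > 1 || p > 1)
      redLead <- firstEq && lr > 1 && la > 1
      if (!redTrail && !redLead)
        out <- rbind(out, data.frame(pos = p, ref = r, alt = a,
                                     stringsAsFactors = FALSE))
    }
  }
  out <- unique(out)
  stopifnot(nrow(out) == 1)
  out
}

# tiny single-chromosome cohort builder
mini_cohort <- function(gt, chrom = "chr1", pos = NULL, ref = "A",
                        alt = "G") {
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq(10, by = 20, length.out = n)
  cohortSites(data.frame(chrom = chrom, pos = pos, id = ".",
                         ref = rep_len(ref, n), alt = rep_len(alt, n),
                         stringsAsFactors = FALSE), gt)
}

gt_matrix <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  m
}
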