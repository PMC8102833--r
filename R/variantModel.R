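## Variant data model: chromosome-name harmonization, multiallelic
## decomposition, left-alignment/minimal representation, variant keys.

#' Harmonize chromosome names to one dialect
#'
#' VCFs and external catalogs mix "1"/"chr1" naming and "MT"/"chrM" for the
#' mitochondrion.  All keys in this package use a single dialect so that
#' set operations across files are well defined.
#'
#' @param name character vector of contig labels.
#' @param contigs optional character vector of declared contig labels (in
#'   the target dialect); any harmonized name absent from it is an error.
#' @param style `"chr"` (default, "chr"-prefixed, mitochondrion "chrM") or
#'   `"plain"` (no prefix, mitochondrion "MT").
#' @return character vector of harmonized labels.  Idempotent.
#' @examples
#' harmonizeChrom(c("1", "chr1", "MT"))
#' @export
harmonizeChrom <- function(name, contigs = NULL, style = c("chr", "plain")) {
  style <- match.arg(style)
  if (any(!nzchar(name) | is.na(name))) stop("contig labels must be non-empty")
  bare <- sub("^chr", "", name)
  bare[bare %in% c("MT", "M")] <- if (style == "chr") "M" else "MT"
  out <- if (style == "chr") paste0("chr", bare) else bare
  if (!is.null(contigs)) {
    miss <- setdiff(unique(out), contigs)
    if (length(miss) > 0)
      stop("unknown contig label(s): ", paste(miss, collapse = ", "))
  }
  out
}

#' Canonical key for a normalized biallelic variant
#'
#' @param chrom,pos,ref,alt variant fields (vectors recycled together).
#' @param harmonize harmonize `chrom` first (default TRUE).
#' @param style chromosome dialect passed to [harmonizeChrom()].
#' @return character vector `"chrom:pos:ref:alt"`; equal variants map to
#'   equal keys regardless of the input file's chromosome dialect.
#' @export
variantKey <- function(chrom, pos, ref, alt, harmonize = TRUE, style = "chr") {
  if (harmonize) chrom <- harmonizeChrom(chrom, style = style)
  paste(chrom, pos, ref, alt, sep = ":")
}

## ---- GT string parsing -----------------------------------------------------
## GT matrices contain few distinct strings; parse each unique string once.

parse_gt_strings <- function(u) {
  # returns a 2-column integer matrix of allele indices (NA = missing / absent
  # second allele for haploid calls)
  core <- sub(":.*", "", u)
  parts <- strsplit(core, "[/|]")
  a1 <- vapply(parts, function(p) p[1], "")
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  conv <- function(a) {
    a[a == "." | a == ""] <- NA_character_
    suppressWarnings(as.integer(a))
  }
  cbind(conv(a1), conv(a2))
}

# split a GT matrix into two allele-index matrices (same dim, NA = missing)
gt_alleles <- function(geno) {
  u <- unique(as.vector(geno))
  tab <- parse_gt_strings(u)
  idx <- match(geno, u)
  a1 <- matrix(tab[idx, 1], nrow = nrow(geno), ncol = ncol(geno),
               dimnames = dimnames(geno))
  a2 <- matrix(tab[idx, 2], nrow = nrow(geno), ncol = ncol(geno),
               dimnames = dimnames(geno))
  list(a1 = a1, a2 = a2,
       phased = matrix(grepl("|", geno, fixed = TRUE), nrow = nrow(geno)))
}

make_gt_string <- function(a1, a2) {
  s1 <- ifelse(is.na(a1), ".", as.character(a1))
  s2 <- ifelse(is.na(a2), ".", as.character(a2))
  out <- paste0(s1, "/", s2)
  hap <- is.na(a2) & !is.na(a1)
  out[hap] <- s1[hap]
  out
}

## ---- multiallelic decomposition --------------------------------------------

#' Decompose multiallelic sites into biallelic records
#'
#' Each site with k alternate alleles becomes k biallelic records.  In the
#' record for alternate allele a, genotype indices referring to *other*
#' alternates are recoded to the reference-like (non-carrier) state, so each
#' record's AC counts only allele a while AN still counts all called
#' alleles.  Summed alt-allele carriage over the outputs equals carriage in
#' the input, and per-site alternate AFs sum to at most 1 — which is what
#' guarantees at most one majority alternate per site.
#'
#' @param x a [CohortSites-class] object.
#' @return a [CohortSites-class] object in which every site is biallelic;
#'   a `provenance` column names the originating site.
#' @export
decomposeSites <- function(x) {
  stopifnot(is(x, "CohortSites"))
  s <- x@sites
  if (nrow(s) == 0) return(x)
  altList <- strsplit(s$alt, ",", fixed = TRUE)
  nAlt <- lengths(altList)
  if (any(nAlt < 1)) stop("every site must have at least one alternate allele")
  if (all(nAlt == 1)) {
    out <- x
    out@sites$provenance <- variantKey(s$chrom, s$pos, s$ref, s$alt,
                                       harmonize = FALSE)
    return(out)
  }
  al <- gt_alleles(x@geno)
  rows <- rep(seq_len(nrow(s)), nAlt)         # site row for each output record
  altIdx <- unlist(lapply(nAlt, seq_len))     # which alt the record carries
  newSites <- data.frame(chrom = s$chrom[rows], pos = s$pos[rows],
                         id = s$id[rows], ref = s$ref[rows],
                         alt = unlist(altList),
                         provenance = variantKey(s$chrom, s$pos, s$ref, s$alt,
                                                 harmonize = FALSE)[rows],
                         stringsAsFactors = FALSE)
  recode <- function(a, target) {
    # allele index == target -> 1, any other called allele -> 0, NA stays
    out <- integer(length(a))
    out[is.na(a)] <- NA_integer_
    out[!is.na(a) & a == target] <- 1L
    out
  }
  n <- length(rows)
  geno <- matrix(NA_character_, nrow = n, ncol = ncol(x@geno),
                 dimnames = list(NULL, colnames(x@geno)))
  passthrough <- nAlt[rows] == 1L   # biallelic sites need no recoding
  geno[passthrough, ] <- x@geno[rows[passthrough], , drop = FALSE]
  for (r in which(!passthrough)) {
    i <- rows[r]
    geno[r, ] <- make_gt_string(recode(al$a1[i, ], altIdx[r]),
                                recode(al$a2[i, ], altIdx[r]))
  }
  cohortSites(newSites, geno)
}

## ---- normalization ---------------------------------------------------------

fetch_ref <- function(genomeChar, chrom, start, end) {
  if (!chrom %in% names(genomeChar)) stop("contig absent from genome: ", chrom)
  substr(genomeChar[[chrom]], start, end)
}

normalize_one <- function(chrom, pos, ref, alt, seqChar) {
  # left-align + minimal representation (the vt/bcftools algorithm):
  # repeatedly trim identical trailing bases, extending left with the
  # preceding reference base whenever ref or alt would become empty; then
  # trim identical leading bases while both alleles stay non-empty.
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      if (pos == 1) stop("cannot extend past contig start at ", chrom, ":", pos)
      pos <- pos - 1
      b <- substr(seqChar, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    }
    if (last(ref) == last(alt)) {
      if (nchar(ref) == 1 || nchar(alt) == 1) {
        if (pos == 1) break
        pos <- pos - 1
        b <- substr(seqChar, pos, pos)
        ref <- paste0(b, substr(ref, 1, nchar(ref) - 1))
        alt <- paste0(b, substr(alt, 1, nchar(alt) - 1))
      } else {
        ref <- substr(ref, 1, nchar(ref) - 1)
        alt <- substr(alt, 1, nchar(alt) - 1)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-align and trim biallelic variants
#'
#' Produces the unique left-aligned minimal representation of each variant
#' against its reference context: identical trailing bases are trimmed
#' (extending leftwards with the preceding reference base whenever an
#' allele would empty out), then identical leading bases are trimmed while
#' both alleles remain non-empty.  Idempotent; applying the variant to the
#' reference yields the same haplotype before and after.
#'
#' @param chrom,pos,ref,alt vectors describing biallelic variants
#'   (1-based VCF-style positions).
#' @param genome a [Biostrings::DNAStringSet] (or named character vector of
#'   sequences) providing the reference context.
#' @return data.frame with normalized `chrom`, `pos`, `ref`, `alt`.
#' @export
normalizeVariants <- function(chrom, pos, ref, alt, genome) {
  seqs <- genome_as_char(genome)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  outPos <- integer(n); outRef <- character(n); outAlt <- character(n)
  for (i in seq_len(n)) {
    sc <- seqs[[chrom[i]]]
    if (is.null(sc)) stop("contig absent from genome: ", chrom[i])
    obs <- substr(sc, pos[i], pos[i] + nchar(ref[i]) - 1)
    if (!identical(obs, ref[i]))
      stop(sprintf("reference mismatch at %s:%d (variant ref %s, genome %s)",
                   chrom[i], pos[i], ref[i], obs))
    # fast path: already minimal SNP
    if (nchar(ref[i]) == 1 && nchar(alt[i]) == 1 && ref[i] != alt[i]) {
      outPos[i] <- pos[i]; outRef[i] <- ref[i]; outAlt[i] <- alt[i]
      next
    }
    v <- normalize_one(chrom[i], pos[i], ref[i], alt[i], sc)
    outPos[i] <- v$pos; outRef[i] <- v$ref; outAlt[i] <- v$alt
  }
  data.frame(chrom = chrom, pos = outPos, ref = outRef, alt = outAlt,
             stringsAsFactors = FALSE)
}

#' Normalize all sites of a cohort
#'
#' Convenience wrapper: decomposes multiallelic sites, then left-aligns
#' each resulting biallelic record against the genome.
#'
#' @param x a [CohortSites-class] object.
#' @param genome reference sequences (DNAStringSet or named character).
#' @return a biallelic, normalized [CohortSites-class] object.
#' @export
normalizeCohort <- function(x, genome) {
  x <- decomposeSites(x)
  s <- x@sites
  if (nrow(s) == 0) return(x)
  norm <- normalizeVariants(s$chrom, s$pos, s$ref, s$alt, genome)
  x@sites$pos <- norm$pos
  x@sites$ref <- norm$ref
  x@sites$alt <- norm$alt
  x
}

# coerce DNAStringSet / character genome to a plain named character list
genome_as_char <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.list(as.character(genome))
    names(out) <- sub(" .*", "", names(genome))
    out
  } else if (is.character(genome)) {
    as.list(genome)
  } else if (is.list(genome)) {
    genome
  } else stop("genome must be a DNAStringSet or named character vector")
}
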