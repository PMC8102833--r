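## Cohort allele frequencies, AF spectrum, majority-allele site selection.

#' Compute cohort allele frequencies
#'
#' For each biallelic site: AC = number of alternate alleles among called
#' (non-missing) genotype alleles, AN = number of called alleles,
#' AF = AC/AN.  Missing alleles (`.`) never enter AN; hemizygous calls
#' contribute a single allele.  Sites with AN = 0 are dropped with a
#' warning.
#'
#' @param x a biallelic [CohortSites-class] object (run
#'   [decomposeSites()] / [normalizeCohort()] first).
#' @return An [AfTable-class] object, one record per retained site.
#' @examples
#' cs <- cohortSites(
#'   data.frame(chrom = "chr1", pos = 100, id = ".", ref = "A", alt = "G"),
#'   matrix(c("0/0", "0/1", "1/1", "./."), nrow = 1,
#'          dimnames = list(NULL, paste0("s", 1:4))))
#' afRecords(computeAf(cs))  # AC 3, AN 6, AF 0.5
#' @export
computeAf <- function(x) {
  stopifnot(is(x, "CohortSites"))
  s <- x@sites
  if (any(grepl(",", s$alt, fixed = TRUE)))
    stop("multiallelic sites present; run decomposeSites() first")
  al <- gt_alleles(x@geno)
  AC <- rowSums(al$a1 == 1L, na.rm = TRUE) + rowSums(al$a2 == 1L, na.rm = TRUE)
  AN <- rowSums(!is.na(al$a1)) + rowSums(!is.na(al$a2))
  keep <- AN > 0
  if (any(!keep))
    warning(sum(!keep), " site(s) dropped with AN = 0 (no called alleles)")
  afTable(data.frame(chrom = s$chrom[keep], pos = s$pos[keep],
                     ref = s$ref[keep], alt = s$alt[keep],
                     AC = as.integer(AC[keep]), AN = as.integer(AN[keep]),
                     AF = AC[keep] / AN[keep], stringsAsFactors = FALSE))
}

AF_CATEGORIES <- c("rare_alt", "common_alt", "common_ref",
                   "rare_or_unobserved_ref")

#' Classify an alternate allele frequency into the four spectrum categories
#'
#' Rare alternate (< 5%), common alternate (5-50%), common reference
#' (50-95%), rare-or-unobserved reference (>= 95%).  The 0.5 boundary
#' belongs to the common-alternate bin, consistent with the strict > 50%
#' majority rule used for substitution.  AF = 1 sites fall in the last
#' category and are additionally tracked as the fixed-alternate sub-count
#' by [afSpectrum()].
#'
#' @param af numeric vector of allele frequencies in `[0, 1]`.
#' @return factor with levels `rare_alt`, `common_alt`, `common_ref`,
#'   `rare_or_unobserved_ref`.
#' @export
classifyAfBin <- function(af) {
  if (any(is.na(af) | af < 0 | af > 1)) stop("AF must lie in [0, 1]")
  out <- character(length(af))
  out[af < 0.05] <- "rare_alt"
  out[af >= 0.05 & af <= 0.5] <- "common_alt"
  out[af > 0.5 & af < 0.95] <- "common_ref"
  out[af >= 0.95] <- "rare_or_unobserved_ref"
  factor(out, levels = AF_CATEGORIES)
}

#' Allele-frequency spectrum
#'
#' Bins AF values into 20 intervals of width 0.05 (last bin closed at 1)
#' and tallies the four spectrum categories plus the fixed-alternate
#' (AF = 1) sub-count.  Invariant under record order.
#'
#' @param x an [AfTable-class] object or a numeric vector of AFs.
#' @return An [AfSpectrum-class] object.
#' @export
afSpectrum <- function(x) {
  af <- if (is(x, "AfTable")) x@records$AF else as.numeric(x)
  if (any(is.na(af) | af < 0 | af > 1)) stop("AF must lie in [0, 1]")
  edges <- seq(0, 1, by = 0.05)
  bin <- findInterval(af, edges, rightmost.closed = TRUE)  # 1..20
  counts <- tabulate(bin, nbins = 20L)
  n <- length(af)
  hist <- data.frame(bin_low = edges[-21], bin_high = edges[-1],
                     count = counts,
                     fraction = if (n > 0) counts / n else rep(0, 20))
  cats <- table(classifyAfBin(af))
  new("AfSpectrum",
      histogram = hist,
      categories = stats::setNames(as.integer(cats), names(cats)),
      fixedAlt = sum(af == 1),
      total = n)
}

#' Select major-alternate-allele substitution sites
#'
#' Returns the sites whose cohort alternate AF strictly exceeds the
#' majority threshold — the edits that define the major-allele reference.
#' At the default threshold the comparison is the exact rational test
#' `2*AC > AN`, so 50% ties are reproducibly excluded.  Under the
#' decomposition accounting (per-site alternate AFs sum to <= 1) at most
#' one alternate per original site can qualify; this is asserted.
#'
#' @param x an [AfTable-class] object of normalized biallelic records.
#' @param threshold majority threshold (default 0.5, strict).
#' @return A [SubstitutionSet-class] object, sorted per chromosome.
#' @export
selectMajorSites <- function(x, threshold = 0.5) {
  stopifnot(is(x, "AfTable"))
  r <- x@records
  keep <- if (identical(threshold, 0.5)) 2L * r$AC > r$AN
          else r$AC > threshold * r$AN
  e <- r[keep, , drop = FALSE]
  if (anyDuplicated(paste(e$chrom, e$pos, e$ref)))
    stop("multiple majority alternates at one site; decomposition accounting violated")
  e <- e[order(e$chrom, e$pos), , drop = FALSE]
  rownames(e) <- NULL
  new("SubstitutionSet", edits = e, threshold = threshold)
}
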