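## Per-sample heterozygosity statistics, inbreeding coefficient,
## correlation with admixture, population-specific variant filters.

#' Per-sample heterozygosity and inbreeding statistics
#'
#' Counts heterozygous, homozygous-alternate and homozygous-reference
#' genotypes per sample over biallelic sites; the het/hom ratio uses the
#' homozygous non-reference count as denominator (standard QC convention)
#' and is NA when that count is zero.  The inbreeding coefficient is the
#' method-of-moments estimator `F = 1 - O_het / E_het`, with
#' `E_het = sum over the sample's called sites of 2 p (1 - p)` and p the
#' cohort alternate AF at the site (no small-sample correction).
#'
#' @param x a biallelic [CohortSites-class] object.
#' @param af an [AfTable-class] of cohort AFs covering the sites; computed
#'   from `x` when NULL.
#' @return data.frame with one row per sample: `sample`, `n_het`,
#'   `n_hom_alt`, `n_hom_ref`, `het_hom_ratio`, `inbreeding_f`.
#' @export
sampleStats <- function(x, af = NULL) {
  stopifnot(is(x, "CohortSites"))
  if (is.null(af)) af <- computeAf(x)
  s <- x@sites
  key <- variantKey(s$chrom, s$pos, s$ref, s$alt, harmonize = FALSE)
  r <- af@records
  p <- r$AF[match(key, variantKey(r$chrom, r$pos, r$ref, r$alt,
                                  harmonize = FALSE))]
  if (any(is.na(p)))
    stop("cohort AF table does not cover all sites")
  al <- gt_alleles(x@geno)
  called <- !is.na(al$a1) & !is.na(al$a2)
  het <- called & al$a1 != al$a2
  homAlt <- called & al$a1 == 1L & al$a2 == 1L
  homRef <- called & al$a1 == 0L & al$a2 == 0L
  nHet <- colSums(het)
  nHomAlt <- colSums(homAlt)
  nHomRef <- colSums(homRef)
  eHet <- as.vector(t(called) %*% (2 * p * (1 - p)))
  data.frame(sample = sampleIds(x),
             n_het = as.integer(nHet),
             n_hom_alt = as.integer(nHomAlt),
             n_hom_ref = as.integer(nHomRef),
             het_hom_ratio = ifelse(nHomAlt > 0, nHet / nHomAlt, NA_real_),
             inbreeding_f = ifelse(eHet > 0, 1 - nHet / eHet, NA_real_),
             row.names = NULL)
}

#' Pearson product-moment correlation
#'
#' Validating wrapper around the standard estimator, used for relating
#' per-sample inbreeding to admixture proportions.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least three observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y, method = "pearson")
}

#' Population-specific variant filter
#'
#' Keeps records that are common in the cohort (`af > cohortMin`) and rare
#' or missing in every external population (`external AF < externalMax`,
#' with NA counting as rare).  Thresholds are strict, idempotent and
#' order-insensitive by construction.
#'
#' @param records data.frame of annotated AF records.
#' @param cohortMin cohort AF threshold (strictly greater; default 0.05).
#' @param externalMax external AF ceiling (strictly less; default 0.01).
#' @param afCol name of the cohort AF column (default `"af"`).
#' @param externalCols names of the external population AF columns; by
#'   default every numeric column other than `afCol`.
#' @return the filtered data.frame.
#' @export
populationSpecificFilter <- function(records, cohortMin = 0.05,
                                     externalMax = 0.01, afCol = "af",
                                     externalCols = NULL) {
  if (!afCol %in% names(records)) stop("no cohort AF column '", afCol, "'")
  if (is.null(externalCols))
    externalCols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                            c(afCol, "pos", "AC", "AN"))
  keep <- records[[afCol]] > cohortMin
  for (cc in externalCols) {
    v <- records[[cc]]
    keep <- keep & (is.na(v) | v < externalMax)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loss-of-function variant filter
#'
#' Keeps records with the requested impact severity and cohort AF above
#' the threshold.  Composable with [populationSpecificFilter()] to obtain
#' the "common here, rare elsewhere" loss-of-function list.
#'
#' @param records data.frame of annotated records.
#' @param minAf cohort AF threshold (strictly greater; default 0.01).
#' @param severity impact severity label to keep (default `"high"`,
#'   case-insensitive).
#' @param afCol,severityCol column names.
#' @return the filtered data.frame.
#' @export
lofFilter <- function(records, minAf = 0.01, severity = "high",
                      afCol = "af", severityCol = "impact_severity") {
  if (!severityCol %in% names(records))
    stop("no impact severity column '", severityCol, "'")
  keep <- tolower(records[[severityCol]]) == tolower(severity) &
    records[[afCol]] > minAf
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
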