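## Constructors, accessors and show methods.

#' Construct a CohortSites object
#'
#' @param sites data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param geno character matrix of GT strings (sites x samples) with sample
#'   ids as column names.
#' @return A [CohortSites-class] object.
#' @export
cohortSites <- function(sites, geno) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!"id" %in% names(sites)) sites$id <- "."
  rownames(sites) <- NULL
  new("CohortSites", sites = sites, geno = geno)
}

#' Construct an AfTable
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `AC`, `AN`, `AF`.
#' @return An [AfTable-class] object.
#' @export
afTable <- function(records) {
  rownames(records) <- NULL
  new("AfTable", records = as.data.frame(records, stringsAsFactors = FALSE))
}

#' @rdname cohortSites
#' @param x a CohortSites object.
#' @export
siteInfo <- function(x) {
  stopifnot(is(x, "CohortSites"))
  x@sites
}

#' @rdname cohortSites
#' @export
genoMatrix <- function(x) {
  stopifnot(is(x, "CohortSites"))
  x@geno
}

#' @rdname cohortSites
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "CohortSites"))
  colnames(x@geno)
}

#' @rdname cohortSites
#' @export
nSites <- function(x) {
  stopifnot(is(x, "CohortSites"))
  nrow(x@sites)
}

#' Extract allele-frequency records
#'
#' @param x an AfTable or SubstitutionSet.
#' @return data.frame of records.
#' @export
afRecords <- function(x) {
  stopifnot(is(x, "AfTable"))
  x@records
}

#' Extract substitution edits
#'
#' @param x a SubstitutionSet.
#' @return data.frame of substitution records.
#' @export
substitutions <- function(x) {
  stopifnot(is(x, "SubstitutionSet"))
  x@edits
}

#' Extract liftover chain blocks
#'
#' @param x a LiftoverChain.
#' @return data.frame of aligned blocks.
#' @export
chainBlocks <- function(x) {
  stopifnot(is(x, "LiftoverChain"))
  x@blocks
}

#' @rdname chainBlocks
#' @export
chainLengths <- function(x) {
  stopifnot(is(x, "LiftoverChain"))
  x@lengths
}

#' Extract the variant entries of a callset
#'
#' @param x a Callset.
#' @return data.frame of variant entries.
#' @export
variantCalls <- function(x) {
  stopifnot(is(x, "Callset"))
  x@variants
}

#' @rdname variantCalls
#' @export
callsetSample <- function(x) {
  stopifnot(is(x, "Callset"))
  x@sample
}

#' Extract the per-chromosome rows of a comparison table
#'
#' @param x a ComparisonTable.
#' @return data.frame with counts, differences and unrounded percents.
#' @export
comparisonRows <- function(x) {
  stopifnot(is(x, "ComparisonTable"))
  x@perChrom
}

#' @rdname comparisonRows
#' @export
comparisonTotals <- function(x) {
  stopifnot(is(x, "ComparisonTable"))
  x@totals
}

setMethod("show", "CohortSites", function(object) {
  cat(sprintf("CohortSites: %d sites x %d samples\n",
              nrow(object@sites), ncol(object@geno)))
  if (nrow(object@sites) > 0) {
    multi <- sum(grepl(",", object@sites$alt, fixed = TRUE))
    cat(sprintf("  contigs: %s\n",
                paste(unique(object@sites$chrom), collapse = ", ")))
    cat(sprintf("  multiallelic sites: %d\n", multi))
  }
})

setMethod("show", "AfTable", function(object) {
  r <- object@records
  cat(sprintf("AfTable: %d biallelic records\n", nrow(r)))
  if (nrow(r) > 0)
    cat(sprintf("  AF range [%.4g, %.4g]; %d with AF > 0.5\n",
                min(r$AF), max(r$AF), sum(2 * r$AC > r$AN)))
})

setMethod("show", "AfSpectrum", function(object) {
  cat(sprintf("AfSpectrum over %d records\n", object@total))
  fr <- if (object@total > 0) object@categories / object@total else
    object@categories * 0
  for (nm in names(object@categories))
    cat(sprintf("  %-24s %9d  (%.2f%%)\n", nm, object@categories[[nm]],
                100 * fr[[nm]]))
  cat(sprintf("  %-24s %9d\n", "fixed_alt (AF = 1)", object@fixedAlt))
})

setMethod("show", "SubstitutionSet", function(object) {
  cat(sprintf("SubstitutionSet: %d sites with AF > %g\n",
              nrow(object@edits), object@threshold))
  if (nrow(object@edits) > 0) {
    perChrom <- table(object@edits$chrom)
    cat(sprintf("  per contig: %s\n",
                paste(names(perChrom), perChrom, sep = "=", collapse = ", ")))
  }
})

setMethod("show", "EditPlan", function(object) {
  cat(sprintf("EditPlan: %d resolved edits, %d skipped\n",
              nrow(object@edits), nrow(object@skipped)))
})

setMethod("show", "LiftoverChain", function(object) {
  cat(sprintf("LiftoverChain: %d contigs, %d aligned blocks\n",
              nrow(object@lengths), nrow(object@blocks)))
  d <- sum(object@lengths$newLength) - sum(object@lengths$oldLength)
  cat(sprintf("  net length change: %+d bp\n", d))
})

setMethod("show", "Callset", function(object) {
  cat(sprintf("Callset '%s' vs %s: %d variants (%d het, %d hom_alt)\n",
              object@sample, object@reference, nrow(object@variants),
              sum(object@variants$gt == "het"),
              sum(object@variants$gt == "hom_alt")))
})

setMethod("show", "ComparisonTable", function(object) {
  p <- object@perChrom
  p$percent <- round(p$percent, 2)
  print(p, row.names = FALSE)
  t <- object@totals
  cat(sprintf("Totals: %d vs %d, difference %d (%.2f%% of totals; mean of per-chrom %% = %.2f)\n",
              t[["count_a"]], t[["count_b"]], t[["difference"]],
              t[["percent_of_totals"]], t[["mean_percent"]]))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf("OverlapReport: |A intersect B| = %d; A-only = %d (AC>1: %d)\n",
              object@overlap, object@aOnly, object@aOnlyAcGt1))
  cat("  A-only above AF thresholds:",
      paste(names(object@afThresholdCounts), object@afThresholdCounts,
            sep = ">", collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d; %d samples x %d sites; %d contigs (%s bp)\n",
              object@seed, object@nSamples, object@nSites,
              length(object@contigLengths),
              paste(object@contigLengths, collapse = ",")))
  cat("  spectrum:",
      paste(names(object@spectrum), object@spectrum, sep = "=",
            collapse = ", "), "\n")
})
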