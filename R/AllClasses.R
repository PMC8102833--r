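#' @import methods
NULL

## Central S4 containers. Genomes live in Biostrings::DNAStringSet; trees in
## ape::phylo; the classes below carry the variant-level objects that the
## major-allele reference workflow passes between its stages.

#' Multi-sample variant sites with genotypes
#'
#' Holds one row per VCF site (possibly multiallelic) together with the
#' per-sample GT strings.  `sites` columns: `chrom`, `pos` (1-based anchor
#' position), `id`, `ref`, `alt` (comma-separated when multiallelic).
#' `geno` is a character matrix, sites x samples, of VCF GT strings
#' (`"0/1"`, `"1|1"`, `"./."`, haploid `"1"`, ...).
#'
#' @slot sites data.frame of site records.
#' @slot geno character matrix of GT strings, `nrow(sites)` x samples.
#' @exportClass CohortSites
setClass("CohortSites", representation(sites = "data.frame",
                                       geno  = "matrix"))

setValidity("CohortSites", function(object) {
  s <- object@sites
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns", paste(need, collapse = ", ")))
  if (nrow(s) != nrow(object@geno))
    return("geno must have one row per site")
  if (nrow(s) > 0) {
    if (any(is.na(s$ref) | !nzchar(s$ref))) return("ref alleles must be non-empty")
    if (any(s$pos < 1)) return("pos must be >= 1")
  }
  if (is.null(colnames(object@geno)) && ncol(object@geno) > 0)
    return("geno must carry sample ids as column names")
  if (anyDuplicated(colnames(object@geno))) return("sample ids must be unique")
  TRUE
})

#' Cohort allele-frequency records
#'
#' One row per normalized biallelic variant: `chrom`, `pos`, `ref`, `alt`,
#' `AC` (alternate allele count), `AN` (called allele number), `AF = AC/AN`.
#' Sites with `AN == 0` are never stored.
#'
#' @slot records data.frame of AF records.
#' @exportClass AfTable
setClass("AfTable", representation(records = "data.frame"))

setValidity("AfTable", function(object) {
  r <- object@records
  need <- c("chrom", "pos", "ref", "alt", "AC", "AN", "AF")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) == 0) return(TRUE)
  if (any(r$AN <= 0)) return("records with AN == 0 must be excluded")
  if (any(r$AC < 0 | r$AC > r$AN)) return("AC must satisfy 0 <= AC <= AN")
  if (any(abs(r$AF - r$AC / r$AN) > 1e-12)) return("AF must equal AC/AN")
  TRUE
})

#' Allele-frequency spectrum
#'
#' Histogram of alternate allele frequencies in 20 bins of width 0.05 plus
#' the four-category classification (rare alternate, common alternate,
#' common reference, rare-or-unobserved reference) and the fixed-alternate
#' (AF = 1) sub-count.
#'
#' @slot histogram data.frame with `bin_low`, `bin_high`, `count`, `fraction`.
#' @slot categories named integer vector of category counts.
#' @slot fixedAlt integer, number of records with AF exactly 1.
#' @slot total integer, number of records.
#' @exportClass AfSpectrum
setClass("AfSpectrum", representation(histogram = "data.frame",
                                      categories = "integer",
                                      fixedAlt = "integer",
                                      total = "integer"))

setValidity("AfSpectrum", function(object) {
  if (sum(object@histogram$count) != object@total)
    return("histogram total must equal record total")
  if (sum(object@categories) != object@total)
    return("category total must equal record total")
  TRUE
})

#' Major-allele substitution set
#'
#' The sites whose cohort alternate allele frequency exceeds the majority
#' threshold, i.e. the edits that turn the source reference into the
#' population major-allele reference.  `edits` columns: `chrom`, `pos`,
#' `ref`, `alt`, `AC`, `AN`, `AF`; rows sorted by (`chrom`, `pos`).
#'
#' @slot edits data.frame of substitution records.
#' @slot threshold numeric majority threshold (default 0.5, strict).
#' @exportClass SubstitutionSet
setClass("SubstitutionSet", representation(edits = "data.frame",
                                           threshold = "numeric"))

setValidity("SubstitutionSet", function(object) {
  e <- object@edits
  need <- c("chrom", "pos", "ref", "alt", "AF")
  if (!all(need %in% names(e)))
    return(paste("edits must have columns", paste(need, collapse = ", ")))
  if (nrow(e) == 0) return(TRUE)
  if (any(e$AF <= object@threshold))
    return("every substitution must have AF strictly above the threshold")
  bad <- unlist(lapply(split(e$pos, e$chrom), function(p) is.unsorted(p)))
  if (any(bad)) return("edits must be sorted by position within chromosome")
  if (anyDuplicated(paste(e$chrom, e$pos, e$ref)))
    return("at most one substitution per (chrom, pos, ref) site")
  TRUE
})

#' Resolved edit plan for one genome
#'
#' Substitutions verified against the genome and resolved left-most-first so
#' that accepted old-coordinate spans never overlap.  Edits are stored with
#' the shared ref/alt prefix (the VCF anchor base) trimmed off, so `start0`
#' (0-based) and `oldLen` describe exactly the bases that change;
#' `oldLen = 0` encodes a pure insertion before `start0`.
#'
#' @slot edits data.frame: `chrom`, `start0`, `oldLen`, `replacement`,
#'   `pos`, `ref`, `alt` (the originating VCF-style record).
#' @slot skipped data.frame of dropped candidate edits with a `reason`.
#' @exportClass EditPlan
setClass("EditPlan", representation(edits = "data.frame",
                                    skipped = "data.frame"))

#' Liftover chain between two genome builds
#'
#' Ordered aligned blocks mapping old to new coordinates after applying the
#' edit plan.  Blocks (`oldStart0`, `newStart0`, `length`, all 0-based) are
#' monotone in both systems; only length-changing edits interrupt blocks,
#' so same-length substitutions (SNPs) sit inside blocks and a SNP-only
#' build yields one full-length block per contig.
#'
#' @slot blocks data.frame: `chrom`, `oldStart0`, `newStart0`, `length`.
#' @slot lengths data.frame: `chrom`, `oldLength`, `newLength`.
#' @exportClass LiftoverChain
setClass("LiftoverChain", representation(blocks = "data.frame",
                                         lengths = "data.frame"))

setValidity("LiftoverChain", function(object) {
  b <- object@blocks
  for (ch in object@lengths$chrom) {
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    if (is.unsorted(bb$oldStart0, strictly = TRUE) ||
        is.unsorted(bb$newStart0, strictly = TRUE))
      return("blocks must be strictly increasing in both coordinate systems")
    if (any(bb$oldStart0 + bb$length > head_tail_len(object, ch, "oldLength")) ||
        any(bb$newStart0 + bb$length > head_tail_len(object, ch, "newLength")))
      return("blocks must stay within contig bounds")
  }
  TRUE
})

# contig length lookup used by the validity method
head_tail_len <- function(chain, ch, col) {
  chain@lengths[[col]][match(ch, chain@lengths$chrom)]
}

#' Per-sample variant callset relative to a named reference
#'
#' Normalized biallelic variant entries for one sample.  Homozygous
#' reference positions are absent by construction (GVCF semantics: absence
#' means hom-ref).  `variants` columns: `chrom`, `pos`, `ref`, `alt`,
#' `gt` in `{"het", "hom_alt"}`.
#'
#' @slot sample character sample id.
#' @slot reference character name of the reference build.
#' @slot variants data.frame of variant entries.
#' @exportClass Callset
setClass("Callset", representation(sample = "character",
                                   reference = "character",
                                   variants = "data.frame"))

setValidity("Callset", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "gt")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns", paste(need, collapse = ", ")))
  if (nrow(v) > 0 && !all(v$gt %in% c("het", "hom_alt")))
    return("gt must be 'het' or 'hom_alt' (hom-ref entries are absent)")
  TRUE
})

#' Per-chromosome callset comparison (call-reduction table)
#'
#' Per-chromosome counts against two references, their difference
#' (a - b) and percent difference 100*(a - b)/a.  The totals report both
#' the percent of summed counts and the mean of per-chromosome percents,
#' which differ whenever chromosomes differ in size.
#'
#' @slot perChrom data.frame: `chrom`, `count_a`, `count_b`, `difference`,
#'   `percent` (unrounded; NA where `count_a` is 0).
#' @slot totals named numeric: `count_a`, `count_b`, `difference`,
#'   `percent_of_totals`, `mean_percent`.
#' @exportClass ComparisonTable
setClass("ComparisonTable", representation(perChrom = "data.frame",
                                           totals = "numeric"))

#' Biallelic-SNP catalog overlap report
#'
#' @slot overlap integer, size of the key intersection.
#' @slot aOnly integer, catalog-A-only variant count.
#' @slot aOnlyAcGt1 integer, A-only variants with AC > 1.
#' @slot afThresholdCounts named integer, A-only variants with AF strictly
#'   above each threshold.
#' @slot rejected named integer, non-SNP keys rejected from each input.
#' @exportClass OverlapReport
setClass("OverlapReport", representation(overlap = "integer",
                                         aOnly = "integer",
                                         aOnlyAcGt1 = "integer",
                                         afThresholdCounts = "integer",
                                         rejected = "integer"))

#' Synthetic cohort configuration
#'
#' Everything the synthetic generators draw is a pure function of this
#' object (seed included), so all fixtures are reproducible.
#'
#' @slot seed integer RNG seed.
#' @slot contigLengths named numeric vector of contig lengths (bp).
#' @slot nSamples integer number of diploid samples.
#' @slot nSites integer number of variant sites.
#' @slot spectrum named numeric mixing proportions over the four AF
#'   categories (`rare_alt`, `common_alt`, `common_ref`,
#'   `rare_or_unobserved_ref`).
#' @slot inbreeding numeric per-sample inbreeding coefficient(s) F.
#' @slot missingRate numeric per-genotype missingness probability.
#' @slot indelFraction numeric fraction of substitution-eligible sites
#'   planted as indels.
#' @slot indelLenRange integer length-2, indel size range in bp.
#' @slot admixture list or empty: `K` ancestral profiles, `divergence`
#'   (Balding-Nichols F between profiles), `alpha` (Dirichlet
#'   concentration for per-sample proportions).
#' @exportClass SimConfig
setClass("SimConfig", representation(seed = "integer",
                                     contigLengths = "numeric",
                                     nSamples = "integer",
                                     nSites = "integer",
                                     spectrum = "numeric",
                                     inbreeding = "numeric",
                                     missingRate = "numeric",
                                     indelFraction = "numeric",
                                     indelLenRange = "integer",
                                     admixture = "list"))

setValidity("SimConfig", function(object) {
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed is mandatory")
  if (abs(sum(object@spectrum) - 1) > 1e-9)
    return("spectrum proportions must sum to 1")
  cats <- c("rare_alt", "common_alt", "common_ref", "rare_or_unobserved_ref")
  if (!identical(sort(names(object@spectrum)), sort(cats)))
    return("spectrum must be named by the four AF categories")
  if (any(object@contigLengths < 1000))
    return("contig lengths must be >= 1 kb")
  if (!all(object@inbreeding >= -1 & object@inbreeding <= 1))
    return("inbreeding F must lie in [-1, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  TRUE
})
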