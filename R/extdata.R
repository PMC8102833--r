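## Bundled example data: published evaluation numbers for a major-allele
## reference genome built from an admixed Middle-Eastern cohort.

#' Published per-chromosome call counts for four test genomes
#'
#' Variant call counts for four whole genomes, each called twice — once
#' against hg19 and once against the cohort's major-allele reference —
#' as reported for a population reference-genome study of the United Arab
#' Emirates.  Columns: `chrom` plus `<sample>_hg19` and `<sample>_majref`
#' for samples S015-S018.  Feeding a sample's pair of columns into
#' [comparisonTable()] reproduces the published call-reduction table.
#'
#' @return data.frame of per-chromosome counts.
#' @export
publishedCallCounts <- function() {
  utils::read.delim(system.file("extdata", "published_call_counts.tsv",
                                package = "majref"),
                    stringsAsFactors = FALSE)
}

#' Published population-specific high/medium-impact variants
#'
#' The published list of variants common in the study cohort
#' (AF > 0.05) yet rare or absent in every external (gnomAD) population
#' (AF < 0.01); `af` is the cohort alternate AF and `gnomad_af_all` the
#' external AF (NA where the catalog has no record).  Every row passes
#' [populationSpecificFilter()] at those thresholds.
#'
#' @return data.frame of annotated variant records.
#' @export
publishedSpecificVariants <- function() {
  utils::read.delim(system.file("extdata", "published_specific_variants.tsv",
                                package = "majref"),
                    stringsAsFactors = FALSE)
}
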