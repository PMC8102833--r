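## File I/O: VCF (via vcfR), FASTA (via Biostrings), UCSC chain output,
## TSV tables.  All readers are gzip-transparent through the underlying
## libraries.

#' Read a multi-sample VCF into a CohortSites object
#'
#' Sites and GT fields are kept; other FORMAT fields are dropped (the
#' cohort workflow only consumes genotypes).
#'
#' @param path VCF file (plain or bgzip/gzip).
#' @param harmonize harmonize chromosome names (default TRUE).
#' @param style chromosome dialect for [harmonizeChrom()].
#' @return A [CohortSites-class] object.
#' @export
readCohortVcf <- function(path, harmonize = TRUE, style = "chr") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  chrom <- if (harmonize) harmonizeChrom(fix$CHROM, style = style) else fix$CHROM
  sites <- data.frame(chrom = chrom, pos = as.integer(fix$POS),
                      id = ifelse(is.na(fix$ID), ".", fix$ID),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dimnames(gt) <- list(NULL, colnames(gt))
  cohortSites(sites, gt)
}

#' Write a CohortSites object as VCF
#'
#' @param x a [CohortSites-class] object.
#' @param path output path; vcfR writes gzip-compressed VCF, so use a
#'   `.vcf.gz` name.
#' @param contigLengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(x, path, contigLengths = NULL) {
  stopifnot(is(x, "CohortSites"))
  s <- x@sites
  meta <- c("##fileformat=VCFv4.2",
            "##source=majref",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contigLengths))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(contigLengths), as.integer(contigLengths)))
  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos), ID = s$id,
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = rep("GT", nrow(s)), x@geno)
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read / write FASTA genomes
#'
#' Thin wrappers over Biostrings keeping the first header token as the
#' contig name on read and wrapping at 60 columns on write.
#'
#' @param path FASTA file.
#' @return `readFastaSet`: a `DNAStringSet` named by first header token.
#' @export
readFastaSet <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub(" .*", "", names(x))
  x
}

#' @rdname readFastaSet
#' @param x a `DNAStringSet` or named character vector.
#' @export
writeFastaSet <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(unlist(x))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write a liftover chain in UCSC chain format
#'
#' The new (edited) genome is the chain target and the old genome the
#' query, so standard liftover tooling fed with this file projects
#' coordinates from the new build back onto the old one; use
#' [liftPositions()] for either direction in-package.
#'
#' @param chain a [LiftoverChain-class] object.
#' @param path output path.
#' @param oldName,newName genome build labels used as query/target contig
#'   name prefixes (unused in coordinates, kept for readability; contig
#'   names themselves are shared between builds).
#' @return `path`, invisibly.
#' @export
writeChainFile <- function(chain, path, oldName = "old", newName = "new") {
  con <- file(path, "w")
  on.exit(close(con))
  id <- 0L
  for (ch in chain@lengths$chrom) {
    bb <- chain@blocks[chain@blocks$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    id <- id + 1L
    oldL <- chain@lengths$oldLength[match(ch, chain@lengths$chrom)]
    newL <- chain@lengths$newLength[match(ch, chain@lengths$chrom)]
    tStart <- bb$newStart0[1]; tEnd <- bb$newStart0[nrow(bb)] + bb$length[nrow(bb)]
    qStart <- bb$oldStart0[1]; qEnd <- bb$oldStart0[nrow(bb)] + bb$length[nrow(bb)]
    writeLines(sprintf("chain %d %s %d + %d %d %s %d + %d %d %d",
                       sum(bb$length), ch, as.integer(newL), as.integer(tStart),
                       as.integer(tEnd), ch, as.integer(oldL),
                       as.integer(qStart), as.integer(qEnd), id), con)
    n <- nrow(bb)
    if (n > 1) {
      dt <- bb$newStart0[-1] - (bb$newStart0[-n] + bb$length[-n])
      dq <- bb$oldStart0[-1] - (bb$oldStart0[-n] + bb$length[-n])
      writeLines(sprintf("%d\t%d\t%d", as.integer(bb$length[-n]),
                         as.integer(dt), as.integer(dq)), con)
    }
    writeLines(sprintf("%d", as.integer(bb$length[n])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read AF records as TSV
#'
#' Columns: chrom, pos, ref, alt, AC, AN, AF.
#'
#' @param x an [AfTable-class] or [SubstitutionSet-class] object.
#' @param path TSV path.
#' @export
writeAfTable <- function(x, path) {
  r <- if (is(x, "SubstitutionSet")) x@edits else afRecords(x)
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAfTable
#' @export
readAfTable <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  afTable(r[, c("chrom", "pos", "ref", "alt", "AC", "AN", "AF")])
}

#' Write an AF spectrum as TSV
#'
#' @param x an [AfSpectrum-class] object.
#' @param path TSV path.
#' @export
writeSpectrum <- function(x, path) {
  stopifnot(is(x, "AfSpectrum"))
  utils::write.table(x@histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a comparison table as TSV
#'
#' Per-chromosome rows with a totals row appended; percents rounded to two
#' decimals for display (the object keeps unrounded values).
#'
#' @param x a [ComparisonTable-class] object.
#' @param path TSV path.
#' @export
writeComparisonTable <- function(x, path) {
  stopifnot(is(x, "ComparisonTable"))
  p <- x@perChrom
  p$percent <- round(p$percent, 2)
  t <- x@totals
  p <- rbind(p, data.frame(chrom = "Total", count_a = t[["count_a"]],
                           count_b = t[["count_b"]],
                           difference = t[["difference"]],
                           percent = round(t[["mean_percent"]], 2)))
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an admixture proportion table
#'
#' TSV with a `sample` column and one numeric column per ancestry
#' component; proportions must sum to 1 within 1e-6 per sample.
#'
#' @param path TSV path.
#' @return data.frame with `sample` and component columns.
#' @export
readAdmixture <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(a)) stop("admixture table needs a 'sample' column")
  comp <- a[, setdiff(names(a), "sample"), drop = FALSE]
  if (!all(vapply(comp, is.numeric, TRUE)))
    stop("admixture components must be numeric")
  if (any(unlist(comp) < 0 | unlist(comp) > 1))
    stop("admixture proportions must lie in [0, 1]")
  if (any(abs(rowSums(comp) - 1) > 1e-6))
    stop("admixture proportions must sum to 1 per sample")
  a
}

#' Read a single-sample VCF as a Callset
#'
#' Entries with genotype 0/0 or missing are dropped (absence = hom-ref,
#' GVCF semantics).  Multiallelic records are decomposed; variants are
#' left-aligned when a genome is supplied.
#'
#' @param path VCF path.
#' @param sample sample id (defaults to the first sample column).
#' @param reference label of the reference build the calls are against.
#' @param genome optional reference sequences for normalization.
#' @return A [Callset-class] object.
#' @export
readCallsetVcf <- function(path, sample = NULL, reference = "old",
                           genome = NULL) {
  cs <- readCohortVcf(path)
  if (is.null(sample)) sample <- sampleIds(cs)[1]
  if (!sample %in% sampleIds(cs)) stop("sample not in VCF: ", sample)
  cs@geno <- cs@geno[, sample, drop = FALSE]
  cs <- if (is.null(genome)) decomposeSites(cs) else normalizeCohort(cs, genome)
  callsetFromGenotypes(cs, sample, reference = reference)
}
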