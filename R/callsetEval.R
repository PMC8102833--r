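## Callset reprojection between reference builds and call-count comparison.

#' Build per-sample callsets from a biallelic cohort
#'
#' A sample's callset keeps only its variant genotypes (het, hom-alt);
#' hom-ref and missing genotypes are absent, matching the GVCF convention
#' that absence from a final callset means homozygous reference.
#'
#' @param x a biallelic [CohortSites-class] object.
#' @param sample sample id.
#' @param reference label of the reference build.
#' @return A [Callset-class] object.
#' @export
callsetFromGenotypes <- function(x, sample, reference = "old") {
  stopifnot(is(x, "CohortSites"), sample %in% sampleIds(x))
  al <- gt_alleles(x@geno[, sample, drop = FALSE])
  a1 <- al$a1[, 1]; a2 <- al$a2[, 1]
  called <- !is.na(a1) & !is.na(a2)
  gt <- rep(NA_character_, nSites(x))
  gt[called & a1 != a2] <- "het"
  gt[called & a1 == 1L & a2 == 1L] <- "hom_alt"
  keep <- !is.na(gt)
  s <- x@sites[keep, , drop = FALSE]
  new("Callset", sample = sample, reference = reference,
      variants = data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref,
                            alt = s$alt, gt = gt[keep],
                            stringsAsFactors = FALSE, row.names = NULL))
}

#' @rdname callsetFromGenotypes
#' @export
callsetsFromCohort <- function(x, reference = "old") {
  stats::setNames(lapply(sampleIds(x), callsetFromGenotypes, x = x,
                         reference = reference), sampleIds(x))
}

#' Reproject a callset onto the major-allele reference
#'
#' Recomputes a sample's variant set relative to the edited reference
#' without re-alignment, as the exact set-theoretic consequence of the
#' ref/alt role swap at substituted sites.  At a substituted biallelic
#' site with old ref R and old alt A (new ref A, new alt R):
#' \itemize{
#'   \item old hom-alt (1/1) — the sample matches the new reference, so the
#'     call disappears;
#'   \item old het (0/1) — retained as a het with ref and alt swapped;
#'   \item old hom-ref (absent) — a new hom-alt (1/1) call appears.
#' }
#' Non-substituted variants are retained with positions lifted through the
#' chain.  Variants overlapping an edited span without matching the edit
#' (third alleles, calls spanning an applied indel) cannot be resolved
#' without realignment and are moved to a side list; substitution sites
#' touched by such a variant are not assigned the hom-ref default.
#'
#' @param cs a [Callset-class] against the old reference.
#' @param build result of [buildReference()] (or a list with `chain` and
#'   `plan`).
#' @param reference label for the new build.
#' @return list with `callset` (reprojected [Callset-class]) and
#'   `unresolvable` (data.frame of side-listed variants with a `reason`).
#' @export
reprojectCallset <- function(cs, build, reference = "majref") {
  stopifnot(is(cs, "Callset"))
  chain <- build$chain; plan <- build$plan
  v <- cs@variants
  e <- plan@edits
  vKey <- variantKey(v$chrom, v$pos, v$ref, v$alt, harmonize = FALSE)
  eKey <- variantKey(e$chrom, e$pos, e$ref, e$alt, harmonize = FALSE)
  m <- match(vKey, eKey)
  matched <- !is.na(m)

  # --- matched variants: truth table -----------------------------------
  hetAt <- matched & v$gt == "het"
  # hom_alt at substituted site -> drop (becomes hom-ref on new build)

  # --- unmatched variants: conflict with applied edits? ----------------
  un <- which(!matched)
  conflict <- logical(length(un))
  if (length(un) > 0 && nrow(e) > 0) {
    vs <- v$pos[un] - 1L                      # untrimmed variant span, 0-based
    ve <- vs + nchar(v$ref[un])
    for (ch in unique(v$chrom[un])) {
      ee <- e[e$chrom == ch, , drop = FALSE]
      if (nrow(ee) == 0) next
      sel <- which(v$chrom[un] == ch)
      span <- ee[ee$oldLen > 0, , drop = FALSE]     # edits that consume bases
      if (nrow(span) > 0) {
        # disjoint sorted spans: the latest edit starting before the variant
        # end is the only candidate overlap
        j <- findInterval(ve[sel] - 1L, span$start0)
        hit <- j >= 1 & span$start0[pmax(j, 1)] + span$oldLen[pmax(j, 1)] > vs[sel]
        conflict[sel] <- conflict[sel] | hit
      }
      ins <- ee$start0[ee$oldLen == 0]              # pure insertion points
      if (length(ins) > 0) {
        # insertion point strictly inside the variant span
        inside <- findInterval(ve[sel] - 1L, ins) >
          findInterval(vs[sel], ins)
        conflict[sel] <- conflict[sel] | inside
      }
    }
  }
  unresolvable <- v[un[conflict], , drop = FALSE]
  if (nrow(unresolvable) > 0) unresolvable$reason <- "overlaps_applied_edit"

  # --- assemble retained entries ---------------------------------------
  keepIdx <- un[!conflict]
  retained <- v[keepIdx, , drop = FALSE]
  if (nrow(retained) > 0) {
    newPos <- liftPositions(chain, retained$chrom, retained$pos)
    bad <- is.na(newPos)
    if (any(bad)) {     # anchor itself erased by a neighbouring edit
      extra <- retained[bad, , drop = FALSE]
      extra$reason <- "anchor_unmapped"
      unresolvable <- rbind(unresolvable, extra)
      retained <- retained[!bad, , drop = FALSE]
      newPos <- newPos[!bad]
    }
    retained$pos <- newPos
  }
  swapped <- v[hetAt, , drop = FALSE]
  if (nrow(swapped) > 0) {
    swapped$pos <- liftPositions(chain, swapped$chrom, swapped$pos)
    tmp <- swapped$ref; swapped$ref <- swapped$alt; swapped$alt <- tmp
  }
  # substitution sites untouched by any call of this sample -> new hom-alt
  touched <- unique(m[matched])
  if (nrow(unresolvable) > 0 && nrow(e) > 0) {
    # conservative: a conflicting variant may cover several edits
    us <- unresolvable$pos - 1L
    ue <- us + nchar(unresolvable$ref)
    for (k in seq_len(nrow(unresolvable))) {
      ee <- which(e$chrom == unresolvable$chrom[k] &
                  e$start0 < ue[k] & e$start0 + pmax(e$oldLen, 1L) > us[k])
      touched <- union(touched, ee)
    }
  }
  newHom <- e[setdiff(seq_len(nrow(e)), touched), , drop = FALSE]
  added <- if (nrow(newHom) > 0) {
    data.frame(chrom = newHom$chrom,
               pos = liftPositions(chain, newHom$chrom, newHom$pos),
               ref = newHom$alt, alt = newHom$ref, gt = "hom_alt",
               stringsAsFactors = FALSE)
  } else v[0, c("chrom", "pos", "ref", "alt", "gt")]

  out <- rbind(retained[, c("chrom", "pos", "ref", "alt", "gt")],
               swapped[, c("chrom", "pos", "ref", "alt", "gt")],
               added)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  list(callset = new("Callset", sample = cs@sample, reference = reference,
                     variants = out),
       unresolvable = unresolvable)
}

#' Invert a liftover chain
#'
#' @param chain a [LiftoverChain-class] object.
#' @return the chain mapping new coordinates to old ones.
#' @export
invertChain <- function(chain) {
  b <- chain@blocks
  new("LiftoverChain",
      blocks = data.frame(chrom = b$chrom, oldStart0 = b$newStart0,
                          newStart0 = b$oldStart0, length = b$length),
      lengths = data.frame(chrom = chain@lengths$chrom,
                           oldLength = chain@lengths$newLength,
                           newLength = chain@lengths$oldLength))
}

#' Invert a build (for round-trip reprojection)
#'
#' Produces the edit plan and chain that undo a build: ref/alt roles
#' swapped, positions lifted to the new build's coordinates.
#'
#' @param build result of [buildReference()].
#' @return list with `chain` and `plan` describing the inverse edits.
#' @export
invertBuild <- function(build) {
  e <- build$plan@edits
  chain <- build$chain
  npre <- common_prefix_len(e$ref, e$alt)   # symmetric in ref/alt
  newPos <- liftPositions(chain, e$chrom, e$pos)
  inv <- data.frame(chrom = e$chrom,
                    start0 = newPos - 1L + npre,
                    oldLen = nchar(e$alt) - npre,
                    replacement = substring(e$ref, npre + 1L),
                    pos = newPos,
                    ref = e$alt, alt = e$ref, stringsAsFactors = FALSE)
  inv <- inv[order(inv$chrom, inv$start0), , drop = FALSE]
  rownames(inv) <- NULL
  list(chain = invertChain(chain),
       plan = new("EditPlan", edits = inv, skipped = e[0, , drop = FALSE]))
}

#' Per-chromosome comparison of two call-count vectors
#'
#' The arithmetic behind the call-reduction table: difference = a - b and
#' percent = 100 (a - b)/a per chromosome, with totals reported both as
#' percent of summed counts and as the mean of per-chromosome percents.
#'
#' @param countA,countB named integer vectors of per-chromosome call
#'   counts (names = chromosomes; aligned by name).
#' @param chromOrder optional chromosome display order.
#' @return A [ComparisonTable-class] object (percents unrounded; NA where
#'   `countA` is zero).
#' @export
comparisonTable <- function(countA, countB, chromOrder = NULL) {
  if (is.null(chromOrder)) chromOrder <- names(countA)
  a <- countA[chromOrder]
  b <- countB[chromOrder]
  b[is.na(b)] <- 0L
  diffs <- a - b
  pct <- ifelse(a == 0, NA_real_, 100 * diffs / a)
  per <- data.frame(chrom = chromOrder, count_a = as.numeric(a),
                    count_b = as.numeric(b), difference = as.numeric(diffs),
                    percent = pct, row.names = NULL)
  totals <- c(count_a = sum(a), count_b = sum(b), difference = sum(diffs),
              percent_of_totals = if (sum(a) > 0) 100 * sum(diffs) / sum(a)
                                  else NA_real_,
              mean_percent = mean(pct, na.rm = TRUE))
  new("ComparisonTable", perChrom = per, totals = totals)
}

#' Compare two callsets chromosome by chromosome
#'
#' @param a,b [Callset-class] objects (a = old reference, b = new).
#' @param chromOrder optional chromosome order; defaults to the union of
#'   chromosomes seen, in order of appearance in `a` then `b`.
#' @return A [ComparisonTable-class] object.
#' @export
compareCallsets <- function(a, b, chromOrder = NULL) {
  stopifnot(is(a, "Callset"), is(b, "Callset"))
  if (is.null(chromOrder))
    chromOrder <- unique(c(a@variants$chrom, b@variants$chrom))
  ca <- table(factor(a@variants$chrom, levels = chromOrder))
  cb <- table(factor(b@variants$chrom, levels = chromOrder))
  comparisonTable(stats::setNames(as.integer(ca), chromOrder),
                  stats::setNames(as.integer(cb), chromOrder),
                  chromOrder)
}

#' Biallelic-SNP catalog overlap
#'
#' Set intersection on canonical variant keys, restricted to biallelic
#' SNPs; non-SNP records are rejected with a count.  A-only records are
#' tallied by AC > 1 and by strict AF thresholds.
#'
#' @param a an [AfTable-class] object (catalog with AC/AF annotations).
#' @param bKeys character vector of variant keys of catalog B (from
#'   [variantKey()]), or an [AfTable-class].
#' @param thresholds AF thresholds (strictly greater) for the A-only
#'   tallies.
#' @return An [OverlapReport-class] object.
#' @export
catalogOverlap <- function(a, bKeys, thresholds = c(0.01, 0.05, 0.10, 0.50)) {
  stopifnot(is(a, "AfTable"))
  r <- a@records
  isSnp <- nchar(r$ref) == 1 & nchar(r$alt) == 1 &
    r$ref %in% c("A", "C", "G", "T") & r$alt %in% c("A", "C", "G", "T")
  rejA <- sum(!isSnp)
  r <- r[isSnp, , drop = FALSE]
  aKeys <- variantKey(r$chrom, r$pos, r$ref, r$alt)
  if (is(bKeys, "AfTable")) {
    rb <- bKeys@records
    snpB <- nchar(rb$ref) == 1 & nchar(rb$alt) == 1 &
      rb$ref %in% c("A", "C", "G", "T") & rb$alt %in% c("A", "C", "G", "T")
    rejB <- sum(!snpB)
    bKeys <- variantKey(rb$chrom[snpB], rb$pos[snpB], rb$ref[snpB], rb$alt[snpB])
  } else {
    nonSnp <- grepl(":[ACGT]{2,}:|:[ACGT]{2,}$", bKeys)
    rejB <- sum(nonSnp)
    bKeys <- bKeys[!nonSnp]
  }
  inB <- aKeys %in% bKeys
  only <- r[!inB, , drop = FALSE]
  thrCounts <- vapply(thresholds, function(t) sum(only$AF > t), 0L)
  new("OverlapReport",
      overlap = sum(inB),
      aOnly = nrow(only),
      aOnlyAcGt1 = sum(only$AC > 1),
      afThresholdCounts = stats::setNames(as.integer(thrCounts),
                                          as.character(thresholds)),
      rejected = c(a = as.integer(rejA), b = as.integer(rejB)))
}
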