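## Major-allele genome construction: edit planning, sequence editing with
## exact liftover-chain bookkeeping, position translation.

#' Plan substitution edits against a genome
#'
#' Verifies that every substitution's reference allele matches the genome
#' at its coordinates (a mismatch is a hard error naming chrom:pos — it
#' signals a genome/VCF build mismatch; the same applies when the genome
#' holds N), trims the shared ref/alt prefix (the VCF anchor base) so the
#' stored span covers exactly the bases that change, and resolves
#' overlapping candidates left-most-first: candidates are processed in
#' position order and any edit whose (untrimmed) reference span intersects
#' an already accepted span is skipped with reason `"overlap"`.
#'
#' @param subs a [SubstitutionSet-class] object.
#' @param genome a `DNAStringSet` or named character vector.
#' @return An [EditPlan-class] object.
#' @export
planEdits <- function(subs, genome) {
  stopifnot(is(subs, "SubstitutionSet"))
  seqs <- genome_as_char(genome)
  e <- subs@edits
  miss <- setdiff(unique(e$chrom), names(seqs))
  if (length(miss) > 0)
    stop("contig(s) in substitution set absent from genome: ",
         paste(miss, collapse = ", "))
  edits <- vector("list", length(seqs))
  skipped <- vector("list", length(seqs))
  for (ch in unique(e$chrom)) {
    ee <- e[e$chrom == ch, , drop = FALSE]
    sc <- seqs[[ch]]
    L <- nchar(sc)
    if (any(ee$pos + nchar(ee$ref) - 1 > L))
      stop("substitution span exceeds contig bounds on ", ch)
    obs <- substring(sc, ee$pos, ee$pos + nchar(ee$ref) - 1)
    bad <- which(obs != ee$ref)
    if (length(bad) > 0)
      stop(sprintf("reference mismatch at %s:%d (substitution ref %s, genome %s)",
                   ch, ee$pos[bad[1]], ee$ref[bad[1]], obs[bad[1]]))
    # left-most-first overlap resolution on untrimmed VCF spans
    ord <- order(ee$pos)
    ee <- ee[ord, , drop = FALSE]
    start <- ee$pos
    end <- ee$pos + nchar(ee$ref) - 1
    accept <- logical(nrow(ee))
    lastEnd <- 0
    for (i in seq_len(nrow(ee))) {
      if (start[i] > lastEnd) {
        accept[i] <- TRUE
        lastEnd <- end[i]
      }
    }
    acc <- ee[accept, , drop = FALSE]
    # trim shared prefix (anchor base) so spans cover only changed bases
    npre <- common_prefix_len(acc$ref, acc$alt)
    edits[[match(ch, names(seqs))]] <- data.frame(
      chrom = ch,
      start0 = acc$pos - 1L + npre,
      oldLen = nchar(acc$ref) - npre,
      replacement = substr(acc$alt, npre + 1L, nchar(acc$alt)),
      pos = acc$pos, ref = acc$ref, alt = acc$alt,
      stringsAsFactors = FALSE)
    sk <- ee[!accept, , drop = FALSE]
    if (nrow(sk) > 0) {
      sk$reason <- "overlap"
      skipped[[match(ch, names(seqs))]] <- sk
    }
  }
  new("EditPlan",
      edits = rbind_or_empty(edits,
        data.frame(chrom = character(), start0 = integer(),
                   oldLen = integer(), replacement = character(),
                   pos = integer(), ref = character(), alt = character())),
      skipped = rbind_or_empty(skipped,
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), reason = character())))
}

common_prefix_len <- function(a, b) {
  n <- pmin(nchar(a), nchar(b))
  out <- integer(length(a))
  for (i in seq_along(a)) {
    k <- 0L
    while (k < n[i] &&
           substr(a[i], k + 1, k + 1) == substr(b[i], k + 1, k + 1)) k <- k + 1L
    out[i] <- k
  }
  out
}

rbind_or_empty <- function(lst, empty) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(empty)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Apply resolved edits to one chromosome sequence
#'
#' Splices each old-coordinate span out of the sequence and inserts its
#' replacement, and records the liftover blocks.  Only length-changing
#' edits (indels) interrupt blocks; same-length substitutions map affinely
#' inside blocks, so a SNP-only plan yields a single full-length block.
#'
#' @param chromSeq character scalar, the old chromosome sequence.
#' @param edits data.frame of resolved edits for this chromosome
#'   (columns `start0`, `oldLen`, `replacement`, sorted, non-overlapping),
#'   e.g. one chromosome's rows of an [EditPlan-class].
#' @return list with `seq` (new sequence), `blocks` (data.frame
#'   `oldStart0`, `newStart0`, `length`), `newLength`.
#' @export
applyEdits <- function(chromSeq, edits) {
  L <- nchar(chromSeq)
  if (nrow(edits) == 0) {
    return(list(seq = chromSeq,
                blocks = data.frame(oldStart0 = 0L, newStart0 = 0L, length = L),
                newLength = L))
  }
  st <- edits$start0; ol <- edits$oldLen; rp <- edits$replacement
  if (is.unsorted(st) || any(st[-1] < (st + ol)[-length(st)]))
    stop("edits must be sorted and non-overlapping")
  if (any(st + ol > L)) stop("edit span exceeds sequence length")
  # splice: kept pieces interleaved with replacements
  keepStart <- c(0L, st + ol)
  keepEnd <- c(st, L)
  pieces <- substring(chromSeq, keepStart + 1L, keepEnd)
  v <- character(2L * length(st) + 1L)
  v[seq(1, length(v), by = 2)] <- pieces
  v[seq(2, length(v), by = 2)] <- rp
  newSeq <- paste(v, collapse = "")
  # blocks: break only at length-changing edits
  indel <- ol != nchar(rp)
  ist <- st[indel]; iol <- ol[indel]; irp <- nchar(rp[indel])
  segOldStart <- c(0L, ist + iol)
  segOldEnd <- c(ist, L)
  offset <- c(0L, cumsum(irp - iol))
  blocks <- data.frame(oldStart0 = segOldStart,
                       newStart0 = segOldStart + offset,
                       length = segOldEnd - segOldStart)
  blocks <- blocks[blocks$length > 0, , drop = FALSE]
  rownames(blocks) <- NULL
  list(seq = newSeq, blocks = blocks, newLength = nchar(newSeq))
}

#' Build a major-allele reference genome
#'
#' Applies a substitution set to a genome, producing the edited genome, an
#' exact liftover chain and a per-chromosome build report.  The result is
#' byte-identical for any worker count.
#'
#' @param genome a `DNAStringSet` or named character vector (old build).
#' @param subs a [SubstitutionSet-class] object.
#' @param workers number of parallel workers (per-chromosome forks via
#'   `parallel::mclapply`; 1 = serial).
#' @param newName label recorded as the new build's name.
#' @return list with `genome` (`DNAStringSet`, headers carry an
#'   `edits=<n>` provenance suffix), `chain` ([LiftoverChain-class]),
#'   `plan` ([EditPlan-class]) and `report` (data.frame of per-chromosome
#'   edit/skip counts and length deltas).
#' @export
buildReference <- function(genome, subs, workers = 1L, newName = "majref") {
  seqs <- genome_as_char(genome)
  plan <- planEdits(subs, seqs)
  chroms <- names(seqs)
  worker <- function(ch) {
    applyEdits(seqs[[ch]], plan@edits[plan@edits$chrom == ch, , drop = FALSE])
  }
  results <- if (workers > 1L) {
    parallel::mclapply(chroms, worker, mc.cores = workers)
  } else {
    lapply(chroms, worker)
  }
  names(results) <- chroms
  blocks <- do.call(rbind, lapply(chroms, function(ch) {
    b <- results[[ch]]$blocks
    if (nrow(b) == 0) return(NULL)
    cbind(chrom = ch, b)
  }))
  rownames(blocks) <- NULL
  oldLen <- vapply(seqs, nchar, 0L)
  newLen <- vapply(results, function(r) r$newLength, 0)
  chain <- new("LiftoverChain", blocks = blocks,
               lengths = data.frame(chrom = chroms,
                                    oldLength = as.numeric(oldLen),
                                    newLength = as.numeric(newLen),
                                    row.names = NULL))
  nEdits <- vapply(chroms, function(ch) sum(plan@edits$chrom == ch), 0L)
  nSkip <- vapply(chroms, function(ch) sum(plan@skipped$chrom == ch), 0L)
  report <- data.frame(chrom = chroms, edits = nEdits, skipped = nSkip,
                       oldLength = as.numeric(oldLen),
                       newLength = as.numeric(newLen),
                       delta = as.numeric(newLen - oldLen), row.names = NULL)
  out <- Biostrings::DNAStringSet(vapply(results, function(r) r$seq, ""))
  names(out) <- sprintf("%s %s:edits=%d", chroms, newName, nEdits)
  list(genome = out, chain = chain, plan = plan, report = report)
}

#' Translate positions through a liftover chain
#'
#' Positions inside an aligned block map affinely; positions inside an
#' edited (length-changing) span are unmapped and return NA.
#'
#' @param chain a [LiftoverChain-class] object.
#' @param chrom character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param direction `"old2new"` (default) or `"new2old"`.
#' @return integer vector of 1-based positions, NA where unmapped.
#' @export
liftPositions <- function(chain, chrom, pos,
                          direction = c("old2new", "new2old")) {
  direction <- match.arg(direction)
  b <- chain@blocks
  if (direction == "new2old") {
    b <- data.frame(chrom = b$chrom, oldStart0 = b$newStart0,
                    newStart0 = b$oldStart0, length = b$length)
    lenCol <- "newLength"
  } else lenCol <- "oldLength"
  lens <- chain@lengths
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    L <- lens[[lenCol]][match(ch, lens$chrom)]
    if (is.na(L)) stop("contig absent from chain: ", ch)
    p <- pos[sel]
    if (any(p < 1 | p > L))
      stop("position out of bounds on ", ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    p0 <- p - 1L
    i <- findInterval(p0, bb$oldStart0)
    ok <- i >= 1 & p0 < bb$oldStart0[pmax(i, 1)] + bb$length[pmax(i, 1)]
    out[sel[ok]] <- as.integer(bb$newStart0[i[ok]] + (p0[ok] - bb$oldStart0[i[ok]]) + 1)
  }
  out
}

#' Identify the edit covering an unmapped position
#'
#' @param plan an [EditPlan-class] object.
#' @param chrom,pos contig and 1-based old-build position.
#' @return data.frame row(s) of covering edit(s) (0 rows if none).
#' @export
coveringEdit <- function(plan, chrom, pos) {
  e <- plan@edits
  hit <- e$chrom == chrom & pos - 1L >= e$start0 & pos - 1L < e$start0 + e$oldLen
  e[hit, , drop = FALSE]
}
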