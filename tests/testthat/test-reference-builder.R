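make_subs <- function(chrom, pos, ref, alt, af = 0.75) {
  n <- length(chrom)
  e <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  AC = rep(3L, n), AN = rep(4L, n), AF = rep_len(af, n),
                  stringsAsFactors = FALSE)
  e <- e[order(e$chrom, e$pos), ]
  rownames(e) <- NULL
  new("SubstitutionSet", edits = e, threshold = 0.5)
}

test_that("disjoint edits are all accepted; empty sets give empty plans", {
  g <- c(chr1 = "AACGTACGTA")
  plan <- planEdits(make_subs("chr1", c(5, 9), c("T", "T"), c("G", "C")), g)
  expect_equal(nrow(plan@edits), 2)
  expect_equal(nrow(plan@skipped), 0)

  empty <- make_subs(character(0), integer(0), character(0), character(0))
  plan0 <- planEdits(empty, g)
  expect_equal(nrow(plan0@edits), 0)
})

test_that("overlapping candidates resolve left-most-first with a skip log", {
  g <- c(chr1 = "AACGTACGTA")
  # deletion spanning pos 5-8 (ref TACG alt T), then SNP at 6
  subs <- make_subs("chr1", c(5, 6), c("TACG", "A"), c("T", "G"))
  plan <- planEdits(subs, g)
  expect_equal(plan@edits$pos, 5)
  expect_equal(plan@skipped$pos, 6)
  expect_equal(plan@skipped$reason, "overlap")
})

test_that("reference mismatches are hard errors naming the site", {
  g <- c(chr1 = "AACGTACGTA")
  expect_error(planEdits(make_subs("chr1", 5, "G", "A"), g), "chr1:5")
  # N in the genome is a mismatch like any other
  gn <- c(chr1 = "AACGNACGTA")
  expect_error(planEdits(make_subs("chr1", 5, "T", "G"), gn), "chr1:5")
  expect_error(planEdits(make_subs("chr9", 5, "T", "G"), g), "chr9")
})

test_that("SNP, deletion and insertion edits splice correctly with chains", {
  # SNP pos 3 C>G on AACGT
  b <- applyEdits("AACGT", data.frame(start0 = 2L, oldLen = 1L,
                                      replacement = "G"))
  expect_equal(b$seq, "AAGGT")
  expect_equal(nrow(b$blocks), 1)          # same-length edit: no break
  expect_equal(b$blocks$length, 5)

  # deletion pos 2 AC>A: trimmed edit removes base 3 (0-based span [2,3))
  d <- applyEdits("AACGT", data.frame(start0 = 2L, oldLen = 1L,
                                      replacement = ""))
  expect_equal(d$seq, "AAGT")
  chain <- new("LiftoverChain",
               blocks = cbind(chrom = "chr1", d$blocks),
               lengths = data.frame(chrom = "chr1", oldLength = 5,
                                    newLength = d$newLength))
  expect_equal(liftPositions(chain, "chr1", 5), 4L)   # old T
  expect_true(is.na(liftPositions(chain, "chr1", 3))) # deleted C

  # insertion pos 5 T>TAA
  i <- applyEdits("AACGT", data.frame(start0 = 5L, oldLen = 0L,
                                      replacement = "AA"))
  expect_equal(i$seq, "AACGTAA")
  expect_equal(i$newLength, 7)
})

test_that("built genomes equal the splice oracle and chains are coherent", {
  set.seed(19)
  for (rep in 1:25) {
    g <- random_genome(sample(2000:6000, 1), contigs = 2)
    subs <- random_substitutions(g, nPerContig = sample(5:25, 1))
    b <- buildReference(g, subs)
    newChar <- as.character(b$genome)
    names(newChar) <- sub(" .*", "", names(newChar))
    for (ch in names(g)) {
      ee <- b$plan@edits[b$plan@edits$chrom == ch, , drop = FALSE]
      expect_identical(newChar[[ch]], oracle_splice(g[[ch]], ee))
      # position map oracle vs liftPositions, every old position
      map <- oracle_position_map(nchar(g[[ch]]), ee)
      lifted <- liftPositions(b$chain, rep(ch, nchar(g[[ch]])),
                              seq_len(nchar(g[[ch]])))
      expect_identical(lifted, map)
      # round trip new -> old -> new is the identity on mappable positions
      allNew <- seq_len(nchar(newChar[[ch]]))
      back <- liftPositions(b$chain, rep(ch, length(allNew)), allNew,
                            direction = "new2old")
      mappable <- which(!is.na(back))
      again <- liftPositions(b$chain, rep(ch, length(mappable)),
                             back[mappable])
      expect_identical(again, as.integer(mappable))
      # sequence/liftover coherence: bases agree except substituted SNPs
      snpNew <- lifted[ee$pos[ee$oldLen == nchar(ee$replacement) &
                                ee$oldLen == 1L]]
      oldB <- strsplit(g[[ch]], "")[[1]]
      newB <- strsplit(newChar[[ch]], "")[[1]]
      ok <- which(!is.na(lifted))
      agree <- oldB[ok] == newB[lifted[ok]]
      expect_true(all(agree | (lifted[ok] %in% snpNew)))
    }
    # chain length conservation
    lens <- chainLengths(b$chain)
    blocks <- chainBlocks(b$chain)
    for (ch in lens$chrom) {
      bb <- blocks[blocks$chrom == ch, ]
      oldGaps <- lens$oldLength[lens$chrom == ch] - sum(bb$length)
      newGaps <- lens$newLength[lens$chrom == ch] - sum(bb$length)
      expect_gte(oldGaps, 0)
      expect_gte(newGaps, 0)
      expect_equal(lens$newLength[lens$chrom == ch] -
                     lens$oldLength[lens$chrom == ch],
                   sum(nchar(b$plan@edits$replacement[b$plan@edits$chrom == ch]) -
                         b$plan@edits$oldLen[b$plan@edits$chrom == ch]))
    }
  }
})

test_that("SNP-only substitution sets keep one full-length block per contig", {
  set.seed(23)
  g <- random_genome(3000, contigs = 2)
  subs <- random_substitutions(g, nPerContig = 12, indelProb = 0)
  b <- buildReference(g, subs)
  blocks <- chainBlocks(b$chain)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$length, c(3000, 3000))
  expect_equal(blocks$oldStart0, blocks$newStart0)
})

test_that("construction is identical for any worker count", {
  set.seed(29)
  g <- random_genome(2000, contigs = 5)
  subs <- random_substitutions(g, nPerContig = 10)
  b1 <- buildReference(g, subs, workers = 1)
  b2 <- buildReference(g, subs, workers = 3)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(chainBlocks(b1$chain), chainBlocks(b2$chain))
  expect_identical(b1$report, b2$report)
})

test_that("the build report accounts for every planted substitution", {
  set.seed(31)
  g <- random_genome(5000, contigs = 3)
  subs <- random_substitutions(g, nPerContig = 30)
  b <- buildReference(g, subs)
  expect_equal(sum(b$report$edits) + nrow(b$plan@skipped),
               nrow(substitutions(subs)))
  # no substitutions: genome unchanged
  empty <- make_subs(character(0), integer(0), character(0), character(0))
  b0 <- buildReference(g, empty)
  got <- as.character(b0$genome)
  names(got) <- sub(" .*", "", names(got))
  expect_identical(got, unlist(g))
})

test_that("identity chains map positions to themselves and bounds error", {
  g <- c(chr1 = "AACGTACGTA")
  empty <- make_subs(character(0), integer(0), character(0), character(0))
  b <- buildReference(g, empty)
  expect_equal(liftPositions(b$chain, rep("chr1", 10), 1:10), 1:10)
  expect_error(liftPositions(b$chain, "chr1", 11), "out of bounds")
  expect_error(liftPositions(b$chain, "chr1", 0), "out of bounds")
})

test_that("written chain files drive standard liftover tooling correctly", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  set.seed(37)
  g <- random_genome(4000, contigs = 1)
  subs <- random_substitutions(g, nPerContig = 15, indelProb = 0.6)
  b <- buildReference(g, subs)
  path <- tempfile(fileext = ".chain")
  on.exit(unlink(path))
  writeChainFile(b$chain, path)
  ch <- rtracklayer::import.chain(path)
  # our chain: target = new build, query = old; liftOver maps new -> old
  newLen <- chainLengths(b$chain)$newLength[1]
  newPos <- sort(sample(newLen, 200))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(newPos, newPos))
  lifted <- rtracklayer::liftOver(gr, ch)
  mine <- liftPositions(b$chain, rep("chr1", length(newPos)), newPos,
                        direction = "new2old")
  theirs <- vapply(seq_along(newPos), function(i) {
    x <- lifted[[i]]
    if (length(x) == 0) NA_integer_ else as.integer(GenomicRanges::start(x))
  }, 1L)
  expect_identical(mine, theirs)
})

test_that("covering edits are reported for unmapped positions", {
  g <- c(chr1 = "AACGTACGTA")
  subs <- make_subs("chr1", 2, "ACG", "A")   # deletes bases 3-4
  b <- buildReference(g, subs)
  expect_true(is.na(liftPositions(b$chain, "chr1", 3)))
  hit <- coveringEdit(b$plan, "chr1", 3)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pos, 2)
})
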