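## Fixtures: a tiny genome with one substituted SNP and three samples in
## the three genotype states at that site.

truth_table_fixture <- function() {
  g <- c(chr1 = "AACGTACGTACGTACGTACG")
  subs <- new("SubstitutionSet",
              edits = data.frame(chrom = "chr1", pos = 5, ref = "T",
                                 alt = "G", AC = 5L, AN = 6L, AF = 5 / 6),
              threshold = 0.5)
  build <- buildReference(g, subs)
  gt <- matrix(c("1/1", "0/1", "0/0"), nrow = 1,
               dimnames = list(NULL, c("homalt", "het", "homref")))
  cs <- cohortSites(data.frame(chrom = "chr1", pos = 5, id = ".",
                               ref = "T", alt = "G"), gt)
  list(build = build, cohort = cs)
}

test_that("hom-alt calls at substituted sites vanish on the new reference", {
  f <- truth_table_fixture()
  cs <- callsetFromGenotypes(f$cohort, "homalt")
  rp <- reprojectCallset(cs, f$build)
  expect_equal(nrow(variantCalls(rp$callset)), 0)
  expect_equal(nrow(rp$unresolvable), 0)
})

test_that("het calls at substituted sites survive with ref/alt swapped", {
  f <- truth_table_fixture()
  cs <- callsetFromGenotypes(f$cohort, "het")
  rp <- reprojectCallset(cs, f$build)
  v <- variantCalls(rp$callset)
  expect_equal(nrow(v), 1)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "T")
  expect_equal(v$gt, "het")
  expect_equal(v$pos, 5)
})

test_that("hom-ref samples gain a hom-alt call at substituted sites", {
  f <- truth_table_fixture()
  cs <- callsetFromGenotypes(f$cohort, "homref")
  expect_equal(nrow(variantCalls(cs)), 0)     # absent = hom-ref
  rp <- reprojectCallset(cs, f$build)
  v <- variantCalls(rp$callset)
  expect_equal(nrow(v), 1)
  expect_equal(v$gt, "hom_alt")
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "T")
})

test_that("third-allele and indel-overlap calls are side-listed", {
  g <- c(chr1 = "AACGTACGTACGTACGTACG")
  subs <- new("SubstitutionSet",
              edits = data.frame(chrom = "chr1", pos = c(5, 10),
                                 ref = c("T", "ACGT"), alt = c("G", "A"),
                                 AC = 5L, AN = 6L, AF = 5 / 6),
              threshold = 0.5)
  build <- buildReference(g, subs)
  cs <- new("Callset", sample = "x", reference = "old",
            variants = data.frame(
              chrom = "chr1", pos = c(5, 12), ref = c("T", "G"),
              alt = c("C", "C"), gt = "het", stringsAsFactors = FALSE))
  rp <- reprojectCallset(cs, build)
  # pos 5 T>C is a different alt at the substituted SNP; pos 12 sits in
  # the deleted span of the pos-10 indel edit
  expect_equal(nrow(rp$unresolvable), 2)
  # neither substitution may then claim the hom-ref default at those sites:
  # the SNP site is occupied by the conflicting call, the indel overlapped
  v <- variantCalls(rp$callset)
  expect_equal(nrow(v), 0)
})

test_that("the exact reduction identity holds on random cohorts", {
  set.seed(51)
  for (rep in 1:10) {
    g <- random_genome(6000, contigs = 2)
    sim <- simulateCohort(simConfig(seed = 100 + rep, nSamples = 12,
                                    nSites = 120,
                                    contigLengths = c(chr1 = 6000, chr2 = 6000)),
                          Biostrings::DNAStringSet(unlist(g)))
    cohort <- sim$cohort
    af <- suppressWarnings(computeAf(cohort))
    subs <- selectMajorSites(af)
    if (nrow(substitutions(subs)) == 0) next
    gset <- Biostrings::DNAStringSet(unlist(g))
    names(gset) <- names(g)
    build <- buildReference(gset, subs)
    eKey <- variantKey(substitutions(subs)$chrom, substitutions(subs)$pos,
                       substitutions(subs)$ref, substitutions(subs)$alt,
                       harmonize = FALSE)
    for (s in sampleIds(cohort)[1:4]) {
      cs <- callsetFromGenotypes(cohort, s)
      v <- variantCalls(cs)
      vKey <- variantKey(v$chrom, v$pos, v$ref, v$alt, harmonize = FALSE)
      rp <- reprojectCallset(cs, build)
      # guard-gapped simulated sites never straddle applied edits
      expect_equal(nrow(rp$unresolvable), 0)
      nHomAltAtSubs <- sum(vKey %in% eKey & v$gt == "hom_alt")
      nHomRefAbsent <- sum(!eKey %in% vKey)
      reduction <- nrow(v) - nrow(variantCalls(rp$callset))
      expect_equal(reduction, nHomAltAtSubs - nHomRefAbsent)
    }
  }
})

test_that("reprojection is an involution via the inverse build", {
  set.seed(53)
  g <- random_genome(5000, contigs = 1)
  gset <- Biostrings::DNAStringSet(unlist(g))
  sim <- simulateCohort(simConfig(seed = 77, nSamples = 10, nSites = 80,
                                  contigLengths = c(chr1 = 5000),
                                  missingRate = 0),
                        gset)
  cohort <- sim$cohort
  af <- computeAf(cohort)
  subs <- selectMajorSites(af)
  build <- buildReference(gset, subs)
  inv <- invertBuild(build)
  for (s in sampleIds(cohort)[1:5]) {
    cs <- callsetFromGenotypes(cohort, s)
    fwd <- reprojectCallset(cs, build)
    expect_equal(nrow(fwd$unresolvable), 0)
    back <- reprojectCallset(fwd$callset, inv, reference = "old")
    expect_equal(nrow(back$unresolvable), 0)
    v0 <- variantCalls(cs)
    v0 <- v0[order(v0$chrom, v0$pos, v0$ref), ]
    v2 <- variantCalls(back$callset)
    v2 <- v2[order(v2$chrom, v2$pos, v2$ref), ]
    rownames(v0) <- rownames(v2) <- NULL
    expect_equal(v0, v2)
  }
})

test_that("comparison tables reproduce exact differences and percents", {
  ct <- comparisonTable(c(chr1 = 402961), c(chr1 = 323321))
  rows <- comparisonRows(ct)
  expect_equal(rows$difference, 79640)
  expect_equal(round(rows$percent, 2), 19.76)

  # identical callsets: zero differences
  a <- new("Callset", sample = "s", reference = "old",
           variants = data.frame(chrom = c("chr1", "chr2"), pos = c(1, 2),
                                 ref = "A", alt = "G", gt = "het",
                                 stringsAsFactors = FALSE))
  ct0 <- compareCallsets(a, a)
  expect_true(all(comparisonRows(ct0)$difference == 0))

  # b larger than a: negative difference
  ctn <- comparisonTable(c(chrY = 18826), c(chrY = 18881))
  expect_equal(comparisonRows(ctn)$difference, -55)

  # zero count: percent undefined
  ctz <- comparisonTable(c(chrZ = 0), c(chrZ = 5))
  expect_true(is.na(comparisonRows(ctz)$percent))
})

test_that("totals report both percent definitions", {
  ct <- comparisonTable(c(a = 100, b = 1000), c(a = 50, b = 900))
  t <- comparisonTotals(ct)
  expect_equal(t[["difference"]], 150)
  expect_equal(t[["percent_of_totals"]], 100 * 150 / 1100)
  expect_equal(t[["mean_percent"]], mean(c(50, 10)))
})

test_that("catalog overlap equals naive set arithmetic", {
  set.seed(59)
  mk <- function(n, chrom = "chr1") {
    pos <- sample(1e5, n)
    data.frame(chrom = chrom, pos = pos,
               ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               AC = sample(1:50, n, replace = TRUE),
               AN = 100L, stringsAsFactors = FALSE)
  }
  a <- mk(400); a <- a[a$ref != a$alt, ]; a$AF <- a$AC / a$AN
  b <- mk(400); b <- b[b$ref != b$alt, ]; b$AF <- b$AC / b$AN
  shared <- sample(nrow(a), 120)
  b[1:120, ] <- a[shared, ]
  aT <- afTable(a); bT <- afTable(b)
  rep <- catalogOverlap(aT, bT, thresholds = c(0.01, 0.05, 0.10, 0.50))
  aK <- variantKey(a$chrom, a$pos, a$ref, a$alt)
  bK <- variantKey(b$chrom, b$pos, b$ref, b$alt)
  expect_equal(rep@overlap, length(intersect(aK, bK)))
  only <- a[!aK %in% bK, ]
  expect_equal(rep@aOnly, nrow(only))
  expect_equal(rep@aOnlyAcGt1, sum(only$AC > 1))
  expect_equal(unname(rep@afThresholdCounts),
               vapply(c(0.01, 0.05, 0.1, 0.5),
                      function(t) sum(only$AF > t), 0L))
  # monotone non-increasing in threshold
  expect_true(all(diff(rep@afThresholdCounts) <= 0))
})

test_that("catalog overlap handles identity, disjoint and non-SNP inputs", {
  a <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
                  AC = 2L, AN = 10L, AF = 0.2, stringsAsFactors = FALSE)
  aT <- afTable(a)
  same <- catalogOverlap(aT, aT)
  expect_equal(same@overlap, 5L)
  expect_equal(same@aOnly, 0L)
  disj <- catalogOverlap(aT, variantKey("chr2", 1:5, "A", "G"))
  expect_equal(disj@overlap, 0L)
  # indels rejected with a count
  withIndel <- a; withIndel$ref[1] <- "AT"
  rep <- catalogOverlap(afTable(withIndel), aT)
  expect_equal(rep@rejected[["a"]], 1L)
})
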