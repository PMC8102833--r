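## Seeded synthetic fixtures: reference genomes, Hardy-Weinberg diploid
## cohorts with planted AF spectra / admixture / inbreeding, clustered
## genotype matrices, and the analytic call-reduction oracle.

#' Build a synthetic-cohort configuration
#'
#' All generator output is a pure function of this object.  The default
#' spectrum plants roughly 9% of sites with alternate AF above 0.5
#' (8% common-reference + 1% rare-reference), echoing the share of
#' major-alternate sites a large admixed human cohort shows, with the
#' rare-alternate class dominating.
#'
#' @param seed integer RNG seed (mandatory; every draw derives from it).
#' @param contigLengths named numeric vector of contig lengths in bp.
#' @param nSamples number of diploid samples.
#' @param nSites number of variant sites to plant.
#' @param spectrum named category proportions (`rare_alt`, `common_alt`,
#'   `common_ref`, `rare_or_unobserved_ref`), summing to 1.
#' @param inbreeding per-sample inbreeding F (scalar recycled or length
#'   `nSamples`).
#' @param missingRate per-genotype missingness probability.
#' @param indelFraction fraction of substitution-eligible (truth AF > 0.5)
#'   sites planted as indels (default 0.2; the rest are SNPs).
#' @param indelLenRange indel length range in bp (default 1-10).
#' @param admixture NULL, or `list(K =, divergence =, alpha =)` for
#'   K ancestral allele-frequency profiles at Balding-Nichols divergence
#'   `divergence`, mixed per sample with Dirichlet(`alpha`) proportions.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(seed,
                      contigLengths = c(chr1 = 60000, chr2 = 40000),
                      nSamples = 50L,
                      nSites = 500L,
                      spectrum = c(rare_alt = 0.66, common_alt = 0.25,
                                   common_ref = 0.08,
                                   rare_or_unobserved_ref = 0.01),
                      inbreeding = 0,
                      missingRate = 0.01,
                      indelFraction = 0.2,
                      indelLenRange = c(1L, 10L),
                      admixture = NULL) {
  new("SimConfig", seed = as.integer(seed),
      contigLengths = contigLengths,
      nSamples = as.integer(nSamples), nSites = as.integer(nSites),
      spectrum = spectrum, inbreeding = as.numeric(inbreeding),
      missingRate = missingRate, indelFraction = indelFraction,
      indelLenRange = as.integer(indelLenRange),
      admixture = if (is.null(admixture)) list() else admixture)
}

# run expr under a seed derived from the config, restoring the caller's
# RNG state afterwards (single generator threaded through all draws)
with_sim_rng <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg@seed + offset) %% .Machine$integer.max)
  expr
}

#' Simulate a uniform-composition reference genome
#'
#' @param cfg a [SimConfig-class] object.
#' @return a `DNAStringSet` with the configured contigs; deterministic per
#'   seed.
#' @export
simulateReference <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  with_sim_rng(cfg, 0L, {
    seqs <- vapply(cfg@contigLengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(cfg@contigLengths)
    out
  })
}

# draw a true AF for each site given its category
draw_category_af <- function(category, n) {
  lo <- c(rare_alt = 0.002, common_alt = 0.05, common_ref = 0.5,
          rare_or_unobserved_ref = 0.95)
  hi <- c(rare_alt = 0.05, common_alt = 0.5, common_ref = 0.95,
          rare_or_unobserved_ref = 1)
  stats::runif(n, lo[category], hi[category])
}

# Balding-Nichols draw of a derived profile around base frequency p
balding_nichols <- function(p, fst) {
  if (fst <= 0) return(p)
  stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a diploid cohort with a planted AF spectrum
#'
#' Sites are placed on the genome with a guard gap wider than the longest
#' indel so planted spans never overlap.  Each site draws a true
#' alternate AF from the configured category mixture; with admixture, K
#' ancestral profiles are drawn around it and each sample's site
#' frequency is its admixture-weighted mixture.  Genotypes follow
#' inbreeding-adjusted Hardy-Weinberg proportions
#' `(q^2 + Fpq, 2pq(1-F), p^2 + Fpq)`; missingness is applied per
#' genotype.  Substitution-eligible sites (truth AF > 0.5) are planted as
#' indels (anchor-base convention) at the configured fraction.
#'
#' @param cfg a [SimConfig-class] object.
#' @param genome the reference from [simulateReference()] (or compatible).
#' @return list with `cohort` (biallelic, normalized
#'   [CohortSites-class]), `truth` (data.frame: site, true AF, category,
#'   substitution eligibility), and `admixture` (per-sample proportions,
#'   NULL without admixture structure).
#' @export
simulateCohort <- function(cfg, genome) {
  stopifnot(is(cfg, "SimConfig"))
  seqs <- genome_as_char(genome)
  with_sim_rng(cfg, 1L, {
    gap <- cfg@indelLenRange[2] + 2L
    # candidate positions on a guard-gapped grid, away from contig ends
    cand <- lapply(names(seqs), function(ch) {
      L <- nchar(seqs[[ch]])
      seq(gap, L - gap, by = gap)
    })
    names(cand) <- names(seqs)
    total <- sum(lengths(cand))
    if (cfg@nSites > total)
      stop("cannot place ", cfg@nSites, " sites without span collisions; ",
           "use a larger genome")
    take <- round(cfg@nSites * lengths(cand) / total)
    while (sum(take) != cfg@nSites) # rounding fix-up
      take[which.max(lengths(cand) - take)] <-
        take[which.max(lengths(cand) - take)] + sign(cfg@nSites - sum(take))
    pos <- lapply(names(seqs), function(ch)
      sort(sample(cand[[ch]], take[[ch]])))
    chrom <- rep(names(seqs), vapply(pos, length, 0L))
    pos <- unlist(pos)
    n <- length(pos)

    category <- sample(names(cfg@spectrum), n, replace = TRUE,
                       prob = cfg@spectrum)
    trueAf <- draw_category_af(category, n)
    eligible <- trueAf > 0.5

    # alleles: SNPs everywhere, indels at the configured fraction of
    # substitution-eligible sites (half deletions, half insertions)
    refBase <- vapply(seq_len(n), function(i)
      substr(seqs[[chrom[i]]], pos[i], pos[i]), "")
    ref <- refBase
    alt <- vapply(refBase, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    isIndel <- eligible & stats::runif(n) < cfg@indelFraction
    idx <- which(isIndel)
    if (length(idx) > 0) {
      len <- sample(seq(cfg@indelLenRange[1], cfg@indelLenRange[2]),
                    length(idx), replace = TRUE)
      isDel <- stats::runif(length(idx)) < 0.5
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (isDel[k]) {
          ref[i] <- substr(seqs[[chrom[i]]], pos[i], pos[i] + len[k])
          alt[i] <- refBase[i]
        } else {
          ref[i] <- refBase[i]
          alt[i] <- paste0(refBase[i],
                           paste(sample(c("A", "C", "G", "T"), len[k],
                                        replace = TRUE), collapse = ""))
        }
      }
    }

    # per-sample site frequencies
    nS <- cfg@nSamples
    admix <- NULL
    if (length(cfg@admixture) > 0) {
      K <- cfg@admixture$K
      fst <- cfg@admixture$divergence
      alpha <- rep(cfg@admixture$alpha, length.out = K)
      profiles <- vapply(seq_len(K), function(k)
        balding_nichols(trueAf, fst), numeric(n))      # n x K
      q <- matrix(stats::rgamma(nS * K, shape = alpha), nS, K, byrow = TRUE)
      q <- q / rowSums(q)
      P <- profiles %*% t(q)                           # n x nS
      admix <- data.frame(sample = sprintf("s%03d", seq_len(nS)), q)
      names(admix)[-1] <- paste0("anc", seq_len(K))
      trueAf <- rowMeans(P)      # cohort-level truth = mean sample frequency
      eligible <- trueAf > 0.5
    } else {
      P <- matrix(trueAf, n, nS)
    }

    Fv <- rep(cfg@inbreeding, length.out = nS)
    Fm <- matrix(Fv, n, nS, byrow = TRUE)
    pHomRef <- (1 - P)^2 + Fm * P * (1 - P)
    pHet <- 2 * P * (1 - P) * (1 - Fm)
    u <- matrix(stats::runif(n * nS), n, nS)
    g <- (u >= pHomRef) + (u >= pHomRef + pHet)        # 0/1/2 dosage
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n, nS)
    if (cfg@missingRate > 0)
      gt[matrix(stats::runif(n * nS) < cfg@missingRate, n, nS)] <- "./."
    colnames(gt) <- sprintf("s%03d", seq_len(nS))

    sites <- data.frame(chrom = chrom, pos = pos, id = ".",
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
    truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        true_af = trueAf, category = category,
                        major = eligible, indel = isIndel,
                        stringsAsFactors = FALSE)
    list(cohort = cohortSites(sites, gt), truth = truth, admixture = admix)
  })
}

#' Simulate clustered genotype matrices
#'
#' Each cluster owns an ancestral allele-frequency profile drawn around a
#' shared base profile at the given Balding-Nichols divergence; samples
#' are i.i.d. binomial within cluster.  Used to validate that stride
#' selection covers all planted clusters.
#'
#' @param nSamples,nMarkers matrix dimensions.
#' @param nClusters number of planted clusters (>= 2).
#' @param divergence Balding-Nichols F between cluster profiles.
#' @param seed RNG seed.
#' @return list with `genotypes` (samples x markers dosage matrix,
#'   rownames = sample ids) and `labels` (cluster assignment).
#' @export
simulateClusterGenotypes <- function(nSamples = 60L, nMarkers = 300L,
                                     nClusters = 3L, divergence = 0.1,
                                     seed = 1L) {
  stopifnot(nClusters >= 2)
  cfg <- simConfig(seed)
  with_sim_rng(cfg, 2L, {
    base <- stats::runif(nMarkers, 0.1, 0.9)
    profiles <- vapply(seq_len(nClusters), function(k)
      balding_nichols(base, divergence), numeric(nMarkers))
    labels <- sort(rep_len(seq_len(nClusters), nSamples))
    g <- t(vapply(seq_len(nSamples), function(i)
      stats::rbinom(nMarkers, 2L, profiles[, labels[i]]),
      numeric(nMarkers)))
    rownames(g) <- sprintf("s%03d", seq_len(nSamples))
    list(genotypes = g, labels = labels)
  })
}

#' Simulate Hardy-Weinberg GT strings at given site frequencies
#'
#' Draws diploid genotypes independently per sample at the supplied
#' alternate allele frequencies, with optional inbreeding deflation of
#' heterozygosity and per-genotype missingness.  Useful for generating
#' held-out evaluation samples at an existing site table.
#'
#' @param p numeric vector of site alternate allele frequencies.
#' @param nSamples number of samples.
#' @param inbreeding inbreeding coefficient F (scalar or per sample).
#' @param missingRate per-genotype missingness probability.
#' @param prefix sample-id prefix.
#' @return character GT matrix, `length(p)` x `nSamples`.
#' @export
simulateHweGenotypes <- function(p, nSamples, inbreeding = 0,
                                 missingRate = 0, prefix = "e") {
  n <- length(p)
  Fm <- matrix(rep(inbreeding, length.out = nSamples), n, nSamples,
               byrow = TRUE)
  P <- matrix(p, n, nSamples)
  pHomRef <- (1 - P)^2 + Fm * P * (1 - P)
  pHet <- 2 * P * (1 - P) * (1 - Fm)
  u <- matrix(stats::runif(n * nSamples), n, nSamples)
  g <- (u >= pHomRef) + (u >= pHomRef + pHet)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n, nSamples)
  if (missingRate > 0)
    gt[matrix(stats::runif(n * nSamples) < missingRate, n, nSamples)] <- "./."
  colnames(gt) <- sprintf("%s%03d", prefix, seq_len(nSamples))
  gt
}

#' Analytic expected per-sample call reduction
#'
#' Under Hardy-Weinberg genotypes at a substituted site with alternate
#' frequency p, a sample loses a call when homozygous-alternate (p^2) and
#' gains one when homozygous-reference ((1-p)^2), so the expected net
#' reduction per site is `p^2 - (1-p)^2 = 2p - 1`; the total is the sum
#' over substituted sites.
#'
#' @param afs alternate allele frequencies of the substituted sites (all
#'   strictly > 0.5).
#' @return expected per-sample net call reduction.
#' @examples
#' expectedCallReduction(0.75)  # 0.5
#' @export
expectedCallReduction <- function(afs) {
  if (any(afs <= 0.5))
    stop("all substituted-site AFs must exceed 0.5")
  sum(2 * afs - 1)
}
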