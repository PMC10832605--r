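suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## GRanges from 0-based half-open coordinates (the BED convention used in
## the on-disk formats), for readable fixtures
gr0 <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), genome_len = 1e5,
                         max_width = 500L) {
  s0 <- floor(runif(n, 0, genome_len - max_width))
  w <- 1L + floor(runif(n, 0, max_width))
  gr0(sample(chroms, n, replace = TRUE), s0, s0 + w,
      name = sprintf("pk%d", seq_len(n)))
}

## per-base boolean-array oracle: which bases of a chromosome are covered
base_mask <- function(peaks, chrom, genome_len) {
  mask <- logical(genome_len)
  p <- peaks[as.character(seqnames(peaks)) == chrom]
  for (i in seq_along(p)) mask[start(p)[i]:end(p)[i]] <- TRUE
  mask
}

## oracle: is each peak of A shared with >= 1 base of B's coverage?
oracle_shared <- function(A, B, genome_len = 1e5) {
  chroms <- unique(as.character(seqnames(B)))
  masks <- lapply(setNames(chroms, chroms), function(cn)
    base_mask(B, cn, genome_len))
  vapply(seq_along(A), function(i) {
    cn <- as.character(seqnames(A))[i]
    if (!cn %in% chroms) return(FALSE)
    any(masks[[cn]][start(A)[i]:end(A)[i]])
  }, TRUE)
}

## oracle: total covered bases of the union of peak sets
oracle_union_bases <- function(sets, genome_len = 1e5) {
  all <- do.call(c, lapply(sets, granges))
  chroms <- unique(as.character(seqnames(all)))
  sum(vapply(chroms, function(cn)
    sum(base_mask(all, cn, genome_len)), 0))
}

## independent step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

## independent exact hypergeometric upper tail via log binomials
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## exhaustive enumeration of the binned score distribution of all 4^w
## w-mers under the background -- the independent oracle for the DP
enumerate_tail <- function(pwm, bg, threshold, bin = 0.01) {
  lom <- isotarget:::logOddsMatrix(pwm, bg)[, 1:4, drop = FALSE]
  w <- nrow(lom)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (r in seq_len(w)) {
    sc <- sc + round(lom[r, grid[, r]] / bin)   # binned per column
    pr <- pr * bg[grid[, r]]
  }
  sum(pr[sc >= round(threshold / bin)])
}

random_pwm <- function(width, id = "rand") {
  p <- matrix(rgamma(4 * width, 1), width)
  p <- p / rowSums(p)
  colnames(p) <- c("A", "C", "G", "T")
  PWMotif(id, p)
}

## a tiny deterministic two-gene model on one 100-kb chromosome:
##  gplus: + strand [20000,23000) with exons [20000,20500), [21200,21800),
##         [22500,23000) and CDS [20250,22750)
##  gminus: - strand [60000,63000), same internal layout
tiny_gene_model <- function() {
  mk <- function(path) path
  lines <- c(
    paste("chrT", 20000, 23000, "gplus", 0, "+", 20250, 22750, 0, 3,
          "500,600,500", "0,1200,2500", sep = "\t"),
    paste("chrT", 60000, 63000, "gminus", 0, "-", 60250, 62750, 0, 3,
          "500,600,500", "0,1200,2500", sep = "\t"))
  f <- tempfile(fileext = ".bed12")
  writeLines(lines, f)
  readGeneModel(f, "bed12")
}

small_sim_config <- function(seed = 1, ...) {
  syntheticConfig(seed = seed, nChroms = 1L, chromLen = 4e5, nGenes = 40L,
                  ownershipCounts = c(dN_specific = 30L, common = 40L,
                                      TA_specific = 20L),
                  targetCounts = c(dN_only = 10L, common = 6L,
                                   TA_only = 6L),
                  geneSetPlan = list(nPlanted = 2L, nRandom = 4L,
                                     setSize = 10L),
                  ...)
}
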