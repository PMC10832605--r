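test_that("pairwise overlap respects the half-open convention and chrom", {
  a <- gr0("chr1", 100, 200)
  expect_true(intervalOverlaps(a, gr0("chr1", 150, 250)))
  expect_false(intervalOverlaps(a, gr0("chr1", 200, 300)))  # bookended
  expect_false(intervalOverlaps(a, gr0("chr2", 100, 200)))
  expect_false(intervalOverlaps(a, gr0("chr1", 150, 250), minOverlap = 51))
  expect_true(intervalOverlaps(a, gr0("chr1", 150, 250), minOverlap = 50))
})

test_that("peak-set comparison matches the per-base oracle", {
  A <- gr0("chrA", 0, 10); B <- gr0("chrA", 5, 15)
  r <- intersectPeakSets(A, B)
  expect_equal(c(r$n_A_only, nrow(r$pairs), r$n_B_only), c(0L, 1L, 0L))
  r2 <- intersectPeakSets(gr0("chrA", 0, 10), gr0("chrA", 20, 30))
  expect_equal(c(r2$n_A_only, nrow(r2$pairs), r2$n_B_only), c(1L, 0L, 1L))

  set.seed(42)
  for (rep in 1:5) {
    A <- random_peaks(500); B <- random_peaks(300)
    r <- intersectPeakSets(A, B)
    shared <- logical(length(A))
    shared[unique(r$pairs$a)] <- TRUE
    expect_identical(shared, oracle_shared(A, B))
    expect_equal(r$n_A_only + r$n_shared_A, length(A))
  }
})

test_that("union merges bookends and matches the base-count oracle", {
  u <- unionPeaks(gr0("c", 0, 10), gr0("c", 5, 15))
  expect_equal(c(start(u), end(u)), c(1L, 15L))
  u2 <- unionPeaks(gr0("c", 0, 10), gr0("c", 10, 20))
  expect_equal(length(u2), 1L)
  expect_equal(end(u2), 20L)

  set.seed(7)
  sets <- replicate(3, random_peaks(200), simplify = FALSE)
  u <- unionPeaks(sets)
  expect_false(is.unsorted(u))
  expect_true(all(width(IRanges::gaps(ranges(u))) >= 0))
  expect_equal(sum(width(u)), oracle_union_bases(sets))
  ## idempotent and order-invariant
  expect_identical(granges(unionPeaks(u)), granges(u))
  expect_identical(granges(unionPeaks(rev(sets))), granges(u))
})

test_that("gene windows extend and clamp", {
  g <- gr0("c", 50000, 60000, gene_id = "g")
  w <- geneWindow(g, 10000)
  expect_equal(c(start(w) - 1L, end(w)), c(40000L, 70000L))
  g2 <- gr0("c", 5000, 6000)
  w2 <- geneWindow(g2, 10000)
  expect_equal(c(start(w2) - 1L, end(w2)), c(0L, 16000L))
  expect_equal(ranges(geneWindow(g, 0)), ranges(g))
})

test_that("peak-to-gene assignment matches the all-pairs oracle", {
  g <- gr0("c", 50000, 60000, gene_id = "g1")
  expect_equal(nrow(assignPeaksToGenes(gr0("c", 39000, 39500, name = "p"),
                                       g)), 0L)
  expect_equal(nrow(assignPeaksToGenes(gr0("c", 40000, 40100, name = "p"),
                                       g)), 1L)

  set.seed(11)
  peaks <- random_peaks(300)
  genes <- random_peaks(50)
  mcols(genes)$gene_id <- sprintf("g%d", 1:50)
  got <- assignPeaksToGenes(peaks, genes, w = 10000)
  expected <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    hits <- vapply(seq_along(genes), function(j) {
      same <- as.character(seqnames(peaks))[i] ==
        as.character(seqnames(genes))[j]
      lo <- max(1, start(genes)[j] - 10000)
      hi <- end(genes)[j] + 10000
      same && start(peaks)[i] <= hi && end(peaks)[i] >= lo
    }, TRUE)
    if (!any(hits)) return(NULL)
    data.frame(peak = mcols(peaks)$name[i],
               gene_id = mcols(genes)$gene_id[hits])
  }))
  key <- function(d) sort(paste(d$peak, d$gene_id))
  expect_identical(key(got), key(expected))
})

test_that("summit annotation is strand-aware with fixed precedence", {
  gm <- tiny_gene_model()
  ann1 <- function(s0) as.character(
    annotatePeaks(gr0("chrT", s0, s0 + 1), gm))
  expect_equal(ann1(20100), "UTR5")       # + gene, exon before CDS start
  expect_equal(ann1(21500), "Exon")       # middle exon inside CDS
  expect_equal(ann1(22900), "UTR3")       # exon after CDS end
  expect_equal(ann1(20700), "Intron")
  expect_equal(ann1(15000), "Upstream10kb")    # 5 kb 5' of + gene
  expect_equal(ann1(25000), "Downstream10kb")
  expect_equal(ann1(62900), "UTR5")       # - gene: high coords are 5'
  expect_equal(ann1(60100), "UTR3")
  expect_equal(ann1(65000), "Upstream10kb")    # 5' flank of - gene
  expect_equal(ann1(55000), "Downstream10kb")
  expect_equal(ann1(40000), "Intergenic")
  expect_equal(ann1(95000), "Intergenic")      # beyond all flanks
})

test_that("annotation uses the summit when present and exon beats intron", {
  ## two overlapping genes: point is exonic in one, intronic in the other
  f <- tempfile()
  writeLines(c(
    paste("chrT", 1000, 4000, "gA", 0, "+", 1000, 4000, 0, 2,
          "500,500", "0,2500", sep = "\t"),
    paste("chrT", 900, 4100, "gB", 0, "+", 900, 4100, 0, 2,
          "50,100", "0,3100", sep = "\t")), f)
  gm <- readGeneModel(f, "bed12")
  pk <- gr0("chrT", 1000, 3000, summit = 1200L)  # summit in gA exon1
  expect_equal(as.character(annotatePeaks(pk, gm)), "Exon")
  mcols(pk)$summit <- 2000L                      # intron of both
  expect_equal(as.character(annotatePeaks(pk, gm)), "Intron")
})

test_that("annotation is invariant to gene order and fractions normalize", {
  gm <- tiny_gene_model()
  gm_rev <- new("GeneModel", genes = rev(geneBodies(gm)),
                exons = rev(geneExons(gm)))
  set.seed(3)
  pk <- random_peaks(100, chroms = "chrT")
  expect_identical(annotatePeaks(pk, gm), annotatePeaks(pk, gm_rev))
  fr <- annotationDistribution(pk, gm)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_error(annotationDistribution(pk[0], gm), "empty")

  ## deterministic fixture: 2 exonic + 2 intronic
  fix <- gr0("chrT", c(20100, 21500, 20700, 21900),
             c(20110, 21510, 20710, 21910))
  fr2 <- annotationDistribution(fix, gm)
  expect_equal(unname(fr2[c("UTR5", "Exon", "Intron")]),
               c(0.25, 0.25, 0.5))
})
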