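test_that("BED6 peaks parse with coordinate conversion and strict errors", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200\tp1\t50\t.",
               "chr2\t0\t10\tp2\t0\t+"), f)
  pk <- readPeaks(f, "bed6")
  expect_equal(as.character(seqnames(pk)), c("chr1", "chr2"))
  expect_equal(start(pk), c(101L, 1L))   # 0-based half-open -> 1-based
  expect_equal(end(pk), c(200L, 10L))
  expect_equal(mcols(pk)$name, c("p1", "p2"))
  expect_equal(mcols(pk)$score, c(50, 0))

  writeLines("chr1\t200\t100\tp1", f)
  expect_error(readPeaks(f, "bed6"), "line 1.*start >= end")
  writeLines("chr1\t100", f)
  expect_error(readPeaks(f, "bed6"), "columns")
  writeLines(c("chr1\t1\t5\tdup", "chr1\t10\t20\tdup"), f)
  expect_error(readPeaks(f, "bed6"), "duplicate")
})

test_that("narrowPeak summit offsets become genomic summits", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200\tp1\t50\t.\t3.2\t-1\t-1\t25",
               "chr1\t300\t400\tp2\t10\t.\t1.0\t-1\t-1\t-1"), f)
  pk <- readPeaks(f, "narrowPeak")
  expect_equal(mcols(pk)$summit, c(126L, NA))  # 100 + 25, 1-based
  writeLines("chr1\t100\t200\tp1\t50\t.\t3.2\t-1\t-1\t150", f)
  expect_error(readPeaks(f, "narrowPeak"), "summit offset")
  writeLines("chr1\t100\t200\tp1\t50\t.", f)
  expect_error(readPeaks(f, "narrowPeak"), "10 columns")
})

test_that("peak write/read round-trips both dialects", {
  pk <- gr0("chr3", c(10, 500), c(60, 900),
            name = c("a", "b"), score = c(1.5, 7),
            summit = c(36L, NA))
  for (d in c("bed6", "narrowPeak")) {
    f <- tempfile()
    writePeaks(pk, f, d)
    back <- readPeaks(f, d)
    expect_equal(start(back), start(pk))
    expect_equal(end(back), end(pk))
    expect_equal(mcols(back)$name, mcols(pk)$name)
    expect_equal(mcols(back)$score, mcols(pk)$score)
    if (d == "narrowPeak") expect_equal(mcols(back)$summit, mcols(pk)$summit)
  }
})

test_that("readPeaks agrees with rtracklayer on a BED6 fixture", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t50\t+",
               "chr2\t5\t60\tp2\t3\t-"), f)
  ours <- readPeaks(f, "bed6")
  ref <- rtracklayer::import(f, format = "BED")
  expect_equal(start(ours), start(ref))
  expect_equal(end(ours), end(ref))
  expect_equal(as.character(seqnames(ours)), as.character(seqnames(ref)))
  expect_equal(mcols(ours)$name, mcols(ref)$name)
})

test_that("BED12 block arithmetic reconstructs exons", {
  f <- tempfile()
  writeLines(paste("chr1", 1000, 1400, "g1", 0, "+", 1000, 1400, 0, 2,
                   "100,100", "0,300", sep = "\t"), f)
  gm <- readGeneModel(f, "bed12")
  ex <- geneExons(gm)[["g1"]]
  expect_equal(start(ex), c(1001L, 1301L))   # [1000,1100), [1300,1400)
  expect_equal(end(ex), c(1100L, 1400L))

  writeLines(paste("chr1", 1000, 1400, "g1", 0, "+", 1000, 1400, 0, 2,
                   "100,200", "0,300", sep = "\t"), f)
  expect_error(readGeneModel(f, "bed12"), "blocks outside")
  writeLines(rep(paste("chr1", 1000, 1400, "g1", 0, "+", 1000, 1400, 0, 1,
                       "400", "0", sep = "\t"), 2), f)
  expect_error(readGeneModel(f, "bed12"), "duplicate gene_id")
})

test_that("minimal GTF converts 1-based inclusive coordinates", {
  f <- tempfile()
  writeLines(c(
    "chr1\tsrc\tgene\t1001\t1400\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\texon\t1301\t1400\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\tCDS\t1050\t1350\t.\t+\t.\tgene_id \"g1\";"), f)
  gm <- readGeneModel(f, "gtf_min")
  ex <- geneExons(gm)[["g1"]]
  expect_equal(start(ex), c(1001L, 1301L))
  expect_equal(end(ex), c(1100L, 1400L))
  expect_equal(mcols(geneBodies(gm))$cds_start, 1050L)
  expect_equal(mcols(geneBodies(gm))$cds_end, 1350L)

  writeLines(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\tgene\t200\t300\t.\t+\t.\tgene_id \"g1\";"), f)
  expect_error(readGeneModel(f, "gtf_min"), "duplicate gene_id")
})

test_that("FASTA reading sanitizes, round-trips, and rejects empty input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), f)
  g <- readGenome(f)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACXT"), f)
  expect_warning(g <- readGenome(f), "1 non-ACGTN")
  expect_equal(as.character(g[["c1"]]), "ACNT")

  two <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT", c2 = "TTTTNNAA"))
  writeGenome(two, f)
  expect_equal(as.character(readGenome(f)), as.character(two))

  file.create(f2 <- tempfile())
  expect_error(readGenome(f2), "empty")
})

test_that("count matrix reader validates integers and genotypes", {
  f <- tempfile(); fm <- tempfile()
  writeLines(c("gene_id\ts1\ts2", "g1\t5\t8", "g2\t0\t2"), f)
  writeLines(c("sample_id\tgenotype", "s1\tWT", "s2\tdNp63KO"), fm)
  se <- readCounts(f, fm)
  expect_equal(dim(se), c(2L, 2L))
  expect_equal(as.character(se$genotype), c("WT", "dNp63KO"))
  expect_identical(SummarizedExperiment::assay(se)["g2", "s2"], 2L)

  writeLines(c("gene_id\ts1\ts2", "g1\t-1\t8"), f)
  expect_error(readCounts(f, fm), "negative")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t8"), f)
  expect_error(readCounts(f, fm), "non-integer")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t8", "g1\t2\t3"), f)
  expect_error(readCounts(f, fm), "duplicate gene")
})

test_that("GMT parsing and round-trip preserve sets and descriptions", {
  f <- tempfile()
  writeLines(c("S1\tdesc one\tg1\tg2", "S2\tother\tg3"), f)
  sets <- readGmt(f)
  expect_equal(sets$S1, c("g1", "g2"))
  expect_equal(attr(sets, "description")[["S1"]], "desc one")
  f2 <- tempfile()
  writeGmt(sets, f2)
  expect_equal(readGmt(f2)$S2, "g3")
  writeLines("S1\tdesc", f)
  expect_error(readGmt(f), ">= 3 fields")
})

test_that("MEME minimal motifs parse, renormalize, and round-trip", {
  f <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M1",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
               " 0.5 0.5 0.0005 0.0",
               " 0.25 0.25 0.25 0.25"), f)
  ms <- readMemeMotifs(f)
  expect_length(ms, 1)
  expect_equal(sum(motifProbs(ms[[1]])[1, ]), 1)  # renormalized
  expect_equal(motifWidth(ms[[1]]), 2L)

  writeLines(c("MEME version 4", "MOTIF M1",
               "letter-probability matrix: alength= 4 w= 1",
               " 0.5 0.5 0.1 0.0"), f)
  expect_error(readMemeMotifs(f), "off by > 1e-3")

  pair <- p63MotifPair()
  f3 <- tempfile()
  writeMemeMotifs(pair, f3)
  back <- readMemeMotifs(f3)
  expect_equal(vapply(back, motifId, ""), vapply(pair, motifId, ""))
  expect_equal(motifProbs(back[[2]]), motifProbs(pair[[2]]),
               tolerance = 1e-5)
})
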