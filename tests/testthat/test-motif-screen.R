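unif <- uniformBackground()

uniform_pwm <- function(width = 4, id = "unif") {
  p <- matrix(0.25, width, 4)
  colnames(p) <- c("A", "C", "G", "T")
  PWMotif(id, p)
}

test_that("window extraction centers, clips, and validates", {
  chrom <- paste(rep("ACGT", 2500), collapse = "")   # 10 kb
  genome <- Biostrings::DNAStringSet(c(c1 = chrom))
  pk <- gr0("c1", 4990, 5010, name = "p", summit = 5001L)
  w <- extractWindows(pk, genome, 1000)
  expect_equal(Biostrings::width(w), 2000L)
  pk2 <- gr0("c1", 490, 510, name = "p", summit = 501L)
  w2 <- extractWindows(pk2, genome, 1000)
  expect_equal(Biostrings::width(w2), 1500L)   # clipped at chrom start
  expect_error(extractWindows(pk, genome, 0), "halfWidth")
  expect_error(extractWindows(gr0("cX", 0, 10, name = "p"), genome),
               "missing")
})

test_that("DP threshold satisfies its defining tail property", {
  set.seed(13)
  for (w in c(1, 3, 5)) {
    pwm <- random_pwm(w)
    for (pv in c(0.05, 1e-3)) {
      t <- scoreThreshold(pwm, unif, pv)
      if (is.infinite(t)) next
      expect_lte(isotarget:::score_tail_mass(pwm, unif, t), pv)
      expect_gt(isotarget:::score_tail_mass(pwm, unif, t - 0.01), pv)
    }
  }
  ## width-1: four outcomes enumerable by hand
  p <- matrix(c(.97, .01, .01, .01), 1,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  t1 <- scoreThreshold(PWMotif("m", p), unif, 0.25)
  expect_lte(enumerate_tail(PWMotif("m", p), unif, t1), 0.25)
  ## uninformative PWM: no score is rare
  expect_equal(scoreThreshold(uniform_pwm(), unif, 1e-4), Inf)
})

test_that("DP null distribution matches exhaustive enumeration", {
  set.seed(14)
  bg2 <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (w in c(2, 4, 6)) {
    pwm <- random_pwm(w)
    for (bg in list(unif, bg2)) {
      t <- scoreThreshold(pwm, bg, 1e-3)
      expect_equal(isotarget:::score_tail_mass(pwm, bg, t),
                   enumerate_tail(pwm, bg, t), tolerance = 1e-12)
    }
  }
})

test_that("scanning scores log-odds with the stated pseudocount", {
  ## width-2 all-A motif: closed form with pseudocount 0.01
  p <- matrix(rep(c(1, 0, 0, 0), each = 2), 2,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- PWMotif("AA", p)
  expected <- 2 * log2((1.01 / 1.04) / 0.25)
  hits <- scanMotif("AA", pwm, unif, threshold = expected - 0.005)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score[1], expected, tolerance = 1e-12)
  ## uniform PWM scores 0 everywhere
  hits0 <- scanMotif("ACGTACGT", uniform_pwm(), unif, threshold = 0)
  expect_true(all(hits0$score == 0))
  ## N bases contribute 0 bits
  hN <- scanMotif("NN", pwm, unif, threshold = -1)
  expect_equal(hN$score, c(0, 0))
  ## sequence shorter than the motif
  expect_equal(nrow(scanMotif("A", pwm, unif, 0)), 0L)
})

test_that("scanning is strand-symmetric", {
  set.seed(15)
  pwm <- random_pwm(6)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), "")
  t <- scoreThreshold(pwm, unif, 0.01)
  for (s in seqs) {
    fwd <- scanMotif(s, pwm, unif, t)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- scanMotif(rc, pwm, unif, t)
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-12)
    expect_equal(table(factor(fwd$strand, c("+", "-")))[["+"]],
                 table(factor(rev$strand, c("+", "-")))[["-"]])
  }
})

test_that("presence matrix detects planted consensus and ignores N runs", {
  set.seed(16)
  cof <- cofactorMotif()
  bgseq <- function() paste(sample(c("A", "C", "G", "T"), 200,
                                   replace = TRUE), collapse = "")
  with_motif <- paste0(substr(bgseq(), 1, 100), "TGACTCAGC",
                       substr(bgseq(), 110, 200))
  wins <- Biostrings::DNAStringSet(c(w1 = with_motif,
                                     w2 = strrep("N", 200)))
  pres <- presenceMatrix(wins, list(cof), bg = "uniform")
  expect_equal(dim(pres), c(2L, 1L))
  expect_true(pres["w1", "NRF2_like"])
  expect_false(pres["w2", "NRF2_like"])
})

test_that("differential enrichment matches exact and sampled tails", {
  ## 60/100 in group A vs 10/200 elsewhere
  pres <- matrix(FALSE, 300, 1, dimnames = list(NULL, "M"))
  owners <- rep(c("A", "B"), c(100, 200))
  pres[c(1:60, 101:110), 1] <- TRUE
  de <- differentialMotifEnrichment(pres, owners, topK = 10)
  row <- de$table[de$table$group == "A", ]
  expect_equal(row$k, 60L); expect_equal(row$K, 70L)
  expect_equal(row$p, oracle_hyper_tail(60, 70, 300, 100),
               tolerance = 1e-12)
  expect_equal(row$rank, 1L)

  ## Monte-Carlo corroboration on a moderate-tail configuration
  presm <- matrix(FALSE, 300, 1, dimnames = list(NULL, "M"))
  presm[c(1:18, 101:130), 1] <- TRUE
  dem <- differentialMotifEnrichment(presm, owners, topK = 10)
  rowm <- dem$table[dem$table$group == "A", ]
  set.seed(17)
  mc <- mean(rhyper(2e5, rowm$K, 300 - rowm$K, 100) >= rowm$k)
  expect_lt(abs(rowm$p - mc),
            4 * sqrt(mc * (1 - mc) / 2e5) + 1e-4)

  ## boundary: k = n = K = N
  pres1 <- matrix(TRUE, 4, 1, dimnames = list(NULL, "M"))
  de1 <- differentialMotifEnrichment(pres1, rep(c("A", "B"), 2))
  expect_equal(de1$table$p, c(1, 1))

  ## equal rates: odds ratios near 1 and no tiny q
  set.seed(18)
  pres2 <- matrix(runif(600) < 0.3, 300, 2,
                  dimnames = list(NULL, c("M1", "M2")))
  de2 <- differentialMotifEnrichment(pres2, owners)
  expect_true(all(de2$table$q > 0.05))
  expect_lt(max(abs(log(de2$table$odds_ratio))), log(3))
  expect_error(differentialMotifEnrichment(pres2, rep("A", 300)),
               "2 non-empty groups")
})

test_that("PWM similarity is reflexive, reverse-complement aware, and
           discriminates unrelated motifs", {
  pair <- p63MotifPair()
  expect_equal(pwmSimilarity(pair[[1]], pair[[1]]), 1)
  p <- motifProbs(pair[[2]])
  rc <- p[rev(seq_len(nrow(p))), c("T", "G", "C", "A")]
  colnames(rc) <- c("A", "C", "G", "T")
  expect_equal(pwmSimilarity(pair[[2]], PWMotif("rc", rc)), 1)
  expect_gt(pwmSimilarity(pair[[1]], pair[[2]]), 0.9)
  expect_error(pwmSimilarity(PWMotif("a", matrix(c(1, 0, 0, 0), 1,
                                                 dimnames = list(NULL, c("A", "C", "G", "T")))),
                             PWMotif("b", matrix(c(0, 1, 0, 0), 1,
                                                 dimnames = list(NULL, c("A", "C", "G", "T"))))),
               "shorter than 4")
  set.seed(19)
  sims <- vapply(1:40, function(i)
    pwmSimilarity(random_pwm(10), random_pwm(10)), 0)
  expect_gte(mean(sims < 0.8), 0.95)
})

test_that("motif-positive windows partition by an external peak union", {
  pres <- matrix(c(TRUE, TRUE, FALSE), 3, 1,
                 dimnames = list(c("w1", "w2", "w3"), "M"))
  coords <- gr0("c", c(0, 5000, 9000), c(2000, 7000, 9500),
                name = c("w1", "w2", "w3"))
  ext <- gr0("c", 1000, 1500)
  part <- partitionByExternalPeaks(pres, "M", ext, coords)
  expect_equal(part$in_external, "w1")
  expect_equal(part$not_in_external, "w2")
  none <- partitionByExternalPeaks(pres, "M", GRanges(), coords)
  expect_equal(length(none$in_external), 0L)
  expect_setequal(c(part$in_external, part$not_in_external),
                  rownames(pres)[pres[, "M"]])
})
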