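#' @importFrom stats rnbinom rnorm runif
NULL

#' Configuration for the synthetic study generator
#'
#' Defines a self-contained emulation of the three-genotype study design:
#' a small genome, a gene model, per-genotype peak files realizing planted
#' ownership labels, knockout count matrices with planted effects tied to
#' target classes, optional motif instances planted into peak windows at
#' group-specific rates, and gene sets with planted enrichment.
#'
#' Defaults: a 2 x 1 Mb genome carrying 200 genes, planted ownership
#' counts (200, 300, 100) for (dN-specific, common, TA-specific), 80
#' target genes (40 dN-only, 20 common, 20 TA-only), knockout effects of
#' |log2 fold change| = 1.5 on a negative-binomial model with dispersion
#' 0.05, and 3 samples per genotype.
#'
#' @param seed RNG seed; all generator randomness flows from it.
#' @param nChroms,chromLen genome shape.
#' @param nGenes number of non-overlapping genes.
#' @param ownershipCounts named counts of planted peaks per owner class.
#' @param peakWidth planted peak width in bp.
#' @param targetCounts named counts of planted direct-target genes per
#'   class (each bounded by the matching ownership count).
#' @param log2fcPlant |log2 fold change| planted in knockout contrasts.
#' @param alpha negative-binomial dispersion of generated counts.
#' @param nSamplesPerGenotype replicates per genotype.
#' @param baseMeanLog,baseMeanSD log-normal baseline expression
#'   (non-target genes).
#' @param targetBaseMean baseline mean of target genes (kept high so the
#'   planted effects are detectable at the study's replicate number).
#' @param sizeFactorCycle planted per-sample depth factors, recycled.
#' @param baseComposition genome base composition (A, C, G, T).
#' @param motifs list of \linkS4class{PWMotif} written to the motif
#'   library file.
#' @param motifPlantRates named list: motif id -> named rates per owner
#'   class in [0, 1]; instances are planted into the 2-kb peak windows.
#' @param consensusOnly plant the consensus sequence instead of sampling
#'   each base from the motif model.
#' @param geneSetPlan list with \code{nPlanted}, \code{nRandom},
#'   \code{setSize}.
#' @return A validated config (class \code{isotarget_sim_config}).
#' @export
syntheticConfig <- function(seed = 1L,
                            nChroms = 2L, chromLen = 1e6, nGenes = 200L,
                            ownershipCounts = c(dN_specific = 200L,
                                                common = 300L,
                                                TA_specific = 100L),
                            peakWidth = 300L,
                            targetCounts = c(dN_only = 40L, common = 20L,
                                             TA_only = 20L),
                            log2fcPlant = 1.5, alpha = 0.05,
                            nSamplesPerGenotype = 3L,
                            baseMeanLog = log(200), baseMeanSD = 1,
                            targetBaseMean = 300,
                            sizeFactorCycle = c(1, 1.25, 0.8),
                            baseComposition = c(A = 0.29, C = 0.21,
                                                G = 0.21, T = 0.29),
                            motifs = list(),
                            motifPlantRates = list(),
                            consensusOnly = FALSE,
                            geneSetPlan = list(nPlanted = 2L, nRandom = 8L,
                                               setSize = 30L)) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLen = as.integer(chromLen), nGenes = as.integer(nGenes),
              ownershipCounts = ownershipCounts, peakWidth = as.integer(peakWidth),
              targetCounts = targetCounts, log2fcPlant = log2fcPlant,
              alpha = alpha, nSamplesPerGenotype = as.integer(nSamplesPerGenotype),
              baseMeanLog = baseMeanLog, baseMeanSD = baseMeanSD,
              targetBaseMean = targetBaseMean,
              sizeFactorCycle = sizeFactorCycle,
              baseComposition = baseComposition,
              motifs = motifs, motifPlantRates = motifPlantRates,
              consensusOnly = isTRUE(consensusOnly),
              geneSetPlan = geneSetPlan)
  stopifnot(all(names(cfg$ownershipCounts) ==
                  c("dN_specific", "common", "TA_specific")),
            all(cfg$ownershipCounts >= 0),
            all(names(cfg$targetCounts) == c("dN_only", "common", "TA_only")),
            all(cfg$targetCounts >= 0),
            cfg$peakWidth >= 50, cfg$alpha > 0, cfg$log2fcPlant > 0,
            cfg$nSamplesPerGenotype >= 2,
            abs(sum(cfg$baseComposition) - 1) < 1e-6)
  if (cfg$targetCounts["dN_only"] > cfg$ownershipCounts["dN_specific"] ||
      cfg$targetCounts["common"] > cfg$ownershipCounts["common"] ||
      cfg$targetCounts["TA_only"] > cfg$ownershipCounts["TA_specific"])
    stop("targetCounts cannot exceed the matching ownershipCounts",
         call. = FALSE)
  if (sum(cfg$targetCounts) > cfg$nGenes)
    stop("more target genes than genes", call. = FALSE)
  for (id in names(cfg$motifPlantRates)) {
    r <- cfg$motifPlantRates[[id]]
    if (any(r < 0 | r > 1)) stop("motif plant rates must be in [0,1]",
                                 call. = FALSE)
    if (!id %in% vapply(cfg$motifs, motifId, ""))
      stop("plant rates given for motif absent from motifs: ", id,
           call. = FALSE)
  }
  class(cfg) <- "isotarget_sim_config"
  cfg
}

## deterministic slot layout; all coordinates 0-based within chrom
sim_layout <- function(cfg) {
  genesPerChrom <- ceiling(cfg$nGenes / cfg$nChroms)
  slotLen <- cfg$chromLen %/% genesPerChrom
  if (slotLen < 10000)
    stop("chromLen too small for nGenes: need >= 10 kb per gene slot; ",
         "increase chromLen", call. = FALSE)
  gridRel <- seq(6800L, slotLen - 400L, by = 1000L)
  list(genesPerChrom = genesPerChrom, slotLen = slotLen,
       geneRelStart = 3000L, geneLen = 3000L,
       exonRel = cbind(start = c(0L, 1200L, 2500L),
                       end = c(500L, 1800L, 3000L)),
       cdsRel = c(250L, 2750L),
       targetPeakCenterRel = 1800L,
       gridRel = gridRel)
}

sample_motif_instance <- function(pwm, consensusOnly) {
  p <- motifProbs(pwm)
  bases <- c("A", "C", "G", "T")
  if (consensusOnly) {
    paste(bases[apply(p, 1, which.max)], collapse = "")
  } else {
    paste(vapply(seq_len(nrow(p)), function(i)
      sample(bases, 1, prob = p[i, ]), ""), collapse = "")
  }
}

#' Generate a synthetic three-genotype study
#'
#' Emits all pipeline inputs plus the ground truth. Outputs with the same
#' config (and seed) are byte-identical.
#'
#' @param config from \code{\link{syntheticConfig}}.
#' @param outdir output directory (created if needed).
#' @return List with \code{files} (named paths), \code{truth} (planted
#'   labels) and \code{config}.
#' @export
generateSyntheticData <- function(config, outdir) {
  stopifnot(inherits(config, "isotarget_sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  lay <- sim_layout(config)
  nG <- config$nGenes

  ## --- genes ----------------------------------------------------------
  gidx <- seq_len(nG)
  g_chrom <- sprintf("chr%d", (gidx - 1L) %/% lay$genesPerChrom + 1L)
  slot0 <- ((gidx - 1L) %% lay$genesPerChrom) * lay$slotLen
  g_start0 <- slot0 + lay$geneRelStart
  g_end0 <- g_start0 + lay$geneLen
  g_strand <- ifelse(gidx %% 2L == 1L, "+", "-")
  gene_id <- sprintf("g%04d", gidx)

  ## --- target classes -------------------------------------------------
  shuffled <- sample(gidx)
  nT <- config$targetCounts
  t_dN <- shuffled[seq_len(nT["dN_only"])]
  t_co <- shuffled[nT["dN_only"] + seq_len(nT["common"])]
  t_TA <- shuffled[nT["dN_only"] + nT["common"] + seq_len(nT["TA_only"])]
  target_class <- rep("none", nG)
  target_class[t_dN] <- "dN_only"
  target_class[t_co] <- "common"
  target_class[t_TA] <- "TA_only"

  ## planted directions (alternating within class) and knockout log2fc;
  ## regulated-by convention: induced by isoform => down in that knockout
  dir_dN <- rep("none", nG); dir_TA <- rep("none", nG)
  alt <- function(idx) ifelse(seq_along(idx) %% 2L == 1L,
                              "induced", "repressed")
  dir_dN[t_dN] <- alt(t_dN)
  dir_dN[t_co] <- alt(t_co); dir_TA[t_co] <- dir_dN[t_co]
  dir_TA[t_TA] <- alt(t_TA)
  lfc_of <- function(d) ifelse(d == "induced", -config$log2fcPlant,
                               ifelse(d == "repressed", config$log2fcPlant, 0))
  lfc_dN <- lfc_of(dir_dN); lfc_TA <- lfc_of(dir_TA)

  ## --- peaks ----------------------------------------------------------
  hw <- config$peakWidth %/% 2L
  owner_for_class <- c(dN_only = "dN_specific", common = "common",
                       TA_only = "TA_specific")
  target_idx <- c(t_dN, t_co, t_TA)
  pk_chrom <- g_chrom[target_idx]
  pk_center0 <- slot0[target_idx] + lay$targetPeakCenterRel
  pk_owner <- owner_for_class[target_class[target_idx]]
  pk_gene <- gene_id[target_idx]

  remaining <- config$ownershipCounts -
    table(factor(pk_owner, levels = names(config$ownershipCounts)))
  n_extra <- sum(remaining)
  grid_chrom <- rep(g_chrom, each = length(lay$gridRel))
  grid_center0 <- rep(slot0, each = length(lay$gridRel)) +
    rep(lay$gridRel, nG) + hw
  keep_grid <- grid_center0 + hw <= config$chromLen
  grid_chrom <- grid_chrom[keep_grid]; grid_center0 <- grid_center0[keep_grid]
  if (n_extra > length(grid_center0))
    stop("not enough room to place all planted peaks disjointly; ",
         "increase chromLen", call. = FALSE)
  pick <- sample(length(grid_center0), n_extra)
  extra_owner <- sample(rep(names(remaining), remaining))
  pk_chrom <- c(pk_chrom, grid_chrom[pick])
  pk_center0 <- c(pk_center0, grid_center0[pick])
  pk_owner <- c(pk_owner, extra_owner)
  pk_gene <- c(pk_gene, rep(NA_character_, n_extra))
  o <- order(pk_chrom, pk_center0)
  pk_chrom <- pk_chrom[o]; pk_center0 <- pk_center0[o]
  pk_owner <- pk_owner[o]; pk_gene <- pk_gene[o]
  pk_id <- sprintf("P%04d", seq_along(pk_center0))
  pk_start0 <- pk_center0 - hw
  pk_end0 <- pk_center0 + hw

  ## --- genome with planted motif instances ----------------------------
  bases <- c("A", "C", "G", "T")
  chrom_names <- sprintf("chr%d", seq_len(config$nChroms))
  genome_ch <- vapply(chrom_names, function(cn)
    paste(sample(bases, config$chromLen, replace = TRUE,
                 prob = config$baseComposition), collapse = ""), "")
  planted_motifs <- data.frame(peak = character(), motif_id = character(),
                               stringsAsFactors = FALSE)
  if (length(config$motifPlantRates)) {
    win_hw <- 1000L
    occupied <- vector("list", length(pk_id))
    for (mid in names(config$motifPlantRates)) {
      rates <- config$motifPlantRates[[mid]]
      pwm <- config$motifs[[which(vapply(config$motifs, motifId, "") == mid)]]
      w <- motifWidth(pwm)
      for (i in seq_along(pk_id)) {
        r <- rates[pk_owner[i]]
        if (is.na(r) || runif(1) >= r) next
        lo <- max(0L, pk_center0[i] - win_hw)
        hi <- min(config$chromLen, pk_center0[i] + win_hw) - w
        placed <- FALSE
        for (try in 1:10) {
          off0 <- lo + floor(runif(1) * (hi - lo + 1L))
          clash <- any(vapply(occupied[[i]], function(iv)
            off0 < iv[2] && off0 + w > iv[1], TRUE))
          if (!clash) { placed <- TRUE; break }
        }
        if (!placed) next
        inst <- sample_motif_instance(pwm, config$consensusOnly)
        ci <- match(pk_chrom[i], chrom_names)
        substr(genome_ch[ci], off0 + 1L, off0 + w) <- inst
        occupied[[i]] <- c(occupied[[i]], list(c(off0, off0 + w)))
        planted_motifs <- rbind(planted_motifs,
                                data.frame(peak = pk_id[i], motif_id = mid,
                                           stringsAsFactors = FALSE))
      }
    }
  }

  ## --- counts ---------------------------------------------------------
  s <- config$nSamplesPerGenotype
  sample_id <- c(sprintf("WT_%d", 1:s), sprintf("dNp63KO_%d", 1:s),
                 sprintf("TAp63KO_%d", 1:s))
  genotype <- rep(GENOTYPE_LEVELS, each = s)
  sf <- rep_len(config$sizeFactorCycle, 3L * s)
  mu0 <- exp(rnorm(nG, config$baseMeanLog, config$baseMeanSD))
  mu0[target_idx] <- config$targetBaseMean
  lfc_mat <- cbind(WT = 0, dNp63KO = lfc_dN, TAp63KO = lfc_TA)
  counts <- matrix(0L, nG, 3L * s,
                   dimnames = list(gene_id, sample_id))
  for (j in seq_len(3L * s)) {
    mu_j <- sf[j] * mu0 * 2^lfc_mat[, genotype[j]]
    counts[, j] <- rnbinom(nG, mu = mu_j, size = 1 / config$alpha)
  }

  ## --- gene sets ------------------------------------------------------
  gsp <- config$geneSetPlan
  sets <- list(); planted_flag <- logical(); pool_of <- character()
  ## coherent (induced-only) pools so planted sets cluster at one end of
  ## a regulated-by ranking, as pathway sets do
  pool_dN <- gene_id[dir_dN == "induced"]
  pool_TA <- gene_id[dir_TA == "induced"]
  pools <- list(dN = pool_dN, TA = pool_TA)
  for (i in seq_len(gsp$nPlanted)) {
    pool_nm <- names(pools)[(i - 1L) %% 2L + 1L]
    pool <- pools[[pool_nm]]
    sz <- min(gsp$setSize, length(pool))
    if (sz < 3) next
    nm <- sprintf("PLANTED_SET_%d", i)
    sets[[nm]] <- sort(sample(pool, sz))
    planted_flag[nm] <- TRUE
    pool_of[nm] <- pool_nm
  }
  for (i in seq_len(gsp$nRandom)) {
    nm <- sprintf("RANDOM_SET_%d", i)
    sets[[nm]] <- sort(sample(gene_id, min(gsp$setSize, nG)))
    planted_flag[nm] <- FALSE
    pool_of[nm] <- NA_character_
  }
  attr(sets, "description") <- setNames(
    ifelse(planted_flag, "planted enriched set", "random control set"),
    names(sets))

  ## --- write files ----------------------------------------------------
  fp <- function(x) file.path(outdir, x)
  files <- c(genome = fp("genome.fa"), genes = fp("genes.bed12"),
             wt = fp("wt.bed"), dn_ko = fp("dn_ko.bed"),
             ta_ko = fp("ta_ko.bed"), counts = fp("counts.tsv"),
             meta = fp("meta.tsv"), gmt = fp("sets.gmt"),
             truth = fp("truth.json"))
  writeGenome(setNames(genome_ch, chrom_names), files["genome"])

  bed12 <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
    g_chrom, g_start0, g_end0, gene_id, g_strand,
    g_start0 + lay$cdsRel[1], g_start0 + lay$cdsRel[2],
    nrow(lay$exonRel),
    paste(lay$exonRel[, "end"] - lay$exonRel[, "start"], collapse = ","),
    paste(lay$exonRel[, "start"], collapse = ","))
  writeLines(bed12, files["genes"])

  emit_bed <- function(sel, path) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t100\t.", pk_chrom[sel],
                       pk_start0[sel], pk_end0[sel], pk_id[sel]), path)
  }
  emit_bed(seq_along(pk_id), files["wt"])                     # all owners
  emit_bed(which(pk_owner %in% c("TA_specific", "common")), files["dn_ko"])
  emit_bed(which(pk_owner %in% c("dN_specific", "common")), files["ta_ko"])

  cdf <- data.frame(gene_id = gene_id, counts, check.names = FALSE)
  write.table(cdf, files["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = sample_id, genotype = genotype),
              files["meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeGmt(sets, files["gmt"])
  if (length(config$motifs)) {
    files["motifs"] <- fp("motifs.meme")
    writeMemeMotifs(config$motifs, files["motifs"],
                    bg = config$baseComposition)
  }

  truth <- list(
    peaks = data.frame(id = pk_id, chrom = pk_chrom, start = pk_start0,
                       end = pk_end0, owner = pk_owner,
                       target_gene = pk_gene, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_id, target_class = target_class,
                       dir_dN = dir_dN, dir_TA = dir_TA,
                       lfc_dN = lfc_dN, lfc_TA = lfc_TA,
                       base_mean = mu0, stringsAsFactors = FALSE),
    motif_windows = planted_motifs,
    gene_sets = data.frame(set = names(sets),
                           planted = unname(planted_flag[names(sets)]),
                           pool = unname(pool_of[names(sets)]),
                           stringsAsFactors = FALSE),
    size_factors = setNames(sf, sample_id),
    seed = config$seed)
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(files = files, truth = truth, config = config)
}

#' Score pipeline outputs against planted truth
#'
#' Computes per-stage recovery metrics: ownership label accuracy over the
#' planted peaks, knockout-DE sensitivity and empirical FDR against
#' planted effects, the target-class confusion matrix and per-class
#' recovery, the planted motif's rank per group, and planted-set
#' over-representation significance. Stages absent from \code{results}
#' are skipped.
#'
#' @param results list with any of \code{ownership}
#'   (\linkS4class{OwnershipTable}), \code{de} (named list of
#'   \code{\link{nbWaldTest}} data.frames keyed \code{dNp63KO},
#'   \code{TAp63KO}), \code{targets} (\code{\link{classifyTargets}}
#'   output), \code{motifs} (\code{\link{differentialMotifEnrichment}}
#'   output), \code{ora} (\code{\link{hypergeomORA}} output).
#' @param truth from \code{\link{generateSyntheticData}}.
#' @param maxQ FDR threshold used for DE sensitivity/FDR.
#' @return Nested list of metrics.
#' @export
evaluateRecovery <- function(results, truth, maxQ = 0.05) {
  out <- list()
  if (!is.null(results$ownership)) {
    reg <- ownerRegions(results$ownership)
    pk <- GRanges(truth$peaks$chrom,
                  IRanges(truth$peaks$start + 1L, truth$peaks$end))
    hits <- findOverlaps(pk, reg)
    pred <- rep(NA_character_, length(pk))
    pred[queryHits(hits)] <- as.character(
      mcols(reg)$owner[subjectHits(hits)])
    out$ownership <- list(accuracy = mean(!is.na(pred) &
                                            pred == truth$peaks$owner),
                          n_planted = length(pk),
                          counts = ownershipSummary(results$ownership))
  }
  if (!is.null(results$de)) {
    out$de <- list()
    for (ct in names(results$de)) {
      res <- results$de[[ct]]
      col <- if (ct == "dNp63KO") "lfc_dN" else "lfc_TA"
      tl <- truth$genes[[col]][match(res$gene_id, truth$genes$gene_id)]
      if (any(is.na(tl)))
        stop("gene ids in DE results not covered by truth", call. = FALSE)
      called <- res$padj < maxQ
      out$de[[ct]] <- list(
        sensitivity = if (any(tl != 0)) mean(called[tl != 0]) else NA,
        fdr = if (any(called)) mean(tl[called] == 0) else 0,
        sign_agreement = if (any(called & tl != 0))
          mean(sign(res$log2FC[called & tl != 0]) ==
                 sign(tl[called & tl != 0])) else NA)
    }
  }
  if (!is.null(results$targets)) {
    tc <- truth$genes$target_class[match(results$targets$gene_id,
                                         truth$genes$gene_id)]
    if (any(is.na(tc)))
      stop("gene ids in target table not covered by truth", call. = FALSE)
    pred <- as.character(results$targets$target_class)
    conf <- table(truth = factor(tc, levels = TARGET_LEVELS),
                  predicted = factor(pred, levels = TARGET_LEVELS))
    rec <- diag(conf) / pmax(rowSums(conf), 1)
    out$targets <- list(confusion = conf, per_class_recovery = rec)
  }
  if (!is.null(results$motifs) && nrow(truth$motif_windows) > 0) {
    tab <- results$motifs$table
    out$motifs <- list()
    for (mid in unique(truth$motif_windows$motif_id)) {
      sub <- tab[tab$motif_id == mid, , drop = FALSE]
      best <- sub[which.min(sub$p), , drop = FALSE]
      out$motifs[[mid]] <- list(group = best$group, rank = best$rank,
                                q = best$q)
    }
  }
  if (!is.null(results$ora)) {
    oras <- results$ora
    if (is.data.frame(oras)) oras <- list(all = oras)
    gs <- truth$gene_sets[truth$gene_sets$planted, , drop = FALSE]
    p <- q <- numeric(nrow(gs))
    for (i in seq_len(nrow(gs))) {
      tabs <- if (!is.null(gs$pool) && !is.na(gs$pool[i]) &&
                  gs$pool[i] %in% names(oras)) oras[gs$pool[i]] else oras
      pi <- vapply(tabs, function(tt) tt$p[match(gs$set[i], tt$set)], 0)
      qi <- vapply(tabs, function(tt) tt$q[match(gs$set[i], tt$set)], 0)
      p[i] <- min(pi); q[i] <- qi[which.min(pi)]
    }
    out$ora <- list(planted_sets = gs$set, p = p, q = q)
  }
  out
}

#' Two synthetic p63-like motif models sharing a binding core
#'
#' A pair of PWMs built around the same 10-bp p53-family half-site core
#' (RRRCATGYYY-like) with different flank sharpness, mimicking the
#' near-identical response elements recovered from isoform-specific peak
#' sets. Synthetic constructs for testing and simulation; not estimated
#' from data.
#'
#' @return List of two \linkS4class{PWMotif}s.
#' @export
p63MotifPair <- function() {
  core <- function(strong, mixA) {
    w <- (1 - strong) / 3
    row <- function(b) { r <- rep(w, 4); r[b] <- strong; r }
    R <- row(1) * mixA + row(3) * (1 - mixA)      # R = A/G
    Y <- row(4) * mixA + row(2) * (1 - mixA)      # Y = C/T
    rbind(R, R, R, row(2), row(1), row(4), row(3), Y, Y, Y)
  }
  mk <- function(id, strong, mixA) {
    p <- core(strong, mixA)
    colnames(p) <- c("A", "C", "G", "T")
    rownames(p) <- NULL
    PWMotif(id, p, 100L)
  }
  list(mk("p63_dN_like", 0.85, 0.50), mk("p63_TA_like", 0.94, 0.65))
}

#' Synthetic antioxidant-response-like cofactor motif
#'
#' An NRF2/ARE-flavoured consensus (TGACTCAGC) as a sharp PWM, used to
#' plant group-specific cofactor signal in simulations. Synthetic
#' construct; not estimated from data.
#'
#' @param id motif identifier.
#' @param strong probability mass on the consensus base per column.
#' @return A \linkS4class{PWMotif}.
#' @export
cofactorMotif <- function(id = "NRF2_like", strong = 0.92) {
  cons <- c("T", "G", "A", "C", "T", "C", "A", "G", "C")
  w <- (1 - strong) / 3
  p <- t(vapply(cons, function(b) {
    r <- rep(w, 4); names(r) <- c("A", "C", "G", "T"); r[b] <- strong; r
  }, numeric(4)))
  rownames(p) <- NULL
  PWMotif(id, p, 50L)
}
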