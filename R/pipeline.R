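#' @importFrom tools md5sum
NULL

#' Pipeline configuration
#'
#' Houses the analysis constants: the 10-kb gene association window, the
#' 2-kb motif screen windows (half width 1 kb), the DE significance
#' thresholds (FDR-adjusted P < 0.05, linear fold change > 1.25), the
#' motif occurrence tail probability 1e-4, and the permutation count for
#' GSEA. All randomness flows from the single seed.
#'
#' @param seed top-level RNG seed.
#' @param windowBp peak-to-gene association window (bp).
#' @param motifHalfWidth half width of motif screen windows (bp).
#' @param maxQ FDR threshold for DE calls.
#' @param minFold linear fold-change threshold for DE calls.
#' @param motifPval background tail probability for motif occurrence.
#' @param nPerm GSEA permutations.
#' @param requireOwnerMatch require peak-owner consistency in target
#'   classification.
#' @return A validated config (class \code{isotarget_pipe_config}).
#' @export
pipelineConfig <- function(seed = 1L, windowBp = 10000L,
                           motifHalfWidth = 1000L, maxQ = 0.05,
                           minFold = 1.25, motifPval = 1e-4,
                           nPerm = 1000L, requireOwnerMatch = TRUE) {
  stopifnot(windowBp >= 0, motifHalfWidth >= 1,
            maxQ > 0, maxQ < 1, minFold > 1,
            motifPval > 0, motifPval < 1, nPerm >= 100)
  structure(list(seed = as.integer(seed), windowBp = as.integer(windowBp),
                 motifHalfWidth = as.integer(motifHalfWidth),
                 maxQ = maxQ, minFold = minFold, motifPval = motifPval,
                 nPerm = as.integer(nPerm),
                 requireOwnerMatch = isTRUE(requireOwnerMatch)),
            class = "isotarget_pipe_config")
}

write_sidecar <- function(path, config, input_files, seed) {
  sc <- list(tool = "isotarget",
             version = as.character(utils::packageVersion("isotarget")),
             config = unclass(config),
             seed = seed,
             inputs = as.list(md5sum(unname(input_files))),
             output_md5 = unname(md5sum(path)))
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Run the full analysis on a generated study
#'
#' Orchestrates simulate -> read -> classify ownership -> differential
#' expression (both knockout contrasts) -> target integration -> motif
#' screen -> enrichment -> recovery scoring. All stage outputs are written
#' under \code{outdir} with JSON provenance sidecars (package version,
#' config, seed, input checksums); re-running with the same config and
#' inputs reproduces identical outputs.
#'
#' @param simConfig from \code{\link{syntheticConfig}}.
#' @param pipeConfig from \code{\link{pipelineConfig}}.
#' @param outdir output directory.
#' @return List with \code{files} (inputs), \code{ownership}, \code{de},
#'   \code{calls}, \code{directions}, \code{targets}, \code{assignments},
#'   \code{motifs} (NULL without planted motifs), \code{ora},
#'   \code{gsea}, \code{report} (recovery metrics), \code{outputs}
#'   (written paths).
#' @export
runPipeline <- function(simConfig, pipeConfig = pipelineConfig(),
                        outdir = tempfile("isotarget_run_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e)
    stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  sim <- tryCatch(generateSyntheticData(simConfig,
                                        file.path(outdir, "fixtures")),
                  error = function(e) fail("simulate", e))
  fx <- sim$files

  ## read everything back through the validating readers
  st <- tryCatch({
    wt <- readPeaks(fx["wt"], "bed6")
    dn <- readPeaks(fx["dn_ko"], "bed6")
    ta <- readPeaks(fx["ta_ko"], "bed6")
    genes <- readGeneModel(fx["genes"], "bed12")
    genome <- readGenome(fx["genome"])
    se <- readCounts(fx["counts"], fx["meta"])
    sets <- readGmt(fx["gmt"])
    list(wt = wt, dn = dn, ta = ta, genes = genes, genome = genome,
         se = se, sets = sets)
  }, error = function(e) fail("read-inputs", e))

  ownership <- tryCatch(classifyOwnership(st$wt, st$dn, st$ta),
                        error = function(e) fail("classify-peaks", e))
  own_path <- file.path(outdir, "ownership.tsv")
  reg <- ownerRegions(ownership)
  write.table(data.frame(chrom = as.character(seqnames(reg)),
                         start = start(reg) - 1L, end = end(reg),
                         name = mcols(reg)$name,
                         owner = as.character(mcols(reg)$owner),
                         support = mcols(reg)$support),
              own_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(own_path, pipeConfig, fx[c("wt", "dn_ko", "ta_ko")],
                pipeConfig$seed)

  de <- list(); calls <- list()
  for (ct in c("dNp63KO", "TAp63KO")) {
    res <- tryCatch(nbWaldTest(st$se, contrast = ct),
                    error = function(e) fail(paste0("de-", ct), e))
    de[[ct]] <- res
    calls[[ct]] <- callDE(res, pipeConfig$maxQ, pipeConfig$minFold)
    p <- file.path(outdir, sprintf("de_%s.tsv", ct))
    write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    write_sidecar(p, pipeConfig, fx[c("counts", "meta")], pipeConfig$seed)
  }

  directions <- regulatedByIsoform(calls$dNp63KO, calls$TAp63KO)
  concordance <- concordanceTable(directions)
  assignments <- assignPeaksToGenes(reg, st$genes, pipeConfig$windowBp)
  targets <- tryCatch(
    classifyTargets(directions, ownership, assignments,
                    pipeConfig$requireOwnerMatch),
    error = function(e) fail("integrate", e))
  tg_path <- file.path(outdir, "targets.tsv")
  write.table(targets, tg_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sidecar(tg_path, pipeConfig, c(own_path), pipeConfig$seed)

  motifs <- NULL
  if (!is.na(fx["motifs"]) && length(simConfig$motifPlantRates)) {
    motifs <- tryCatch({
      pwms <- readMemeMotifs(fx["motifs"])
      wins <- extractWindows(ownership, st$genome,
                             pipeConfig$motifHalfWidth)
      pres <- presenceMatrix(wins, pwms, bg = "windows",
                             pval = pipeConfig$motifPval)
      differentialMotifEnrichment(pres, peakOwners(ownership))
    }, error = function(e) fail("motif-screen", e))
    mo_path <- file.path(outdir, "motif_enrichment.tsv")
    write.table(motifs$table, mo_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_sidecar(mo_path, pipeConfig, fx[c("genome", "motifs")],
                  pipeConfig$seed)
  }

  ## over-representation of each isoform's regulated gene list
  ora <- list()
  for (iso in c("dN", "TA")) {
    query <- directions$gene_id[directions[[iso]] != "none"]
    ora[[iso]] <- tryCatch(hypergeomORA(query, st$sets,
                                        directions$gene_id),
                           error = function(e) fail("enrich", e))
    p <- file.path(outdir, sprintf("ora_%s.tsv", iso))
    write.table(ora[[iso]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_sidecar(p, pipeConfig, fx["gmt"], pipeConfig$seed)
  }

  ## GSEA of each planted set against the matching isoform ranking
  ## (ranking = regulated-by score, the negated knockout fold change)
  ranked <- list(dN = setNames(-de$dNp63KO$log2FC, de$dNp63KO$gene_id),
                 TA = setNames(-de$TAp63KO$log2FC, de$TAp63KO$gene_id))
  gs_truth <- sim$truth$gene_sets
  planted_sets <- gs_truth$set[gs_truth$planted]
  gsea <- lapply(setNames(planted_sets, planted_sets), function(s) {
    pool <- gs_truth$pool[gs_truth$set == s]
    gseaPermutation(ranked[[pool]], st$sets[[s]], pipeConfig$nPerm,
                    seed = pipeConfig$seed)
  })

  report <- evaluateRecovery(list(ownership = ownership, de = de,
                                  targets = targets, motifs = motifs,
                                  ora = ora),
                             sim$truth, maxQ = pipeConfig$maxQ)
  list(files = fx, ownership = ownership, de = de, calls = calls,
       directions = directions, concordance = concordance,
       targets = targets,
       assignments = assignments, motifs = motifs, ora = ora,
       gsea = gsea, report = report,
       outputs = c(ownership = own_path, targets = tg_path))
}
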