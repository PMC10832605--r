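#' @importFrom stats median pnorm p.adjust cor hclust as.dist lm coef var
NULL

get_counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

get_genotypes <- function(x, genotypes = NULL) {
  if (is.null(genotypes) && is(x, "SummarizedExperiment"))
    genotypes <- as.character(x$genotype)
  if (is.null(genotypes))
    stop("sample genotypes are required", call. = FALSE)
  genotypes
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the median, over genes with nonzero
#' counts in all samples, of the ratio of the sample's count to the
#' geometric-mean pseudo-reference.
#'
#' @param counts count matrix (genes x samples) or
#'   \code{SummarizedExperiment}.
#' @return Positive numeric vector, one factor per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  m <- get_counts(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep))
    stop("no gene has nonzero counts in all samples; ",
         "supply a filtered matrix or use a pseudo-reference fallback",
         call. = FALSE)
  ref <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  sf <- apply(m[keep, , drop = FALSE], 2, function(cj) median(cj / ref))
  if (any(sf <= 0)) stop("non-positive size factor", call. = FALSE)
  sf
}

## raw method-of-moments dispersion, untruncated (may be negative)
dispersion_raw <- function(norm, groups) {
  gs <- unique(groups)
  mg <- vapply(gs, function(g)
    rowMeans(norm[, groups == g, drop = FALSE]), numeric(nrow(norm)))
  vg <- vapply(gs, function(g)
    apply(norm[, groups == g, drop = FALSE], 1, var), numeric(nrow(norm)))
  mbar <- rowMeans(mg)
  s2 <- rowMeans(vg)
  list(alpha = (s2 - mbar) / pmax(mbar, 1e-8)^2, mean = mbar)
}

#' Gene-wise method-of-moments dispersion
#'
#' \eqn{\alpha = \max(\alpha_{min}, (s^2 - \bar m)/\bar m^2)} with the
#' within-group mean and variance of normalized counts averaged across
#' groups.
#'
#' @param counts count matrix or \code{SummarizedExperiment}.
#' @param sizeFactors per-sample factors
#'   (default \code{\link{sizeFactorsMedianRatio}}).
#' @param genotypes group labels per sample (taken from \code{colData}
#'   when \code{counts} is a \code{SummarizedExperiment}).
#' @param alphaMin dispersion floor.
#' @return Numeric vector of per-gene dispersions >= \code{alphaMin}.
#' @export
estimateDispersionGenewise <- function(counts, sizeFactors = NULL,
                                       genotypes = NULL, alphaMin = 1e-8) {
  m <- get_counts(counts)
  genotypes <- get_genotypes(counts, genotypes)
  if (any(table(genotypes) < 2))
    stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  norm <- sweep(m, 2, sizeFactors, "/")
  pmax(alphaMin, dispersion_raw(norm, genotypes)$alpha)
}

#' Trended dispersion
#'
#' Fits the mean--dispersion trend \eqn{\alpha(m) = a_0 + a_1/m} to the raw
#' (untruncated) gene-wise method-of-moments estimates: genes with mean > 5
#' are split into 20 equal-occupancy mean bins, the trend is an ordinary
#' least-squares fit through the bin means, and the coefficients are
#' clamped to be non-negative. Plugging the fitted trend into the Wald test
#' removes the small-sample noise of per-gene estimates that would
#' otherwise inflate the type-I error.
#'
#' @inheritParams estimateDispersionGenewise
#' @param nBins number of mean bins for the trend fit.
#' @return Numeric vector of per-gene trended dispersions.
#' @export
estimateDispersionTrend <- function(counts, sizeFactors = NULL,
                                    genotypes = NULL, alphaMin = 1e-8,
                                    nBins = 20L) {
  m <- get_counts(counts)
  genotypes <- get_genotypes(counts, genotypes)
  if (any(table(genotypes) < 2))
    stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  norm <- sweep(m, 2, sizeFactors, "/")
  raw <- dispersion_raw(norm, genotypes)
  mn <- rowMeans(norm)
  ok <- mn > 5 & is.finite(raw$alpha)
  if (sum(ok) < 2 * nBins)
    return(pmax(alphaMin, raw$alpha))  # too few genes for a trend
  b <- cut(rank(mn[ok], ties.method = "first"), nBins)
  mb <- tapply(mn[ok], b, mean)
  ab <- tapply(raw$alpha[ok], b, mean)
  fit <- lm(ab ~ I(1 / mb))
  a0 <- max(alphaMin, unname(coef(fit)[1]))
  a1 <- max(0, unname(coef(fit)[2]))
  pmax(alphaMin, a0 + a1 / pmax(mn, 1e-8))
}

#' Negative-binomial Wald test of knockout versus wild-type
#'
#' Per gene: group means of normalized counts (floored at 1e-8), fold
#' change \eqn{\log_2((m_{KO}+c_0)/(m_{WT}+c_0))} with
#' \eqn{c_0 = 0.5/\mathrm{median}(s_j)}, and a Wald statistic whose
#' standard error comes from the delta-method variance of each group's log2
#' mean, \eqn{(1/\ln 2)^2\,(1/(n m))(1+\alpha m)}, summed over the two
#' groups. P-values are two-sided standard-normal tails; q-values are BH
#' within the contrast.
#'
#' @param counts count matrix or \code{SummarizedExperiment} with a
#'   \code{genotype} column.
#' @param contrast the knockout genotype to compare against \code{WT}.
#' @param sizeFactors per-sample factors (computed when \code{NULL}).
#' @param alphas per-gene dispersions (default:
#'   \code{\link{estimateDispersionTrend}}).
#' @param genotypes group labels when \code{counts} is a bare matrix.
#' @return data.frame with \code{gene_id}, \code{baseMean}, \code{log2FC},
#'   \code{pvalue}, \code{padj}, \code{contrast}.
#' @export
nbWaldTest <- function(counts, contrast = c("dNp63KO", "TAp63KO"),
                       sizeFactors = NULL, alphas = NULL,
                       genotypes = NULL) {
  contrast <- match.arg(contrast)
  m <- get_counts(counts)
  genotypes <- get_genotypes(counts, genotypes)
  for (g in c("WT", contrast))
    if (sum(genotypes == g) < 2)
      stop("need >= 2 samples of genotype ", g, call. = FALSE)
  use <- genotypes %in% c("WT", contrast)
  m <- m[, use, drop = FALSE]
  genotypes <- genotypes[use]
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  else sizeFactors <- sizeFactors[use]
  if (is.null(alphas))
    alphas <- estimateDispersionTrend(m, sizeFactors, genotypes)
  norm <- sweep(m, 2, sizeFactors, "/")
  c0 <- 0.5 / median(sizeFactors)
  iK <- genotypes == contrast
  iW <- genotypes == "WT"
  mK <- pmax(rowMeans(norm[, iK, drop = FALSE]), 1e-8)
  mW <- pmax(rowMeans(norm[, iW, drop = FALSE]), 1e-8)
  lfc <- log2((mK + c0) / (mW + c0))
  nK <- sum(iK); nW <- sum(iW)
  v <- (1 / log(2))^2 *
    ((1 + alphas * mK) / (nK * mK) + (1 + alphas * mW) / (nW * mW))
  z <- lfc / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  gene_id <- rownames(m)
  if (is.null(gene_id)) gene_id <- sprintf("gene_%d", seq_len(nrow(m)))
  data.frame(gene_id = gene_id,
             baseMean = rowMeans(norm),
             log2FC = lfc,
             pvalue = p,
             padj = bhAdjust(p),
             contrast = paste0(contrast, "_vs_WT"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Call differential expression at the study thresholds
#'
#' A gene is DE iff \code{padj < maxQ} and its linear fold change strictly
#' exceeds \code{minFold} in either direction; the sign of the fold change
#' gives the direction.
#'
#' @param results data.frame from \code{\link{nbWaldTest}}.
#' @param maxQ FDR threshold (default 0.05).
#' @param minFold linear fold-change threshold (default 1.25).
#' @return Named factor (\code{up_in_KO}/\code{down_in_KO}/\code{not_DE})
#'   indexed by \code{gene_id}.
#' @export
callDE <- function(results, maxQ = 0.05, minFold = 1.25) {
  stopifnot(maxQ > 0, maxQ < 1, minFold > 1)
  de <- results$padj < maxQ & abs(results$log2FC) > log2(minFold)
  call <- ifelse(!de, "not_DE",
                 ifelse(results$log2FC > 0, "up_in_KO", "down_in_KO"))
  out <- factor(call, levels = c("up_in_KO", "down_in_KO", "not_DE"))
  names(out) <- results$gene_id
  out
}

#' Pearson-distance hierarchical clustering of samples
#'
#' Distance is \eqn{1 - r} with \eqn{r} the Pearson correlation between
#' \eqn{\log_2(\mathrm{normalized\ count} + 1)} profiles;
#' average-linkage agglomeration.
#'
#' @param counts count matrix or \code{SummarizedExperiment}
#'   (>= 3 samples).
#' @param sizeFactors per-sample factors (computed when \code{NULL}).
#' @return \code{hclust} object over samples.
#' @export
pearsonCluster <- function(counts, sizeFactors = NULL) {
  m <- get_counts(counts)
  if (ncol(m) < 3) stop("need >= 3 samples", call. = FALSE)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  lg <- log2(sweep(m, 2, sizeFactors, "/") + 1)
  if (any(apply(lg, 2, var) == 0))
    stop("constant sample profile: correlation undefined", call. = FALSE)
  d <- as.dist(1 - cor(lg))
  hclust(d, method = "average")
}
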