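#' @importFrom GenomicRanges coverage
#' @importFrom IRanges slice
NULL

#' Classify peak ownership from three-genotype ChIP-seq
#'
#' Builds the merged-region universe (union of the three peak sets) and
#' labels each region by the isoform responsible for the binding, using the
#' knockout genotype semantics: peaks still present in the dN-knockout can
#' only be TA-bound and vice versa. Regions supported only by the wild-type
#' file cannot be attributed to one isoform and default to \code{common}
#' (flagged \code{wt_only} in their support) unless \code{requireWT} drops
#' regions lacking wild-type corroboration.
#'
#' @param wt,dnKO,taKO \code{GRanges} peak sets (wt may be empty).
#' @param requireWT drop merged regions without a wild-type overlap.
#' @param minOverlap minimum shared bases for support.
#' @return An \linkS4class{OwnershipTable}.
#' @export
classifyOwnership <- function(wt, dnKO, taKO, requireWT = FALSE,
                              minOverlap = 1L) {
  if (length(wt) + length(dnKO) + length(taKO) == 0)
    stop("all three peak sets are empty", call. = FALSE)
  uni <- unionPeaks(list(wt, dnKO, taKO))
  in_wt <- overlaps_any(uni, wt, minOverlap)
  in_dn <- overlaps_any(uni, dnKO, minOverlap)
  in_ta <- overlaps_any(uni, taKO, minOverlap)
  owner <- rep(NA_character_, length(uni))
  owner[in_dn & !in_ta] <- "TA_specific"
  owner[in_ta & !in_dn] <- "dN_specific"
  owner[in_dn & in_ta] <- "common"
  wt_only <- in_wt & !in_dn & !in_ta
  if (requireWT) {
    keep <- in_wt & (in_dn | in_ta)
    if (any(!keep))
      message(sum(!keep), " regions dropped (wild-type-only or lacking ",
              "wild-type support)")
  } else {
    owner[wt_only] <- "common"
    keep <- rep(TRUE, length(uni))
  }
  uni <- uni[keep]
  owner <- owner[keep]
  supp <- vapply(seq_along(uni), function(i) "", "")
  tags <- cbind(wt = in_wt[keep], dn_ko = in_dn[keep], ta_ko = in_ta[keep])
  supp <- apply(tags, 1, function(r) paste(colnames(tags)[r], collapse = ","))
  supp[wt_only[keep]] <- "wt_only"
  mcols(uni)$name <- sprintf("region_%d", seq_along(uni))
  mcols(uni)$owner <- factor(owner, levels = OWNER_LEVELS)
  mcols(uni)$support <- supp
  new("OwnershipTable", regions = uni)
}

overlaps_any <- function(query, subject, minOverlap = 1L) {
  if (length(subject) == 0) return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject, minoverlap = minOverlap,
                       ignore.strand = TRUE)
}

#' Count regions per ownership class
#'
#' @param table an \linkS4class{OwnershipTable}.
#' @return Named integer vector over \code{dN_specific}, \code{common},
#'   \code{TA_specific}.
#' @export
ownershipSummary <- function(table) {
  stopifnot(is(table, "OwnershipTable"))
  tab <- table(peakOwners(table))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Per-owner genomic-domain distributions
#'
#' One \code{\link{annotationDistribution}} per ownership class; classes
#' without regions are omitted.
#'
#' @param table an \linkS4class{OwnershipTable}.
#' @param genes a \linkS4class{GeneModel}.
#' @return Matrix (owner x category) of fractions; each row sums to 1.
#' @export
ownershipAnnotationReport <- function(table, genes) {
  reg <- ownerRegions(table)
  owners <- peakOwners(table)
  present <- levels(owners)[table(owners) > 0]
  out <- t(vapply(present, function(ow)
    annotationDistribution(reg[owners == ow], genes),
    numeric(length(ANNOTATION_LEVELS))))
  colnames(out) <- ANNOTATION_LEVELS
  out
}

#' Majority-merge replicate peak files
#'
#' Consolidates replicate peak sets into the regions covered by at least
#' \code{k} of the replicates (coverage-based vote over the reduced peaks
#' of each replicate).
#'
#' @param peakSets list of \code{GRanges}, one per replicate.
#' @param k minimum number of supporting replicates (default 2).
#' @return \code{GRanges} of consensus regions.
#' @export
majorityMerge <- function(peakSets, k = 2L) {
  stopifnot(length(peakSets) >= 1, k >= 1, k <= length(peakSets))
  covs <- lapply(peakSets, function(p) coverage(reduce(granges(p),
                                                       ignore.strand = TRUE)))
  all_seq <- unique(unlist(lapply(covs, names)))
  total <- NULL
  for (cv in covs) {
    missing <- setdiff(all_seq, names(cv))
    for (s in missing) cv[[s]] <- S4Vectors::Rle(0L, 0)
    cv <- cv[all_seq]
    lens <- vapply(all_seq, function(s)
      max(vapply(covs, function(x)
        if (s %in% names(x)) length(x[[s]]) else 0L, 0L)), 0L)
    for (s in all_seq)
      if (length(cv[[s]]) < lens[s])
        cv[[s]] <- c(cv[[s]], S4Vectors::Rle(0L, lens[s] - length(cv[[s]])))
    total <- if (is.null(total)) cv else total + cv
  }
  out <- GRanges(slice(total, lower = k, rangesOnly = TRUE))
  sort(out)
}
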