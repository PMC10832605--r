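#' @importFrom GenomicRanges findOverlaps reduce GRangesList
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Do two interval sets overlap element-wise?
#'
#' Strand is ignored (ChIP peaks are unstranded); two intervals overlap when
#' they share at least \code{minOverlap} bases on the same sequence.
#'
#' @param a,b \code{GRanges} of equal length (or length 1, recycled).
#' @param minOverlap minimum shared bases (>= 1).
#' @return Logical vector.
#' @export
intervalOverlaps <- function(a, b, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= minOverlap
}

#' Compare two peak sets
#'
#' The set-comparison primitive behind peak-set Venn diagrams: a peak of A
#' is shared iff it overlaps at least one peak of B (and symmetrically);
#' within-set peaks need not be disjoint.
#'
#' @param A,B \code{GRanges} peak sets.
#' @param minOverlap minimum shared bases.
#' @return List with \code{A_only}, \code{B_only} (\code{GRanges}),
#'   \code{pairs} (data.frame of overlapping A/B indices) and the Venn
#'   counts \code{n_A_only}, \code{n_shared_A}, \code{n_shared_B},
#'   \code{n_B_only}.
#' @export
intersectPeakSets <- function(A, B, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  hits <- findOverlaps(A, B, minoverlap = minOverlap, ignore.strand = TRUE)
  sharedA <- unique(queryHits(hits))
  sharedB <- unique(subjectHits(hits))
  list(A_only = A[setdiff(seq_along(A), sharedA)],
       B_only = B[setdiff(seq_along(B), sharedB)],
       pairs = data.frame(a = queryHits(hits), b = subjectHits(hits)),
       n_A_only = length(A) - length(sharedA),
       n_shared_A = length(sharedA),
       n_shared_B = length(sharedB),
       n_B_only = length(B) - length(sharedB))
}

#' Merge peak sets into a disjoint union
#'
#' Returns the sorted, pairwise-disjoint cover of all input bases.
#' Bookended intervals (adjacent with no gap) are merged, matching the
#' half-open convention in which adjacency is contact.
#'
#' @param ... any number of \code{GRanges} (or a single list of them).
#' @return Sorted disjoint \code{GRanges}.
#' @export
unionPeaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "GRanges"))
    sets <- sets[[1]]
  all <- do.call(c, lapply(sets, granges))
  reduce(all, ignore.strand = TRUE)
}

#' Window around a gene body
#'
#' Extends each gene by \code{w} bases on both sides (the association
#' window for peak-to-gene assignment), clamped at the sequence start.
#'
#' @param genes \code{GRanges} or \linkS4class{GeneModel}.
#' @param w flank size in bp (>= 0); default 10 kb.
#' @return \code{GRanges} of windows.
#' @export
geneWindow <- function(genes, w = 10000L) {
  stopifnot(w >= 0)
  if (is(genes, "GeneModel")) genes <- geneBodies(genes)
  GRanges(seqnames(genes),
          IRanges(pmax(1L, start(genes) - as.integer(w)),
                  end(genes) + as.integer(w)),
          strand = strand(genes),
          mcols(genes))
}

#' Assign peaks to genes by windowed overlap
#'
#' A (peak, gene) pair is emitted whenever the peak overlaps the gene's
#' \code{w}-extended window; the many-to-many structure is preserved.
#'
#' @param peaks \code{GRanges} with a \code{name} metadata column (added if
#'   missing).
#' @param genes \code{GRanges} or \linkS4class{GeneModel} with
#'   \code{gene_id}.
#' @param w association window in bp; default 10 kb.
#' @param minOverlap minimum shared bases.
#' @return data.frame with columns \code{peak}, \code{gene_id}.
#' @export
assignPeaksToGenes <- function(peaks, genes, w = 10000L, minOverlap = 1L) {
  if (is(genes, "GeneModel")) genes <- geneBodies(genes)
  win <- geneWindow(genes, w)
  hits <- findOverlaps(peaks, win, minoverlap = minOverlap,
                       ignore.strand = TRUE)
  nm <- mcols(peaks)$name
  if (is.null(nm)) nm <- sprintf("peak_%d", seq_along(peaks))
  data.frame(peak = nm[queryHits(hits)],
             gene_id = mcols(genes)$gene_id[subjectHits(hits)],
             stringsAsFactors = FALSE)
}

summit_point <- function(peaks) {
  p <- start(peaks) + (width(peaks) - 1L) %/% 2L
  su <- mcols(peaks)$summit
  if (!is.null(su)) {
    has <- !is.na(su)
    p[has] <- as.integer(su[has])
  }
  p
}

## category of a 1-based point relative to one gene; NA when unrelated
point_category <- function(p, chrom, gs, ge, str, ex_s, ex_e, cs, ce,
                           flank = 10000L) {
  if (p >= gs && p <= ge) {
    in_exon <- any(p >= ex_s & p <= ex_e)
    if (!in_exon) return("Intron")
    if (is.na(cs)) return("Exon")
    if (p < cs) return(if (str == "+") "UTR5" else "UTR3")
    if (p > ce) return(if (str == "+") "UTR3" else "UTR5")
    return("Exon")
  }
  if (p < gs && p >= gs - flank)
    return(if (str == "+") "Upstream10kb" else "Downstream10kb")
  if (p > ge && p <= ge + flank)
    return(if (str == "+") "Downstream10kb" else "Upstream10kb")
  NA_character_
}

#' Annotate peaks with genomic-domain categories
#'
#' Each peak is represented by its summit point (metadata column
#' \code{summit} when present, otherwise the interval midpoint with ties
#' toward the start) and assigned exactly one category against the
#' strand-aware gene model. When the point hits features of several genes
#' the precedence is 5'UTR > Exon > 3'UTR > Intron > Upstream10kb >
#' Downstream10kb > Intergenic; the flanks are 10-kb regions oriented by
#' gene strand.
#'
#' @param peaks \code{GRanges}.
#' @param genes \linkS4class{GeneModel}.
#' @return Factor of categories, one per peak.
#' @export
annotatePeaks <- function(peaks, genes) {
  stopifnot(is(genes, "GeneModel"))
  g <- geneBodies(genes)
  ex <- geneExons(genes)
  pts <- GRanges(seqnames(peaks), IRanges(summit_point(peaks), width = 1L))
  hits <- findOverlaps(pts, geneWindow(g, 10000L), ignore.strand = TRUE)
  out <- rep("Intergenic", length(peaks))
  prec <- match(ANNOTATION_LEVELS, ANNOTATION_LEVELS)  # identity ranks
  best <- rep(length(ANNOTATION_LEVELS), length(peaks)) # Intergenic rank
  p_all <- start(pts)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  for (k in seq_along(qh)) {
    i <- qh[k]; j <- sh[k]
    cat_k <- point_category(p_all[i], NULL, start(g)[j], end(g)[j],
                            as.character(strand(g))[j],
                            start(ex[[j]]), end(ex[[j]]),
                            mcols(g)$cds_start[j], mcols(g)$cds_end[j])
    if (is.na(cat_k)) next
    r <- match(cat_k, ANNOTATION_LEVELS)
    if (r < best[i]) { best[i] <- r; out[i] <- cat_k }
  }
  factor(out, levels = ANNOTATION_LEVELS)
}

#' Genomic-domain distribution of a peak set
#'
#' @param peaks non-empty \code{GRanges}.
#' @param genes \linkS4class{GeneModel}.
#' @return Named numeric vector of fractions over all categories
#'   (sums to 1).
#' @export
annotationDistribution <- function(peaks, genes) {
  if (length(peaks) == 0) stop("empty peak set", call. = FALSE)
  tab <- table(annotatePeaks(peaks, genes))
  as.numeric(tab) / length(peaks) -> fr
  names(fr) <- names(tab)
  fr
}
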