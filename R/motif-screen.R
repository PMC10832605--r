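#' @importFrom Biostrings subseq
#' @importFrom stats phyper sd
NULL

#' Zero-order background model from a sequence set
#'
#' Base frequencies over the scanned windows (N excluded), with an add-one
#' pseudocount so every base has positive probability.
#'
#' @param windows \code{DNAStringSet} or character vector.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
backgroundModel <- function(windows) {
  ch <- paste(as.character(windows), collapse = "")
  v <- strsplit(ch, "")[[1]]
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(v == b), 0L)
  (cnt + 1) / sum(cnt + 1)
}

#' Uniform background model
#' @return Named numeric vector, 0.25 each.
#' @export
uniformBackground <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

## log2-odds score matrix (width x 5): columns A,C,G,T,N; N scores 0.
## PWM probabilities get pseudocount 0.01 then are renormalized.
logOddsMatrix <- function(pwm, bg, pseudocount = 0.01) {
  p <- motifProbs(pwm)
  p <- (p + pseudocount) / (1 + 4 * pseudocount)
  s <- log2(sweep(p, 2, bg[colnames(p)], "/"))
  cbind(s, N = 0)
}

revcomp_lom <- function(lom) {
  out <- lom[rev(seq_len(nrow(lom))), c("T", "G", "C", "A", "N"), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T", "N")
  out
}

#' Extract peak-centered sequence windows
#'
#' Windows of up to \code{2 * halfWidth} bases centered on each region's
#' summit (metadata column \code{summit} when present, otherwise the
#' midpoint), clipped at chromosome ends and uppercased.
#'
#' @param peaks an \linkS4class{OwnershipTable} or \code{GRanges} with a
#'   \code{name} metadata column.
#' @param genome named \code{DNAStringSet} covering all peak chromosomes.
#' @param halfWidth half window size in bp (>= 1); default 1000 for the
#'   2-kb screen windows.
#' @return Named \code{DNAStringSet} of windows.
#' @export
extractWindows <- function(peaks, genome, halfWidth = 1000L) {
  if (halfWidth < 1L) stop("halfWidth must be >= 1", call. = FALSE)
  if (is(peaks, "OwnershipTable")) peaks <- ownerRegions(peaks)
  chroms <- as.character(seqnames(peaks))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("chromosomes missing from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ctr <- summit_point(peaks)          # 1-based center
  lens <- Biostrings::width(genome)[match(chroms, names(genome))]
  from <- pmax(1L, ctr - as.integer(halfWidth))
  to <- pmin(lens, ctr + as.integer(halfWidth) - 1L)
  seqs <- DNAStringSet(vapply(seq_along(peaks), function(i)
    toupper(as.character(subseq(genome[[chroms[i]]], from[i], to[i]))), ""))
  nm <- mcols(peaks)$name
  if (is.null(nm)) nm <- sprintf("peak_%d", seq_along(peaks))
  names(seqs) <- nm
  seqs
}

#' Exact PWM score threshold by dynamic programming
#'
#' Computes the null distribution of the log-odds score of a random
#' background-generated w-mer by position-wise convolution of per-column
#' score masses, discretized at \code{bin} bits, and returns the smallest
#' score whose upper-tail mass is at most \code{pval}. \code{Inf} when no
#' attainable score is that rare (e.g. an uninformative PWM).
#'
#' @param pwm a \linkS4class{PWMotif}.
#' @param bg background probabilities over A, C, G, T.
#' @param pval tail probability defining a match (default 1e-4).
#' @param bin discretization width in bits.
#' @return Threshold in bits (possibly \code{Inf}).
#' @export
scoreThreshold <- function(pwm, bg, pval = 1e-4, bin = 0.01) {
  stopifnot(pval > 0, pval < 1)
  lom <- logOddsMatrix(pwm, bg)[, 1:4, drop = FALSE]
  ib <- round(lom / bin)               # integer bin indices per column
  cur_lo <- 0L                         # distribution starts at score 0
  cur <- 1
  for (r in seq_len(nrow(ib))) {
    k <- ib[r, ]
    new_lo <- cur_lo + min(k)
    new_hi <- cur_lo + length(cur) - 1L + max(k)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + k[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  ok <- which(tail <= pval)
  if (!length(ok)) return(Inf)
  (cur_lo + ok[1] - 1L) * bin
}

## exact tail mass P(score >= t) under bg, same discretization as above
score_tail_mass <- function(pwm, bg, t, bin = 0.01) {
  lom <- logOddsMatrix(pwm, bg)[, 1:4, drop = FALSE]
  ib <- round(lom / bin)
  cur_lo <- 0L; cur <- 1
  for (r in seq_len(nrow(ib))) {
    k <- ib[r, ]
    new_lo <- cur_lo + min(k)
    new <- numeric((cur_lo + length(cur) - 1L + max(k)) - new_lo + 1L)
    for (b in 1:4) {
      idx <- seq_along(cur) + (cur_lo + k[b] - new_lo)
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  kt <- round(t / bin)
  sum(cur[(seq_along(cur) + cur_lo - 1L) >= kt])
}

encode_seq <- function(s) {
  v <- strsplit(toupper(as.character(s)), "")[[1]]
  i <- match(v, c("A", "C", "G", "T"))
  i[is.na(i)] <- 5L
  i
}

scan_one_strand <- function(enc, ib_or_lom, w) {
  L <- length(enc)
  npos <- L - w + 1L
  if (npos < 1L) return(numeric(0))
  sc <- numeric(npos)
  for (r in seq_len(w))
    sc <- sc + ib_or_lom[r, enc[r:(r + npos - 1L)]]
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scoring with pseudocount 0.01 on the PWM probabilities; N
#' bases contribute 0 bits. A hit is any position (on either strand) whose
#' score reaches the threshold; scores are compared on the same
#' discretization grid used by \code{\link{scoreThreshold}}.
#'
#' @param sequence character or \code{DNAString}(Set element).
#' @param pwm a \linkS4class{PWMotif}.
#' @param bg background probabilities.
#' @param threshold score threshold in bits (from
#'   \code{\link{scoreThreshold}}).
#' @param bin discretization width in bits.
#' @return data.frame with \code{offset} (0-based, forward-strand
#'   coordinates of the match start), \code{strand}, \code{score} (bits).
#' @export
scanMotif <- function(sequence, pwm, bg, threshold, bin = 0.01) {
  w <- motifWidth(pwm)
  enc <- encode_seq(sequence)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(enc) < w || is.infinite(threshold)) return(empty)
  lom <- logOddsMatrix(pwm, bg)
  kt <- round(threshold / bin)
  res <- list()
  for (str in c("+", "-")) {
    m <- if (str == "+") lom else revcomp_lom(lom)
    sc <- scan_one_strand(enc, m, w)
    hit <- which(round(sc / bin) >= kt)
    if (length(hit))
      res[[str]] <- data.frame(offset = hit - 1L, strand = str,
                               score = sc[hit], stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Peak-by-motif presence matrix
#'
#' TRUE iff the window contains at least one hit of the motif at its
#' background-calibrated threshold.
#'
#' @param windows named \code{DNAStringSet} from
#'   \code{\link{extractWindows}}.
#' @param pwms list of \linkS4class{PWMotif}.
#' @param bg \code{"windows"} (0-order model estimated from the scanned
#'   windows), \code{"uniform"}, or a numeric background vector.
#' @param pval per-motif tail probability for the score threshold.
#' @return Logical matrix, rows = windows, columns = motif ids.
#' @export
presenceMatrix <- function(windows, pwms, bg = "windows", pval = 1e-4) {
  if (is.character(bg) && length(bg) == 1L)
    bg <- switch(bg, windows = backgroundModel(windows),
                 uniform = uniformBackground(),
                 stop("unknown background model", call. = FALSE))
  out <- matrix(FALSE, nrow = length(windows), ncol = length(pwms),
                dimnames = list(names(windows),
                                vapply(pwms, motifId, "")))
  for (j in seq_along(pwms)) {
    thr <- scoreThreshold(pwms[[j]], bg, pval)
    if (is.infinite(thr)) next
    for (i in seq_along(windows))
      out[i, j] <- nrow(scanMotif(windows[[i]], pwms[[j]], bg, thr)) > 0
  }
  out
}

#' Differential motif abundance across ownership groups
#'
#' One-vs-rest hypergeometric upper-tail test per (motif, group) with a
#' Haldane-corrected odds ratio; BH across all motif x group tests; per
#' group, motifs are ranked by ascending p, then descending odds ratio,
#' then motif id.
#'
#' @param presence logical peak x motif matrix from
#'   \code{\link{presenceMatrix}}.
#' @param owners factor/character of group labels parallel to the rows.
#' @param topK rows kept per group in the \code{top} report (default 10).
#' @return List with \code{table} (all rows) and \code{top} (top-K per
#'   group); columns \code{motif_id}, \code{group}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{odds_ratio}, \code{p}, \code{q},
#'   \code{rank}.
#' @export
differentialMotifEnrichment <- function(presence, owners, topK = 10L) {
  owners <- as.character(owners)
  stopifnot(nrow(presence) == length(owners))
  groups <- unique(owners)
  sizes <- table(owners)[groups]
  empty <- names(sizes)[sizes == 0]
  if (length(empty)) {
    warning("empty groups excluded: ", paste(empty, collapse = ", "),
            call. = FALSE)
    groups <- setdiff(groups, empty)
  }
  if (length(groups) < 2)
    stop("need >= 2 non-empty groups", call. = FALSE)
  N <- nrow(presence)
  Kall <- colSums(presence)
  rows <- list()
  for (g in groups) {
    ing <- owners == g
    n <- sum(ing)
    k <- colSums(presence[ing, , drop = FALSE])
    K <- Kall
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- ((k + 0.5) * (N - n - K + k + 0.5)) /
      ((K - k + 0.5) * (n - k + 0.5))
    rows[[g]] <- data.frame(motif_id = colnames(presence), group = g,
                            k = as.integer(k), n = n, K = as.integer(K),
                            N = N, odds_ratio = or, p = p,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q <- bhAdjust(tab$p)
  tab$rank <- NA_integer_
  for (g in groups) {
    i <- which(tab$group == g)
    o <- i[order(tab$p[i], -tab$odds_ratio[i], tab$motif_id[i])]
    tab$rank[o] <- seq_along(o)
  }
  top <- tab[tab$rank <= topK, , drop = FALSE]
  top <- top[order(top$group, top$rank), , drop = FALSE]
  list(table = tab, top = top)
}

#' Pearson similarity of two PWMs
#'
#' Maximum, over all relative offsets with at least \code{minCols}
#' aligned columns and over the second motif versus its reverse
#' complement, of the Pearson correlation between the flattened aligned
#' probability columns.
#'
#' @param a,b \linkS4class{PWMotif}s; at least one must have width >= 4.
#' @param minCols minimum aligned columns (default 4).
#' @return Similarity in [-1, 1].
#' @export
pwmSimilarity <- function(a, b, minCols = 4L) {
  pa <- motifProbs(a); pb <- motifProbs(b)
  if (nrow(pa) < 4 && nrow(pb) < 4)
    stop("both motifs are shorter than 4 columns", call. = FALSE)
  rc <- function(p) {
    out <- p[rev(seq_len(nrow(p))), c("T", "G", "C", "A"), drop = FALSE]
    colnames(out) <- c("A", "C", "G", "T")
    out
  }
  best <- -1
  for (pb2 in list(pb, rc(pb))) {
    wa <- nrow(pa); wb <- nrow(pb2)
    for (off in (-wb + minCols):(wa - minCols)) {
      ia <- max(1, 1 + off):min(wa, wb + off)
      ib <- ia - off
      if (length(ia) < minCols) next
      x <- as.vector(t(pa[ia, , drop = FALSE]))
      y <- as.vector(t(pb2[ib, , drop = FALSE]))
      if (sd(x) == 0 || sd(y) == 0) next
      best <- max(best, cor(x, y))
    }
  }
  best
}

#' Partition motif-positive windows by an external peak union
#'
#' @param presence logical peak x motif matrix.
#' @param motif motif id (column of \code{presence}).
#' @param external merged \code{GRanges} (e.g. the union of external
#'   ChIP-seq peak sets).
#' @param windowCoords \code{GRanges} of the window genomic intervals,
#'   parallel to the rows of \code{presence} (names matching row names).
#' @return List with \code{in_external} and \code{not_in_external} window
#'   name vectors.
#' @export
partitionByExternalPeaks <- function(presence, motif, external,
                                     windowCoords) {
  stopifnot(motif %in% colnames(presence))
  pos <- rownames(presence)[presence[, motif]]
  nm <- mcols(windowCoords)$name
  if (is.null(nm)) nm <- names(windowCoords)
  idx <- match(pos, nm)
  inx <- overlaps_any(windowCoords[idx], external)
  list(in_external = pos[inx], not_in_external = pos[!inx])
}
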