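#' Hypergeometric over-representation analysis
#'
#' For each set: \eqn{p = \sum_{i \ge k} C(K,i) C(N-K,n-i) / C(N,n)} with
#' N the universe size, K the set size within the universe, n the query
#' size and k the overlap. Sets are intersected with the universe before
#' testing; BH across sets; sorted by p.
#'
#' @param query character vector of gene ids (subset of the universe;
#'   ids outside it are dropped with a message).
#' @param sets named list of gene-id vectors (e.g. \code{\link{readGmt}}).
#' @param universe character vector of all testable gene ids.
#' @return data.frame with \code{set}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p}, \code{q}, sorted by ascending p.
#' @export
hypergeomORA <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  out_of <- setdiff(query, universe)
  if (length(out_of)) {
    message(length(out_of), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- bhAdjust(tab$p)
  tab <- tab[order(tab$p, tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov--Smirnov-style running sum over a ranked gene list:
#' set members add \eqn{|s|^w / \sum_{hits} |s|^w}, non-members subtract
#' \eqn{1/(N - N_{hits})}; the enrichment score is the signed extremum of
#' the running sum.
#'
#' @param scores named numeric vector of ranking scores; sorted in
#'   decreasing order internally (stable for ties).
#' @param set character vector of gene ids; must intersect the list.
#' @param weight score weight exponent (default 1, the classic choice).
#' @return Enrichment score in [-1, 1].
#' @export
gseaES <- function(scores, set, weight = 1) {
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  hit <- names(scores) %in% set
  if (!any(hit)) stop("set does not intersect the ranked list",
                      call. = FALSE)
  wts <- abs(scores)^weight
  denom <- sum(wts[hit])
  if (denom == 0)
    stop("all hit scores are zero: weights undefined", call. = FALSE)
  nmiss <- sum(!hit)
  step <- ifelse(hit, wts / denom,
                 if (nmiss > 0) -1 / nmiss else 0)
  run <- cumsum(step)
  ex <- range(run)
  if (abs(ex[2]) >= abs(ex[1])) ex[2] else ex[1]
}

#' GSEA with a gene-label permutation null
#'
#' The observed enrichment score is compared with scores of
#' \code{nPerm} random sets of the same size (gene-label permutation);
#' \eqn{p = (1 + \#\{|ES_{perm}| \ge |ES_{obs}|\})/(n_{perm}+1)}. The
#' normalized score divides by the mean |ES| of same-sign permutations.
#'
#' @inheritParams gseaES
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed for reproducibility.
#' @return List with \code{es}, \code{nes}, \code{p_perm}, \code{n_perm}.
#' @export
gseaPermutation <- function(scores, set, nPerm = 1000L, seed = 1L,
                            weight = 1) {
  stopifnot(nPerm >= 100)
  es_obs <- gseaES(scores, set, weight)
  m <- sum(names(scores) %in% set)
  genes <- names(scores)
  set.seed(seed)
  es_perm <- vapply(seq_len(nPerm), function(i)
    gseaES(scores, sample(genes, m), weight), 0)
  p <- (1 + sum(abs(es_perm) >= abs(es_obs))) / (nPerm + 1)
  same <- es_perm[sign(es_perm) == sign(es_obs)]
  nes <- if (length(same) && mean(abs(same)) > 0)
    es_obs / mean(abs(same)) else 0
  list(es = es_obs, nes = nes, p_perm = p, n_perm = as.integer(nPerm))
}
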