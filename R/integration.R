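#' Per-isoform regulation directions from knockout DE calls
#'
#' An isoform induces a gene when the gene goes down upon knockout of that
#' isoform, and represses it when the gene goes up (loss of the regulator
#' reverses its effect).
#'
#' @param callsDN,callsTA named factors from \code{\link{callDE}} for the
#'   dN-knockout and TA-knockout contrasts, over the same gene universe.
#' @return data.frame with \code{gene_id}, \code{dN}, \code{TA}
#'   (\code{induced}/\code{repressed}/\code{none}).
#' @export
regulatedByIsoform <- function(callsDN, callsTA) {
  genes <- names(callsDN)
  if (!setequal(genes, names(callsTA)))
    stop("the two contrasts cover different gene universes", call. = FALSE)
  callsTA <- callsTA[genes]
  flip <- function(x)
    ifelse(x == "down_in_KO", "induced",
           ifelse(x == "up_in_KO", "repressed", "none"))
  data.frame(gene_id = genes,
             dN = factor(flip(as.character(callsDN)),
                         levels = DIRECTION_LEVELS),
             TA = factor(flip(as.character(callsTA)),
                         levels = DIRECTION_LEVELS),
             stringsAsFactors = FALSE)
}

owner_matches <- function(owner, isoform) {
  if (isoform == "dN") owner %in% c("dN_specific", "common")
  else owner %in% c("TA_specific", "common")
}

#' Three-way direct-target classification
#'
#' A gene is a direct target of an isoform iff the isoform regulates it
#' (direction not \code{none}) and an assigned peak within the association
#' window has a consistent owner (isoform-specific or common when
#' \code{requireOwnerMatch}, any owner otherwise). The target class is the
#' combination of isoforms that pass.
#'
#' @param directions data.frame from \code{\link{regulatedByIsoform}}.
#' @param ownership an \linkS4class{OwnershipTable}.
#' @param assignments data.frame of \code{peak}, \code{gene_id} pairs from
#'   \code{\link{assignPeaksToGenes}} run on the ownership regions.
#' @param requireOwnerMatch require peak-owner consistency (default TRUE).
#' @return data.frame with \code{gene_id}, \code{target_class},
#'   \code{dir_dN}, \code{dir_TA}, \code{supporting_peaks} (comma-joined
#'   \code{name:owner}).
#' @export
classifyTargets <- function(directions, ownership, assignments,
                            requireOwnerMatch = TRUE) {
  reg <- ownerRegions(ownership)
  owner_of <- as.character(mcols(reg)$owner)
  names(owner_of) <- mcols(reg)$name
  peaks_of <- split(assignments$peak, assignments$gene_id)
  n <- nrow(directions)
  target_class <- character(n)
  support <- character(n)
  for (i in seq_len(n)) {
    gid <- directions$gene_id[i]
    pk <- peaks_of[[gid]]
    ow <- owner_of[pk]
    pass <- c(dN = FALSE, TA = FALSE)
    for (iso in c("dN", "TA")) {
      if (directions[[iso]][i] == "none") next
      okpk <- if (requireOwnerMatch) ow[owner_matches(ow, iso)] else ow
      pass[iso] <- length(okpk) > 0
    }
    target_class[i] <-
      if (pass["dN"] && pass["TA"]) "common"
      else if (pass["dN"]) "dN_only"
      else if (pass["TA"]) "TA_only"
      else "none"
    support[i] <- if (target_class[i] == "none" || !length(pk)) ""
                  else paste(pk, ow, sep = ":", collapse = ",")
  }
  data.frame(gene_id = directions$gene_id,
             target_class = factor(target_class, levels = TARGET_LEVELS),
             dir_dN = directions$dN,
             dir_TA = directions$TA,
             supporting_peaks = support,
             stringsAsFactors = FALSE)
}

#' Direction concordance among genes regulated by both isoforms
#'
#' @param directions data.frame from \code{\link{regulatedByIsoform}}.
#' @return Named integer vector: \code{both_induced},
#'   \code{both_repressed}, \code{dN_repressed_TA_induced},
#'   \code{dN_induced_TA_repressed}; the four counts sum to the number of
#'   genes regulated by both isoforms.
#' @export
concordanceTable <- function(directions) {
  both <- directions$dN != "none" & directions$TA != "none"
  d <- directions[both, , drop = FALSE]
  c(both_induced = sum(d$dN == "induced" & d$TA == "induced"),
    both_repressed = sum(d$dN == "repressed" & d$TA == "repressed"),
    dN_repressed_TA_induced = sum(d$dN == "repressed" & d$TA == "induced"),
    dN_induced_TA_repressed = sum(d$dN == "induced" & d$TA == "repressed"))
}

#' Venn partition of two or three gene sets
#'
#' @param a,b,c character vectors of gene ids (\code{c} optional).
#' @return Named integer vector of region counts (\code{a_only},
#'   \code{ab}, ... ; seven regions with three sets).
#' @export
geneSetVenn <- function(a, b, c = NULL) {
  a <- unique(a); b <- unique(b)
  if (is.null(c)) {
    c(a_only = length(setdiff(a, b)),
      ab = length(intersect(a, b)),
      b_only = length(setdiff(b, a)))
  } else {
    c <- unique(c)
    inA <- unique(c(a, b, c)) %in% a
    u <- unique(c(a, b, c))
    inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
    c(a_only = sum(inA & !inB & !inC),
      b_only = sum(!inA & inB & !inC),
      c_only = sum(!inA & !inB & inC),
      ab = sum(inA & inB & !inC),
      ac = sum(inA & !inB & inC),
      bc = sum(!inA & inB & inC),
      abc = sum(inA & inB & inC))
  }
}

#' Map a gene set through an ortholog table and intersect
#'
#' Replaces coordinate lift-over by an explicit many-to-many ID mapping:
#' returns the external-species genes that both receive a mapping from the
#' query set and are regulated in the external dataset.
#'
#' @param genes character vector of source gene ids.
#' @param mapping data.frame with \code{source_id}, \code{target_id}.
#' @param externalRegulated character vector of external gene ids.
#' @return Sorted character vector of conserved regulated genes.
#' @export
mapConserved <- function(genes, mapping, externalRegulated) {
  genes <- unique(genes)
  unmapped <- setdiff(genes, mapping$source_id)
  if (length(unmapped))
    message(length(unmapped), " query ids had no mapping and were dropped")
  mapped <- unique(mapping$target_id[mapping$source_id %in% genes])
  sort(intersect(mapped, unique(externalRegulated)))
}
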