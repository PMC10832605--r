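#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

OWNER_LEVELS <- c("dN_specific", "common", "TA_specific")
GENOTYPE_LEVELS <- c("WT", "dNp63KO", "TAp63KO")
ANNOTATION_LEVELS <- c("UTR5", "Exon", "UTR3", "Intron",
                       "Upstream10kb", "Downstream10kb", "Intergenic")
TARGET_LEVELS <- c("dN_only", "common", "TA_only", "none")
DIRECTION_LEVELS <- c("induced", "repressed", "none")

#' Gene model container
#'
#' Holds gene bodies as a \linkS4class{GRanges} (metadata columns
#' \code{gene_id}, \code{cds_start}, \code{cds_end}; the CDS bounds are
#' 1-based inclusive genomic positions, \code{NA} for non-coding genes)
#' together with a parallel \linkS4class{GRangesList} of exons per gene.
#'
#' @slot genes \code{GRanges} of gene bodies, stranded (+/-).
#' @slot exons \code{GRangesList}, one element per gene, exons sorted and
#'   disjoint, contained in the gene body.
#' @export
setClass("GeneModel", slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModel", function(object) {
  g <- object@genes
  e <- object@exons
  msg <- character()
  if (length(g) != length(e))
    msg <- c(msg, "genes and exons must be parallel")
  if (is.null(mcols(g)$gene_id) || anyDuplicated(mcols(g)$gene_id))
    msg <- c(msg, "gene_id must be present and unique")
  if (!all(as.character(strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be + or -")
  for (i in seq_along(g)) {
    ex <- e[[i]]
    if (length(ex) == 0) { msg <- c(msg, "every gene needs >= 1 exon"); break }
    if (any(start(ex) < start(g)[i]) || any(end(ex) > end(g)[i])) {
      msg <- c(msg, sprintf("exons of gene %s outside gene span",
                            mcols(g)$gene_id[i])); break
    }
    if (is.unsorted(start(ex)) ||
        (length(ex) > 1 && any(start(ex)[-1] <= end(ex)[-length(ex)]))) {
      msg <- c(msg, sprintf("exons of gene %s not sorted/disjoint",
                            mcols(g)$gene_id[i])); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Peak ownership table
#'
#' The three-genotype partition of a merged peak universe: each region is
#' labeled with the isoform responsible for the binding (\code{dN_specific},
#' \code{common}, \code{TA_specific}) plus the genotype peak files supporting
#' it.
#'
#' @slot regions \code{GRanges} with metadata columns \code{name},
#'   \code{owner} (factor over the three ownership labels) and
#'   \code{support} (comma-joined genotype tags).
#' @export
setClass("OwnershipTable", slots = c(regions = "GRanges"))

setValidity("OwnershipTable", function(object) {
  m <- mcols(object@regions)
  msg <- character()
  if (!all(c("name", "owner", "support") %in% colnames(m)))
    msg <- c(msg, "regions need name/owner/support metadata")
  else {
    if (!all(as.character(m$owner) %in% OWNER_LEVELS))
      msg <- c(msg, "unknown owner label")
    if (any(!nzchar(as.character(m$support))))
      msg <- c(msg, "every region needs >= 1 supporting genotype")
    if (anyDuplicated(m$name))
      msg <- c(msg, "region names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Position weight matrix motif model
#'
#' Per-position base probabilities of a transcription factor motif, scored
#' against sequence by log-odds to a background model.
#'
#' @slot motifId single motif identifier.
#' @slot probs numeric width x 4 matrix, columns A, C, G, T; rows sum to 1.
#' @slot nsites integer source site count (\code{NA} if unknown).
#' @export
setClass("PWMotif",
         slots = c(motifId = "character", probs = "matrix",
                   nsites = "integer"))

setValidity("PWMotif", function(object) {
  p <- object@probs
  msg <- character()
  if (length(object@motifId) != 1L || !nzchar(object@motifId))
    msg <- c(msg, "motifId must be a single non-empty string")
  if (!is.numeric(p) || nrow(p) < 1L || ncol(p) != 4L)
    msg <- c(msg, "probs must be a width x 4 numeric matrix")
  else {
    if (!identical(colnames(p), c("A", "C", "G", "T")))
      msg <- c(msg, "probs columns must be A, C, G, T")
    if (any(p < 0))
      msg <- c(msg, "probabilities must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      msg <- c(msg, "each probs row must sum to 1 (tol 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param motifId motif identifier.
#' @param probs width x 4 probability matrix (columns A, C, G, T; any
#'   matching column names are accepted and reordered).
#' @param nsites optional number of source sites.
#' @return A \linkS4class{PWMotif}.
#' @export
PWMotif <- function(motifId, probs, nsites = NA_integer_) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- c("A", "C", "G", "T")
  probs <- probs[, c("A", "C", "G", "T"), drop = FALSE]
  rownames(probs) <- NULL
  new("PWMotif", motifId = as.character(motifId), probs = probs,
      nsites = as.integer(nsites))
}

#' @describeIn PWMotif-class motif identifier
#' @param x a \code{PWMotif}.
#' @export
motifId <- function(x) x@motifId

#' @describeIn PWMotif-class probability matrix
#' @export
motifProbs <- function(x) x@probs

#' @describeIn PWMotif-class motif width in bp
#' @export
motifWidth <- function(x) nrow(x@probs)

#' @describeIn OwnershipTable-class the labeled merged regions
#' @param x an \code{OwnershipTable}.
#' @export
ownerRegions <- function(x) x@regions

#' @describeIn OwnershipTable-class owner label per region
#' @export
peakOwners <- function(x) {
  factor(as.character(mcols(x@regions)$owner), levels = OWNER_LEVELS)
}

#' @describeIn GeneModel-class gene bodies
#' @param x a \code{GeneModel}.
#' @export
geneBodies <- function(x) x@genes

#' @describeIn GeneModel-class exons per gene
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneModel-class gene identifiers
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel with", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "sequences\n")
})

setMethod("show", "OwnershipTable", function(object) {
  tab <- table(peakOwners(object))
  cat("OwnershipTable with", length(object@regions), "regions:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@motifId, "width", nrow(object@probs), "\n")
})

setMethod("length", "OwnershipTable", function(x) length(x@regions))
setMethod("length", "GeneModel", function(x) length(x@genes))
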