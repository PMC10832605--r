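#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom utils read.delim write.table
NULL

stop_line <- function(path, i, what) {
  stop(sprintf("%s: line %d: %s", path, i, what), call. = FALSE)
}

split_tab <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read peak calls from BED6 or narrowPeak
#'
#' Coordinates on file are 0-based half-open (BED convention) and are
#' converted to the in-memory 1-based closed representation of
#' \code{GRanges}. The narrowPeak summit offset (column 10) is converted to
#' an absolute genomic \code{summit} position; \code{-1} means no summit.
#'
#' @param path peak file.
#' @param dialect \code{"bed6"} (>= 3 tab-separated columns) or
#'   \code{"narrowPeak"} (exactly 10 columns).
#' @return \code{GRanges} with metadata columns \code{name}, \code{score}
#'   and \code{summit} (integer genomic position or \code{NA}); input order
#'   preserved.
#' @export
readPeaks <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(path, ": empty peak file", call. = FALSE)
  fields <- split_tab(lines)
  need <- if (dialect == "bed6") 3L else 10L
  chrom <- character(length(fields)); s0 <- integer(length(fields))
  e0 <- integer(length(fields)); nm <- character(length(fields))
  sc <- numeric(length(fields)); su <- rep(NA_integer_, length(fields))
  st <- rep(".", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (dialect == "narrowPeak" && length(f) != 10L)
      stop_line(path, i, "narrowPeak requires exactly 10 columns")
    if (length(f) < need)
      stop_line(path, i, sprintf("expected >= %d columns, got %d",
                                 need, length(f)))
    if (!nzchar(f[1])) stop_line(path, i, "empty chrom")
    a <- suppressWarnings(as.integer(f[2])); b <- suppressWarnings(as.integer(f[3]))
    if (is.na(a) || is.na(b)) stop_line(path, i, "non-integer coordinates")
    if (a < 0) stop_line(path, i, "start < 0")
    if (a >= b) stop_line(path, i, "start >= end")
    chrom[i] <- f[1]; s0[i] <- a; e0[i] <- b
    nm[i] <- if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") f[4]
             else sprintf("peak_%d", i)
    if (length(f) >= 5 && f[5] != ".") {
      v <- suppressWarnings(as.numeric(f[5]))
      if (is.na(v) || v < 0) stop_line(path, i, "score must be a number >= 0")
      sc[i] <- v
    }
    if (length(f) >= 6 && f[6] %in% c("+", "-", ".")) st[i] <- f[6]
    if (dialect == "narrowPeak") {
      off <- suppressWarnings(as.integer(f[10]))
      if (is.na(off)) stop_line(path, i, "non-integer summit offset")
      if (off != -1L) {
        if (off < 0L || off >= b - a)
          stop_line(path, i, "summit offset outside peak")
        su[i] <- a + off + 1L
      }
    }
  }
  if (anyDuplicated(nm))
    stop(path, ": duplicate peak names", call. = FALSE)
  st[st == "."] <- "*"
  GRanges(chrom, IRanges(s0 + 1L, e0), strand = st,
          name = nm, score = sc, summit = su)
}

#' Write peak calls to BED6 or narrowPeak
#'
#' Inverse of \code{\link{readPeaks}} (modulo default-filled columns).
#'
#' @param peaks \code{GRanges}; metadata columns \code{name}, \code{score},
#'   \code{summit} used when present.
#' @param path output file.
#' @param dialect output dialect.
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(peaks, path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  m <- mcols(peaks)
  nm <- if (!is.null(m$name)) as.character(m$name)
        else sprintf("peak_%d", seq_along(peaks))
  sc <- if (!is.null(m$score)) as.numeric(m$score) else rep(0, length(peaks))
  st <- as.character(strand(peaks)); st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = nm, score = sc, strand = st,
                   stringsAsFactors = FALSE)
  if (dialect == "narrowPeak") {
    off <- rep(-1L, length(peaks))
    if (!is.null(m$summit)) {
      has <- !is.na(m$summit)
      off[has] <- as.integer(m$summit[has]) - start(peaks)[has]
    }
    df$signalValue <- 0; df$pValue <- -1; df$qValue <- -1; df$peak <- off
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_bed12_gene <- function(f, path, i) {
  a <- as.integer(f[2]); b <- as.integer(f[3])
  if (is.na(a) || is.na(b) || a >= b) stop_line(path, i, "bad gene span")
  nblocks <- as.integer(f[10])
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  starts <- as.integer(strsplit(f[12], ",")[[1]])
  if (length(sizes) != nblocks || length(starts) != nblocks)
    stop_line(path, i, "blockCount does not match block lists")
  es <- a + starts; ee <- es + sizes
  if (any(es < a) || any(ee > b))
    stop_line(path, i, "blocks outside gene span")
  if (is.unsorted(es, strictly = TRUE) ||
      (nblocks > 1 && any(es[-1] < ee[-nblocks])))
    stop_line(path, i, "blocks not sorted/disjoint")
  thickS <- as.integer(f[7]); thickE <- as.integer(f[8])
  coding <- !is.na(thickS) && !is.na(thickE) && thickS < thickE
  list(chrom = f[1], start = a, end = b, gene_id = f[4], strand = f[6],
       exon_start = es, exon_end = ee,
       cds_start = if (coding) thickS else NA_integer_,
       cds_end = if (coding) thickE else NA_integer_)
}

#' Read a gene model from BED12 or minimal GTF
#'
#' BED12 blocks become exons and the thick span the CDS. Minimal GTF uses
#' \code{gene}, \code{exon} and \code{CDS} features carrying a
#' \code{gene_id "X";} attribute; 1-based inclusive GTF coordinates are
#' converted at this boundary.
#'
#' @param path gene model file.
#' @param dialect \code{"bed12"} or \code{"gtf_min"}.
#' @return A \linkS4class{GeneModel}.
#' @export
readGeneModel <- function(path, dialect = c("bed12", "gtf_min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(path, ": empty gene model", call. = FALSE)
  recs <- list()
  if (dialect == "bed12") {
    fields <- split_tab(lines)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 12L) stop_line(path, i, "BED12 requires 12 columns")
      if (!f[6] %in% c("+", "-")) stop_line(path, i, "gene strand must be +/-")
      r <- parse_bed12_gene(f, path, i)
      if (!is.null(recs[[r$gene_id]]))
        stop_line(path, i, sprintf("duplicate gene_id %s", r$gene_id))
      recs[[r$gene_id]] <- r
    }
  } else {
    fields <- split_tab(lines)
    gid_of <- function(attr, i) {
      m <- regmatches(attr, regexec('gene_id "([^"]+)"', attr))[[1]]
      if (length(m) < 2) stop_line(path, i, "missing gene_id attribute")
      m[2]
    }
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 9L) stop_line(path, i, "GTF requires 9 columns")
      feat <- f[3]
      if (!feat %in% c("gene", "exon", "CDS")) next
      gid <- gid_of(f[9], i)
      s1 <- as.integer(f[4]); e1 <- as.integer(f[5])
      if (is.na(s1) || is.na(e1) || s1 > e1)
        stop_line(path, i, "bad coordinates")
      if (feat == "gene") {
        if (!is.null(recs[[gid]]) && !is.null(recs[[gid]]$start))
          stop_line(path, i, sprintf("duplicate gene_id %s", gid))
        r <- recs[[gid]]
        if (is.null(r)) r <- list(exon_start = integer(), exon_end = integer(),
                                  cds_start = NA_integer_, cds_end = NA_integer_)
        r$chrom <- f[1]; r$start <- s1 - 1L; r$end <- e1
        r$gene_id <- gid; r$strand <- f[7]
        recs[[gid]] <- r
      } else if (feat == "exon") {
        r <- recs[[gid]]
        if (is.null(r)) r <- list(cds_start = NA_integer_, cds_end = NA_integer_,
                                  exon_start = integer(), exon_end = integer())
        r$exon_start <- c(r$exon_start, s1 - 1L)
        r$exon_end <- c(r$exon_end, e1)
        recs[[gid]] <- r
      } else {
        r <- recs[[gid]]
        if (is.null(r)) r <- list(exon_start = integer(), exon_end = integer())
        r$cds_start <- min(r$cds_start, s1 - 1L, na.rm = TRUE)
        r$cds_end <- max(r$cds_end, e1, na.rm = TRUE)
        recs[[gid]] <- r
      }
    }
    for (gid in names(recs)) {
      r <- recs[[gid]]
      if (is.null(r$start))
        stop(path, ": gene_id ", gid, " has exons but no gene line",
             call. = FALSE)
      o <- order(r$exon_start)
      r$exon_start <- r$exon_start[o]; r$exon_end <- r$exon_end[o]
      if (!length(r$exon_start)) {
        r$exon_start <- r$start; r$exon_end <- r$end
      }
      if (any(r$exon_start < r$start) || any(r$exon_end > r$end))
        stop(path, ": exons of ", gid, " outside gene span", call. = FALSE)
      if (is.null(r$cds_start)) r$cds_start <- NA_integer_
      if (is.null(r$cds_end)) r$cds_end <- NA_integer_
      recs[[gid]] <- r
    }
  }
  gids <- names(recs)
  g <- GRanges(unname(vapply(recs, `[[`, "", "chrom")),
               IRanges(unname(vapply(recs, function(r) r$start + 1L, 0L)),
                       unname(vapply(recs, `[[`, 0L, "end"))),
               strand = unname(vapply(recs, `[[`, "", "strand")),
               gene_id = gids,
               cds_start = unname(vapply(recs, function(r) {
                 cs <- as.integer(r$cds_start)
                 if (is.na(cs)) NA_integer_ else cs + 1L
               }, 0L)),
               cds_end = unname(vapply(recs, function(r)
                 as.integer(r$cds_end), 0L)))
  ex <- GenomicRanges::GRangesList(lapply(recs, function(r)
    GRanges(r$chrom, IRanges(r$exon_start + 1L, r$exon_end),
            strand = r$strand)))
  names(ex) <- gids
  new("GeneModel", genes = g, exons = ex)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased; any character outside A/C/G/T/N is replaced by
#' N with a warning reporting the replacement count.
#'
#' @param path FASTA file.
#' @return Named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop(path, ": empty FASTA", call. = FALSE)
  x <- readBStringSet(path)
  if (!length(x)) stop(path, ": empty FASTA", call. = FALSE)
  ch <- toupper(as.character(x))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", ch), function(m)
    if (m[1] == -1L) 0L else length(m), 0L))
  if (n_bad > 0) {
    warning(sprintf("%s: %d non-ACGTN characters replaced by N", path, n_bad),
            call. = FALSE)
    ch <- gsub("[^ACGTN]", "N", ch)
  }
  out <- DNAStringSet(ch)
  names(out) <- names(x)
  out
}

#' Write a genome FASTA
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(genome, path) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read a count matrix with sample genotypes
#'
#' The counts file is a TSV with a header of sample ids and gene ids in the
#' first column; the metadata sidecar maps \code{sample_id} to
#' \code{genotype}. Counts must be non-negative integers.
#'
#' @param path counts TSV.
#' @param metaPath metadata TSV with columns \code{sample_id},
#'   \code{genotype}.
#' @return A \code{SummarizedExperiment} with assay \code{counts} and
#'   \code{colData} column \code{genotype}.
#' @export
readCounts <- function(path, metaPath) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) stop(path, ": duplicate gene ids", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop(path, ": duplicate sample ids", call. = FALSE)
  if (!is.numeric(m) || any(is.na(m)))
    stop(path, ": counts must be numeric", call. = FALSE)
  if (any(m < 0)) stop(path, ": negative counts", call. = FALSE)
  if (any(m != round(m))) stop(path, ": non-integer counts", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "genotype") %in% colnames(meta)))
    stop(metaPath, ": needs sample_id and genotype columns", call. = FALSE)
  if (!all(colnames(m) %in% meta$sample_id))
    stop("samples missing from metadata: ",
         paste(setdiff(colnames(m), meta$sample_id), collapse = ", "),
         call. = FALSE)
  geno <- meta$genotype[match(colnames(m), meta$sample_id)]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = DataFrame(genotype = geno, row.names = colnames(m)))
}

#' Write a count matrix and its metadata sidecar
#'
#' @param se \code{SummarizedExperiment} from \code{\link{readCounts}} or
#'   the synthetic generator.
#' @param path counts TSV path.
#' @param metaPath metadata TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(se, path, metaPath) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(m),
                     genotype = as.character(se$genotype))
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member gene ids).
#' @return Named list of character vectors; per-set descriptions in
#'   \code{attr(,"description")}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(path, ": empty GMT", call. = FALSE)
  fields <- split_tab(lines)
  sets <- list(); desc <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stop_line(path, i, "GMT line needs >= 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_line(path, i, "empty gene set")
    if (!is.null(sets[[f[1]]])) stop_line(path, i, "duplicate set name")
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; optional
#'   \code{attr(,"description")}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses \code{MEME version}, \code{ALPHABET= ACGT}, optional background
#' lines, and \code{MOTIF} blocks with a letter-probability matrix. Rows
#' whose sum is within 1e-3 of 1 are renormalized; larger deviations are an
#' error.
#'
#' @param path MEME minimal motif file.
#' @return List of \linkS4class{PWMotif}.
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    stop(path, ": missing 'MEME version' header", call. = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) < 2) stop(path, ": MOTIF line without id", call. = FALSE)
      id <- toks[2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines))
        stop(path, ": motif ", id, " has no letter-probability matrix",
             call. = FALSE)
      hdr <- lines[j]
      w <- suppressWarnings(as.integer(
        sub(".*w=\\s*(\\d+).*", "\\1", hdr)))
      ns <- suppressWarnings(as.integer(
        if (grepl("nsites=", hdr)) sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)
        else NA))
      rows <- list(); k <- j + 1L
      while (k <= length(lines) && length(rows) < ifelse(is.na(w), 1e9, w)) {
        ln <- trimws(lines[k])
        if (!nzchar(ln)) { if (is.na(w)) break else { k <- k + 1L; next } }
        if (startsWith(ln, "MOTIF")) break
        vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(vals) != 4 || any(is.na(vals))) {
          if (is.na(w)) break
          stop(path, ": motif ", id, ": bad matrix row", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- vals
        k <- k + 1L
      }
      if (!is.na(w) && length(rows) != w)
        stop(path, ": motif ", id, ": expected ", w, " rows", call. = FALSE)
      p <- do.call(rbind, rows)
      rs <- rowSums(p)
      if (any(abs(rs - 1) > 1e-3))
        stop(path, ": motif ", id, ": probability row sum off by > 1e-3",
             call. = FALSE)
      if (any(p < 0))
        stop(path, ": motif ", id, ": negative probability", call. = FALSE)
      p <- p / rs
      colnames(p) <- c("A", "C", "G", "T")
      out[[length(out) + 1L]] <- PWMotif(id, p, ns)
      i <- k
    } else i <- i + 1L
  }
  if (!length(out)) stop(path, ": no motifs found", call. = FALSE)
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms list of \linkS4class{PWMotif}.
#' @param path output file.
#' @param bg background probabilities written to the header.
#' @return \code{path}, invisibly.
#' @export
writeMemeMotifs <- function(pwms, path, bg = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (m in pwms) {
    writeLines(sprintf("MOTIF %s", motifId(m)), con)
    ns <- if (is.na(m@nsites)) 20L else m@nsites
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      motifWidth(m), ns), con)
    apply(motifProbs(m), 1, function(r)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4]), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read a two-column ID mapping table
#'
#' @param path TSV with columns \code{source_id}, \code{target_id}
#'   (many-to-many).
#' @return data.frame with those two character columns.
#' @export
readIdMapping <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% colnames(tab)))
    stop(path, ": needs source_id and target_id columns", call. = FALSE)
  tab[, c("source_id", "target_id")]
}
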