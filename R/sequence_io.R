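# FASTA / BED / minimal GFF I/O, promoter extraction and non-coding
# region sets.  All internal coordinates are 0-based half-open; BED is
# native, GFF (1-based closed) is converted on read.  Case is preserved
# throughout: lowercase and N encode repeat masking.

#' Read a FASTA file, preserving case
#'
#' @param path FASTA file.
#' @return named character vector of sequences (one per record, case
#'   preserved; masked positions recoverable via [mask_positions()]).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- as.character(set)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) stop("zero-length record in ", path)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED file of gene records
#'
#' BED6; the transcription start site is taken to be `chromStart` for
#' `+` genes and `chromEnd - 1` is not used -- for `-` genes the TSS is
#' `chromEnd` in 0-based terms, i.e. the first transcribed base is
#' `chromEnd - 1` and the upstream region starts at `chromEnd`.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param tissue_label optional label attached to every record.
#' @return data.frame with gene_id, chrom, strand, tss (0-based),
#'   tissue_label.
#' @export
read_genes_bed <- function(path, tissue_label = "none") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("gene BED must have 6 columns")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  data.frame(gene_id = bed$name,
             chrom = bed$chrom,
             strand = bed$strand,
             tss = ifelse(bed$strand == "+", bed$start, bed$end),
             tissue_label = tissue_label,
             stringsAsFactors = FALSE)
}

#' Extract promoter sequences upstream of TSSs
#'
#' For a `+` gene the promoter is `[tss - L, tss)` on the forward strand;
#' for a `-` gene it is `[tss, tss + L)` reverse-complemented, so the
#' returned sequence always reads 5' to 3' towards the gene.  Promoters
#' running off a contig edge are truncated with a warning; genes on
#' missing contigs are skipped with a warning.
#'
#' @param genes data.frame as returned by [read_genes_bed()] (columns
#'   gene_id, chrom, strand, tss; optional tissue_label).
#' @param genome named character vector of contig sequences.
#' @param upstream_len promoter length in nt (1000 and 2000 are the
#'   conventional choices).
#' @return list with `seqs` (named character vector, one per gene kept)
#'   and `info` (data.frame: gene_id, chrom, start, end, strand,
#'   truncated).
#' @export
extract_promoters <- function(genes, genome, upstream_len = 1000) {
  stopifnot(upstream_len >= 1)
  seqs <- character(0)
  info <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(genome)) {
      warning("gene ", g$gene_id, " on missing contig ", g$chrom, "; skipped")
      next
    }
    clen <- nchar(genome[[g$chrom]])
    if (g$strand == "+") {
      start <- g$tss - upstream_len; end <- g$tss
    } else {
      start <- g$tss; end <- g$tss + upstream_len
    }
    trunc <- FALSE
    if (start < 0) { start <- 0; trunc <- TRUE }
    if (end > clen) { end <- clen; trunc <- TRUE }
    if (trunc) warning("promoter of ", g$gene_id, " truncated at contig edge")
    if (end <= start) next
    s <- substr(genome[[g$chrom]], start + 1, end)
    if (g$strand == "-") s <- revcomp(s)
    seqs[[as.character(g$gene_id)]] <- s
    info[[length(info) + 1]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = start, end = end,
      strand = g$strand, truncated = trunc, stringsAsFactors = FALSE)
  }
  list(seqs = seqs, info = do.call(rbind, info))
}

#' Non-coding regions of a genome from a minimal GFF annotation
#'
#' Takes the complement of the annotated exonic/coding intervals on each
#' contig and keeps pieces of at least `min_len` nt (default 60, the
#' conventional floor for conserved non-coding elements).
#'
#' @param annotation path to a GFF3 file, or a `GRanges`.  Features of
#'   type in `coding_types` define the coding space.
#' @param genome named character vector of contig sequences.
#' @param min_len minimum region length kept.
#' @param coding_types feature types treated as coding.
#' @return data.frame (chrom, start, end) 0-based half-open, sorted and
#'   non-overlapping, with attribute `set_id = "noncoding_all"`.
#' @export
noncoding_regions <- function(annotation, genome, min_len = 60,
                              coding_types = c("exon", "CDS")) {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else annotation
  gr <- gr[as.character(gr$type) %in% coding_types]
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 names(genome))
  if (length(bad)) stop("annotation contig absent from genome: ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (chrom in names(genome)) {
    clen <- nchar(genome[[chrom]])
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (length(sub)) {
      # GFF is 1-based closed; move to 0-based half-open
      ex <- IRanges::reduce(IRanges::IRanges(
        start = GenomicRanges::start(sub), end = GenomicRanges::end(sub)))
      starts0 <- GenomicRanges::start(ex) - 1L
      ends0 <- GenomicRanges::end(ex)
      starts0 <- pmax(starts0, 0L); ends0 <- pmin(ends0, clen)
      gaps_start <- c(0L, ends0)
      gaps_end <- c(starts0, clen)
    } else {
      gaps_start <- 0L; gaps_end <- clen
    }
    keep <- (gaps_end - gaps_start) >= min_len
    if (any(keep)) {
      out[[chrom]] <- data.frame(chrom = chrom,
                                 start = gaps_start[keep],
                                 end = gaps_end[keep],
                                 stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  rownames(res) <- NULL
  attr(res, "set_id") <- "noncoding_all"
  res
}

#' Extract the sequences of a region set
#'
#' @param regions data.frame (chrom, start, end), 0-based half-open.
#' @param genome named character vector.
#' @return named character vector, names `chrom:start-end`.
#' @export
region_sequences <- function(regions, genome) {
  if (nrow(regions) == 0) return(character(0))
  stats::setNames(
    vapply(seq_len(nrow(regions)), function(i) {
      substr(genome[[regions$chrom[i]]], regions$start[i] + 1, regions$end[i])
    }, character(1)),
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end))
}

#' Read a BED file as a region set
#' @param path BED file (>= 3 columns).
#' @param set_id label for the set.
#' @return data.frame (chrom, start, end) with `set_id` attribute.
#' @export
read_regions_bed <- function(path, set_id = basename(path)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  res <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                    stringsAsFactors = FALSE)
  if (any(res$start >= res$end)) stop("BED interval with start >= end")
  attr(res, "set_id") <- set_id
  res
}

#' Write intervals as BED
#' @param df data.frame with chrom, start, end and optionally name,
#'   score, strand columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
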