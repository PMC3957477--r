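# Both-strand PSSM scanning of masked sequences, composite-cluster
# detection (anchor + partner within a spacing window) and cluster
# densities per kilobase of unmasked sequence.

# Window scores for one encoded sequence: numeric vector of length
# L - w + 1, NA where the window touches a masked position.
window_scores <- function(code, scores) {
  w <- ncol(scores)
  L <- length(code)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (i in seq_len(w)) {
    acc <- acc + scores[, i][code[seq.int(i, i + n - 1L)]]
  }
  acc
}

scan_encoded <- function(codes, sm, dist, alpha, both_strands = TRUE,
                         dist_rev = NULL) {
  w <- ncol(sm$scores)
  sm_rc <- if (both_strands) revcomp_matrix(sm) else NULL
  hits <- vector("list", 2 * length(codes))
  k <- 0L
  for (sid in names(codes)) {
    code <- codes[[sid]]
    for (strand in if (both_strands) c("+", "-") else "+") {
      sc <- window_scores(code, if (strand == "+") sm$scores else sm_rc$scores)
      if (!length(sc)) next
      pv <- pvalue(if (strand == "+") dist else (dist_rev %||% dist), sc)
      sel <- which(!is.na(pv) & pv <= alpha)
      if (!length(sel)) next
      k <- k + 1L
      hits[[k]] <- data.frame(
        seq_id = sid, motif_id = sm$motif_id,
        start = sel - 1L, end = sel - 1L + w, strand = strand,
        score = sc[sel], pvalue = pv[sel], stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, hits[seq_len(k)]) else empty_hits()
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(seq_id = character(0), motif_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             score = numeric(0), pvalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Scan sequences with a scoring matrix
#'
#' Every width-w window whose letters are all unmasked A/C/G/T is scored
#' on both strands; windows with p-value at most `alpha` are reported.
#' Reverse-strand hits are given in forward coordinates.  When the
#' distribution's background is not strand-symmetric a separate
#' distribution is used for the reverse strand.
#'
#' @param seqs named character vector of (masked) sequences.
#' @param sm a `scoring_matrix`.
#' @param dist the matrix's `score_distribution`; defaults to computing
#'   it from `sm`.
#' @param alpha p-value threshold in (0, 1].
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame of hits: seq_id, motif_id, start, end (0-based
#'   half-open, forward coordinates), strand, score, pvalue; sorted by
#'   (seq_id, start, strand).
#' @export
scan_sequences <- function(seqs, sm, dist = score_distribution(sm),
                           alpha = 1e-4, both_strands = TRUE) {
  stopifnot(alpha > 0, alpha <= 1)
  codes <- lapply(seqs, encode_sequence)
  dist_rev <- NULL
  bg <- as.numeric(dist$bg)
  if (both_strands && max(abs(bg - rev(bg))) > 1e-9) {
    dist_rev <- score_distribution(revcomp_matrix(sm), bg = dist$bg,
                                   bin_width = dist$bin_width)
  }
  scan_encoded(codes, sm, dist, alpha, both_strands, dist_rev)
}

#' Count scannable windows in a sequence set
#'
#' The denominator of per-window site rates: windows of width `w` whose
#' positions are all unmasked, times 2 when both strands are scanned.
#'
#' @param seqs named character vector.
#' @param w matrix width.
#' @param both_strands count each window twice (default TRUE).
#' @return integer count.
#' @export
scannable_windows <- function(seqs, w, both_strands = TRUE) {
  n <- sum(vapply(seqs, function(s) {
    code <- encode_sequence(s)
    L <- length(code)
    if (L < w) return(0L)
    ok <- !is.na(code)
    # window is scannable iff all w positions unmasked
    cs <- cumsum(ok)
    full <- cs[w:L] - c(0L, cs[seq_len(L - w)])
    sum(full == w)
  }, integer(1)))
  if (both_strands) 2L * n else n
}

#' Number of unmasked positions in a sequence set
#' @param seqs named character vector.
#' @return integer count of positions that are uppercase A/C/G/T.
#' @export
unmasked_length <- function(seqs) {
  sum(vapply(seqs, function(s) sum(!is.na(encode_sequence(s))), integer(1)))
}

#' Pair anchor hits with partner hits into composite clusters
#'
#' One cluster per anchor hit that has at least one partner hit on the
#' same sequence with edge-to-edge gap at most `window` nt on either
#' side (overlapping hits count as gap 0).  Anchors without a partner
#' yield no cluster; an anchor with several partners yields a single
#' cluster listing all of them.
#'
#' @param anchor_hits,partner_hits hit data.frames from
#'   [scan_sequences()] over the same sequence set.
#' @param window maximum edge-to-edge gap in nt (default 40).
#' @param metric `"edge"` (default) or `"center"` distance between
#'   anchor and partner.
#' @return data.frame of clusters: seq_id, anchor_motif, anchor_start,
#'   anchor_end, anchor_strand, n_partners, span_start, span_end, gap
#'   (distance to the closest partner); sorted by anchor position.
#' @export
detect_clusters <- function(anchor_hits, partner_hits, window = 40,
                            metric = c("edge", "center")) {
  metric <- match.arg(metric)
  stopifnot(window >= 0)
  if (nrow(anchor_hits) == 0 || nrow(partner_hits) == 0) {
    return(empty_clusters())
  }
  out <- list()
  for (sid in unique(anchor_hits$seq_id)) {
    a <- anchor_hits[anchor_hits$seq_id == sid, , drop = FALSE]
    p <- partner_hits[partner_hits$seq_id == sid, , drop = FALSE]
    if (nrow(p) == 0) next
    for (i in seq_len(nrow(a))) {
      gaps <- if (metric == "edge") {
        pmax(p$start - a$end[i], a$start[i] - p$end, 0)
      } else {
        abs((p$start + p$end) / 2 - (a$start[i] + a$end[i]) / 2)
      }
      near <- gaps <= window
      if (!any(near)) next
      out[[length(out) + 1]] <- data.frame(
        seq_id = sid,
        anchor_motif = a$motif_id[i],
        anchor_start = a$start[i], anchor_end = a$end[i],
        anchor_strand = a$strand[i],
        n_partners = sum(near),
        span_start = min(a$start[i], p$start[near]),
        span_end = max(a$end[i], p$end[near]),
        gap = min(gaps[near]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_clusters()
  res <- res[order(res$seq_id, res$anchor_start, res$anchor_strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_clusters <- function() {
  data.frame(seq_id = character(0), anchor_motif = character(0),
             anchor_start = integer(0), anchor_end = integer(0),
             anchor_strand = character(0), n_partners = integer(0),
             span_start = integer(0), span_end = integer(0),
             gap = numeric(0), stringsAsFactors = FALSE)
}

#' Cluster density over a region set
#'
#' Clusters per kilobase of unmasked sequence, the repeat-masked
#' normalization used when comparing region sets of different size.
#'
#' @param clusters cluster data.frame from [detect_clusters()].
#' @param seqs the (masked) sequences of the scanned region set.
#' @param set_id label for the result row.
#' @return data.frame with set_id, n_clusters, scanned_kb, density.
#' @export
cluster_density <- function(clusters, seqs, set_id = "regions") {
  kb <- unmasked_length(seqs) / 1000
  if (kb <= 0) stop("region set has no unmasked sequence")
  data.frame(set_id = set_id,
             n_clusters = nrow(clusters),
             scanned_kb = kb,
             density = nrow(clusters) / kb,
             stringsAsFactors = FALSE)
}

#' Export hits or clusters as a BED-like table
#'
#' BED6 plus extra columns (motif id, score, p-value or partner count).
#'
#' @param x a hits or clusters data.frame.
#' @param path output path.
#' @export
write_hits_bed <- function(x, path) {
  if ("pvalue" %in% names(x)) {
    df <- data.frame(chrom = x$seq_id, start = x$start, end = x$end,
                     name = x$motif_id, score = round(x$score, 4),
                     strand = x$strand, pvalue = signif(x$pvalue, 6))
  } else {
    df <- data.frame(chrom = x$seq_id, start = x$span_start,
                     end = x$span_end, name = x$anchor_motif,
                     score = x$n_partners, strand = x$anchor_strand,
                     gap = x$gap)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
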