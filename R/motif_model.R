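# Count matrices, log-odds scoring, exact score distributions and
# column-permutation nulls.
#
# The p-value machinery follows the classical exact-DP construction for
# PSSMs: per-column scores are discretized onto a fixed bin grid
# (floor rounding), the null distribution of the binned total score
# under an iid order-0 background is obtained by position-wise
# convolution, and look-ups are offset by one bin per column so that a
# reported p-value can never undershoot the exact enumeration value.

#' Construct a binding-site count matrix
#'
#' @param counts numeric 4 x w matrix of per-position nucleotide counts,
#'   rows in order A, C, G, T (row names optional; if present they are
#'   used to reorder).
#' @param motif_id identifier for the site model.
#' @param pseudocount non-negative number added to every cell before
#'   frequencies are formed. Default 0.25 (uniform-prior convention).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, motif_id = "motif", pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES)) {
      stop("count matrix rows must be named A, C, G, T")
    }
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- DNA_BASES
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(colSums(counts) + 4 * pseudocount <= 0)) {
    stop("degenerate column")
  }
  structure(list(motif_id = as.character(motif_id),
                 counts = counts,
                 pseudocount = pseudocount),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix", x$motif_id, " width", ncol(x$counts),
      " pseudocount", x$pseudocount, "\n")
  print(x$counts)
  invisible(x)
}

#' Matrix width
#' @param x a count or scoring matrix.
#' @return integer number of positions.
#' @export
motif_width <- function(x) {
  if (inherits(x, "count_matrix")) ncol(x$counts)
  else if (inherits(x, "scoring_matrix")) ncol(x$scores)
  else stop("not a matrix object")
}

#' Order-0 background nucleotide distribution
#'
#' @param probs named numeric vector of A, C, G, T probabilities; must be
#'   strictly positive and sum to 1.
#' @return an object of class `background0`.
#' @export
background0 <- function(probs) {
  if (!setequal(names(probs), DNA_BASES)) {
    stop("background must name probabilities for A, C, G, T")
  }
  probs <- probs[DNA_BASES]
  if (any(probs <= 0)) stop("background probabilities must be positive")
  if (abs(sum(probs) - 1) > 1e-12) stop("background probabilities must sum to 1")
  structure(probs, class = "background0")
}

#' @rdname background0
#' @export
uniform_background <- function() {
  background0(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

#' Estimate an order-0 background from a set of sequences
#'
#' Masked (lowercase/N) positions are excluded.  With `symmetrize = TRUE`
#' (the default) base and complement frequencies are averaged, so the
#' background is strand-symmetric and one theoretical score distribution
#' serves both scanned strands.
#'
#' @param seqs named character vector of sequences.
#' @param symmetrize average complementary base frequencies.
#' @return a `background0`.
#' @export
estimate_background <- function(seqs, symmetrize = TRUE) {
  codes <- unlist(lapply(seqs, encode_sequence), use.names = FALSE)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) stop("no unmasked positions to estimate background from")
  n <- tabulate(codes, nbins = 4) + 1  # +1 smoothing keeps all probs positive
  if (symmetrize) n <- (n + rev(n)) / 2
  background0(stats::setNames(n / sum(n), DNA_BASES))
}

#' Convert a count matrix into a log-odds scoring matrix
#'
#' `score[i, x] = log2( f_i(x) / bg(x) )` with
#' `f_i(x) = (counts[i, x] + pseudocount) / sum_y (counts[i, y] + pseudocount)`.
#'
#' @param cm a `count_matrix`.
#' @param bg a `background0`.
#' @return an object of class `scoring_matrix`; carries the background it
#'   was built against.
#' @export
build_scoring_matrix <- function(cm, bg = uniform_background()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(bg, "background0"))
  k <- cm$counts + cm$pseudocount
  tot <- colSums(k)
  if (any(tot <= 0)) stop("degenerate column")
  freq <- sweep(k, 2, tot, "/")
  if (any(freq == 0)) stop("degenerate column")   # log-odds undefined
  scores <- log2(freq / as.numeric(bg))
  structure(list(motif_id = cm$motif_id,
                 scores = scores,
                 bg = bg,
                 pseudocount = cm$pseudocount),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("scoring_matrix", x$motif_id, " width", ncol(x$scores), "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Reverse-complement a scoring matrix
#'
#' A hit of the reverse-complemented matrix on the forward strand is a
#' hit of the original matrix on the reverse strand at the same window.
#'
#' @param sm a `scoring_matrix`.
#' @return a `scoring_matrix` for the opposite strand.
#' @export
revcomp_matrix <- function(sm) {
  stopifnot(inherits(sm, "scoring_matrix"))
  sc <- sm$scores[4:1, rev(seq_len(ncol(sm$scores))), drop = FALSE]
  rownames(sc) <- DNA_BASES
  sm$scores <- sc
  sm
}

#' Score one word with a scoring matrix
#'
#' @param sm a `scoring_matrix`.
#' @param word DNA string of the matrix width, strictly over A/C/G/T.
#'   Windows containing masked (lowercase) or ambiguous letters are not
#'   scoreable and return `NA` with attribute `unscoreable`.
#' @return numeric score (sum over positions), or `NA`.
#' @export
score_word <- function(sm, word) {
  w <- ncol(sm$scores)
  code <- encode_sequence(word)
  if (length(code) != w) stop("word length must equal matrix width")
  if (anyNA(code)) {
    return(structure(NA_real_, unscoreable = TRUE))
  }
  sum(sm$scores[cbind(code, seq_len(w))])
}

#' Exact theoretical score distribution of a scoring matrix
#'
#' Per-column scores are floored onto a `bin_width` grid and the
#' distribution of the binned total score under iid draws from `bg` is
#' computed by position-wise convolution.  Flooring means every word's
#' binned score is at most its exact score; [pvalue()] compensates with a
#' one-bin-per-column offset so reported p-values are conservative
#' (never smaller than the exact enumeration p-value).
#'
#' @param sm a `scoring_matrix`.
#' @param bg background to convolve under; defaults to the background the
#'   matrix was built against.
#' @param bin_width score discretization step (log2 units), default 0.001.
#' @return an object of class `score_distribution` with elements
#'   `bins` (integer bin indices), `prob`, `cum_upper` (P(score >= bin)),
#'   `bin_width`, `width`.
#' @export
score_distribution <- function(sm, bg = sm$bg, bin_width = 0.001) {
  stopifnot(inherits(sm, "scoring_matrix"))
  if (bin_width <= 0) stop("bin_width must be positive")
  w <- ncol(sm$scores)
  B <- floor(sm$scores / bin_width)          # 4 x w integer bins
  if (any(apply(B, 2, function(b) length(unique(b))) == 1L) &&
      any(apply(sm$scores, 2, function(s) length(unique(s))) > 1L)) {
    warning("bin_width collapses distinct column scores")
  }
  p <- as.numeric(bg)
  lo <- 0; v <- 1                            # distribution over bins, offset lo
  for (i in seq_len(w)) {
    b <- B[, i]
    newlo <- lo + min(b)
    newlen <- length(v) + (max(b) - min(b))
    nv <- numeric(newlen)
    for (x in 1:4) {
      off <- b[x] - min(b)
      idx <- seq_along(v) + off
      nv[idx] <- nv[idx] + v * p[x]
    }
    v <- nv; lo <- newlo
  }
  keep <- v > 0 | seq_along(v) %in% c(1L, length(v))
  bins <- (lo + seq_along(v) - 1L)[keep]
  prob <- v[keep]
  cum <- rev(cumsum(rev(prob)))
  cum <- pmin(cum, 1)
  structure(list(bins = bins, prob = prob, cum_upper = cum,
                 bin_width = bin_width, width = w,
                 min_score = sum(apply(sm$scores, 2, min)),
                 max_score = sum(apply(sm$scores, 2, max)),
                 motif_id = sm$motif_id, bg = bg),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("score_distribution", x$motif_id %||% "", ": width", x$width,
      ", bin_width", x$bin_width, ",", length(x$bins), "support bins\n")
  cat("  score range [", min(x$bins) * x$bin_width, ",",
      max(x$bins) * x$bin_width, "], min p-value",
      signif(min_pvalue(x), 3), "\n")
  invisible(x)
}

#' Conservative p-value of a score
#'
#' Returns `P(binned score >= floor(s / bin_width) - (w - 1))`, which is
#' provably at least the exact `P(score >= s)` under the distribution's
#' background: flooring each of the `w` columns loses strictly less than
#' one bin per column, so any word whose exact score reaches `s` has a
#' binned score strictly above `s - w * bin_width`.
#'
#' @param dist a `score_distribution`.
#' @param s numeric vector of scores.
#' @return numeric vector of upper-tail probabilities, non-increasing in
#'   `s`; 1 at or below the minimum achievable score, 0 above the top bin.
#' @export
pvalue <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  k <- floor(s / dist$bin_width) - (dist$width - 1L)
  # first support bin >= k
  i <- findInterval(k - 0.5, dist$bins) + 1L
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s)
  inside <- ok & i <= length(dist$bins)
  out[inside] <- dist$cum_upper[i[inside]]
  out[ok & !inside] <- 0
  out
}

#' Smallest attainable p-value of a distribution
#'
#' The p-value [pvalue()] reports for the maximum achievable score; no
#' scanned window can be more significant.  Enrichment verdicts ignore
#' thresholds below this floor, where observed and null curves are both
#' identically zero.
#'
#' @param dist a `score_distribution`.
#' @return probability.
#' @export
min_pvalue <- function(dist) {
  pvalue(dist, dist$max_score)
}

#' Permute the columns of a count matrix
#'
#' The column-permutation null: shuffling matrix positions destroys the
#' biological word while leaving the per-column score multiset -- and
#' hence the theoretical score distribution under an order-0 background
#' -- unchanged.
#'
#' @param cm a `count_matrix`.
#' @param mode only `"columns"` is supported.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return a `count_matrix` with permuted columns.
#' @export
permute_matrix <- function(cm, mode = "columns", seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  mode <- match.arg(mode, "columns")
  w <- ncol(cm$counts)
  perm <- with_seed(seed, sample.int(w))
  cm$counts <- cm$counts[, perm, drop = FALSE]
  cm
}

#' Read a count matrix file
#'
#' Whitespace-delimited, JASPAR-like: an optional `>motif_id` header
#' followed by four rows labeled A, C, G, T.
#'
#' @param path file path.
#' @param pseudocount pseudocount to attach.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  motif_id <- tools::file_path_sans_ext(basename(path))
  if (startsWith(lines[1], ">")) {
    motif_id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) != 4) stop("expected 4 count rows (A, C, G, T)")
  rows <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- toupper(vapply(rows, `[`, character(1), 1))
  num <- lapply(rows, function(r) as.numeric(r[-1]))
  if (!setequal(lab, DNA_BASES)) stop("rows must be labeled A, C, G, T")
  if (length(unique(lengths(num))) != 1) stop("ragged count rows")
  m <- do.call(rbind, num)
  rownames(m) <- lab
  count_matrix(m, motif_id = motif_id, pseudocount = pseudocount)
}

#' Write a count matrix file
#' @param cm a `count_matrix`.
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", cm$motif_id), con)
  for (b in DNA_BASES) {
    writeLines(paste(b, paste(cm$counts[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Export a score distribution as TSV
#'
#' Two columns: the score at the lower edge of each support bin and
#' `P(score >= bin)`.
#'
#' @param dist a `score_distribution`.
#' @param path output path.
#' @export
write_score_distribution <- function(dist, path) {
  utils::write.table(
    data.frame(score_bin = dist$bins * dist$bin_width,
               p_ge = dist$cum_upper),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
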