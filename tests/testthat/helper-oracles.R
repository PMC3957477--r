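# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force: enumeration over all 4^w
# words, per-base membership checks, plain string search.  None of it
# reuses the package's DP/scanning code paths.

BASES <- c("A", "C", "G", "T")

# all 4^w words as a (4^w x w) matrix of codes 1..4
all_word_codes <- function(w) {
  as.matrix(rev(expand.grid(rev(rep(list(1:4), w)))))
}

# exact score of every word plus its background probability
enum_scores <- function(scores, bg) {
  w <- ncol(scores)
  words <- all_word_codes(w)
  s <- rowSums(matrix(scores[cbind(as.vector(words),
                                   rep(seq_len(w), each = nrow(words)))],
                      nrow = nrow(words)))
  p <- apply(words, 1, function(cd) prod(bg[cd]))
  list(score = s, prob = p, words = words)
}

# exact upper-tail p-value by enumeration
enum_pvalue <- function(enum, s, tol = 1e-9) {
  sum(enum$prob[enum$score >= s - tol])
}

# random count matrix with irregular counts (rich score support)
random_count_matrix <- function(w, seed, total = 50) {
  withr_seed(seed)
  m <- matrix(0, 4, w, dimnames = list(BASES, NULL))
  for (i in seq_len(w)) {
    m[, i] <- as.numeric(stats::rmultinom(1, total, prob = stats::runif(4, 0.05, 1)))
  }
  count_matrix(m, motif_id = sprintf("rand_w%d_s%d", w, seed),
               pseudocount = 0.25)
}

# local set.seed that does not leak into the test RNG state management
withr_seed <- function(seed) set.seed(seed)

# plain string search for a word and its reverse complement; returns
# 0-based starts on the forward strand
string_search <- function(seq, word) {
  starts <- function(pat) {
    out <- integer(0); from <- 1
    repeat {
      i <- regexpr(pat, substr(seq, from, nchar(seq)), fixed = TRUE)
      if (i < 0) break
      out <- c(out, from + i - 2L)   # 0-based
      from <- from + i
    }
    out
  }
  list(fwd = starts(word), rev = starts(revcomp(word)))
}

# random DNA string (uppercase)
random_dna <- function(n, seed) {
  withr_seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

MEIS2_PROBE <- "ATGACAGCTCGGAATGATTAATGGCCCAAATA"
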