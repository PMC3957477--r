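#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this helper so that no
# exported function silently consumes or perturbs the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic substream seeds: a named stage plus replicate index are
# folded into the root seed so that adding replicates to one stage never
# perturbs the draws of another.  Result stays within 32-bit range.
substream_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.double(seed) * 48271 + h * 1009 + index) %% 2147483629) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Byte lookup: A/C/G/T -> 1..4, everything else (lowercase = repeat
# masked, N, ...) -> NA.  Encoding once per sequence makes the scanner's
# inner loop pure integer indexing.
.code_table <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1] <- 1L
  tab[utf8ToInt("C") + 1] <- 2L
  tab[utf8ToInt("G") + 1] <- 3L
  tab[utf8ToInt("T") + 1] <- 4L
  tab
})

encode_sequence <- function(s) {
  .code_table[as.integer(charToRaw(s)) + 1]
}

#' Positions treated as repeat-masked in a sequence
#'
#' Masked positions are exactly the lowercase letters and any `N`/`n`;
#' this mirrors the convention of repeat-masked genome FASTA files.
#'
#' @param s a single DNA sequence (character scalar, case preserved).
#' @return integer vector of 0-based masked positions.
#' @export
mask_positions <- function(s) {
  which(is.na(encode_sequence(s))) - 1L
}

#' Reverse complement preserving case and masking characters
#'
#' @param s DNA sequence (character scalar); lowercase and `N` survive.
#' @return the reverse complement, same length.
#' @export
revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) {
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}
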