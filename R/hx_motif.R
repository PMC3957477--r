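# Hexapeptide (HX) scanning: the short Hox-family motif that mediates
# PBC binding -- an invariant tryptophan in a hydrophobic context with a
# lysine or arginine at offset +2 to +5 -- optionally reported relative
# to an annotated homeodomain start.

HYDROPHOBIC_DEFAULT <- c("A", "V", "L", "I", "M", "F", "Y", "P")

#' Scan a protein sequence for hexapeptide (HX) candidates
#'
#' Reports every tryptophan that has a K or R at offset +2..+5.  The
#' hydrophobic-context condition (at least one of the residues at -1/+1
#' in `hydrophobic`) is reported as a flag, not used as a filter, so
#' divergent single-tryptophan motifs are not silently discarded.  When
#' the homeodomain start is known, whether the W lies upstream of it and
#' at what distance is reported as well.
#'
#' @param residues protein sequence (single character string, uppercase
#'   one-letter amino-acid codes; `X` never matches anything).
#' @param prot_id identifier copied into the output.
#' @param hd_start optional 0-based position of the homeodomain's first
#'   residue.
#' @param hydrophobic residue set defining "hydrophobic context".
#' @return data.frame, one row per match, sorted by position:
#'   prot_id, position (0-based index of the W), basic_offset (smallest
#'   matching offset in 2..5), context_ok, upstream_of_hd,
#'   distance_to_hd (NA when `hd_start` is missing).
#' @export
hx_scan <- function(residues, prot_id = "protein", hd_start = NA,
                    hydrophobic = HYDROPHOBIC_DEFAULT) {
  if (!nzchar(residues)) stop("empty protein sequence")
  aa <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (!is.na(hd_start) && (hd_start < 0 || hd_start >= n)) {
    stop("hd_start outside sequence")
  }
  ws <- which(aa == "W")
  rows <- list()
  for (p in ws) {
    offs <- 2:5
    offs <- offs[p + offs <= n]
    basic <- offs[aa[p + offs] %in% c("K", "R")]
    if (!length(basic)) next
    neigh <- aa[intersect(c(p - 1, p + 1), seq_len(n))]
    rows[[length(rows) + 1]] <- data.frame(
      prot_id = prot_id,
      position = p - 1L,
      basic_offset = basic[1],
      context_ok = any(neigh %in% hydrophobic),
      upstream_of_hd = if (is.na(hd_start)) NA else (p - 1L) < hd_start,
      distance_to_hd = if (is.na(hd_start)) NA_integer_
                       else as.integer(hd_start - (p - 1L)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(prot_id = character(0), position = integer(0),
                      basic_offset = integer(0), context_ok = logical(0),
                      upstream_of_hd = logical(0),
                      distance_to_hd = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Scan a protein FASTA for HX candidates
#'
#' @param path protein FASTA.
#' @param hd_positions optional named integer vector (or two-column
#'   data.frame: prot_id, hd_start) of 0-based homeodomain starts.
#' @param ... passed to [hx_scan()].
#' @return combined data.frame over all records.
#' @export
hx_scan_fasta <- function(path, hd_positions = NULL, ...) {
  seqs <- read_fasta(path)
  if (is.data.frame(hd_positions)) {
    hd_positions <- stats::setNames(hd_positions[[2]], hd_positions[[1]])
  }
  out <- lapply(names(seqs), function(id) {
    hx_scan(seqs[[id]], prot_id = id,
            hd_start = if (!is.null(hd_positions) && id %in% names(hd_positions))
              hd_positions[[id]] else NA, ...)
  })
  do.call(rbind, out)
}
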