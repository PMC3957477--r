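# Both-strand scanning, composite-cluster detection and densities.

anchor_sm <- function(bg = uniform_background()) {
  build_scoring_matrix(consensus_pwm("TGATTAAT", 97, "hox_II"), bg)
}
meis_sm <- function(bg = uniform_background()) {
  build_scoring_matrix(consensus_pwm("TGACAG", 97, "meis"), bg)
}

test_that("scanning the printed central-class probe finds the two sites", {
  probe <- c(meis2 = MEIS2_PROBE)
  a <- scan_sequences(probe, anchor_sm(), alpha = 1e-3)
  m <- scan_sequences(probe, meis_sm(), alpha = 1e-3)
  expect_equal(nrow(a), 1)
  expect_equal(a$start, 14); expect_equal(a$end, 22)
  expect_equal(a$strand, "+")
  # the oracle: plain string search for the consensus words
  expect_equal(string_search(MEIS2_PROBE, "TGATTAAT")$fwd, 14)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1); expect_equal(m$end, 7)
  expect_equal(string_search(MEIS2_PROBE, "TGACAG")$fwd, 1)
})

test_that("masked and short sequences yield no hits", {
  expect_equal(nrow(scan_sequences(c(x = tolower(MEIS2_PROBE)), anchor_sm(),
                                   alpha = 1)), 0)
  expect_equal(nrow(scan_sequences(c(x = "TGATT"), anchor_sm(), alpha = 1)), 0)
  # masking one base of the site kills exactly that hit
  probe <- MEIS2_PROBE
  substr(probe, 16, 16) <- "n"
  expect_equal(nrow(scan_sequences(c(x = probe), anchor_sm(), alpha = 1e-3)),
               0)
})

test_that("scanning is strand-symmetric under coordinate reflection", {
  sm <- anchor_sm()
  for (seed in c(21, 22)) {
    L <- 500
    seqs <- c(s1 = random_dna(L, seed))
    fwd <- scan_sequences(seqs, sm, alpha = 0.01)
    rc <- c(s1 = revcomp(seqs[[1]]))
    bwd <- scan_sequences(rc, sm, alpha = 0.01)
    # reflect: a hit [s, e) strand z on the reverse complement maps to
    # [L - e, L - s) with flipped strand on the original
    reflected <- data.frame(start = L - bwd$end, end = L - bwd$start,
                            strand = ifelse(bwd$strand == "+", "-", "+"))
    o1 <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand")]
    o2 <- reflected[order(reflected$start, reflected$strand), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
    expect_equal(sort(fwd$score), sort(bwd$score))
  }
})

test_that("planted consensus sites are recovered at alpha = 1e-3", {
  withr_seed(33)
  seqs <- vapply(1:10, function(i) random_dna(800, 330 + i), character(1))
  names(seqs) <- paste0("s", 1:10)
  planted <- data.frame(seq = names(seqs),
                        pos = sample(0:(800 - 8), 10))
  for (i in 1:10) {
    s <- seqs[[planted$seq[i]]]
    substr(s, planted$pos[i] + 1, planted$pos[i] + 8) <- "TGATTAAT"
    seqs[[planted$seq[i]]] <- s
  }
  hits <- scan_sequences(seqs, anchor_sm(), alpha = 1e-3)
  for (i in 1:10) {
    expect_true(any(hits$seq_id == planted$seq[i] &
                      hits$start == planted$pos[i] & hits$strand == "+"))
  }
})

test_that("cluster pairing follows the spacing window rule", {
  probe <- c(meis2 = MEIS2_PROBE)
  a <- scan_sequences(probe, anchor_sm(), alpha = 1e-3)
  m <- scan_sequences(probe, meis_sm(), alpha = 1e-3)
  cl <- detect_clusters(a, m, window = 40)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$gap, 7)   # edges [1,7) and [14,22): 14 - 7 = 7
  expect_equal(cl$span_start, 1); expect_equal(cl$span_end, 22)
  expect_equal(nrow(detect_clusters(a, m, window = 5)), 0)
  expect_equal(nrow(detect_clusters(a, m, window = 7)), 1)

  # one anchor with two partners inside the window -> one cluster
  a1 <- data.frame(seq_id = "x", motif_id = "A", start = 50L, end = 58L,
                   strand = "+", score = 1, pvalue = 1e-5)
  p2 <- data.frame(seq_id = "x", motif_id = "M", start = c(30L, 70L),
                   end = c(36L, 76L), strand = c("+", "-"),
                   score = 1, pvalue = 1e-4)
  cl2 <- detect_clusters(a1, p2, window = 40)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$n_partners, 2)
  expect_equal(cl2$gap, 12)  # closest partner: 70 - 58
  expect_equal(cl2$span_start, 30); expect_equal(cl2$span_end, 76)

  # overlap counts as gap 0
  p0 <- data.frame(seq_id = "x", motif_id = "M", start = 55L, end = 61L,
                   strand = "+", score = 1, pvalue = 1e-4)
  expect_equal(detect_clusters(a1, p0, window = 0)$gap, 0)

  # partners on another sequence never pair
  p3 <- p2; p3$seq_id <- "y"
  expect_equal(nrow(detect_clusters(a1, p3, window = 1000)), 0)
})

test_that("cluster count is monotone non-decreasing in the window", {
  withr_seed(44)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    a <- data.frame(seq_id = "x", motif_id = "A",
                    start = sample(0:500, n), strand = "+",
                    score = 1, pvalue = 1e-5)
    a$end <- a$start + 8L
    m <- data.frame(seq_id = "x", motif_id = "M",
                    start = sample(0:500, n), strand = "+",
                    score = 1, pvalue = 1e-4)
    m$end <- m$start + 6L
    counts <- vapply(c(0, 5, 10, 20, 40, 80, 1000),
                     function(W) nrow(detect_clusters(a, m, W)), numeric(1))
    expect_true(all(diff(counts) >= 0))
    expect_lte(max(counts), n)  # one cluster per anchor at most
  }
})

test_that("density normalizes by unmasked kilobases and partitions consistently", {
  seqs <- c(r1 = random_dna(600, 51), r2 = random_dna(400, 52))
  cl <- data.frame(seq_id = c("r1", "r2"), anchor_motif = "A",
                   anchor_start = c(10L, 20L), anchor_end = c(18L, 28L),
                   anchor_strand = "+", n_partners = 1L,
                   span_start = c(5L, 15L), span_end = c(18L, 28L), gap = 2)
  d <- cluster_density(cl, seqs)
  expect_equal(d$density, 2 / 1.0)
  expect_equal(cluster_density(cl[0, ], seqs)$density, 0)

  # masked positions drop out of the denominator
  seqs_m <- seqs
  seqs_m[["r1"]] <- paste0(tolower(substr(seqs_m[["r1"]], 1, 100)),
                           substr(seqs_m[["r1"]], 101, 600))
  expect_equal(cluster_density(cl, seqs_m)$scanned_kb, 0.9)

  expect_error(cluster_density(cl, c(x = "nnnn")), "no unmasked")

  # partition consistency: density over the union equals the
  # count-weighted mean over disjoint parts
  part1 <- cluster_density(cl[cl$seq_id == "r1", ], seqs["r1"])
  part2 <- cluster_density(cl[cl$seq_id == "r2", ], seqs["r2"])
  pooled <- (part1$density * part1$scanned_kb +
               part2$density * part2$scanned_kb) /
    (part1$scanned_kb + part2$scanned_kb)
  expect_equal(d$density, pooled)
})

test_that("scannable window counts respect masks and strand doubling", {
  expect_equal(scannable_windows(c(x = "ACGTACGT"), 8), 2)
  expect_equal(scannable_windows(c(x = "ACGTACGT"), 8, both_strands = FALSE), 1)
  expect_equal(scannable_windows(c(x = "ACgTACGT"), 4, both_strands = FALSE), 2)
  expect_equal(scannable_windows(c(x = "ACG"), 8), 0)
  expect_equal(unmasked_length(c(x = "ACgTN", y = "AA")), 5)
})

test_that("hits and clusters export as BED-like tables", {
  probe <- c(meis2 = MEIS2_PROBE)
  a <- scan_sequences(probe, anchor_sm(), alpha = 1e-3)
  p <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(a, p)
  tab <- read.delim(p, header = FALSE)
  expect_equal(tab$V2, 14)
  expect_equal(tab$V6, "+")
})
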