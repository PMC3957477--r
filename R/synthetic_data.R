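# Seeded generators for every input the pipeline needs: order-k Markov
# backgrounds, repeat tracts, consensus-derived count matrices, and
# labeled promoter sets with planted anchor+partner clusters recorded as
# ground truth.  Generation is a pure function of (parameters, seed).

#' Train an order-k Markov model on sequences
#'
#' Maximum-likelihood transition probabilities with +1 smoothing on every
#' context (so unseen contexts get a uniform distribution and no
#' probability is ever zero).  Masked positions break the context chain.
#'
#' @param seqs named character vector.
#' @param order k >= 0; order 0 is an iid base model.
#' @return an object of class `markov_model` with elements `order`,
#'   `initial` (probabilities over k-mers) and `transitions`
#'   (4^k x 4 matrix, rows = contexts in lexicographic A<C<G<T order).
#' @export
train_markov <- function(seqs, order = 0) {
  if (order < 0) stop("order must be >= 0")
  k <- as.integer(order)
  nctx <- 4L^k
  trans <- matrix(1, nrow = nctx, ncol = 4)  # +1 smoothing
  init <- rep(1, nctx)
  for (s in seqs) {
    code <- encode_sequence(s)
    L <- length(code)
    if (L < k + 1L) next
    if (k == 0L) {
      nxt <- code
      ok <- !is.na(nxt)
      if (any(ok)) {
        tb <- tabulate(nxt[ok], nbins = 4)
        trans[1, ] <- trans[1, ] + tb
      }
    } else {
      # ctx[t] = index of the k-mer ending at position t (t >= k)
      idx <- rep(0, L)
      for (j in 0:(k - 1)) {
        shifted <- c(rep(NA_integer_, j), code[seq_len(L - j)])
        idx <- idx + (shifted - 1) * 4^j
      }
      ctx_at <- idx + 1          # NA where any of the k letters is masked
      pos <- seq.int(k + 1L, L)
      cc <- ctx_at[pos - 1L]
      nn <- code[pos]
      ok <- !is.na(cc) & !is.na(nn)
      if (any(ok)) {
        counts <- table(factor(cc[ok], levels = seq_len(nctx)),
                        factor(nn[ok], levels = 1:4))
        trans <- trans + as.matrix(counts)
        seen <- tabulate(cc[ok], nbins = nctx)
        init <- init + seen
      }
    }
  }
  trans <- trans / rowSums(trans)
  init <- init / sum(init)
  rownames(trans) <- kmer_names(k)
  colnames(trans) <- DNA_BASES
  names(init) <- kmer_names(k)
  structure(list(order = k, initial = init, transitions = trans),
            class = "markov_model")
}

kmer_names <- function(k) {
  if (k == 0L) return("")
  apply(do.call(expand.grid,
                rev(rep(list(DNA_BASES), k)))[, k:1, drop = FALSE],
        1, paste, collapse = "")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("markov_model of order", x$order, "(", nrow(x$transitions),
      "contexts )\n")
  invisible(x)
}

#' An order-0 uniform Markov model
#' @return a `markov_model`.
#' @export
uniform_markov <- function() {
  structure(list(order = 0L,
                 initial = stats::setNames(1, ""),
                 transitions = matrix(0.25, 1, 4,
                                      dimnames = list("", DNA_BASES))),
            class = "markov_model")
}

#' Sample a sequence from a Markov model
#'
#' @param model a `markov_model`.
#' @param length sequence length (>= model order).
#' @param seed integer seed; the same (model, length, seed) gives a
#'   byte-identical sequence.
#' @return a character scalar over A/C/G/T.
#' @export
sample_markov <- function(model, length, seed = NULL) {
  k <- model$order
  stopifnot(length >= k)
  with_seed(seed, {
    if (k == 0L) {
      p <- model$transitions[1, ]
      return(paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                   collapse = ""))
    }
    out <- integer(length)
    start_ctx <- sample.int(4L^k, 1, prob = model$initial)
    # decode the k-mer index into its letters (first letter = most
    # significant base-4 digit)
    rem <- start_ctx - 1L
    for (j in k:1) {
      out[j] <- rem %% 4L + 1L
      rem <- rem %/% 4L
    }
    if (length > k) {
      cum <- t(apply(model$transitions, 1, cumsum))
      u <- stats::runif(length - k)
      pow <- 4L^(k - 1L)
      ctx <- 0L
      for (j in 1:k) ctx <- ctx * 4L + (out[j] - 1L)
      ctx <- ctx + 1L
      for (t in seq.int(k + 1L, length)) {
        r <- cum[ctx, ]
        b <- 1L + (u[t - k] > r[1]) + (u[t - k] > r[2]) + (u[t - k] > r[3])
        out[t] <- b
        ctx <- ((ctx - 1L) %% pow) * 4L + (b - 1L) + 1L
      }
    }
    paste(DNA_BASES[out], collapse = "")
  })
}

#' Build a count matrix from a consensus string
#'
#' Each column holds `concentration` counts for the consensus letter and
#' 1 for the other three, so with the default `concentration = 97` the
#' consensus letter has frequency 0.97 per position (before
#' pseudocounts).
#'
#' @param consensus DNA string over A/C/G/T.
#' @param concentration consensus count per position (> 1 for an
#'   informative matrix; 1 gives the uniform matrix).
#' @param motif_id identifier; defaults to the consensus string.
#' @param pseudocount pseudocount carried by the matrix (default 0, so
#'   column frequencies are exactly `concentration / (concentration + 3)`).
#' @return a `count_matrix`.
#' @export
consensus_pwm <- function(consensus, concentration = 97,
                          motif_id = consensus, pseudocount = 0) {
  code <- encode_sequence(consensus)
  if (anyNA(code)) stop("consensus must be uppercase A/C/G/T")
  w <- length(code)
  m <- matrix(1, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  m[cbind(code, seq_len(w))] <- concentration
  count_matrix(m, motif_id = motif_id, pseudocount = pseudocount)
}

#' Default anchor and partner matrices
#'
#' Consensus-derived stand-ins for the three Hox/Pbx site classes
#' (cores TGATTGAT, TGATTAAT, TGATTTAT -- anterior, central, posterior
#' preferences, differing at one core position) and a TGACAG-core Meis
#' matrix.  Real SELEX-derived matrices can be supplied through
#' [read_count_matrix()] instead.
#'
#' @param concentration consensus weight passed to [consensus_pwm()].
#' @return named list of `count_matrix` objects: hox_class_I,
#'   hox_class_II, hox_class_III, meis.
#' @export
default_matrices <- function(concentration = 97) {
  list(
    hox_class_I = consensus_pwm("TGATTGAT", concentration, "hox_class_I"),
    hox_class_II = consensus_pwm("TGATTAAT", concentration, "hox_class_II"),
    hox_class_III = consensus_pwm("TGATTTAT", concentration, "hox_class_III"),
    meis = consensus_pwm("TGACAG", concentration, "meis"))
}

#' Default synthetic background model
#'
#' An order-2 Markov chain trained on a 100-kb synthetic genome that is
#' itself generated order-0 with a mild AT bias (A=T=0.3, C=G=0.2) under
#' a fixed seed.  Exercising an order-2 background against the order-0
#' p-value theory mirrors the fact that real genomic backgrounds are not
#' iid.
#'
#' @param genome_len training genome length (default 1e5).
#' @param order Markov order (default 2).
#' @param seed seed for the training genome (fixed default so the
#'   bundled background is stable across sessions).
#' @return a `markov_model`.
#' @export
default_background_model <- function(genome_len = 1e5, order = 2,
                                     seed = 20140521) {
  base <- structure(list(order = 0L, initial = stats::setNames(1, ""),
                         transitions = matrix(c(0.3, 0.2, 0.2, 0.3), 1, 4,
                                              dimnames = list("", DNA_BASES))),
                    class = "markov_model")
  genome <- sample_markov(base, genome_len, seed = seed)
  train_markov(c(g = genome), order = order)
}

#' Specification of planted composite clusters
#'
#' @param hox_matrix a `count_matrix` for the anchor (Hox/Pbx) site.
#' @param meis_matrix a `count_matrix` for the partner (Meis) site.
#' @param clusters_per_promoter fixed integer count (when
#'   `poisson = FALSE`, default) or Poisson rate per promoter.
#' @param poisson draw the per-promoter count from a Poisson law.
#' @param window maximum planted edge-to-edge spacing; spacing is drawn
#'   uniformly on 0..window.
#' @param site_sampling `"consensus"` plants the exact consensus word;
#'   `"pwm"` samples each letter from the matrix frequencies.
#' @param repeat_fraction target fraction of masked (lowercase) tract
#'   per promoter, in [0, 1).
#' @param repeat_mean_len mean geometric tract length (default 150 nt).
#' @return a `planting_spec` list.
#' @export
planting_spec <- function(hox_matrix, meis_matrix,
                          clusters_per_promoter = 1, poisson = FALSE,
                          window = 40,
                          site_sampling = c("consensus", "pwm"),
                          repeat_fraction = 0, repeat_mean_len = 150) {
  site_sampling <- match.arg(site_sampling)
  stopifnot(clusters_per_promoter >= 0, window >= 0,
            repeat_fraction >= 0, repeat_fraction < 1)
  structure(list(hox_matrix = hox_matrix, meis_matrix = meis_matrix,
                 clusters_per_promoter = clusters_per_promoter,
                 poisson = poisson, window = window,
                 site_sampling = site_sampling,
                 repeat_fraction = repeat_fraction,
                 repeat_mean_len = repeat_mean_len),
            class = "planting_spec")
}

sample_site_word <- function(cm, site_sampling) {
  f <- sweep(cm$counts, 2, colSums(cm$counts), "/")
  w <- ncol(f)
  if (site_sampling == "consensus") {
    paste(DNA_BASES[apply(cm$counts, 2, which.max)], collapse = "")
  } else {
    paste(vapply(seq_len(w), function(i) {
      sample(DNA_BASES, 1, prob = f[, i])
    }, character(1)), collapse = "")
  }
}

plant_in_sequence <- function(seq, spec, n_clusters, occupied) {
  # returns list(seq, truth rows); occupied = logical vector of length L
  L <- nchar(seq)
  truth <- list()
  for (ci in seq_len(n_clusters)) {
    aw <- sample_site_word(spec$hox_matrix, spec$site_sampling)
    pw <- sample_site_word(spec$meis_matrix, spec$site_sampling)
    a_strand <- sample(c("+", "-"), 1)
    p_strand <- sample(c("+", "-"), 1)
    a_ins <- if (a_strand == "+") aw else revcomp(aw)
    p_ins <- if (p_strand == "+") pw else revcomp(pw)
    gap <- sample.int(spec$window + 1L, 1) - 1L
    partner_first <- sample(c(TRUE, FALSE), 1)
    block <- if (partner_first) c(p_ins, a_ins) else c(a_ins, p_ins)
    blen <- nchar(block[1]) + gap + nchar(block[2])
    placed <- FALSE
    for (try in seq_len(1000)) {
      s0 <- sample.int(L - blen + 1L, 1) - 1L
      span <- seq.int(s0 + 1L, s0 + blen)
      if (any(occupied[span])) next
      first_end <- s0 + nchar(block[1])
      substr(seq, s0 + 1L, first_end) <- block[1]
      substr(seq, first_end + gap + 1L, s0 + blen) <- block[2]
      occupied[span] <- TRUE
      a0 <- if (partner_first) first_end + gap else s0
      p0 <- if (partner_first) s0 else first_end + gap
      truth[[length(truth) + 1]] <- data.frame(
        motif_id = c(spec$hox_matrix$motif_id, spec$meis_matrix$motif_id),
        role = c("anchor", "partner"),
        start = c(a0, p0),
        end = c(a0 + nchar(a_ins), p0 + nchar(p_ins)),
        strand = c(a_strand, p_strand),
        word = c(aw, pw),
        gap = gap, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place planted cluster after 1000 attempts")
  }
  list(seq = seq, occupied = occupied,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

insert_repeats <- function(seq, occupied, fraction, mean_len) {
  L <- nchar(seq)
  target <- round(fraction * L)
  masked <- 0L
  guard <- 0L
  while (masked < target && guard < 10000L) {
    guard <- guard + 1L
    len <- min(1L + stats::rgeom(1, 1 / mean_len), target - masked, L)
    s0 <- sample.int(L - len + 1L, 1) - 1L
    span <- seq.int(s0 + 1L, s0 + len)
    if (any(occupied[span])) next
    substr(seq, s0 + 1L, s0 + len) <-
      tolower(substr(seq, s0 + 1L, s0 + len))
    occupied[span] <- TRUE
    masked <- masked + len
  }
  list(seq = seq, occupied = occupied)
}

#' Generate labeled synthetic promoter sets with planted clusters
#'
#' The endoderm-labeled set carries planted anchor+partner clusters at
#' the rate given by `planting`; the ectoderm-labeled set and the random
#' pool are background-only.  Planted intervals are recorded as ground
#' truth; repeat tracts never overwrite planted sites.
#'
#' @param n_per_set promoters per labeled set (default 38).
#' @param length promoter length in nt (1000 or 2000 conventionally).
#' @param background a `markov_model` (default
#'   [default_background_model()]).
#' @param planting a [planting_spec()]; `NULL` plants nothing.
#' @param n_pool size of the background-only pool used for random-set
#'   controls (default 100).
#' @param seed root seed; all draws are derived from it.
#' @return list with `endoderm`, `ectoderm`, `pool` (named character
#'   vectors), `truth` (data.frame of planted sites: seq_id, motif_id,
#'   role, start, end, strand, word, gap) and `params`.
#' @export
make_promoter_sets <- function(n_per_set = 38, length = 1000,
                               background = default_background_model(),
                               planting = NULL, n_pool = 100, seed = 1) {
  gen_set <- function(n, prefix, stage) {
    stats::setNames(
      vapply(seq_len(n), function(i) {
        sample_markov(background, length,
                      seed = substream_seed(seed, stage, i))
      }, character(1)),
      sprintf("%s_%03d", prefix, seq_len(n)))
  }
  endo <- gen_set(n_per_set, "endo", "endoderm_bg")
  ecto <- gen_set(n_per_set, "ecto", "ectoderm_bg")
  pool <- gen_set(n_pool, "pool", "pool_bg")
  truth <- list()
  if (!is.null(planting)) {
    for (i in seq_along(endo)) {
      res <- with_seed(substream_seed(seed, "planting", i), {
        n_cl <- if (planting$poisson) {
          stats::rpois(1, planting$clusters_per_promoter)
        } else as.integer(planting$clusters_per_promoter)
        occupied <- rep(FALSE, nchar(endo[[i]]))
        pl <- plant_in_sequence(endo[[i]], planting, n_cl, occupied)
        if (planting$repeat_fraction > 0) {
          rp <- insert_repeats(pl$seq, pl$occupied,
                               planting$repeat_fraction,
                               planting$repeat_mean_len)
          pl$seq <- rp$seq
        }
        pl
      })
      endo[[i]] <- res$seq
      if (!is.null(res$truth)) {
        res$truth$seq_id <- names(endo)[i]
        truth[[length(truth) + 1]] <- res$truth
      }
    }
    if (planting$repeat_fraction > 0) {
      for (i in seq_along(ecto)) {
        ecto[[i]] <- with_seed(substream_seed(seed, "repeats_ecto", i), {
          insert_repeats(ecto[[i]], rep(FALSE, nchar(ecto[[i]])),
                         planting$repeat_fraction,
                         planting$repeat_mean_len)$seq
        })
      }
    }
  }
  truth <- if (length(truth)) {
    df <- do.call(rbind, truth)
    df[, c("seq_id", "motif_id", "role", "start", "end", "strand",
           "word", "gap")]
  } else NULL
  list(endoderm = endo, ectoderm = ecto, pool = pool, truth = truth,
       params = list(n_per_set = n_per_set, length = length,
                     order = background$order, seed = seed,
                     planting = if (is.null(planting)) NULL else {
                       planting[setdiff(names(planting),
                                        c("hox_matrix", "meis_matrix"))]
                     }))
}
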