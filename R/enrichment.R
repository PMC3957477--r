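# Observed-vs-theoretical site-rate curves over a p-value threshold
# grid, null control bands (random gene sets, column-permuted matrices)
# and the endoderm-vs-ectoderm comparison with a declared, size-
# controlled enrichment verdict.

#' Default p-value threshold grid
#'
#' Half-decade steps from 1e-1 down to 1e-6.
#' @return decreasing numeric vector.
#' @export
default_alpha_grid <- function() {
  10^(-seq(1, 6, by = 0.5))
}

#' Per-window site-rate curve
#'
#' For each threshold, the fraction of scannable windows (both strands)
#' carrying a hit with p-value at most the threshold.  Under the
#' theoretical null this rate is close to the threshold itself, so the
#' expected curve is the identity.
#'
#' @param hits hit data.frame produced at the loosest alpha of the grid.
#' @param scanned_windows denominator from [scannable_windows()].
#' @param alphas decreasing threshold grid.
#' @return data.frame: alpha, observed_rate, expected_rate, fold.
#' @export
site_rate_curve <- function(hits, scanned_windows,
                            alphas = default_alpha_grid()) {
  if (scanned_windows <= 0) stop("no scannable windows")
  obs <- vapply(alphas, function(a) sum(hits$pvalue <= a), numeric(1)) /
    scanned_windows
  data.frame(alpha = alphas, observed_rate = obs, expected_rate = alphas,
             fold = obs / alphas)
}

summarize_band <- function(rates, alphas, label, seed, percentiles = c(0.025, 0.975)) {
  # rates: n_replicates x n_alphas matrix
  structure(list(
    label = label,
    alphas = alphas,
    mean = colMeans(rates),
    lower = apply(rates, 2, stats::quantile, probs = percentiles[1],
                  names = FALSE),
    upper = apply(rates, 2, stats::quantile, probs = percentiles[2],
                  names = FALSE),
    rates = rates,
    n_replicates = nrow(rates),
    seed = seed), class = "control_band")
}

#' @export
print.control_band <- function(x, ...) {
  cat("control_band", x$label, ":", x$n_replicates, "replicates over",
      length(x$alphas), "thresholds\n")
  invisible(x)
}

#' Random-gene-set control band
#'
#' Draws sets of promoters from a pool without replacement and records
#' the per-window site-rate curve of each draw; the spread of these
#' curves is what a "random set of gene promoters" of the same size
#' produces under the same scan.
#'
#' @param pool named character vector of promoter sequences.
#' @param set_size promoters per draw.
#' @param n_draws number of seeded draws (default 100).
#' @param seed root seed.
#' @param sm,dist,alphas scan parameters (hits are collected at the
#'   loosest alpha of the grid).
#' @return a `control_band`.
#' @export
random_set_control <- function(pool, set_size, n_draws = 100, seed = 1,
                               sm, dist = score_distribution(sm),
                               alphas = default_alpha_grid()) {
  if (length(pool) < set_size) stop("pool smaller than set_size")
  alpha0 <- max(alphas)
  hits <- scan_sequences(pool, sm, dist, alpha = alpha0)
  w <- ncol(sm$scores)
  win_per_seq <- vapply(names(pool), function(id) {
    scannable_windows(pool[id], w)
  }, numeric(1))
  rates <- matrix(NA_real_, n_draws, length(alphas))
  for (r in seq_len(n_draws)) {
    take <- with_seed(substream_seed(seed, "random_sets", r),
                      sample(names(pool), set_size))
    h <- hits[hits$seq_id %in% take, , drop = FALSE]
    denom <- sum(win_per_seq[take])
    rates[r, ] <- site_rate_curve(h, denom, alphas)$observed_rate
  }
  summarize_band(rates, alphas, "random_gene_sets", seed)
}

#' Column-permuted-matrix control band
#'
#' Rescans the same promoters with seeded column permutations of the
#' count matrix (default 100).  Permutation destroys the biological
#' word but leaves the theoretical score distribution unchanged, so the
#' band shows what the observed curve would look like with the signal
#' removed.
#'
#' @param cm the `count_matrix` to permute.
#' @param promoters named character vector to rescan.
#' @param n_perms number of permutations (default 100).
#' @param seed root seed.
#' @param bg background for scoring (default estimated from the
#'   promoters, strand-symmetrized).
#' @param alphas threshold grid.
#' @param bin_width score discretization.
#' @return a `control_band`; also carries `cluster_counts` when
#'   `partner_sm` is given.
#' @param partner_sm optional partner `scoring_matrix`: when given, the
#'   number of anchor+partner clusters at `window`/`cluster_alpha` is
#'   recorded per permutation.
#' @param window,cluster_alpha cluster parameters used when
#'   `partner_sm` is given.
#' @export
permuted_matrix_control <- function(cm, promoters, n_perms = 100, seed = 1,
                                    bg = estimate_background(promoters),
                                    alphas = default_alpha_grid(),
                                    bin_width = 0.001,
                                    partner_sm = NULL, window = 40,
                                    cluster_alpha = 1e-4) {
  stopifnot(n_perms >= 1)
  w <- ncol(cm$counts)
  codes <- lapply(promoters, encode_sequence)
  # all sequences scored as one vector, separated by w-1 NAs so no
  # window straddles two promoters
  spacer <- rep(NA_integer_, max(w - 1L, 0L))
  big <- unlist(lapply(codes, function(x) c(x, spacer)), use.names = FALSE)
  # the theoretical distribution is permutation-invariant: compute once
  sm0 <- build_scoring_matrix(cm, bg)
  dist <- score_distribution(sm0, bg, bin_width)
  denom <- scannable_windows(promoters, w)
  partner_hits <- NULL
  if (!is.null(partner_sm)) {
    pa <- max(cluster_alpha, min_pvalue(score_distribution(partner_sm, bg,
                                                           bin_width)))
    partner_hits <- scan_sequences(promoters, partner_sm, alpha = pa)
  }
  rates <- matrix(NA_real_, n_perms, length(alphas))
  n_clusters <- if (is.null(partner_sm)) NULL else integer(n_perms)
  anchor_alpha <- max(cluster_alpha, min_pvalue(dist))
  for (r in seq_len(n_perms)) {
    pcm <- permute_matrix(cm, seed = substream_seed(seed, "permutations", r))
    psm <- build_scoring_matrix(pcm, bg)
    pv <- pvalue(dist, c(window_scores(big, psm$scores),
                         window_scores(big, revcomp_matrix(psm)$scores)))
    rates[r, ] <- vapply(alphas, function(a) sum(pv <= a, na.rm = TRUE),
                         numeric(1)) / denom
    if (!is.null(partner_sm)) {
      anchors <- scan_encoded(codes, psm, dist, anchor_alpha)
      n_clusters[r] <- nrow(detect_clusters(anchors, partner_hits, window))
    }
  }
  band <- summarize_band(rates, alphas, "permuted_matrix", seed)
  band$cluster_counts <- n_clusters
  band
}

#' Markov-background control band
#'
#' Rescans random sequences generated from a Markov model trained on the
#' promoters themselves, preserving each promoter's length and
#' (optionally) its repeat-mask layout -- the number and positions of
#' masked tracts are copied onto every replicate.  Results depend on the
#' chosen Markov order, which is why this control is exposed with `order`
#' as a parameter rather than fixed.
#'
#' @param promoters named character vector of (masked) sequences.
#' @param order Markov order of the trained null model (default 2).
#' @param n_reps replicate sequence sets (default 100).
#' @param seed root seed.
#' @param sm,dist,alphas scan parameters.
#' @param copy_masks reapply each promoter's lowercase mask layout to its
#'   replicates (default TRUE).
#' @return a `control_band` labeled `markov_background`.
#' @export
markov_background_control <- function(promoters, order = 2, n_reps = 100,
                                      seed = 1, sm,
                                      dist = score_distribution(sm),
                                      alphas = default_alpha_grid(),
                                      copy_masks = TRUE) {
  model <- train_markov(promoters, order = order)
  lens <- nchar(promoters)
  masks <- lapply(promoters, mask_positions)
  denom <- scannable_windows(promoters, ncol(sm$scores))
  rates <- matrix(NA_real_, n_reps, length(alphas))
  for (r in seq_len(n_reps)) {
    sim <- vapply(seq_along(promoters), function(i) {
      s <- sample_markov(model, lens[i],
                         seed = substream_seed(seed, "markov_bg",
                                               (r - 1L) * length(promoters) + i))
      if (copy_masks && length(masks[[i]])) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[masks[[i]] + 1] <- tolower(ch[masks[[i]] + 1])
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1))
    names(sim) <- names(promoters)
    pv <- scan_sequences(sim, sm, dist, alpha = max(alphas))$pvalue
    rates[r, ] <- vapply(alphas, function(a) sum(pv <= a), numeric(1)) / denom
  }
  summarize_band(rates, alphas, "markov_background", seed)
}

#' Compare labeled promoter sets against permutation nulls
#'
#' The end-to-end enrichment analysis: scan both sets with the same
#' matrices and background, compute site-rate curves, permuted-matrix
#' control bands per set, composite-cluster counts and densities, and an
#' enrichment verdict per set.
#'
#' A set is flagged `enriched` when its observed curve lies strictly
#' above the upper percentile of its permuted-matrix band at every grid
#' threshold between `alpha_star` (default 1e-3) and the smallest
#' p-value the matrix can attain (thresholds below that floor are
#' vacuous: observed and null rates are both identically zero there).
#'
#' @param endoderm,ectoderm named character vectors of promoter
#'   sequences.
#' @param anchor_cm anchor `count_matrix` (one class) or a named list of
#'   them (curves and verdicts are then reported per class and the
#'   verdict refers to the first).
#' @param meis_cm partner `count_matrix` for cluster detection, or NULL
#'   to skip clusters.
#' @param window cluster spacing window in nt (default 40).
#' @param alphas threshold grid.
#' @param alpha_star loosest threshold entering the verdict.
#' @param cluster_alpha site-calling threshold for clusters (default
#'   1e-4).
#' @param n_perms permutations per control band (default 100).
#' @param background `"auto"` (order-0 estimated from both sets pooled,
#'   strand-symmetrized), `"uniform"`, or a `background0`.
#' @param seed root seed.
#' @param bin_width score discretization.
#' @return an `enrichment_result`: per-set curves, bands, cluster
#'   tables, fold enrichments and verdicts.
#' @export
compare_sets <- function(endoderm, ectoderm, anchor_cm, meis_cm = NULL,
                         window = 40, alphas = default_alpha_grid(),
                         alpha_star = 1e-3, cluster_alpha = 1e-4,
                         n_perms = 100, background = "auto", seed = 1,
                         bin_width = 0.001) {
  if (!length(endoderm) || !length(ectoderm)) stop("both sets must be non-empty")
  if (inherits(anchor_cm, "count_matrix")) {
    anchor_cm <- stats::setNames(list(anchor_cm), anchor_cm$motif_id)
  }
  bg <- if (inherits(background, "background0")) background
        else if (identical(background, "uniform")) uniform_background()
        else estimate_background(c(endoderm, ectoderm))
  sets <- list(endoderm = endoderm, ectoderm = ectoderm)
  meis_sm <- if (!is.null(meis_cm)) build_scoring_matrix(meis_cm, bg)
  per_class <- list()
  for (cls in names(anchor_cm)) {
    cm <- anchor_cm[[cls]]
    sm <- build_scoring_matrix(cm, bg)
    dist <- score_distribution(sm, bg, bin_width)
    verdict_alphas <- alphas[alphas <= alpha_star & alphas >= min_pvalue(dist)]
    res_sets <- list()
    for (lab in names(sets)) {
      seqs <- sets[[lab]]
      hits <- scan_sequences(seqs, sm, dist, alpha = max(alphas))
      denom <- scannable_windows(seqs, ncol(sm$scores))
      curve <- site_rate_curve(hits, denom, alphas)
      # same permutation substream for both sets: paired controls, and
      # swapping the set labels swaps the verdicts exactly
      band <- permuted_matrix_control(
        cm, seqs, n_perms = n_perms,
        seed = substream_seed(seed, paste0("perm_", cls)),
        bg = bg, alphas = alphas, bin_width = bin_width)
      iv <- match(verdict_alphas, alphas)
      enriched <- length(iv) > 0 &&
        all(curve$observed_rate[iv] > band$upper[iv])
      clusters <- NULL; density <- NULL
      if (!is.null(meis_sm)) {
        # a matrix too short to attain cluster_alpha would make every
        # site uncallable: clamp at its minimal attainable p-value so an
        # exact-consensus site always qualifies
        a_anchor <- max(cluster_alpha, min_pvalue(dist))
        a_partner <- max(cluster_alpha,
                         min_pvalue(score_distribution(meis_sm, bg,
                                                       bin_width)))
        anchors <- hits[hits$pvalue <= a_anchor, , drop = FALSE]
        partners <- scan_sequences(seqs, meis_sm, alpha = a_partner)
        clusters <- detect_clusters(anchors, partners, window)
        density <- cluster_density(clusters, seqs, set_id = lab)
      }
      res_sets[[lab]] <- list(curve = curve, band = band,
                              enriched = enriched, n_hits = nrow(hits),
                              clusters = clusters, density = density,
                              scanned_windows = denom)
    }
    per_class[[cls]] <- res_sets
  }
  structure(list(classes = per_class,
                 params = list(window = window, alphas = alphas,
                               alpha_star = alpha_star,
                               cluster_alpha = cluster_alpha,
                               n_perms = n_perms, seed = seed,
                               background = as.numeric(bg),
                               bin_width = bin_width),
                 verdicts = vapply(per_class, function(cl) {
                   c(endoderm = cl$endoderm$enriched,
                     ectoderm = cl$ectoderm$enriched)
                 }, logical(2))),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (", length(x$classes), "anchor class(es) )\n")
  for (cls in names(x$classes)) {
    for (lab in names(x$classes[[cls]])) {
      r <- x$classes[[cls]][[lab]]
      cat(sprintf("  %-14s %-9s hits=%-5d %s\n", cls, lab, r$n_hits,
                  if (r$enriched) "ENRICHED" else "not enriched"))
      if (!is.null(r$density)) {
        cat(sprintf("    clusters=%d  density=%.4g /kb\n",
                    r$density$n_clusters, r$density$density))
      }
    }
  }
  invisible(x)
}

#' Per-promoter best-hit curve (secondary statistic)
#'
#' Fraction of promoters whose best site reaches each threshold.
#'
#' @param hits hit data.frame.
#' @param seq_ids all promoter ids in the set (promoters with no hit
#'   count in the denominator).
#' @param alphas threshold grid.
#' @return data.frame: alpha, fraction.
#' @export
best_hit_curve <- function(hits, seq_ids, alphas = default_alpha_grid()) {
  best <- tapply(hits$pvalue, hits$seq_id, min)
  data.frame(alpha = alphas,
             fraction = vapply(alphas, function(a) {
               sum(best <= a, na.rm = TRUE)
             }, numeric(1)) / length(seq_ids))
}
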