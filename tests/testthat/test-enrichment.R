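# Site-rate curves, control bands and the set comparison verdict.

test_that("site_rate_curve handles trivial cases", {
  hits0 <- data.frame(pvalue = numeric(0))
  cv <- site_rate_curve(hits0, 100, alphas = c(1e-2, 1e-3))
  expect_equal(cv$observed_rate, c(0, 0))
  expect_error(site_rate_curve(hits0, 0), "scannable")

  # every window a hit at alpha = 1 -> rate 1
  hits1 <- data.frame(pvalue = rep(1, 50))
  expect_equal(site_rate_curve(hits1, 50, alphas = 1)$observed_rate, 1)

  # rates are non-increasing as alpha decreases
  withr_seed(12)
  hits <- data.frame(pvalue = runif(200)^3)
  cv2 <- site_rate_curve(hits, 400)
  expect_true(all(diff(cv2$observed_rate) <= 0))
  expect_true(all(cv2$observed_rate >= 0 & cv2$observed_rate <= 1))
})

test_that("fold enrichment is rate-based: duplicating promoters leaves it unchanged", {
  seqs <- c(p1 = random_dna(400, 13), p2 = random_dna(400, 14))
  sm <- build_scoring_matrix(consensus_pwm("TGATTAAT", 97), uniform_background())
  d <- score_distribution(sm)
  alphas <- c(1e-1, 1e-2)
  h1 <- scan_sequences(seqs, sm, d, alpha = max(alphas))
  c1 <- site_rate_curve(h1, scannable_windows(seqs, 8), alphas)
  dup <- c(seqs, stats::setNames(seqs, c("p3", "p4")))
  h2 <- scan_sequences(dup, sm, d, alpha = max(alphas))
  c2 <- site_rate_curve(h2, scannable_windows(dup, 8), alphas)
  expect_equal(c1$fold, c2$fold)
})

test_that("random-set control collapses onto the pool curve for a full draw", {
  pool <- stats::setNames(
    vapply(1:6, function(i) random_dna(300, 140 + i), character(1)),
    paste0("p", 1:6))
  sm <- build_scoring_matrix(consensus_pwm("TGATTAAT", 97), uniform_background())
  alphas <- c(1e-1, 1e-2, 1e-3)
  band <- random_set_control(pool, set_size = 6, n_draws = 1, seed = 2,
                             sm = sm, alphas = alphas)
  hits <- scan_sequences(pool, sm, alpha = 0.1)
  own <- site_rate_curve(hits, scannable_windows(pool, 8), alphas)
  expect_equal(as.numeric(band$mean), own$observed_rate)
  expect_equal(band$lower, band$upper)  # one replicate: zero-width band

  b1 <- random_set_control(pool, 3, n_draws = 5, seed = 9, sm = sm,
                           alphas = alphas)
  b2 <- random_set_control(pool, 3, n_draws = 5, seed = 9, sm = sm,
                           alphas = alphas)
  expect_identical(b1$rates, b2$rates)
  expect_error(random_set_control(pool, 10, 2, 1, sm), "smaller")
})

test_that("random-set bands on homogeneous pools cover the pool-wide curve", {
  pool <- stats::setNames(
    vapply(1:30, function(i) random_dna(400, 150 + i), character(1)),
    paste0("p", 1:30))
  sm <- build_scoring_matrix(consensus_pwm("TGATTAAT", 97), uniform_background())
  alphas <- c(1e-1, 3e-2, 1e-2, 3e-3, 1e-3)
  band <- random_set_control(pool, set_size = 10, n_draws = 100, seed = 5,
                             sm = sm, alphas = alphas)
  hits <- scan_sequences(pool, sm, alpha = 0.1)
  own <- site_rate_curve(hits, scannable_windows(pool, 8), alphas)
  covered <- own$observed_rate >= band$lower & own$observed_rate <= band$upper
  expect_gte(mean(covered), 0.95)
})

test_that("width-1 matrices give a zero-width permutation band", {
  cm <- count_matrix(matrix(c(5, 1, 1, 1), 4, 1), motif_id = "w1")
  seqs <- c(x = random_dna(300, 19))
  band <- permuted_matrix_control(cm, seqs, n_perms = 10, seed = 3,
                                  bg = uniform_background(),
                                  alphas = c(0.5, 0.25))
  expect_equal(band$lower, band$upper)
  expect_equal(band$n_replicates, 10)
})

test_that("permutation bands cover the null and are beaten by planted signal", {
  mats <- default_matrices()
  alphas <- c(1e-2, 1e-3, 1e-4)
  # null promoters: original curve inside the band
  null_seqs <- stats::setNames(
    vapply(1:20, function(i) random_dna(1000, 160 + i), character(1)),
    paste0("n", 1:20))
  bg <- uniform_background()
  sm <- build_scoring_matrix(mats$hox_class_II, bg)
  d <- score_distribution(sm)
  band <- permuted_matrix_control(mats$hox_class_II, null_seqs,
                                  n_perms = 50, seed = 7, bg = bg,
                                  alphas = alphas)
  own <- site_rate_curve(scan_sequences(null_seqs, sm, d, alpha = 1e-2),
                         scannable_windows(null_seqs, 8), alphas)
  expect_true(all(own$observed_rate <= band$upper))

  # planted signal: one consensus site per promoter
  planted <- null_seqs
  withr_seed(99)
  for (i in seq_along(planted)) {
    pos <- sample(0:(1000 - 8), 1)
    s <- planted[[i]]; substr(s, pos + 1, pos + 8) <- "TGATTAAT"
    planted[[i]] <- s
  }
  band_p <- permuted_matrix_control(mats$hox_class_II, planted,
                                    n_perms = 50, seed = 7, bg = bg,
                                    alphas = alphas)
  own_p <- site_rate_curve(scan_sequences(planted, sm, d, alpha = 1e-2),
                           scannable_windows(planted, 8), alphas)
  expect_gt(own_p$observed_rate[3], band_p$upper[3])  # alpha = 1e-4
})

test_that("compare_sets is symmetric and flags only the planted set", {
  mats <- default_matrices()
  spec <- planting_spec(mats$hox_class_II, mats$meis, 1, window = 40)
  sets <- make_promoter_sets(12, 1000, uniform_markov(), spec,
                             n_pool = 0, seed = 23)
  res <- compare_sets(sets$endoderm, sets$ectoderm, mats$hox_class_II,
                      mats$meis, n_perms = 30, seed = 23,
                      background = "uniform")
  cl <- res$classes$hox_class_II
  expect_true(cl$endoderm$enriched)
  expect_false(cl$ectoderm$enriched)
  expect_gte(cl$endoderm$density$n_clusters, 12 * 0.9)
  expect_equal(cl$ectoderm$density$n_clusters, 0)

  # identical sets give identical curves and a fold ratio of 1
  res_id <- compare_sets(sets$ectoderm, sets$ectoderm, mats$hox_class_II,
                         n_perms = 5, seed = 4, background = "uniform")
  cid <- res_id$classes$hox_class_II
  expect_equal(cid$endoderm$curve, cid$ectoderm$curve)

  # swapping the labels swaps the verdicts exactly
  res_sw <- compare_sets(sets$ectoderm, sets$endoderm, mats$hox_class_II,
                         mats$meis, n_perms = 30, seed = 23,
                         background = "uniform")
  swl <- res_sw$classes$hox_class_II
  expect_equal(swl$endoderm$enriched, cl$ectoderm$enriched)
  expect_equal(swl$ectoderm$enriched, cl$endoderm$enriched)
  expect_equal(swl$ectoderm$curve, cl$endoderm$curve)

  expect_error(compare_sets(character(0), sets$ectoderm,
                            mats$hox_class_II), "non-empty")
})

test_that("best-hit curves count promoters, not sites", {
  hits <- data.frame(seq_id = c("a", "a", "b"),
                     pvalue = c(1e-5, 1e-2, 1e-3))
  cv <- best_hit_curve(hits, c("a", "b", "c"), alphas = c(1e-2, 1e-4))
  expect_equal(cv$fraction, c(2 / 3, 1 / 3))
})

test_that("markov-background control is seeded, mask-preserving and covers the null", {
  withr_seed(77)
  seqs <- stats::setNames(
    vapply(1:10, function(i) random_dna(500, 770 + i), character(1)),
    paste0("p", 1:10))
  # mask a tract in one promoter; replicates must reproduce its layout
  seqs[[3]] <- paste0(substr(seqs[[3]], 1, 100),
                      tolower(substr(seqs[[3]], 101, 160)),
                      substr(seqs[[3]], 161, 500))
  sm <- build_scoring_matrix(consensus_pwm("TGATTAAT", 97), uniform_background())
  alphas <- c(1e-1, 1e-2, 1e-3)
  b1 <- markov_background_control(seqs, order = 0, n_reps = 10, seed = 5,
                                  sm = sm, alphas = alphas)
  b2 <- markov_background_control(seqs, order = 0, n_reps = 10, seed = 5,
                                  sm = sm, alphas = alphas)
  expect_identical(b1$rates, b2$rates)
  expect_equal(b1$label, "markov_background")
  # the band straddles the theoretical expectation on iid-ish input
  expect_true(all(b1$lower <= alphas & alphas <= pmax(b1$upper, alphas)))
  # own curve sits inside the band at the loosest alpha
  own <- site_rate_curve(scan_sequences(seqs, sm, alpha = 0.1),
                         scannable_windows(seqs, 8), alphas)
  expect_gte(own$observed_rate[1], b1$lower[1] * 0.5)
})
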