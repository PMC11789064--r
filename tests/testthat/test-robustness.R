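test_that("paired t tests handle identity, shift, and Holm across cells", {
  x <- c(1, 2, 3, 4, 5)
  same <- paired_ttest_holm(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$hedges_g, 0)
  expect_true(same$flagged)
  # constant nonzero shift: g undefined, flagged, never infinite
  shift <- paired_ttest_holm(x + 2, x)
  expect_true(shift$flagged)
  expect_true(is.na(shift$hedges_g))
  # multi-cell family: adjusted p monotone in raw p and never smaller
  set.seed(1)
  xs <- rnorm(30); ys <- xs + rnorm(30, 0.3)
  cells <- rep(c("a", "b", "c"), each = 10)
  res <- paired_ttest_holm(xs, ys, cell = cells)
  expect_true(all(res$p_holm >= res$p - 1e-15))
  expect_equal(res$p_holm, holm_by_hand(res$p))
  expect_error(paired_ttest_holm(1:2, 2:3), "3 pairs")
})

test_that("paired Hedge's g applies the small-sample correction", {
  set.seed(2)
  x <- rnorm(12); y <- x - 0.8 + rnorm(12, 0, 0.3)
  res <- paired_ttest_holm(x, y)
  d <- x - y
  expect_equal(res$hedges_g,
               mean(d) / sd(d) * (1 - 3 / (4 * 11 - 1)), tolerance = 1e-12)
})

test_that("mann_whitney matches brute-force enumeration on 4 vs 4", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.8, 2.9, 4.0, 1.1)
  got <- mann_whitney(x, y)
  oracle <- mw_enumeration(x, y)
  expect_equal(got$W, oracle$W)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)
  # identical multisets -> p near 1; full separation -> extreme W
  expect_gt(mann_whitney(c(1, 2, 3), c(3, 1, 2))$p, 0.9)
  expect_equal(mann_whitney(c(10, 11, 12), c(1, 2, 3))$W, 9)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 11, 12))$W, 0)
})

test_that("bootstrap_scores: self-comparison is null and ranks sum to B", {
  sim <- quick_sim(n_images = 80, n_raters = 12, seed = 31)
  fc <- feature_sim_config(n_layers = 2, dims_per_layer = c(16, 32), seed = 32)
  bank <- simulate_feature_bank(fc, sim$truth)
  bs <- bootstrap_scores(list(m1 = bank, m2 = bank), sim$ratings,
                         B = 200, seed = 5, mode = "rescore")
  expect_true(all(bs$scores[, 1] == bs$scores[, 2]))
  expect_equal(bs$pairs$p, 1)
  expect_equal(unname(colSums(bs$ranks)), rep(200L, 2))
  expect_equal(unname(rowSums(bs$ranks)), rep(200L, 2))
})

test_that("a dominant model is ranked first in essentially all bootstraps", {
  sim <- quick_sim(n_images = 150, n_raters = 15, seed = 33)
  strong <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 32,
                       decodable_fraction = 0.8, seed = 34), sim$truth)
  weak <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 32,
                       depth_profile = "zero", seed = 35), sim$truth)
  bs <- bootstrap_scores(list(strong = strong, weak = weak), sim$ratings,
                         B = 200, seed = 6, mode = "rescore")
  expect_gte(bs$ranks["strong", 1], 198L)
  expect_lt(bs$pairs$p_holm, 0.02)
  expect_gt(bs$pairs$mean_delta, 0)
})

test_that("refit and rescore bootstrap modes agree on a small problem", {
  sim <- quick_sim(n_images = 60, n_raters = 10, seed = 36)
  bank <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 16,
                       decodable_fraction = 0.7, seed = 37), sim$truth)
  a <- bootstrap_scores(list(m = bank), sim$ratings, B = 60, seed = 7,
                        mode = "refit")
  b <- bootstrap_scores(list(m = bank), sim$ratings, B = 60, seed = 7,
                        mode = "rescore")
  expect_equal(mean(a$scores), mean(b$scores), tolerance = 0.1)
})

test_that("a respondent who rates at the group mean decodes exactly like the group", {
  sim <- quick_sim(n_images = 50, n_raters = 8, seed = 38)
  ga <- group_average(sim$ratings)
  bank <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 16,
                       decodable_fraction = 0.8, seed = 39), sim$truth)
  X <- bank$layers[[1]]
  rownames(X) <- bank$image_ids
  # append a synthetic respondent whose ratings equal the group means
  extra <- data.frame(respondent_id = "rmean", image_id = ga$image_id,
                      rating = ga$mean, affect = "beauty",
                      image_category = "all", dataset_id = "sim")
  tab <- rbind(sim$ratings, extra)
  ind <- decode_individual(X, tab, min_images = 10)
  r_group <- decode_bank(bank, ga)$layers[[1]]$r
  r_mean_resp <- ind$per_respondent$r[ind$per_respondent$respondent_id == "rmean"]
  expect_equal(r_mean_resp, r_group, tolerance = 1e-10)
})

test_that("divergent raters are less decodable (taste-typicality relationship)", {
  # two rater groups: low vs high idiosyncratic variance
  cfg <- rater_sim_config(n_images = 250, n_raters = 30,
                          var_idio = c(rep(0.3, 15), rep(8, 15)),
                          var_noise = 1, discretize = FALSE, seed = 40)
  sim <- simulate_ratings(cfg)
  bank <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 64,
                       decodable_fraction = 0.85, noise_scale = 0.25,
                       seed = 41), sim$truth)
  X <- bank$layers[[1]]
  rownames(X) <- bank$image_ids
  ind <- decode_individual(X, sim$ratings, min_images = 20)
  expect_gt(ind$cor_with_mm1, 0.3)
  # negative individual accuracies, if any, are reported as-is (not clipped)
  expect_true(all(ind$per_respondent$r >= -1 & ind$per_respondent$r <= 1))
})

test_that("respondents under the image floor are skipped and reported", {
  sim <- quick_sim(n_images = 40, n_raters = 6, seed = 42)
  bank <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 8,
                       n_signal_dims = 4, seed = 43), sim$truth)
  X <- bank$layers[[1]]
  rownames(X) <- bank$image_ids
  expect_message(ind <- decode_individual(X, sim$ratings, min_images = 50),
                 "skipped")
  expect_equal(length(ind$skipped), 6)
})

test_that("cross_decode diagonal equals within-set leave-one-out decoding", {
  sim <- quick_sim(n_images = 60, n_raters = 10, seed = 44)
  bank <- simulate_feature_bank(
    feature_sim_config(n_layers = 1, dims_per_layer = 24,
                       decodable_fraction = 0.7, seed = 45), sim$truth)
  X <- bank$layers[[1]]
  y <- group_average(sim$ratings)$mean
  cell <- cross_decode(X, y, seq_len(60), seq_len(60))
  expect_true(cell$diagonal)
  expect_equal(cell$r, decode_bank(bank, group_average(sim$ratings))$layers[[1]]$r,
               tolerance = 1e-12)
  expect_error(cross_decode(X, y, 1:40, 30:60), "overlap")
})

test_that("cross_decode_matrix is labelled, sized, and CI-bracketed", {
  set.seed(46)
  n <- 40; D <- 12
  g <- rnorm(n)
  mk <- function() list(features = cbind(g + rnorm(n, 0, 0.3) %o% rep(1, D / 2),
                                         matrix(rnorm(n * D / 2), n)),
                        y = g + rnorm(n, 0, 0.2))
  sets <- list(one = mk(), two = mk())
  cdm <- cross_decode_matrix(sets, lambda = 10, B = 100, seed = 1)
  expect_equal(dim(cdm$r), c(2L, 2L))
  expect_true(all(!is.na(cdm$r)))
  expect_true(all(cdm$ci_lo <= cdm$r + 1e-9 & cdm$r <= cdm$ci_hi + 1e-9))
})

test_that("bootstrap p for a true-null pair is not anticonservative", {
  # The default (refit-per-replicate) bootstrap is checked on a null where
  # its resampled randomness drives the score difference: targets with no
  # stable image component (var_shared = 0) and signal-free banks. The
  # fixed-prediction rescore shortcut is NOT calibrated for this null (the
  # chance-fitting adaptation is never resampled); see the methods vignette.
  ps <- vapply(1:30, function(i) {
    sim <- simulate_ratings(rater_sim_config(n_images = 100, n_raters = 20,
                                             var_shared = 0, var_idio = 2,
                                             var_noise = 2, discretize = FALSE,
                                             seed = 100 + i))
    b1 <- simulate_feature_bank(
      feature_sim_config(n_layers = 1, dims_per_layer = 8, n_signal_dims = 4,
                         depth_profile = "zero", seed = 200 + i), sim$truth)
    b2 <- simulate_feature_bank(
      feature_sim_config(n_layers = 1, dims_per_layer = 8, n_signal_dims = 4,
                         depth_profile = "zero", seed = 300 + i), sim$truth)
    bootstrap_scores(list(a = b1, b = b2), sim$ratings, B = 200,
                     seed = i, mode = "refit")$pairs$p
  }, numeric(1))
  # coarse calibration: no piling at the rejection end, mass spread out
  expect_lte(mean(ps < 0.05), 0.1)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.85)
  expect_gt(sd(ps), 0.1)
})
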