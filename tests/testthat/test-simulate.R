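test_that("rater config invariants are enforced", {
  expect_error(rater_sim_config(coverage = 0), "coverage")
  expect_error(rater_sim_config(coverage = 1.2), "coverage")
  expect_error(rater_sim_config(var_shared = -1), "variances")
  expect_error(rater_sim_config(scale_min = 7, scale_max = 0), "scale_min")
  expect_error(rater_sim_config(var_idio = c(1, 2, 3), n_raters = 5),
               "var_idio")
})

test_that("every rater rates exactly round(coverage * n_images) images", {
  sim <- simulate_ratings(rater_sim_config(n_images = 100, n_raters = 60,
                                           coverage = 0.25, seed = 4))
  counts <- table(sim$ratings$respondent_id)
  expect_true(all(counts == 25))
  expect_equal(length(counts), 60)
  # and the viewed sets differ between raters
  per_rater <- split(sim$ratings$image_id, sim$ratings$respondent_id)
  expect_gt(length(unique(vapply(per_rater, paste, character(1),
                                 collapse = ","))), 1)
})

test_that("coverage leaving an image under 2 raters errors with the image named", {
  expect_error(
    simulate_ratings(rater_sim_config(n_images = 50, n_raters = 2,
                                      coverage = 0.04, seed = 1)),
    "img[0-9]+.*raters|rater")
})

test_that("noise-free raters agree perfectly before discretization", {
  sim <- simulate_ratings(rater_sim_config(n_images = 40, n_raters = 6,
                                           var_idio = 0, var_noise = 0,
                                           discretize = FALSE, seed = 2))
  res <- mm1(sim$ratings)
  expect_equal(res$r_mm1, rep(1, 6), tolerance = 1e-12)
  # ratings respect the scale bounds
  expect_true(all(sim$ratings$rating >= 0 & sim$ratings$rating <= 7))
})

test_that("variance of group means matches s + (v_i + v_e)/m on the raw scale", {
  sim <- simulate_ratings(rater_sim_config(n_images = 1500, n_raters = 30,
                                           var_idio = 2, var_noise = 2,
                                           discretize = FALSE, seed = 6))
  ga <- group_average(sim$ratings)
  raw_var <- var(ga$mean) / sim$truth$scale_map$slope^2
  expect_equal(raw_var, 1 + 4 / 30, tolerance = 0.12)
})

test_that("analytic expected_rsplit matches the variance-components formula", {
  sim <- quick_sim(n_images = 50, n_raters = 40, seed = 1,
                   var_idio = 2, var_noise = 2)
  expect_equal(sim$truth$expected_rsplit, 1 / (1 + 4 / 40))
})

test_that("discretization to the 0-7 scale never increases reliability", {
  for (seed in 1:3) {
    cfg_c <- rater_sim_config(n_images = 300, n_raters = 20, discretize = FALSE,
                              seed = seed)
    cfg_d <- rater_sim_config(n_images = 300, n_raters = 20, discretize = TRUE,
                              seed = seed)
    sh_c <- split_half(simulate_ratings(cfg_c)$ratings, n_splits = 200, seed = 9)
    sh_d <- split_half(simulate_ratings(cfg_d)$ratings, n_splits = 200, seed = 9)
    expect_lte(sh_d$mean, sh_c$mean + 0.005)
  }
})

test_that("feature config invariants are enforced", {
  expect_error(feature_sim_config(dims_per_layer = 8, n_signal_dims = 16),
               "D >= k")
  expect_error(feature_sim_config(decodable_fraction = 1.5), "decodable")
  expect_error(feature_sim_config(depth_profile = function(d) 1 - d),
               "nondecreasing")
})

test_that("a perfect-signal bank decodes the deepest layer to r near 1", {
  sim <- simulate_ratings(rater_sim_config(n_images = 300, n_raters = 10,
                                           var_idio = 0, var_noise = 0,
                                           discretize = FALSE, seed = 3))
  fc <- feature_sim_config(n_layers = 2, dims_per_layer = c(32, 64),
                           decodable_fraction = 1, noise_scale = 0, seed = 5)
  bank <- simulate_feature_bank(fc, sim$truth)
  dec <- decode_bank(bank, group_average(sim$ratings))
  expect_gt(dec$layers[["layer_02"]]$r, 0.999)
})

test_that("signal-free banks decode near zero", {
  sim <- quick_sim(n_images = 400, n_raters = 20, seed = 8)
  fc <- feature_sim_config(n_layers = 3, dims_per_layer = c(32, 64, 128),
                           depth_profile = "zero", seed = 7)
  bank <- simulate_feature_bank(fc, sim$truth)
  dec <- decode_bank(bank, group_average(sim$ratings))
  expect_true(all(abs(vapply(dec$layers, function(l) l$r, numeric(1))) < 0.15))
})

test_that("paired banks share shapes and depths; untrained gains are zero", {
  sim <- quick_sim(n_images = 60, n_raters = 8, seed = 10)
  fc <- feature_sim_config(n_layers = 3, dims_per_layer = c(16, 24, 32),
                           seed = 11)
  pair <- make_paired_banks(fc, sim$truth)
  expect_identical(lapply(pair$trained$layers, dim),
                   lapply(pair$untrained$layers, dim))
  expect_identical(pair$trained$depths, pair$untrained$depths)
  expect_true(all(pair$untrained$design$gains == 0))
  expect_true(any(pair$trained$design$gains > 0))
})

test_that("two-dataset generator respects the category overlap flag", {
  rc <- rater_sim_config(n_images = 60, n_raters = 10, seed = 12)
  fc <- feature_sim_config(n_layers = 1, dims_per_layer = 128, seed = 13)
  two <- simulate_two_datasets(rc, rc, feature_config = fc,
                               shared_category_overlap = TRUE, seed = 14)
  expect_identical(two$shared, "landscape")
  expect_setequal(unique(two$a$categories), c("landscape", "object"))
  expect_setequal(unique(two$b$categories), c("landscape", "art"))
  expect_equal(dim(two$a$bank$layers[[1]]), c(60L, 128L))
  expect_error(
    simulate_two_datasets(rc, rc, feature_config = fc,
                          shared_category_overlap = FALSE,
                          categories_a = "x", categories_b = "x"),
    "disjoint")
})

test_that("all randomness flows from the seed: identical seeds reproduce", {
  a <- quick_sim(n_images = 50, n_raters = 6, seed = 123)
  b <- quick_sim(n_images = 50, n_raters = 6, seed = 123)
  expect_identical(a$ratings, b$ratings)
  fc <- feature_sim_config(n_layers = 2, dims_per_layer = c(8, 16),
                           n_signal_dims = 4, seed = 99)
  expect_identical(simulate_feature_bank(fc, a$truth)$layers,
                   simulate_feature_bank(fc, b$truth)$layers)
})
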