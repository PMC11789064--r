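test_that("pearson accuracy matches manual arithmetic and handles degeneracy", {
  y <- c(1, 2, 3, 4, 5)
  yhat <- c(2, 1, 4, 3, 5)
  # by hand: centered cross-product 8, both SS = 10 -> r = 8/10
  expect_equal(pearson_accuracy(y, yhat), 0.8, tolerance = 1e-12)
  expect_equal(pearson_accuracy(y, y), 1)
  expect_equal(pearson_accuracy(y, -y), -1)
  r0 <- pearson_accuracy(y, rep(2, 5))
  expect_true(is.na(r0))
  expect_match(attr(r0, "flagged"), "constant")
})

test_that("eve evaluates, keeps its fixed points, and is never clipped", {
  expect_equal(as.numeric(eve(0.8, 0.9)), 0.64 / 0.81, tolerance = 1e-12)
  expect_equal(as.numeric(eve(0.7, 0.7)), 1)
  expect_equal(as.numeric(eve(0, 0.9)), 0)
  expect_gt(as.numeric(eve(0.95, 0.9)), 1) # above the ceiling, reported as-is
  expect_error(eve(0.5, 0), "r_split")
  expect_equal(attr(eve(-0.4, 0.9), "sign_r"), -1)
})

test_that("eve is invariant to common affine rescaling of the ratings", {
  set.seed(1)
  y <- rnorm(50)
  yhat <- y + rnorm(50)
  base <- as.numeric(eve(pearson_accuracy(y, yhat), 0.9))
  scaled <- as.numeric(eve(pearson_accuracy(3 * y + 2, 3 * yhat + 2), 0.9))
  expect_equal(base, scaled, tolerance = 1e-12)
})

test_that("relative depth hits the quoted endpoints and midpoint", {
  expect_equal(relative_depth(1, 5), 0)
  expect_equal(relative_depth(5, 5), 1)
  expect_equal(relative_depth(3, 5), 0.5)
  d1 <- relative_depth(1, 1)
  expect_equal(as.numeric(d1), 0)
  expect_match(attr(d1, "flagged"), "single-layer")
  expect_error(relative_depth(6, 5), "range")
})

test_that("best_layer picks the argmax and breaks exact ties shallow", {
  sc <- data.frame(model_id = "m", layer_id = c("a", "b", "c"),
                   depth = c(0, 0.5, 1), r = c(0.1, 0.2, 0.3),
                   eve = c(0.01, 0.04, 0.09))
  expect_equal(best_layer(sc)$layer_id, "c")
  expect_equal(best_layer(sc[1, ])$layer_id, "a")
  tie <- data.frame(model_id = "m", layer_id = c("x", "y"),
                    depth = c(0.3, 0.9), r = c(0.5, 0.5))
  expect_message(out <- best_layer(tie), "tie")
  expect_equal(out$depth, 0.3)
  expect_true(attr(out, "tie"))
})

test_that("depth regression recovers flat and identity profiles", {
  flat <- data.frame(model_id = "m", depth = seq(0, 1, 0.1), r = 0.4)
  expect_equal(depth_profile(flat)$mean_coefficient, 0, tolerance = 1e-12)
  ident <- data.frame(model_id = "m", depth = seq(0, 1, 0.1),
                      r = seq(0, 1, 0.1))
  da <- depth_profile(ident)
  expect_equal(da$mean_coefficient, 1, tolerance = 1e-12)
  expect_equal(nrow(da$bins), 10)
  expect_equal(sum(da$bins$n), 11)
})

test_that("representativeness counts strictly lower respondents and is monotone", {
  expect_equal(representativeness(0.7, c(0.2, 0.5, 0.8)), 2 / 3)
  expect_equal(representativeness(0.9, c(0.2, 0.5, 0.8)), 1)
  expect_equal(representativeness(0.1, c(0.2, 0.5, 0.8)), 0)
  mm <- runif(50)
  vals <- vapply(seq(0, 1, 0.05), representativeness, numeric(1),
                 mm1_values = mm)
  expect_false(is.unsorted(vals))
})

test_that("layer_scores carries depths and squares accuracies against the ceiling", {
  sim <- quick_sim(n_images = 60, n_raters = 8, seed = 21)
  fc <- feature_sim_config(n_layers = 3, dims_per_layer = c(8, 16, 24),
                           n_signal_dims = 4,
                           seed = 22)
  bank <- simulate_feature_bank(fc, sim$truth)
  dec <- decode_bank(bank, group_average(sim$ratings))
  sc <- layer_scores(dec, r_split = 0.9)
  expect_equal(sc$depth, c(0, 0.5, 1))
  expect_equal(sc$eve, sc$r^2 / 0.81, tolerance = 1e-12)
})

test_that("grouped scoring matches ungrouped for a single group and skips tiny ones", {
  sim <- quick_sim(n_images = 60, n_raters = 10, seed = 23)
  fc <- feature_sim_config(n_layers = 1, dims_per_layer = 16, seed = 24)
  bank <- simulate_feature_bank(fc, sim$truth)
  dec <- decode_bank(bank, group_average(sim$ratings))
  pred <- dec$layers[[1]]$predictions
  gs <- score_by_group(pred, sim$ratings, grouping = "image_category",
                       n_splits = 100, seed = 1)
  expect_equal(nrow(gs$scores), 1)
  expect_equal(gs$scores$r, dec$layers[[1]]$r, tolerance = 1e-12)
  # a 2-image group must be skipped, not scored
  tab2 <- sim$ratings
  tab2$image_category <- ifelse(tab2$image_id %in% c("img0001", "img0002"),
                                "tiny", "rest")
  expect_message(gs2 <- score_by_group(pred, tab2, n_splits = 50, seed = 1),
                 "tiny")
  expect_identical(gs2$skipped, "tiny")
  expect_equal(gs2$scores$group, "rest")
})

test_that("group ceilings come from the group's own rating rows", {
  # two categories with very different rater agreement
  quiet <- simulate_ratings(rater_sim_config(n_images = 40, n_raters = 16,
                                             var_idio = 0.1, var_noise = 0.1,
                                             discretize = FALSE, seed = 25))
  noisy <- simulate_ratings(rater_sim_config(n_images = 40, n_raters = 16,
                                             var_idio = 6, var_noise = 6,
                                             discretize = FALSE, seed = 26))
  nz <- noisy$ratings
  nz$image_id <- sub("img0", "img9", nz$image_id)
  nz$image_category <- "noisy"
  qt <- quiet$ratings
  qt$image_category <- "quiet"
  tab <- rbind(qt, nz)
  pred <- data.frame(image_id = unique(tab$image_id), y = 0, yhat = 0)
  ga <- group_average(tab)
  pred$y <- ga$mean[match(pred$image_id, ga$image_id)]
  pred$yhat <- pred$y + rnorm(nrow(pred), 0, 0.2)
  gs <- score_by_group(pred, tab, n_splits = 200, seed = 2)
  ceilings <- setNames(gs$scores$r_split, gs$scores$group)
  expect_gt(ceilings["quiet"], ceilings["noisy"])
})
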