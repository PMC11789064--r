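#' Configuration for a simulated rater pool
#'
#' Defines the generative model for a pool of respondents rating images on a
#' bounded scale. Each observed rating decomposes as
#' \deqn{rating_{ij} = t_j + u_{ij} + e_{ij}}
#' where `t_j ~ N(0, var_shared)` is the image-level affect latent shared by
#' all raters, `u_ij ~ N(0, var_idio)` is rater `i`'s stable idiosyncratic
#' preference for image `j` (drawn once per rater-image pair), and
#' `e_ij ~ N(0, var_noise)` is trial noise. Raw values are affinely mapped
#' into `[scale_min, scale_max]` and optionally rounded to integers, mirroring
#' a 0-7 rating task.
#'
#' @param n_images number of images.
#' @param n_raters number of respondents.
#' @param var_shared variance of the shared image latent (`s`).
#' @param var_idio variance of stable idiosyncratic preference (`v_i`); a
#'   scalar, or a vector of length `n_raters` to give raters heterogeneous
#'   "taste-typicality".
#' @param var_noise trial noise variance (`v_e`).
#' @param coverage fraction of images each rater rates, in (0, 1]. Every rater
#'   rates exactly `round(coverage * n_images)` images (a fixed per-rater
#'   count, emulating designs where each respondent views a fixed subset).
#' @param scale_min,scale_max rating scale bounds (default 0 and 7).
#' @param discretize round mapped ratings to integers on the scale. Recovery
#'   identities are exact only for continuous ratings, so this is a flag.
#' @param seed RNG seed for this generator.
#' @return an object of class `rater_sim_config`.
#' @export
rater_sim_config <- function(n_images = 900, n_raters = 40, var_shared = 1,
                             var_idio = 2, var_noise = 2, coverage = 1,
                             scale_min = 0, scale_max = 7, discretize = TRUE,
                             seed = 1) {
  .check(n_images >= 2, "n_images must be >= 2")
  .check(n_raters >= 2, "n_raters must be >= 2")
  .check(all(var_idio >= 0) && var_shared >= 0 && var_noise >= 0,
         "variances must be >= 0")
  .check(length(var_idio) == 1L || length(var_idio) == n_raters,
         "var_idio must be scalar or length n_raters")
  .check(coverage > 0 && coverage <= 1, "coverage must be in (0, 1]")
  .check(scale_min < scale_max, "scale_min must be < scale_max")
  structure(list(n_images = as.integer(n_images),
                 n_raters = as.integer(n_raters),
                 var_shared = var_shared, var_idio = var_idio,
                 var_noise = var_noise, coverage = coverage,
                 scale_min = scale_min, scale_max = scale_max,
                 discretize = isTRUE(discretize), seed = as.integer(seed)),
            class = "rater_sim_config")
}

#' Configuration for a simulated layerwise feature bank
#'
#' Defines a feature hierarchy in which linearly decodable affect signal
#' grows with layer depth. Layer `l` at relative depth `d_l` contains `k`
#' signal columns `alpha(d_l) * g * w_j + noise` (fixed-scale column noise,
#' so the per-column signal-to-noise ratio grows with the depth gain) padded
#' with pure-noise columns up to the layer width. The image-level signal
#' carrier `g` is a mixture of the standardized shared rating latent and an
#' independent nuisance component, mixed so that the best linear read-out of
#' the deepest layer attains a *designed explainable-variance-explained* of
#' `decodable_fraction` against the group-average ratings (see the methods
#' vignette for the calibration).
#'
#' @param n_layers number of layers.
#' @param dims_per_layer integer vector of layer widths `D_l` (recycled to
#'   `n_layers` if scalar).
#' @param n_signal_dims number `k` of signal-carrying dimensions per layer.
#' @param depth_profile monotone gain profile `alpha(d)` on relative depth
#'   `d` in `[0,1]`: one of `"quadratic"` (default, `d^2`), `"linear"`,
#'   `"zero"` (signal-free, the "untrained" analog), or a function.
#' @param decodable_fraction designed fraction `f` of explainable variance
#'   recoverable from the deepest layer, in `[0, 1]`.
#' @param noise_scale SD of the noise added to signal columns.
#' @param seed RNG seed.
#' @return an object of class `feature_sim_config`.
#' @export
feature_sim_config <- function(n_layers = 6,
                               dims_per_layer = c(32, 64, 128, 256, 512, 1024),
                               n_signal_dims = 16,
                               depth_profile = "quadratic",
                               decodable_fraction = 0.6,
                               noise_scale = 0.5, seed = 1) {
  .check(n_layers >= 1, "n_layers must be >= 1")
  dims <- as.integer(rep_len(dims_per_layer, n_layers))
  k <- as.integer(n_signal_dims)
  .check(k >= 1 && all(dims >= k), "every layer width must satisfy D >= k >= 1")
  .check(decodable_fraction >= 0 && decodable_fraction <= 1,
         "decodable_fraction must be in [0, 1]")
  .check(noise_scale >= 0, "noise_scale must be >= 0")
  alpha <- .resolve_depth_profile(depth_profile)
  dgrid <- seq(0, 1, length.out = 101)
  ag <- vapply(dgrid, alpha, numeric(1))
  .check(ag[1] >= 0 && !is.unsorted(ag),
         "depth_profile must be nondecreasing with alpha(0) >= 0")
  structure(list(n_layers = as.integer(n_layers), dims_per_layer = dims,
                 n_signal_dims = k, depth_profile = depth_profile,
                 alpha = alpha, decodable_fraction = decodable_fraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "feature_sim_config")
}

.resolve_depth_profile <- function(p) {
  if (is.function(p)) return(p)
  switch(match.arg(p, c("quadratic", "linear", "zero")),
         quadratic = function(d) d^2,
         linear = function(d) d,
         zero = function(d) 0 * d)
}

#' Simulate a rater pool with known variance components
#'
#' Draws ratings from the variance-components model of [rater_sim_config()],
#' maps them affinely onto the rating scale, and returns both the long-format
#' ratings table and a `sim_truth` object recording the generative ground
#' truth, including the analytic Spearman-Brown corrected split-half
#' reliability `s / (s + (v_i + v_e) / m)` for `m` raters per image.
#'
#' @param config a [rater_sim_config()].
#' @param affect affect label for the table (default `"beauty"`).
#' @param dataset_id dataset label.
#' @param image_category optional per-image category labels (length
#'   `n_images`); default a single `"all"` category.
#' @return a list with elements `ratings` (long data.frame with columns
#'   `respondent_id, image_id, rating, affect, image_category, dataset_id`)
#'   and `truth` (class `sim_truth`: `latent`, `m`, `expected_rsplit`,
#'   `scale_map` -- the affine offset/slope applied to the raw ratings --
#'   and `configs`, plus slots filled in by [simulate_feature_bank()]).
#' @export
#' @examples
#' sim <- simulate_ratings(rater_sim_config(n_images = 30, n_raters = 8,
#'                                          seed = 2))
#' head(sim$ratings)
#' sim$truth$expected_rsplit
simulate_ratings <- function(config, affect = "beauty", dataset_id = "sim",
                             image_category = NULL) {
  stopifnot(inherits(config, "rater_sim_config"))
  n <- config$n_images
  nr <- config$n_raters
  if (is.null(image_category)) image_category <- rep("all", n)
  .check(length(image_category) == n,
         "image_category must have one label per image")
  set.seed(config$seed)
  t_lat <- rnorm(n, 0, sqrt(config$var_shared))
  v_idio <- rep_len(config$var_idio, nr)
  n_view <- max(1L, as.integer(round(config$coverage * n)))
  M <- matrix(NA_real_, n, nr)
  for (r in seq_len(nr)) {
    rows <- if (n_view == n) seq_len(n) else sort(sample.int(n, n_view))
    M[rows, r] <- t_lat[rows] +
      rnorm(n_view, 0, sqrt(v_idio[r])) +
      rnorm(n_view, 0, sqrt(config$var_noise))
  }
  m_j <- rowSums(!is.na(M))
  if (any(m_j < 2L)) {
    bad <- which(m_j < 2L)[1L]
    .fail(sprintf(
      "coverage %.3f leaves image img%04d with %d rater(s); >= 2 required",
      config$coverage, bad, m_j[bad]))
  }
  # affine map of observed values onto the rating scale (correlation-invariant)
  obs <- M[!is.na(M)]
  lo <- min(obs); hi <- max(obs)
  if (hi > lo) {
    slope <- (config$scale_max - config$scale_min) / (hi - lo)
    offset <- config$scale_min - lo * slope
    M <- offset + M * slope
  } else {
    slope <- 0
    offset <- (config$scale_min + config$scale_max) / 2
    M[!is.na(M)] <- offset
  }
  if (config$discretize) M <- round(M)

  image_id <- sprintf("img%04d", seq_len(n))
  respondent_id <- sprintf("r%04d", seq_len(nr))
  idx <- which(!is.na(M), arr.ind = TRUE)
  ratings <- data.frame(
    respondent_id = respondent_id[idx[, 2]],
    image_id = image_id[idx[, 1]],
    rating = M[idx],
    affect = affect,
    image_category = image_category[idx[, 1]],
    dataset_id = dataset_id,
    stringsAsFactors = FALSE)
  ratings <- ratings[order(ratings$respondent_id, ratings$image_id), ]
  rownames(ratings) <- NULL

  m_bar <- mean(m_j)
  v_total <- mean(v_idio) + config$var_noise
  s <- config$var_shared
  truth <- structure(list(
    latent = setNames(t_lat, image_id),
    m = m_bar,
    expected_rsplit = if (s + v_total / m_bar > 0) s / (s + v_total / m_bar) else NA_real_,
    scale_map = list(offset = offset, slope = slope),
    weights = NULL,
    expected_max_r2 = NULL,
    configs = list(rater = config, feature = NULL)),
    class = "sim_truth")
  list(ratings = ratings, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  images: %d, mean raters/image: %.1f\n",
              length(x$latent), x$m))
  cat(sprintf("  expected split-half reliability (SB-corrected): %.4f\n",
              x$expected_rsplit))
  if (!is.null(x$expected_max_r2))
    cat(sprintf("  designed max decodable r^2: %.4f\n", x$expected_max_r2))
  invisible(x)
}

# Signal carrier g: mixture of the standardized shared latent and an
# independent nuisance, calibrated so the best linear read-out of the deepest
# layer attains EVE = f. Two analytic facts go into the mixture weight:
#   cor(g, Y)^2 = a^2 * r_SB           (Y = group mean; r_SB = s/(s + v/m))
#   cor(readout, g)^2 = k/(k + sigma^2) (k signal columns with ||w||^2 = k
#                                        and per-column noise SD sigma)
# so with a^2 = f * r_SB * (k + sigma^2)/k the recoverable r^2 against Y is
# f * r_SB^2, i.e. EVE = r^2 / r_split^2 = f by design.
.signal_carrier <- function(truth, f, k, noise_scale) {
  t_lat <- truth$latent
  n <- length(t_lat)
  tc <- t_lat - mean(t_lat)
  sdt <- sqrt(mean(tc^2))
  t_std <- if (sdt > 0) tc / sdt else rep(0, n) # degenerate latent: no signal
  r_sb <- truth$expected_rsplit
  attn <- k / (k + noise_scale^2)
  a2 <- f * r_sb / attn
  .check(is.finite(a2) && a2 <= 1,
         "decodable_fraction incompatible with the rating reliability and ",
         "feature noise (requires f * r_split / (k/(k + noise_scale^2)) <= 1)")
  g <- sqrt(a2) * t_std + sqrt(1 - a2) * rnorm(n)
  list(g = as.numeric(g), a2 = a2, r_sb = r_sb, attn = attn)
}

#' Simulate a layerwise feature bank tied to a rating simulation
#'
#' Builds an ordered set of layer matrices in which the decodable affect
#' signal grows with relative depth according to the configured gain profile.
#' The deepest layer is calibrated so that a perfect linear read-out attains
#' an explainable-variance-explained of `decodable_fraction` against the
#' group-average ratings implied by `truth`.
#'
#' @param config a [feature_sim_config()].
#' @param truth the `sim_truth` returned by [simulate_ratings()] (supplies the
#'   shared latent and the rating variance components).
#' @param model_id label for the bank.
#' @return a [feature_bank()] whose `design` element records the read-out
#'   weights, mixture weight, per-layer gains, and the designed ceilings
#'   (`expected_eve = f`, `expected_r2 = f * r_split^2`).
#' @export
simulate_feature_bank <- function(config, truth, model_id = "sim_model") {
  stopifnot(inherits(config, "feature_sim_config"),
            inherits(truth, "sim_truth"))
  n <- length(truth$latent)
  k <- config$n_signal_dims
  L <- config$n_layers
  set.seed(derive_seed(config$seed, model_id, "carrier"))
  sc <- .signal_carrier(truth, config$decodable_fraction, k,
                        config$noise_scale)
  w <- rnorm(k)
  w <- w * sqrt(k) / sqrt(sum(w^2)) # fix ||w||^2 = k: deterministic SNR
  depths <- if (L == 1L) 1 else (seq_len(L) - 1) / (L - 1)
  layers <- vector("list", L)
  names(layers) <- sprintf("layer_%02d", seq_len(L))
  for (l in seq_len(L)) {
    D <- config$dims_per_layer[l]
    set.seed(derive_seed(config$seed, model_id, names(layers)[l]))
    a_l <- config$alpha(depths[l])
    X <- matrix(rnorm(n * D), n, D)
    X[, seq_len(k)] <- a_l * tcrossprod(sc$g, w) +
      matrix(rnorm(n * k, 0, config$noise_scale), n, k)
    layers[[l]] <- X
  }
  bank <- feature_bank(model_id = model_id, layers = layers, depths = depths,
                       image_ids = names(truth$latent),
                       provenance = "synthetic")
  bank$design <- list(weights = w, mixture_a2 = sc$a2,
                      gains = vapply(depths, config$alpha, numeric(1)),
                      decodable_fraction = config$decodable_fraction,
                      expected_eve = config$decodable_fraction,
                      expected_r2 = config$decodable_fraction * sc$r_sb^2,
                      feature_config = config)
  bank
}

#' Generate a trained/untrained pair of feature banks
#'
#' The "untrained" bank has identical layer shapes and depths but a
#' signal-free gain profile, emulating a randomly initialized counterpart of
#' a trained network.
#'
#' @inheritParams simulate_feature_bank
#' @return list with elements `trained` and `untrained`.
#' @export
make_paired_banks <- function(config, truth, model_id = "sim_model") {
  stopifnot(inherits(config, "feature_sim_config"))
  cfg0 <- config
  cfg0$depth_profile <- "zero"
  cfg0$alpha <- .resolve_depth_profile("zero")
  cfg0$seed <- derive_seed(config$seed, "untrained")
  list(trained = simulate_feature_bank(config, truth, model_id = model_id),
       untrained = simulate_feature_bank(cfg0, truth,
                                         model_id = paste0(model_id, "_untrained")))
}

#' Simulate two image datasets with category-structured decodable signal
#'
#' Emulates the cross-decoding setting: two datasets of images, each split
#' into categories, each with its own rater pool, and a single (deepest)
#' feature space per dataset. Every distinct category name owns a private
#' block of feature dimensions and a private read-out weight vector; when a
#' category name is shared between the datasets it uses the *same* block and
#' weights in both, so decoders fit on one dataset transfer to the other for
#' that category and only that category.
#'
#' @param rater_config_a,rater_config_b [rater_sim_config()]s for the two
#'   rater pools (defaults: `rater_config_b = rater_config_a`).
#' @param feature_config a [feature_sim_config()]; its deepest width, signal
#'   dimensionality, noise scale and decodable fraction are used. The
#'   generated banks have a single layer at relative depth 1. The default
#'   width (1024) is deliberately large relative to the signal blocks: a
#'   finite-width decoder noise-fits a spurious alignment of order
#'   `sqrt(k / D)` onto unrelated signal blocks, and the no-transfer condition
#'   is only represented cleanly when that term is small.
#' @param shared_category_overlap if `TRUE` the first category name is shared
#'   between the datasets; if `FALSE` all categories are disjoint.
#' @param categories_a,categories_b category names for each dataset.
#' @param seed RNG seed for the cross-dataset weight draws.
#' @return list with elements `a` and `b`, each
#'   `list(ratings, bank, truth)`, plus `shared` (the shared category name or
#'   `NA`).
#' @export
simulate_two_datasets <- function(rater_config_a,
                                  rater_config_b = rater_config_a,
                                  feature_config = feature_sim_config(
                                    n_layers = 1, dims_per_layer = 1024),
                                  shared_category_overlap = TRUE,
                                  categories_a = c("landscape", "object"),
                                  categories_b = if (shared_category_overlap)
                                    c("landscape", "art") else c("portrait", "art"),
                                  seed = 1) {
  if (shared_category_overlap) {
    .check(length(intersect(categories_a, categories_b)) >= 1,
           "shared_category_overlap = TRUE requires a common category name")
  } else {
    .check(length(intersect(categories_a, categories_b)) == 0,
           "shared_category_overlap = FALSE requires disjoint category names")
  }
  k <- feature_config$n_signal_dims
  D <- feature_config$dims_per_layer[feature_config$n_layers]
  all_cats <- unique(c(categories_a, categories_b))
  .check(D >= k * length(all_cats),
         "deepest layer width too small for one signal block per category")
  set.seed(derive_seed(seed, "cross_weights"))
  w_by_cat <- lapply(seq_along(all_cats), function(i) {
    w <- rnorm(k)
    w * sqrt(k) / sqrt(sum(w^2))
  })
  names(w_by_cat) <- all_cats
  block_by_cat <- lapply(seq_along(all_cats),
                         function(i) ((i - 1) * k + 1):(i * k))
  names(block_by_cat) <- all_cats

  build <- function(cfg, cats, ds_id, stream) {
    n <- cfg$n_images
    cat_lab <- sort(rep_len(cats, n))
    sim <- simulate_ratings(cfg, dataset_id = ds_id, image_category = cat_lab)
    set.seed(derive_seed(seed, stream, "features"))
    sc <- .signal_carrier(sim$truth, feature_config$decodable_fraction, k,
                          feature_config$noise_scale)
    X <- matrix(rnorm(n * D), n, D)
    for (cc in cats) {
      rows <- which(cat_lab == cc)
      X[rows, block_by_cat[[cc]]] <-
        tcrossprod(sc$g[rows], w_by_cat[[cc]]) +
        matrix(rnorm(length(rows) * k, 0, feature_config$noise_scale),
               length(rows), k)
    }
    bank <- feature_bank(model_id = paste0("sim_", ds_id),
                         layers = list(layer_01 = X), depths = 1,
                         image_ids = names(sim$truth$latent),
                         provenance = "synthetic")
    list(ratings = sim$ratings, bank = bank, truth = sim$truth,
         categories = cat_lab)
  }
  a <- build(rater_config_a, categories_a, "set_a", "a")
  b <- build(rater_config_b, categories_b, "set_b", "b")
  shared <- intersect(categories_a, categories_b)
  list(a = a, b = b,
       shared = if (length(shared)) shared[1] else NA_character_)
}
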