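#' Pearson prediction accuracy
#'
#' The Pearson correlation across images between pooled out-of-fold
#' predictions and the observed group-average ratings. Constant inputs yield
#' `NA` with a `"flagged"` attribute rather than an error, so degenerate
#' layers are reported, not dropped.
#'
#' @param y observed ratings.
#' @param yhat predicted ratings.
#' @return correlation in `[-1, 1]`, or flagged `NA`.
#' @export
pearson_accuracy <- function(y, yhat) {
  .check(length(y) == length(yhat), "y and yhat must have equal length")
  .check(length(y) >= 3, "need at least 3 images to score")
  r <- .safe_cor(y, yhat)
  if (is.na(r)) attr(r, "flagged") <- "constant input"
  r
}

#' Explainable variance explained (noise-corrected accuracy)
#'
#' \deqn{r^2_{EVE} = r(y, \hat y)^2 / r_{split}^2}
#' the squared prediction accuracy divided by the squared Spearman-Brown
#' corrected split-half reliability: the fraction of non-noise variance a
#' model explains. Values are *not* clipped at 1 -- with a finite respondent
#' pool the estimate can legitimately exceed 1 -- and the sign of `r` is
#' carried as an attribute so squaring cannot hide an anticorrelated
#' predictor.
#'
#' @param r Pearson prediction accuracy.
#' @param r_split split-half reliability ceiling (nonzero).
#' @return `r^2 / r_split^2`, with attribute `"sign_r"`.
#' @export
#' @examples
#' eve(0.8, 0.9) # 0.64 / 0.81
eve <- function(r, r_split) {
  .check(is.numeric(r) && is.numeric(r_split), "inputs must be numeric")
  .check(all(r_split != 0), "r_split = 0: explainable variance undefined")
  out <- r^2 / r_split^2
  attr(out, "sign_r") <- sign(r)
  out
}

#' Relative depth of a layer
#'
#' `(index - 1) / (n_layers - 1)`: 0 for the first (shallowest) layer, 1 for
#' the last (deepest). A single-layer model gets depth 0 by convention, with
#' a `"flagged"` attribute.
#'
#' @param layer_index 1-based layer position.
#' @param n_layers total layer count.
#' @return depth in `[0, 1]`.
#' @export
relative_depth <- function(layer_index, n_layers) {
  .check(n_layers >= 1, "n_layers must be >= 1")
  .check(all(layer_index >= 1 & layer_index <= n_layers),
         "layer_index out of range")
  if (n_layers == 1L) {
    d <- rep(0, length(layer_index))
    attr(d, "flagged") <- "single-layer model: depth 0 by convention"
    return(d)
  }
  (layer_index - 1) / (n_layers - 1)
}

#' Per-layer score table for a decode result
#'
#' @param result a `decode_result` from [decode_bank()].
#' @param r_split split-half reliability used for the EVE denominator
#'   (typically `split_half(...)$mean` for the matching dataset/affect cell).
#' @return data.frame of class `layer_scores` with columns
#'   `model_id, layer_id, depth, r, eve, n_images`.
#' @export
layer_scores <- function(result, r_split) {
  stopifnot(inherits(result, "decode_result"))
  rs <- vapply(result$layers, function(l) l$r, numeric(1))
  out <- data.frame(
    model_id = result$model_id,
    layer_id = vapply(result$layers, function(l) l$layer_id, character(1)),
    depth = vapply(result$layers, function(l) l$depth, numeric(1)),
    r = rs,
    eve = as.numeric(eve(rs, r_split)),
    n_images = length(result$image_ids),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("layer_scores", "data.frame")
  out
}

#' Select the most predictive layer of a model
#'
#' Argmax of `r` over layers. Exact ties are broken toward the shallowest
#' layer and flagged.
#'
#' @param scores a `layer_scores` data.frame (or any data.frame with columns
#'   `layer_id, depth, r`, optionally `eve`).
#' @return one-row data.frame of class `model_score` with the winning layer;
#'   attribute `"tie"` is `TRUE` if a tie was broken.
#' @export
best_layer <- function(scores) {
  .check(nrow(scores) >= 1, "no layer scores supplied")
  r <- scores$r
  .check(!all(is.na(r)), "all layer accuracies are undefined")
  best <- max(r, na.rm = TRUE)
  hits <- which(!is.na(r) & r == best)
  pick <- hits[which.min(scores$depth[hits])] # shallowest on exact tie
  out <- scores[pick, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_score", "data.frame")
  attr(out, "tie") <- length(hits) > 1L
  if (length(hits) > 1L)
    message("best_layer: exact tie among ", length(hits),
            " layers; shallowest (depth ", out$depth, ") selected")
  out
}

#' Depth profile of predictive accuracy
#'
#' Bins layer accuracies into equal-width relative-depth bins for display,
#' and regresses accuracy on (unbinned) relative depth per model by ordinary
#' least squares. The headline number is the mean per-model depth
#' coefficient, with a bootstrap CI over models.
#'
#' @param scores a data.frame with columns `model_id, depth, r` (rows =
#'   layers, possibly of several models), e.g. stacked [layer_scores()].
#' @param n_bins number of depth bins on `[0, 1]` (default 10).
#' @param B bootstrap replicates for the CI of the mean coefficient.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `depth_analysis`: `bins` (data.frame `bin, depth_mid,
#'   mean_r, n`), `coefficients` (per model), `mean_coefficient`, `ci`.
#' @export
depth_profile <- function(scores, n_bins = 10, B = 1000, seed = 1) {
  .check(all(c("model_id", "depth", "r") %in% names(scores)),
         "scores needs columns model_id, depth, r")
  .check(length(unique(scores$depth)) >= 2, "need >= 2 distinct depths")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores$depth, edges, include.lowest = TRUE, labels = FALSE)
  bins <- data.frame(
    bin = seq_len(n_bins),
    depth_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    mean_r = vapply(seq_len(n_bins),
                    function(b) mean(scores$r[bin == b], na.rm = TRUE),
                    numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1)))
  coefs <- vapply(split(scores, scores$model_id), function(df) {
    if (length(unique(df$depth)) < 2) return(NA_real_)
    unname(coef(lm(r ~ depth, data = df))[2])
  }, numeric(1))
  ok <- coefs[!is.na(coefs)]
  set.seed(derive_seed(seed, "depth_profile"))
  boots <- if (length(ok) > 1)
    replicate(B, mean(sample(ok, length(ok), replace = TRUE)))
  else ok
  structure(list(bins = bins, coefficients = coefs,
                 mean_coefficient = mean(ok),
                 ci = .pctl_ci(boots)),
            class = "depth_analysis")
}

#' @export
print.depth_analysis <- function(x, ...) {
  cat(sprintf(
    "<depth_analysis> mean depth-on-accuracy coefficient %.4f [%.4f, %.4f] over %d model(s)\n",
    x$mean_coefficient, x$ci[1], x$ci[2], length(x$coefficients)))
  invisible(x)
}

#' Representativeness of a model relative to the respondent pool
#'
#' The proportion of respondents whose mean-minus-one correlation is strictly
#' below the model's mean predictive accuracy: how many individual humans the
#' model out-predicts as a stand-in for the group average. Monotone
#' nondecreasing in `model_mean_r`.
#'
#' @param model_mean_r mean predictive accuracy `r(y, yhat)` across models.
#' @param mm1_values per-respondent `r_MM1` values (NAs are ignored).
#' @return proportion in `[0, 1]`.
#' @export
representativeness <- function(model_mean_r, mm1_values) {
  vals <- mm1_values[!is.na(mm1_values)]
  .check(length(vals) >= 1, "mm1_values must be nonempty")
  mean(vals < model_mean_r)
}

#' Score predictions within image groups
#'
#' Recomputes accuracy and EVE within each level of a grouping column
#' (image category, affect, or dataset), using a group-specific split-half
#' ceiling computed from that group's own rating rows. Groups with fewer than
#' 3 images are skipped and listed in the `skipped` element.
#'
#' @param predictions data.frame with columns `image_id, y, yhat` (e.g. the
#'   `predictions` element of a decoded layer).
#' @param table the long ratings table the targets came from (supplies group
#'   labels and the rows for group ceilings).
#' @param grouping column of `table` to group by: `"image_category"`
#'   (default), `"affect"`, or `"dataset_id"`.
#' @param n_splits splits for the per-group ceilings.
#' @param seed RNG seed.
#' @param affect passed through to the reliability computations when `table`
#'   holds several affects.
#' @return list of class `group_scores`: `scores` (data.frame `group, n_images,
#'   r, r_split, eve`), `skipped` (character).
#' @export
score_by_group <- function(predictions, table,
                           grouping = c("image_category", "affect", "dataset_id"),
                           n_splits = 1000, seed = 1, affect = NULL) {
  grouping <- match.arg(grouping)
  .check(grouping %in% names(table), "table lacks column ", grouping)
  .check(all(c("image_id", "y", "yhat") %in% names(predictions)),
         "predictions needs columns image_id, y, yhat")
  lab <- table[[grouping]][match(predictions$image_id, table$image_id)]
  .check(!anyNA(lab), "some predicted images have no group label in the table")
  groups <- sort(unique(lab))
  rows <- list(); skipped <- character(0)
  for (g in groups) {
    in_g <- lab == g
    if (sum(in_g) < 3) {
      skipped <- c(skipped, g)
      next
    }
    sub_tab <- table[table[[grouping]] == g &
                       table$image_id %in% predictions$image_id[in_g], ,
                     drop = FALSE]
    sh <- split_half(sub_tab, n_splits = n_splits,
                     seed = derive_seed(seed, "group", g), affect = affect)
    r_g <- .safe_cor(predictions$y[in_g], predictions$yhat[in_g])
    rows[[g]] <- data.frame(group = g, n_images = sum(in_g), r = r_g,
                            r_split = sh$mean,
                            eve = as.numeric(eve(r_g, sh$mean)),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("score_by_group: skipped group(s) with < 3 images: ",
            paste(skipped, collapse = ", "))
  structure(list(scores = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 skipped = skipped, grouping = grouping),
            class = "group_scores")
}
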