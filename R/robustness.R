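#' Bootstrap decoding scores over the respondent pool
#'
#' Resamples the respondent pool `B` times ([bootstrap_group()]), recomputes
#' the group-average targets per replicate, and scores each model against
#' them. In `"refit"` mode (the default, matching the full procedure) the
#' decoding regressions are refit to every replicate's targets; `"rescore"`
#' mode keeps each model's out-of-fold predictions from the observed targets
#' fixed and only re-correlates them with the resampled targets -- a cheap
#' approximation for smoke tests. Per-replicate model ranks are tabulated and
#' all pairwise score differences are summarized with percentile CIs and
#' two-sided sign-fraction bootstrap p values, Holm-corrected over the family
#' of pairs.
#'
#' @param banks named list of [feature_bank()]s (one per model).
#' @param table long ratings table.
#' @param spec a [ridge_spec()].
#' @param proj a [projection_spec()].
#' @param B bootstrap replicates (>= 100 recommended for p values).
#' @param seed RNG seed.
#' @param affect affect label if `table` holds several.
#' @param mode `"refit"` or `"rescore"`.
#' @param metric `"r"` (best-layer accuracy per replicate) or `"eve"`
#'   (accuracy normalized by a split-half ceiling computed once on the
#'   observed pool).
#' @param n_splits splits for the ceiling when `metric = "eve"`.
#' @return list of class `bootstrap_result`: `scores` (B x models), `ranks`
#'   (models x rank positions, counts summing to B per position), `pairs`
#'   (data.frame with `model_a, model_b, mean_delta, ci_lo, ci_hi, p, p_holm`),
#'   `B`, `mode`, `seed`.
#' @export
bootstrap_scores <- function(banks, table, spec = ridge_spec(),
                             proj = projection_spec(), B = 1000, seed = 1,
                             affect = NULL, mode = c("refit", "rescore"),
                             metric = c("r", "eve"), n_splits = 1000) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  .check(is.list(banks) && length(banks) >= 1, "banks must be a nonempty list")
  if (is.null(names(banks)) || any(names(banks) == ""))
    names(banks) <- vapply(banks, function(b) b$model_id, character(1))
  .check(B >= 1, "B must be >= 1")
  if (B < 100) message("bootstrap_scores: B < 100; p values will be coarse")
  ga <- group_average(table, affect)
  boot <- bootstrap_group(table, B = B, seed = seed, affect = affect)
  ceiling2 <- if (metric == "eve")
    split_half(table, n_splits = n_splits, seed = seed, affect = affect)$mean
  else NA_real_

  # fixed-prediction pass (also supplies best layers for refit mode)
  base <- lapply(banks, function(bk) {
    dec <- decode_bank(bk, ga, spec, proj)
    sc <- layer_scores(dec, r_split = if (metric == "eve") ceiling2 else 1)
    bl <- best_layer(sc)
    list(dec = dec, best_id = bl$layer_id,
         yhat = dec$layers[[bl$layer_id]]$predictions$yhat)
  })

  models <- names(banks)
  scores <- matrix(NA_real_, B, length(models),
                   dimnames = list(NULL, models))
  for (b in seq_len(B)) {
    yb <- boot$means[b, ]
    yb <- yb[match(banks[[1]]$image_ids, boot$image_id)]
    for (m in models) {
      if (mode == "rescore") {
        r <- .safe_cor(yb, base[[m]]$yhat)
      } else {
        # refit the best layer's regression to the resampled targets
        bk <- banks[[m]]
        P <- project_features(bk$layers[[base[[m]]$best_id]], proj,
                              layer_id = base[[m]]$best_id,
                              model_id = bk$model_id)
        Ps <- standardize_columns(P)
        fit <- ridge_loo(Ps, as.numeric(standardize_target(yb)), spec$lambda)
        r <- .safe_cor(yb, fit$yhat)
      }
      scores[b, m] <- if (metric == "eve") as.numeric(eve(r, ceiling2)) else r
    }
  }

  # rank tabulation: rank 1 = best score in the replicate
  nm <- length(models)
  ranks <- matrix(0L, nm, nm, dimnames = list(models, paste0("rank_", seq_len(nm))))
  for (b in seq_len(B)) {
    rk <- rank(-scores[b, ], ties.method = "first")
    for (m in seq_len(nm)) ranks[m, rk[m]] <- ranks[m, rk[m]] + 1L
  }

  pairs <- NULL
  if (nm >= 2) {
    combs <- utils::combn(models, 2)
    pairs <- data.frame(model_a = combs[1, ], model_b = combs[2, ],
                        mean_delta = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(ncol(combs))) {
      d <- scores[, combs[1, i]] - scores[, combs[2, i]]
      ci <- .pctl_ci(d)
      # two-sided sign-fraction bootstrap p, capped at 1 (a degenerate
      # all-zero difference yields p = 1)
      p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
      pairs[i, c("mean_delta", "ci_lo", "ci_hi", "p")] <-
        c(mean(d), ci[1], ci[2], p)
    }
    pairs$p_holm <- p.adjust(pairs$p, method = "holm")
  }
  structure(list(scores = scores, ranks = ranks, pairs = pairs,
                 B = as.integer(B), mode = mode, metric = metric,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d, mode = %s, metric = %s\n",
              x$B, x$mode, x$metric))
  cat("  times ranked first:\n")
  for (m in rownames(x$ranks))
    cat(sprintf("    %-20s %d/%d\n", m, x$ranks[m, 1], x$B))
  invisible(x)
}

#' Paired t tests with Holm correction and Hedge's g
#'
#' One paired t test per cell of a comparison family (e.g. each combination
#' of image category, affect, and dataset), Holm step-down correction across
#' the family, and the paired-design Hedge's g: `mean(d)/sd(d)` times the
#' small-sample correction `1 - 3/(4 df - 1)`. Degenerate cells (zero-variance
#' differences) are flagged: an all-zero difference scores `g = 0, p = 1`;
#' a constant nonzero shift has undefined `g` (reported `NA`, never infinite).
#'
#' @param x,y paired score vectors (e.g. trained vs untrained model accuracy).
#' @param cell optional factor assigning each pair to a family cell; default
#'   one cell.
#' @return data.frame of class `comparison_result` with columns
#'   `cell, n, t, df, p, p_holm, hedges_g, flagged`.
#' @export
paired_ttest_holm <- function(x, y, cell = NULL) {
  .check(length(x) == length(y), "x and y must be paired (equal length)")
  if (is.null(cell)) cell <- rep("all", length(x))
  .check(length(cell) == length(x), "cell must match the pair count")
  out <- lapply(split(seq_along(x), cell), function(idx) {
    d <- x[idx] - y[idx]
    n <- length(d)
    .check(n >= 3, "fewer than 3 pairs in cell '", cell[idx[1]], "'")
    df <- n - 1
    corr <- 1 - 3 / (4 * df - 1)
    if (sd(d) == 0) {
      if (all(d == 0))
        data.frame(cell = as.character(cell[idx[1]]), n = n, t = 0, df = df,
                   p = 1, hedges_g = 0, flagged = TRUE)
      else
        data.frame(cell = as.character(cell[idx[1]]), n = n, t = NA_real_,
                   df = df, p = NA_real_, hedges_g = NA_real_, flagged = TRUE)
    } else {
      tt <- t.test(x[idx], y[idx], paired = TRUE)
      data.frame(cell = as.character(cell[idx[1]]), n = n,
                 t = unname(tt$statistic), df = df, p = tt$p.value,
                 hedges_g = mean(d) / sd(d) * corr, flagged = FALSE)
    }
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$p_holm <- p.adjust(res$p, method = "holm")
  res <- res[, c("cell", "n", "t", "df", "p", "p_holm", "hedges_g", "flagged")]
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Nonparametric two-sample comparison: exact p for small tie-free samples,
#' tie-corrected normal approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y score samples, each of size >= 2.
#' @return list of class `comparison_result_mw`: `W`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  .check(length(x) >= 2 && length(y) >= 2, "both samples need >= 2 values")
  wt <- suppressWarnings(wilcox.test(x, y))
  structure(list(W = unname(wt$statistic), p = wt$p.value,
                 method = wt$method),
            class = "comparison_result_mw")
}

#' Decode the ratings of individual respondents
#'
#' Refits the decoder to each respondent separately: feature rows are
#' restricted to exactly the images that respondent rated, features and the
#' respondent's own ratings are standardized, and the leave-one-out ridge is
#' fit. Reports the per-respondent accuracy and its Pearson correlation with
#' the respondents' mean-minus-one correlations (the "taste-typicality"
#' relationship: divergent respondents are harder to predict). Respondents
#' below the image floor are skipped and listed.
#'
#' @param features matrix of the chosen (typically most predictive) layer,
#'   images x dimensions, with image ids as rownames (or supplied via
#'   `image_ids`).
#' @param table long ratings table.
#' @param spec a [ridge_spec()].
#' @param proj a [projection_spec()]; wide layers are projected once, before
#'   the per-respondent row subsetting, so all respondents share a feature
#'   space.
#' @param min_images minimum rated-image count per respondent (default 20).
#' @param affect affect label if `table` holds several.
#' @param image_ids image ids for the feature rows if not in rownames.
#' @return list of class `individual_decode`: `per_respondent` (data.frame
#'   `respondent_id, n_images, r, r_mm1`), `cor_with_mm1`, `skipped`.
#' @export
decode_individual <- function(features, table, spec = ridge_spec(),
                              proj = projection_spec(), min_images = 20,
                              affect = NULL, image_ids = NULL) {
  features <- flatten_features(features)
  if (is.null(image_ids)) image_ids <- rownames(features)
  .check(!is.null(image_ids) && length(image_ids) == nrow(features),
         "feature rows need image ids (rownames or image_ids argument)")
  P_all <- project_features(features, proj, layer_id = "individual")
  M <- as_ratings_matrix(table, affect)
  row_of <- match(rownames(M), image_ids)
  .check(!anyNA(row_of), "rated image(s) missing from the feature matrix")
  mm <- mm1(table, affect, min_images = min(3, min_images))
  res <- list(); skipped <- character(0)
  for (r in seq_len(ncol(M))) {
    rid <- colnames(M)[r]
    rated <- which(!is.na(M[, r]))
    if (length(rated) < min_images) {
      skipped <- c(skipped, rid)
      next
    }
    own <- M[rated, r]
    if (sd(own) == 0) {
      res[[rid]] <- data.frame(respondent_id = rid, n_images = length(rated),
                               r = NA_real_, stringsAsFactors = FALSE)
      next
    }
    Ps <- standardize_columns(P_all[row_of[rated], , drop = FALSE])
    fit <- ridge_loo(Ps, as.numeric(standardize_target(own)), spec$lambda)
    res[[rid]] <- data.frame(respondent_id = rid, n_images = length(rated),
                             r = .safe_cor(own, fit$yhat),
                             stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("decode_individual: skipped ", length(skipped),
            " respondent(s) below the ", min_images, "-image floor")
  per <- if (length(res))
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  else
    data.frame(respondent_id = character(0), n_images = integer(0),
               r = numeric(0), stringsAsFactors = FALSE)
  per$r_mm1 <- mm$r_mm1[match(per$respondent_id, mm$respondent_id)]
  ok <- !is.na(per$r) & !is.na(per$r_mm1)
  structure(list(per_respondent = per,
                 cor_with_mm1 = if (sum(ok) >= 3)
                   .safe_cor(per$r_mm1[ok], per$r[ok]) else NA_real_,
                 skipped = skipped),
            class = "individual_decode")
}

#' Cross-decoding between image subsets
#'
#' Fits a single ridge regression (no cross-validation) on the training rows
#' -- standardizing features and target with *training-set* parameters only --
#' and evaluates the Pearson accuracy on the held-out test rows. When the
#' train and test row sets are identical the within-set leave-one-out result
#' is returned instead (the matrix diagonal); any partial overlap is an error.
#'
#' @param features feature matrix covering all rows involved (e.g. the
#'   stacked most-predictive layers of two image sets).
#' @param y target vector aligned with `features` rows.
#' @param train_idx,test_idx integer row indices.
#' @param lambda ridge penalty.
#' @return list of class `cross_decode_cell`: `r`, `n_train`, `n_test`,
#'   `diagonal`.
#' @export
cross_decode <- function(features, y, train_idx, test_idx, lambda = 1e4) {
  features <- flatten_features(features)
  .check(length(y) == nrow(features), "y must match feature rows")
  train_idx <- as.integer(train_idx); test_idx <- as.integer(test_idx)
  if (setequal(train_idx, test_idx)) {
    Ps <- standardize_columns(features[train_idx, , drop = FALSE])
    ys <- standardize_target(y[train_idx])
    fit <- ridge_loo(Ps, as.numeric(ys), lambda)
    return(structure(list(r = .safe_cor(y[train_idx], fit$yhat),
                          yhat = fit$yhat, y_test = y[train_idx],
                          n_train = length(train_idx),
                          n_test = length(test_idx), diagonal = TRUE),
                     class = "cross_decode_cell"))
  }
  .check(length(intersect(train_idx, test_idx)) == 0,
         "off-diagonal train and test rows overlap")
  Ptr <- standardize_columns(features[train_idx, , drop = FALSE])
  ytr <- standardize_target(y[train_idx])
  beta <- .ridge_fit(Ptr, as.numeric(ytr), lambda)
  Pte <- apply_standardization(features[test_idx, , drop = FALSE], Ptr)
  yhat <- as.numeric(Pte %*% beta)
  structure(list(r = .safe_cor(y[test_idx], yhat),
                 yhat = yhat, y_test = y[test_idx],
                 n_train = length(train_idx), n_test = length(test_idx),
                 diagonal = FALSE),
            class = "cross_decode_cell")
}

#' Full cross-decoding matrix over named subsets
#'
#' Every ordered (train, test) pair of subsets gets a cross-decoding accuracy;
#' the diagonal holds the within-subset leave-one-out accuracy. Optional
#' percentile CIs by resampling test images with replacement.
#'
#' @param sets named list; each element is `list(features = matrix,
#'   y = numeric)` for one subset (e.g. one image category of one dataset).
#' @param lambda ridge penalty.
#' @param B bootstrap replicates for cell CIs (0 = none).
#' @param seed RNG seed for the CIs.
#' @return list of class `cross_decode_matrix`: `r` (train x test matrix),
#'   `ci_lo`, `ci_hi` (or NULL), `n` (subset sizes).
#' @export
cross_decode_matrix <- function(sets, lambda = 1e4, B = 0, seed = 1) {
  .check(is.list(sets) && length(sets) >= 2 && !is.null(names(sets)),
         "sets must be a named list of >= 2 subsets")
  D <- unique(vapply(sets, function(s) ncol(flatten_features(s$features)),
                     integer(1)))
  .check(length(D) == 1, "all subsets must share the feature dimension")
  feats <- do.call(rbind, lapply(sets, function(s) flatten_features(s$features)))
  y <- unlist(lapply(sets, function(s) s$y), use.names = FALSE)
  sizes <- vapply(sets, function(s) length(s$y), integer(1))
  offs <- cumsum(c(0, sizes[-length(sizes)]))
  idx_of <- lapply(seq_along(sets), function(i) offs[i] + seq_len(sizes[i]))
  names(idx_of) <- names(sets)
  nm <- names(sets)
  r <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  ci_lo <- ci_hi <- if (B > 0) r else NULL
  for (a in nm) for (b in nm) {
    cell <- cross_decode(feats, y, idx_of[[a]], idx_of[[b]], lambda)
    r[a, b] <- cell$r
    if (B > 0) {
      # percentile CI by resampling (prediction, target) image pairs
      set.seed(derive_seed(seed, "crosscell", a, b))
      nt <- length(cell$y_test)
      boots <- replicate(B, {
        s <- sample.int(nt, nt, replace = TRUE)
        .safe_cor(cell$y_test[s], cell$yhat[s])
      })
      ci <- .pctl_ci(boots)
      ci_lo[a, b] <- ci[1]; ci_hi[a, b] <- ci[2]
    }
  }
  structure(list(r = r, ci_lo = ci_lo, ci_hi = ci_hi, n = sizes,
                 lambda = lambda),
            class = "cross_decode_matrix")
}

#' @export
print.cross_decode_matrix <- function(x, ...) {
  cat("<cross_decode_matrix> rows = train set, cols = test set\n")
  print(round(x$r, 3))
  invisible(x)
}
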