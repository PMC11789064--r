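# Independent oracles and small fixture builders. These deliberately avoid
# the package's own computational shortcuts: the ridge oracle refits every
# fold explicitly, Holm is stepped by hand, and Mann-Whitney is enumerated.

# explicit per-fold ridge refit (no hat-matrix identity)
naive_ridge_loo <- function(P, y, lambda) {
  n <- nrow(P)
  vapply(seq_len(n), function(i) {
    Pt <- P[-i, , drop = FALSE]
    G <- crossprod(Pt) + diag(lambda, ncol(P))
    beta <- solve(G, crossprod(Pt, y[-i]))
    as.numeric(P[i, , drop = FALSE] %*% beta)
  }, numeric(1))
}

# Holm step-down applied by hand: sort ascending, multiply by (m - i + 1),
# enforce monotonicity, cap at 1
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney U (reported as W by wilcox.test for the first sample) and its
# exact two-sided p by enumerating all assignments of the pooled values
mw_enumeration <- function(x, y) {
  m <- length(x); n <- length(y)
  U_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  U_obs <- U_of(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(m + n, m)
  U_null <- apply(combs, 2, function(ix) U_of(pooled[ix], pooled[-ix]))
  tail_p <- if (U_obs > m * n / 2) mean(U_null >= U_obs) else mean(U_null <= U_obs)
  list(W = U_obs, p = min(1, 2 * tail_p))
}

# long ratings table from an images x raters matrix (NA = unrated)
table_from_matrix <- function(M, affect = "beauty", dataset_id = "toy",
                              image_category = NULL) {
  n <- nrow(M)
  if (is.null(image_category)) image_category <- rep("all", n)
  img <- sprintf("img%04d", seq_len(n))
  rsp <- sprintf("r%04d", seq_len(ncol(M)))
  idx <- which(!is.na(M), arr.ind = TRUE)
  data.frame(respondent_id = rsp[idx[, 2]], image_id = img[idx[, 1]],
             rating = M[idx], affect = affect,
             image_category = image_category[idx[, 1]],
             dataset_id = dataset_id, stringsAsFactors = FALSE)
}

# small ratings simulation used by several tests
quick_sim <- function(n_images = 200, n_raters = 20, seed = 1, ...) {
  simulate_ratings(rater_sim_config(n_images = n_images, n_raters = n_raters,
                                    discretize = FALSE, seed = seed, ...))
}
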