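#' Validate a long-format ratings table and pivot it to images x respondents
#'
#' @param table data.frame with columns `respondent_id, image_id, rating`,
#'   and optionally `affect, image_category, dataset_id`.
#' @param affect if the table contains several affect labels, the one to
#'   select; must be unambiguous.
#' @return numeric matrix, rows = images (sorted by `image_id`), columns =
#'   respondents (sorted), `NA` where unrated. Row/column names carry the ids.
#' @export
as_ratings_matrix <- function(table, affect = NULL) {
  need <- c("respondent_id", "image_id", "rating")
  .check(all(need %in% names(table)),
         "ratings table must have columns respondent_id, image_id, rating")
  if ("affect" %in% names(table)) {
    labs <- unique(table$affect)
    if (is.null(affect)) {
      .check(length(labs) == 1L,
             "table contains several affect labels (", paste(labs, collapse = ", "),
             "); pass `affect =` to select one")
      affect <- labs
    }
    table <- table[table$affect == affect, , drop = FALSE]
    .check(nrow(table) > 0, "no rows for affect '", affect, "'")
  }
  key <- paste(table$respondent_id, table$image_id)
  .check(!anyDuplicated(key),
         "duplicate (respondent, image) rating for key: ",
         key[which(duplicated(key))[1]])
  imgs <- sort(unique(table$image_id))
  resp <- sort(unique(table$respondent_id))
  M <- matrix(NA_real_, length(imgs), length(resp),
              dimnames = list(imgs, resp))
  M[cbind(match(table$image_id, imgs), match(table$respondent_id, resp))] <-
    table$rating
  M
}

#' Per-image group-average ratings
#'
#' Arithmetic mean over all respondents who rated each image -- the decoding
#' target. Errors if any image has fewer than 2 raters.
#'
#' @inheritParams as_ratings_matrix
#' @return data.frame of class `group_ratings` with columns
#'   `image_id, mean, n_raters`, ordered by image id.
#' @export
#' @examples
#' tab <- data.frame(respondent_id = c("a", "b", "a", "b"),
#'                   image_id = c("i1", "i1", "i2", "i2"),
#'                   rating = c(2, 4, 1, 3))
#' group_average(tab)
group_average <- function(table, affect = NULL) {
  M <- as_ratings_matrix(table, affect)
  m_j <- rowSums(!is.na(M))
  if (any(m_j < 2L)) {
    bad <- rownames(M)[which(m_j < 2L)[1]]
    .fail("image '", bad, "' has fewer than 2 raters")
  }
  out <- data.frame(image_id = rownames(M),
                    mean = rowMeans(M, na.rm = TRUE),
                    n_raters = as.integer(m_j),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("group_ratings", "data.frame")
  out
}

#' Mean-minus-one correlations (the ceiling of shared taste)
#'
#' For each respondent, the Pearson correlation -- over exactly the images
#' that respondent rated -- between their ratings and the group-average rating
#' computed with that respondent excluded. Respondents whose ratings (or whose
#' leave-one-out group means) have zero variance get `NA` with `flagged =
#' TRUE`; they are reported, never silently dropped.
#'
#' @inheritParams as_ratings_matrix
#' @param min_images minimum number of rated images per respondent (default 3).
#' @return data.frame with columns `respondent_id, n_images, r_mm1, flagged`.
#' @export
mm1 <- function(table, affect = NULL, min_images = 3) {
  M <- as_ratings_matrix(table, affect)
  m_j <- rowSums(!is.na(M))
  .check(all(m_j >= 2), "every image needs >= 2 raters for leave-one-out means")
  sums <- rowSums(M, na.rm = TRUE)
  res <- data.frame(respondent_id = colnames(M),
                    n_images = NA_integer_, r_mm1 = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(M))) {
    rated <- which(!is.na(M[, r]))
    .check(length(rated) >= min_images,
           "respondent '", colnames(M)[r], "' rated fewer than ",
           min_images, " images")
    own <- M[rated, r]
    loo <- (sums[rated] - own) / (m_j[rated] - 1)
    res$n_images[r] <- length(rated)
    rc <- .safe_cor(own, loo)
    res$r_mm1[r] <- rc
    res$flagged[r] <- is.na(rc)
  }
  res
}

#' Spearman-Brown prophecy correction
#'
#' Projects a half-sample reliability to the full sample: `2 r / (1 + r)`.
#' Monotone increasing on (-1, 1], with fixed points 0 and 1. Undefined at
#' `r = -1`.
#'
#' @param r_half numeric vector of half-sample correlations, each > -1.
#' @return corrected correlations.
#' @export
#' @examples
#' spearman_brown(0.5) # 2/3
spearman_brown <- function(r_half) {
  .check(is.numeric(r_half), "r_half must be numeric")
  .check(all(is.na(r_half) | r_half > -1),
         "Spearman-Brown correction undefined at r_half = -1")
  2 * r_half / (1 + r_half)
}

#' Split-half reliability of group-average ratings (the noise ceiling)
#'
#' Repeatedly partitions the respondent pool into two equal halves (with an
#' odd pool, one respondent is dropped at random per split), computes
#' per-image mean ratings within each half, correlates the two mean vectors
#' across images, and applies the Spearman-Brown correction. Images unrated
#' in either half of a given split are excluded from that split's correlation
#' and counted.
#'
#' @inheritParams as_ratings_matrix
#' @param n_splits number of random splits (default 10000).
#' @param seed RNG seed.
#' @return list of class `split_half`: `r_split` (corrected value per split),
#'   `mean`, `ci` (95% percentile interval over splits), `raw_mean`
#'   (uncorrected), `n_splits`, `seed`, `excluded_images` (count per split).
#' @export
split_half <- function(table, n_splits = 10000, seed = 1, affect = NULL) {
  .check(n_splits >= 1, "n_splits must be >= 1")
  M <- as_ratings_matrix(table, affect)
  nr <- ncol(M)
  .check(nr >= 2, "need at least 2 respondents to split")
  half <- nr %/% 2L
  set.seed(derive_seed(seed, "split_half"))
  r_corr <- numeric(n_splits)
  r_raw <- numeric(n_splits)
  excl <- integer(n_splits)
  for (s in seq_len(n_splits)) {
    perm <- sample.int(nr)
    h1 <- perm[seq_len(half)]
    h2 <- perm[(half + 1L):(2L * half)]
    m1 <- rowMeans(M[, h1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(M[, h2, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(m1) & is.finite(m2)
    excl[s] <- sum(!ok)
    r <- .safe_cor(m1[ok], m2[ok])
    r_raw[s] <- r
    r_corr[s] <- if (is.na(r) || r <= -1) NA_real_ else spearman_brown(r)
  }
  structure(list(r_split = r_corr, mean = mean(r_corr, na.rm = TRUE),
                 ci = .pctl_ci(r_corr), raw_mean = mean(r_raw, na.rm = TRUE),
                 n_splits = as.integer(n_splits), seed = as.integer(seed),
                 excluded_images = excl),
            class = "split_half")
}

#' @export
print.split_half <- function(x, ...) {
  cat(sprintf(
    "<split_half> mean corrected r_split = %.4f [%.4f, %.4f] over %d splits\n",
    x$mean, x$ci[1], x$ci[2], x$n_splits))
  if (any(x$excluded_images > 0))
    cat(sprintf("  images excluded (unrated in one half): mean %.2f per split\n",
                mean(x$excluded_images)))
  invisible(x)
}

#' Bootstrap the respondent pool and recompute group-average ratings
#'
#' Each replicate resamples respondents with replacement (keeping each
#' drawn respondent's full set of rating rows, with multiplicity) and
#' recomputes per-image means. Images left with no raters in a replicate
#' carry the original full-pool mean and are flagged.
#'
#' @inheritParams as_ratings_matrix
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param identity if `TRUE`, replicate 1 is forced to the identity resample
#'   (every respondent once) -- useful for testing.
#' @return list of class `bootstrap_group`: `means` (B x n_images matrix),
#'   `image_id`, `n_flagged` (per replicate count of images that carried the
#'   original mean), `B`, `seed`.
#' @export
bootstrap_group <- function(table, B = 1000, seed = 1, affect = NULL,
                            identity = FALSE) {
  .check(B >= 1, "B must be >= 1")
  M <- as_ratings_matrix(table, affect)
  nr <- ncol(M)
  full_mean <- rowMeans(M, na.rm = TRUE)
  rated <- !is.na(M)
  M0 <- M
  M0[!rated] <- 0
  set.seed(derive_seed(seed, "bootstrap_group"))
  means <- matrix(NA_real_, B, nrow(M),
                  dimnames = list(NULL, rownames(M)))
  n_flagged <- integer(B)
  for (b in seq_len(B)) {
    idx <- if (identity && b == 1L) seq_len(nr)
           else sample.int(nr, nr, replace = TRUE)
    w <- tabulate(idx, nbins = nr)
    tot <- as.numeric(M0 %*% w)
    cnt <- as.numeric(rated %*% w)
    mu <- tot / cnt
    empty <- cnt == 0
    mu[empty] <- full_mean[empty]
    n_flagged[b] <- sum(empty)
    means[b, ] <- mu
  }
  structure(list(means = means, image_id = rownames(M),
                 n_flagged = n_flagged, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "bootstrap_group")
}

#' Reliability report: both ceilings with bootstrap CIs
#'
#' Convenience wrapper bundling [mm1()] (with a respondent-pool bootstrap CI
#' of its mean) and [split_half()].
#'
#' @inheritParams split_half
#' @param B bootstrap replicates for the CI of mean `r_mm1`.
#' @return list of class `reliability_report`.
#' @export
reliability_report <- function(table, n_splits = 10000, B = 1000, seed = 1,
                               affect = NULL) {
  mm <- mm1(table, affect)
  sh <- split_half(table, n_splits = n_splits, seed = seed, affect = affect)
  vals <- mm$r_mm1[!is.na(mm$r_mm1)]
  set.seed(derive_seed(seed, "mm1_ci"))
  boots <- replicate(B, mean(sample(vals, length(vals), replace = TRUE)))
  structure(list(per_respondent = mm,
                 mm1_mean = mean(vals), mm1_ci = .pctl_ci(boots),
                 r_split_mean = sh$mean, r_split_ci = sh$ci,
                 split = sh, n_splits = sh$n_splits,
                 seed = as.integer(seed)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat(sprintf("  mean r_MM1  = %.4f [%.4f, %.4f] over %d respondents (%d flagged)\n",
              x$mm1_mean, x$mm1_ci[1], x$mm1_ci[2],
              nrow(x$per_respondent), sum(x$per_respondent$flagged)))
  cat(sprintf("  mean r_split = %.4f [%.4f, %.4f] over %d splits\n",
              x$r_split_mean, x$r_split_ci[1], x$r_split_ci[2], x$n_splits))
  invisible(x)
}
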