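#' Johnson-Lindenstrauss minimum embedding dimension
#'
#' The closed-form bound on the number of dimensions needed to preserve the
#' pairwise distances of `n` points within a distortion factor `epsilon`:
#' \deqn{p \ge \frac{4 \ln n}{\epsilon^2/2 - \epsilon^3/3}.}
#' For `n = 900` points at `epsilon = 0.1` the bound evaluates to about
#' 5830.6; with the default `floor` rounding this returns 5830.
#'
#' @param n number of points (images); `n >= 1`.
#' @param epsilon distortion factor, in (0, 1).
#' @param rounding `"floor"` (default) or `"ceil"`. Floor reproduces the
#'   conventional printed value for (900, 0.1); ceiling is exposed for
#'   conventions that round the bound up.
#' @return integer minimum dimension.
#' @export
#' @examples
#' jl_min_dim(900, 0.1) # 5830
jl_min_dim <- function(n, epsilon, rounding = c("floor", "ceil")) {
  rounding <- match.arg(rounding)
  .check(is.numeric(n) && length(n) == 1L && n >= 1, "n must be >= 1")
  .check(is.numeric(epsilon) && length(epsilon) == 1L &&
           epsilon > 0 && epsilon < 1, "epsilon must lie in (0, 1)")
  val <- 4 * log(n) / (epsilon^2 / 2 - epsilon^3 / 3)
  as.integer(if (rounding == "floor") floor(val) else ceiling(val))
}

#' Specification for sparse random projection
#'
#' @param epsilon distortion factor (default 0.1).
#' @param p target dimension; default 5830, the Johnson-Lindenstrauss minimum
#'   for 900 points at `epsilon = 0.1` (see [jl_min_dim()]).
#' @param apply_threshold layer width above which projection is applied;
#'   narrower layers pass through unchanged. Default equals `p`.
#' @param seed RNG seed; per-layer projection matrices are derived from it via
#'   [derive_seed()] so layers are independent yet reproducible.
#' @return object of class `projection_spec`.
#' @export
projection_spec <- function(epsilon = 0.1, p = 5830, apply_threshold = p,
                            seed = 1) {
  .check(epsilon > 0 && epsilon < 1, "epsilon must lie in (0, 1)")
  .check(p >= 1, "p must be >= 1")
  structure(list(epsilon = epsilon, p = as.integer(p),
                 apply_threshold = as.integer(apply_threshold),
                 seed = as.integer(seed)),
            class = "projection_spec")
}

#' Build a sparse random projection matrix
#'
#' Returns a `D x p` matrix `R` with i.i.d. entries
#' `+sqrt(sqrt(D)/p)` with probability `1/(2 sqrt(D))`,
#' `-sqrt(sqrt(D)/p)` with probability `1/(2 sqrt(D))`, and 0 otherwise
#' (density `1/sqrt(D)`). This scaling makes the projection norm-preserving
#' in expectation: `E||uR||^2 = ||u||^2` for any fixed vector `u`, since each
#' column contributes `E[(u . r)^2] = ||u||^2 / p`.
#'
#' @param D input dimension.
#' @param p output dimension.
#' @param seed RNG seed; the matrix is deterministic given the seed.
#' @return list of class `projection_matrix` with elements `R` (a
#'   `Matrix::sparseMatrix`), `density`, `magnitude`, `seed`.
#' @export
build_projection <- function(D, p, seed = 1) {
  .check(D >= 1 && p >= 1, "D and p must be >= 1")
  D <- as.integer(D); p <- as.integer(p)
  density <- 1 / sqrt(D)
  magnitude <- sqrt(sqrt(D) / p)
  total <- as.double(D) * as.double(p)
  .check(total <= .Machine$integer.max,
         "D * p exceeds the addressable size for a single projection matrix")
  set.seed(derive_seed(seed, "projection", D, p))
  n_nonzero <- rbinom(1L, as.integer(total), density)
  if (n_nonzero > 0) {
    pos <- sample.int(as.integer(total), n_nonzero) # uniform positions, i.i.d. conditional on count
    i <- ((pos - 1L) %% D) + 1L
    j <- ((pos - 1L) %/% D) + 1L
    x <- sample(c(-magnitude, magnitude), n_nonzero, replace = TRUE)
  } else {
    i <- integer(0); j <- integer(0); x <- numeric(0)
  }
  R <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(D, p))
  structure(list(R = R, D = D, p = p, density = density,
                 magnitude = magnitude, seed = as.integer(seed)),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf(
    "<projection_matrix> %d x %d, density 1/sqrt(D) = %.4g, entries +/- %.4g\n",
    x$D, x$p, x$density, x$magnitude))
  cat(sprintf("  nonzeros: %d (expected %.0f)\n",
              length(x$R@x), x$density * as.double(x$D) * x$p))
  invisible(x)
}

#' Project a feature matrix to the target dimension
#'
#' Computes `P = F R` with a sparse random projection when the feature width
#' exceeds `spec$apply_threshold`; otherwise returns `F` unchanged (identity
#' pass-through). The decision, the dimensions, and the layer-specific seed
#' are recorded in the `"projection"` attribute of the result.
#'
#' @param F numeric matrix, images x dimensions. All values must be finite.
#' @param spec a [projection_spec()].
#' @param layer_id optional label used in error messages and to derive the
#'   layer-specific projection seed.
#' @param model_id optional model label folded into the seed derivation.
#' @return numeric matrix, images x `min(D, p)` columns, with attribute
#'   `"projection"` describing what was done.
#' @export
project_features <- function(F, spec = projection_spec(), layer_id = NULL,
                             model_id = NULL) {
  stopifnot(inherits(spec, "projection_spec"))
  F <- flatten_features(F)
  if (!all(is.finite(F)))
    .fail("non-finite feature values in layer '",
          if (is.null(layer_id)) "<unnamed>" else layer_id, "'")
  D <- ncol(F)
  if (D <= spec$apply_threshold) {
    attr(F, "projection") <- list(applied = FALSE, D = D, p = D,
                                  reason = "width <= apply_threshold")
    return(F)
  }
  seed_l <- derive_seed(spec$seed,
                        if (is.null(model_id)) "" else model_id,
                        if (is.null(layer_id)) "" else layer_id)
  pm <- build_projection(D, spec$p, seed = seed_l)
  P <- as.matrix(F %*% pm$R)
  attr(P, "projection") <- list(applied = TRUE, D = D, p = spec$p,
                                density = pm$density, seed = seed_l)
  P
}
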