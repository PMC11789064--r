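#' Derive a reproducible child seed from a global seed and labels
#'
#' All randomness in the package flows from one integer seed; independent
#' random streams (per layer, per model, per stage) are derived by folding
#' string labels into the seed with a multiplicative congruential scheme.
#' The result always lies in `[0, 2^31 - 2]`, so it is a valid R seed.
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer seed, deterministic in `(seed, ...)`.
#' @export
#' @examples
#' derive_seed(1, "model_a", "layer_03")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.double(seed)) %% m
  labels <- vapply(list(...), function(x) paste(as.character(x), collapse = "/"),
                   character(1))
  bytes <- utf8ToInt(paste(labels, collapse = "\x1f"))
  for (b in bytes) h <- (h * 69069 + b) %% m # products stay < 2^53
  as.integer(h)
}

# internal: consistent stop() with a short context prefix
.fail <- function(...) stop(..., call. = FALSE)

# internal: check a single logical condition with message
.check <- function(cond, ...) if (!isTRUE(cond)) .fail(...)

# Pearson correlation that returns NA (instead of erroring/warning) when
# either vector is constant; callers decide how to flag it.
.safe_cor <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# percentile bootstrap CI bounds
.pctl_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}
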