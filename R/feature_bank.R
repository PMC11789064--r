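#' Construct a layerwise feature bank
#'
#' A feature bank is the ordered set of layer activation matrices one model
#' produces for a fixed set of images, with a relative-depth coordinate per
#' layer (0 = shallowest, 1 = deepest). Layers supplied as multi-axis arrays
#' (e.g. `n x h x w x c` convolutional maps) are flattened row-wise to
#' `n x D` on ingest, so each image is one feature vector per layer.
#'
#' @param model_id model label.
#' @param layers named list of numeric matrices/arrays, first axis = images.
#' @param depths numeric vector of relative depths in `[0, 1]`, one per layer,
#'   nondecreasing. Defaults to the [relative_depth()] convention.
#' @param image_ids character vector of image keys, length matching the row
#'   count of every layer.
#' @param provenance `"synthetic"` or `"external"`.
#' @return object of class `feature_bank`.
#' @export
feature_bank <- function(model_id, layers, depths = NULL, image_ids = NULL,
                         provenance = c("synthetic", "external")) {
  provenance <- match.arg(provenance)
  .check(is.list(layers) && length(layers) >= 1, "layers must be a nonempty list")
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    names(layers) <- sprintf("layer_%02d", seq_along(layers))
  layers <- lapply(layers, flatten_features)
  n <- nrow(layers[[1]])
  .check(all(vapply(layers, nrow, integer(1)) == n),
         "all layers must have the same number of images (rows)")
  if (is.null(depths)) {
    L <- length(layers)
    depths <- if (L == 1L) 0 else (seq_len(L) - 1) / (L - 1)
  }
  .check(length(depths) == length(layers), "one depth per layer required")
  .check(all(depths >= 0 & depths <= 1), "depths must lie in [0, 1]")
  .check(!is.unsorted(depths), "layer order must match depth order")
  if (is.null(image_ids)) image_ids <- sprintf("img%04d", seq_len(n))
  .check(length(image_ids) == n, "image_ids length must match layer rows")
  structure(list(model_id = model_id, layers = layers,
                 depths = as.numeric(depths),
                 image_ids = as.character(image_ids),
                 provenance = provenance, design = NULL),
            class = "feature_bank")
}

#' Flatten a multi-axis feature array to images x dimensions
#'
#' The first axis indexes images; remaining axes are unrolled in row-major
#' (C) order, so a `10 x 4 x 4 x 3` tensor becomes a `10 x 48` matrix.
#'
#' @param x a numeric matrix or array (first axis = images), or a vector
#'   (treated as a one-column matrix).
#' @return a numeric matrix.
#' @export
flatten_features <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.null(dim(x))) return(matrix(as.numeric(x), ncol = 1))
  d <- dim(x)
  # row-major unroll of trailing axes: permute so the image axis is last and
  # trailing axes are reversed, then refold column-major
  perm <- c(rev(seq_along(d)[-1]), 1L)
  matrix(as.numeric(aperm(x, perm)), nrow = d[1], byrow = TRUE)
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> model '%s' (%s): %d image(s), %d layer(s)\n",
              x$model_id, x$provenance, length(x$image_ids), length(x$layers)))
  widths <- vapply(x$layers, ncol, integer(1))
  for (i in seq_along(x$layers))
    cat(sprintf("  %-12s depth %.3f  width %6d\n",
                names(x$layers)[i], x$depths[i], widths[i]))
  invisible(x)
}
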