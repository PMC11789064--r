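#' Read and validate a long-format ratings CSV
#'
#' Expected header: `respondent_id, image_id, rating, affect,
#' image_category, dataset_id`. Malformed data are rejected, never coerced:
#' missing columns, out-of-range ratings (with row numbers), and duplicate
#' `(respondent, image, affect)` keys are all errors.
#'
#' @param path CSV file path.
#' @param scale_min,scale_max admissible rating range (default 0-7).
#' @return validated data.frame.
#' @export
read_ratings <- function(path, scale_min = 0, scale_max = 7) {
  .check(file.exists(path), "ratings file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "image_id", "rating", "affect",
            "image_category", "dataset_id")
  missing_cols <- setdiff(need, names(tab))
  .check(length(missing_cols) == 0,
         "ratings file lacks column(s): ", paste(missing_cols, collapse = ", "))
  .check(is.numeric(tab$rating), "rating column must be numeric")
  bad <- which(!is.finite(tab$rating) | tab$rating < scale_min |
                 tab$rating > scale_max)
  .check(length(bad) == 0,
         "rating out of [", scale_min, ", ", scale_max, "] at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  key <- paste(tab$respondent_id, tab$image_id, tab$affect, sep = "|")
  dup <- which(duplicated(key))
  .check(length(dup) == 0,
         "duplicate (respondent, image, affect) key: ", key[dup[1]],
         " at row ", dup[1])
  tab
}

#' Write a ratings table as CSV
#'
#' @param table ratings data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# full-precision numeric CSV for layer arrays: "%.17g" renders every double
# exactly, so write -> read round-trips are bitwise
.write_array_csv <- function(x, path) {
  txt <- apply(x, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

.read_array_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a feature bank to a directory (manifest + per-layer arrays)
#'
#' Layout: `manifest.json` describing the model, image ids, and one record
#' per layer (id, width, relative depth, array file, md5 checksum), plus one
#' full-precision CSV per layer. Image identity is carried by the manifest's
#' id list, ordered -- never by file order.
#'
#' @param bank a [feature_bank()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "feature_bank"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", names(bank$layers))
  for (l in seq_along(bank$layers))
    .write_array_csv(bank$layers[[l]], file.path(dir, files[l]))
  sums <- unname(tools::md5sum(file.path(dir, files)))
  manifest <- list(
    model_id = bank$model_id,
    provenance = bank$provenance,
    image_ids = bank$image_ids,
    layers = lapply(seq_along(bank$layers), function(l) list(
      layer_id = names(bank$layers)[l],
      width = ncol(bank$layers[[l]]),
      depth = bank$depths[l],
      file = files[l],
      md5 = sums[l])))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a feature bank from a directory
#'
#' Validates the manifest against the array files: missing files, checksum
#' mismatches, and shape mismatches are errors. Arrays are returned exactly
#' as written.
#'
#' @param dir directory written by [write_feature_bank()].
#' @return a [feature_bank()].
#' @export
read_feature_bank <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  .check(file.exists(mpath), "manifest.json not found in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  files <- vapply(man$layers, function(l) l$file, character(1))
  missing_f <- files[!file.exists(file.path(dir, files))]
  .check(length(missing_f) == 0,
         "manifest lists ", length(man$layers), " layer file(s); missing: ",
         paste(missing_f, collapse = ", "))
  layers <- list()
  for (l in man$layers) {
    fpath <- file.path(dir, l$file)
    got <- unname(tools::md5sum(fpath))
    .check(identical(got, l$md5),
           "checksum mismatch for ", l$file, " (expected ", l$md5, ")")
    X <- .read_array_csv(fpath)
    .check(nrow(X) == length(man$image_ids) && ncol(X) == l$width,
           "shape mismatch for ", l$file, ": manifest says ",
           length(man$image_ids), " x ", l$width, ", file is ",
           nrow(X), " x ", ncol(X))
    layers[[l$layer_id]] <- X
  }
  feature_bank(model_id = man$model_id, layers = layers,
               depths = vapply(man$layers, function(l) l$depth, numeric(1)),
               image_ids = unlist(man$image_ids),
               provenance = man$provenance)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list(latent = as.list(truth$latent), m = truth$m,
              expected_rsplit = truth$expected_rsplit,
              expected_max_r2 = truth$expected_max_r2,
              rater_config = unclass(truth$configs$rater))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a reliability report as JSON (plus a per-respondent CSV)
#'
#' @param report a `reliability_report`.
#' @param path JSON output path; the per-respondent table goes to the same
#'   name with suffix `_respondents.csv`.
#' @return `path`, invisibly.
#' @export
write_reliability <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  out <- list(mm1_mean = report$mm1_mean,
              mm1_ci = as.numeric(report$mm1_ci),
              r_split_mean = report$r_split_mean,
              r_split_ci = as.numeric(report$r_split_ci),
              n_splits = report$n_splits,
              n_respondents = nrow(report$per_respondent),
              n_flagged = sum(report$per_respondent$flagged),
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(report$per_respondent,
            sub("\\.json$", "_respondents.csv", path), row.names = FALSE)
  invisible(path)
}
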