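.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a feature-intensity table
#'
#' Reads a CSV/TSV (delimiter chosen by extension) with the sample id in the
#' first column and one column per RT_mz feature; feature names are preserved
#' verbatim. Set `features_in_rows = TRUE` for the transposed orientation
#' (first column = feature id, one column per sample).
#'
#' @param path CSV or TSV file.
#' @param features_in_rows transpose on read.
#' @return numeric matrix, samples in rows, sample ids as row names.
#' @export
read_feature_table <- function(path, features_in_rows = FALSE) {
  df <- .read_delim_auto(path)
  if (ncol(df) < 2 || nrow(df) == 0) stop("empty feature table: ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated ", if (features_in_rows) "feature" else "sample",
         " id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!apply(m, 2, function(v) all(!is.na(suppressWarnings(as.numeric(v)))))]
    stop("non-numeric intensities in column(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  rownames(m) <- ids
  if (features_in_rows) m <- t(m)
  m
}

#' Read a sample metadata table
#'
#' @param path CSV or TSV file with a `sample_id` column (or the sample id in
#'   the first column).
#' @return data.frame with a `sample_id` column.
#' @export
read_metadata <- function(path) {
  df <- .read_delim_auto(path)
  if (!"sample_id" %in% names(df)) names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  df
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the feature table and metadata as CSV (samples in rows, sample id
#' first) and the ground truth as JSON.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(dir, "features.csv")
  mpath <- file.path(dir, "metadata.csv")
  tpath <- file.path(dir, "truth.json")
  ft <- data.frame(sample_id = rownames(sim$features),
                   sim$features, check.names = FALSE)
  utils::write.csv(ft, fpath, row.names = FALSE)
  utils::write.csv(sim$metadata, mpath, row.names = FALSE)
  jsonlite::write_json(sim$truth, tpath, digits = NA, auto_unbox = TRUE)
  invisible(c(features = fpath, metadata = mpath, truth = tpath))
}
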