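#' Read a labeled expression matrix from delimited text
#'
#' Expects a rectangular table of samples x features with one label
#' column. Label values are mapped to `{0, 1}`; with two arbitrary label
#' values the lexicographically smaller one becomes 0 unless `positive`
#' names the value to map to 1. The mapping is reported via `message()`
#' and stored in the `label_mapping` attribute.
#'
#' @param path file path.
#' @param delimiter field delimiter (default `","`).
#' @param label_column name of the label column; default: the last
#'   column.
#' @param positive optional label value to map to class 1.
#' @return a tibble with numeric feature columns and an integer `label`
#'   column.
#' @export
read_labeled_matrix <- function(path, delimiter = ",", label_column = NULL,
                                positive = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(label_column)) label_column <- names(raw)[ncol(raw)]
  if (!label_column %in% names(raw)) {
    stop("label column '", label_column, "' not found", call. = FALSE)
  }
  feats <- raw[setdiff(names(raw), label_column)]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric feature cell at row ", bad, ", column '",
           names(feats)[j], "'", call. = FALSE)
    }
    if (anyNA(col)) {
      stop("missing value at row ", which(is.na(col))[1], ", column '",
           names(feats)[j], "'", call. = FALSE)
    }
  }
  lab <- raw[[label_column]]
  vals <- sort(unique(as.character(lab)))
  if (length(vals) > 2L) {
    stop("label column has ", length(vals), " distinct values; ",
         "binary labels required", call. = FALSE)
  }
  if (!is.null(positive)) {
    if (!as.character(positive) %in% vals) {
      stop("positive level '", positive, "' not present in labels", call. = FALSE)
    }
    vals <- c(setdiff(vals, as.character(positive)), as.character(positive))
  }
  y <- as.integer(match(as.character(lab), vals) - 1L)
  mapping <- stats::setNames(seq_along(vals) - 1L, vals)
  message("label mapping: ",
          paste(names(mapping), mapping, sep = " -> ", collapse = ", "),
          " (", nrow(raw), " samples x ", ncol(feats), " features)")
  out <- tibble::as_tibble(feats)
  out$label <- y
  attr(out, "label_mapping") <- mapping
  out
}

#' Write a labeled dataset to delimited text
#'
#' Features first, label column last; round-trips through
#' [read_labeled_matrix()].
#'
#' @param data data frame with a `label` column.
#' @param path file path.
#' @param delimiter field delimiter.
#' @return the path, invisibly.
#' @export
write_labeled_matrix <- function(data, path, delimiter = ",") {
  stopifnot("label" %in% names(data))
  data <- data[c(setdiff(names(data), "label"), "label")]
  utils::write.table(as.data.frame(data), path, sep = delimiter,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records seed, configuration and package version next to a result file
#' so that any output table can be regenerated exactly.
#'
#' @param path manifest path (JSON).
#' @param seed integer seed used for the run.
#' @param config named list of run parameters.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = list()) {
  obj <- list(
    seed = seed,
    config = config,
    package = "consvm",
    version = as.character(utils::packageVersion("consvm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}
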