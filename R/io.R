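# Delimited-table readers and model serialization. Tables are plain TSV/CSV:
# header row, first column sample ids, one row per sample.

#' @noRd
pick_delim <- function(path, delim = NULL) {
  delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a samples-by-features table
#'
#' Reads a delimited text table (TSV by default, CSV by `.csv` extension or
#' explicit `delim`) whose first column holds sample identifiers and whose
#' remaining columns are numeric features. Missing or non-numeric cells are
#' rejected with the offending sample and feature named.
#'
#' @param path File path.
#' @param delim Field delimiter; default inferred from the extension.
#' @return A tibble with a character `sample_id` column followed by numeric
#'   feature columns.
#' @export
read_feature_table <- function(path, delim = NULL) {
  raw <- readr::read_delim(path, delim = pick_delim(path, delim),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("'%s': expected a header row, a sample-id column and at least one feature", path))
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("'%s': duplicate sample ids: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble::tibble(sample_id = as.character(ids))
  for (col in names(raw)[-1]) {
    v <- raw[[col]]
    missing <- which(is.na(v) | v == "")
    if (length(missing) > 0) {
      abort(sprintf("'%s': missing value for sample '%s', feature '%s'",
                    path, ids[missing[1]], col))
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("'%s': non-numeric value '%s' for sample '%s', feature '%s'",
                    path, v[bad[1]], ids[bad[1]], col))
    }
    out[[col]] <- num
  }
  out
}

#' Read a sample-to-class label table
#'
#' Two-column delimited table: sample id, class label (two levels).
#'
#' @inheritParams read_feature_table
#' @return A tibble with columns `sample_id` and `class`.
#' @export
read_label_table <- function(path, delim = NULL) {
  raw <- readr::read_delim(path, delim = pick_delim(path, delim),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(raw) < 2 || nrow(raw) == 0) {
    abort(sprintf("'%s': expected two columns (sample id, class)", path))
  }
  out <- tibble::tibble(sample_id = as.character(raw[[1]]),
                        class = raw[[2]])
  if (anyDuplicated(out$sample_id)) {
    abort(sprintf("'%s': duplicate sample ids", path))
  }
  if (anyNA(out$class)) abort(sprintf("'%s': missing class labels", path))
  out
}

#' Read a samples-by-covariates table
#'
#' Same format and checks as [read_feature_table()]; binary covariates must be
#' 0/1 coded and categorical covariates pre-encoded as indicators.
#'
#' @inheritParams read_feature_table
#' @return A tibble with `sample_id` and numeric covariate columns.
#' @export
read_covariate_table <- function(path, delim = NULL) {
  read_feature_table(path, delim)
}

#' Align feature, label and covariate tables by sample id
#'
#' Inner-joins the tables on `sample_id` (so row order may differ between
#' files), reports how many samples were dropped from each table, and fails
#' on duplicate ids, an empty intersection, or column-name collisions.
#'
#' @param features Feature tibble (from [read_feature_table()]).
#' @param labels Label tibble (from [read_label_table()]).
#' @param covariates Optional covariate tibble.
#' @return A single aligned tibble: `sample_id`, `class`, covariate columns,
#'   feature columns.
#' @export
validate_alignment <- function(features, labels, covariates = NULL) {
  for (tb in list(features, labels, covariates)) {
    if (!is.null(tb) && anyDuplicated(tb$sample_id)) {
      abort("duplicate sample ids in an input table")
    }
  }
  clash <- intersect(setdiff(names(features), "sample_id"),
                     c("class", if (!is.null(covariates))
                       setdiff(names(covariates), "sample_id")))
  if (length(clash) > 0) {
    abort(paste0("column name collision between tables: ",
                 paste(clash, collapse = ", ")))
  }
  out <- dplyr::inner_join(labels, features, by = "sample_id")
  if (!is.null(covariates)) {
    out <- dplyr::inner_join(covariates, out, by = "sample_id") |>
      dplyr::relocate("sample_id", "class")
  }
  if (nrow(out) == 0) abort("no samples shared across the input tables")
  report_drop <- function(tb, what) {
    d <- sum(!tb$sample_id %in% out$sample_id)
    if (d > 0) inform(sprintf("dropped %d unmatched sample(s) from the %s table", d, what))
  }
  report_drop(features, "feature")
  report_drop(labels, "label")
  if (!is.null(covariates)) report_drop(covariates, "covariate")
  out
}

#' Save a fitted TSP or K-TSP model as JSON
#'
#' Models are keyed by feature name, never by column position, so prediction
#' tolerates reordered feature tables. The package version is embedded.
#'
#' @param model A `"tsp"` or `"ktsp"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsp_model <- function(model, path) {
  if (!inherits(model, c("tsp", "ktsp"))) abort("not a tsp/ktsp model")
  payload <- list(
    type = class(model)[1],
    package = "covtsp",
    version = as.character(packageVersion("covtsp")),
    levels = model$levels,
    class_counts = model$class_counts
  )
  if (inherits(model, "tsp")) {
    payload$pair <- as.list(model$pair)
    payload$orientation <- model$orientation
  } else {
    payload$pairs <- model$pairs
    payload$k_star <- model$k_star
    payload$tau <- model$tau
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a TSP or K-TSP model saved by [write_tsp_model()]
#'
#' @param path JSON file path.
#' @return A `"tsp"` or `"ktsp"` object usable with `predict()`.
#' @export
read_tsp_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$package, "covtsp")) {
    abort(sprintf("'%s' is not a covtsp model file", path))
  }
  if (payload$type == "tsp") {
    structure(
      list(pair = tibble::as_tibble(payload$pair),
           orientation = payload$orientation,
           levels = payload$levels,
           class_counts = payload$class_counts),
      class = "tsp"
    )
  } else {
    structure(
      list(pairs = tibble::as_tibble(payload$pairs),
           k_star = payload$k_star,
           tau = tibble::as_tibble(payload$tau),
           levels = payload$levels,
           class_counts = payload$class_counts),
      class = "ktsp"
    )
  }
}
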