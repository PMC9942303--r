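# Internal helpers shared across modules: resolving feature columns, sample ids
# and class labels from a samples-by-variables data frame.

#' @noRd
resolve_id_col <- function(data, id_col = "sample_id") {
  if (!is.null(id_col) && id_col %in% names(data)) id_col else NULL
}

#' @noRd
sample_ids <- function(data, id_col = "sample_id") {
  idc <- resolve_id_col(data, id_col)
  if (is.null(idc)) return(as.character(seq_len(nrow(data))))
  ids <- as.character(data[[idc]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample ids in column '%s': %s", idc,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ids
}

# Default feature set: every numeric column that is not the id column and not
# explicitly excluded (label / covariate columns).
#' @noRd
resolve_features <- function(data, features = NULL, exclude = character(),
                             id_col = "sample_id") {
  if (is.null(features)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(num, c(id_col, exclude))
  } else if (is.numeric(features)) {
    features <- names(data)[features]
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("feature column(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(features)) abort("duplicate feature names")
  features
}

# Numeric matrix of the selected feature columns, rownames = sample ids.
#' @noRd
feature_matrix <- function(data, features, id_col = "sample_id") {
  X <- as.matrix(as.data.frame(data)[, features, drop = FALSE])
  if (!is.numeric(X)) abort("feature columns must be numeric")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value in feature '%s' for sample '%s'",
                  features[bad[2]], sample_ids(data, id_col)[bad[1]]))
  }
  rownames(X) <- sample_ids(data, id_col)
  X
}

# `labels` may be the name of a column in `data` or a vector aligned with rows.
#' @noRd
resolve_labels <- function(data, labels) {
  if (is.character(labels) && length(labels) == 1 && labels %in% names(data)) {
    return(data[[labels]])
  }
  if (length(labels) != nrow(data)) {
    abort("`labels` must name a column of `data` or be a vector with one value per row")
  }
  labels
}

# Map an arbitrary two-level label vector onto classes 1 and 2.
# Factor levels (or sorted unique values) define the order: first level -> class 1.
#' @noRd
normalize_classes <- function(values) {
  if (anyNA(values)) abort("class labels contain missing values")
  lev <- if (is.factor(values)) {
    as.character(levels(droplevels(values)))
  } else {
    as.character(sort(unique(values)))
  }
  if (length(lev) != 2) {
    abort(sprintf("expected exactly 2 classes, found %d (%s)",
                  length(lev), paste(head(lev, 5), collapse = ", ")))
  }
  cls <- match(as.character(values), lev)
  list(cls = cls, levels = lev)
}

#' @noRd
check_both_classes <- function(cls) {
  if (!all(c(1L, 2L) %in% cls)) {
    abort("both classes must be present (degenerate labels)")
  }
}

# Within-sample ranks of feature values (ties -> average rank), one row per sample.
#' @noRd
profile_ranks <- function(X) {
  t(apply(X, 1L, rank, ties.method = "average"))
}
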