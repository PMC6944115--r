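# Internal validation and coercion helpers shared across modules.

# Coerce an expression input to a genes x samples numeric matrix.
# Accepts a numeric matrix with rownames, or a data frame whose first column
# holds gene identifiers and remaining columns hold per-sample values.
as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (!is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix.", arg))
    if (is.null(rownames(x))) abort(sprintf("`%s` must have gene identifiers as rownames.", arg))
    m <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(sprintf("`%s` must have a gene column plus at least one sample column.", arg))
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) abort(sprintf("`%s` has non-numeric expression values.", arg))
    rownames(m) <- genes
  } else {
    abort(sprintf("`%s` must be a matrix or data frame of expression values.", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` contains duplicate gene identifiers; collapse them first (see `collapse_genes()`).", arg))
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` must have unique sample identifiers as column names.", arg))
  }
  m
}

# Expression matrix back to a tibble with a `gene` first column.
expr_as_tibble <- function(m) {
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

# Validate a clinical/survival data frame and return a canonical tibble with
# columns sample_id, time, event.
as_survival_tbl <- function(data, sample_id = "sample_id", time = "time", event = "event") {
  if (!is.data.frame(data)) abort("`data` must be a data frame of survival records.")
  missing_cols <- setdiff(c(sample_id, time, event), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s) in survival data: %s.", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    sample_id = as.character(data[[sample_id]]),
    time = as.numeric(data[[time]]),
    event = as.numeric(data[[event]])
  )
  if (nrow(out) == 0) abort("Survival data has no records.")
  if (anyNA(out$time) || any(out$time <= 0)) abort("Survival times must be positive and non-missing.")
  if (!all(out$event %in% c(0, 1))) abort("Event status must be 0 (censored) or 1 (dead).")
  if (anyDuplicated(out$sample_id)) abort("Duplicate sample identifiers in survival data.")
  out
}

# Named hi/lo label vector from either a named character vector or a
# data frame with sample_id + label columns.
as_label_vector <- function(labels, label_col = "label", arg = "labels") {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", label_col) %in% names(labels))) {
      abort(sprintf("`%s` needs columns sample_id and %s.", arg, label_col))
    }
    v <- setNames(as.character(labels[[label_col]]), as.character(labels$sample_id))
  } else if (is.character(labels) && !is.null(names(labels))) {
    v <- labels
  } else {
    abort(sprintf("`%s` must be a data frame (sample_id, %s) or a named character vector.", arg, label_col))
  }
  bad <- setdiff(unique(v), c("hi", "lo"))
  if (length(bad) > 0) {
    abort(sprintf("`%s` must only contain \"hi\"/\"lo\" labels (found: %s).", arg, paste(bad, collapse = ", ")))
  }
  v
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
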