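#' Read and write gene-by-sample expression matrices
#'
#' Delimited text with gene identifiers in the first column and one column
#' per sample. The delimiter is inferred from the extension (`.csv` comma,
#' otherwise tab). Duplicate gene rows are rejected unless a collapse
#' mapping is supplied (see [collapse_genes()]); duplicate sample ids and
#' non-numeric cells are always rejected, with row/column context.
#'
#' @param path File path.
#' @param mapping Optional `row_id -> gene_id` mapping forwarded to
#'   [collapse_genes()] when rows are duplicated.
#' @return A genes x samples numeric matrix.
#' @export
read_expression <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  if (ncol(df) < 2) abort(sprintf("%s: need a gene column plus at least one sample column.", path))
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("%s: duplicate sample id `%s`.", path, samples[duplicated(samples)][1]))
  }
  vals <- df[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric expression column `%s`.", path, names(vals)[bad[1]]))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(as.matrix(vals)), arr.ind = TRUE)[1, ]
    abort(sprintf("%s: missing value at gene row %d, sample `%s`.",
                  path, idx[1], names(vals)[idx[2]]))
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    if (is.null(mapping)) {
      abort(sprintf("%s: duplicate gene id `%s`; supply a collapse mapping.",
                    path, genes[duplicated(genes)][1]))
    }
    m <- as.matrix(vals)
    rownames(m) <- make.unique(genes)
    map <- if (is.data.frame(mapping)) {
      setNames(as.character(mapping$gene_id), as.character(mapping$row_id))
    } else {
      mapping
    }
    return(collapse_genes(m, setNames(unname(map[genes]), rownames(m))))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' @rdname read_expression
#' @param x Matrix (genes x samples) to write.
#' @export
write_expression <- function(x, path) {
  m <- as_expr_matrix(x)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(expr_as_tibble(m), path, delim = delim)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Duplicate genes within a set are deduplicated with a
#' warning; malformed lines (fewer than 3 fields) and duplicate set names
#' are errors reported with their line number.
#'
#' @param path File path.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("%s: empty GMT file.", path))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("%s: malformed GMT line %d (need name, description, >=1 gene).", path, i))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) abort(sprintf("%s: duplicate set name `%s` at line %d.", path, nm, i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("%s: set `%s` lists duplicated gene(s); deduplicated.", path, nm))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors to write.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets))) abort("`sets` must be a named list.")
  desc <- descriptions %||% names(sets)
  lines <- purrr::map2_chr(names(sets), seq_along(sets), function(nm, i) {
    paste(c(nm, desc[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with at least `sample_id`, `time`, `event`; free covariate columns
#' are kept. Times must be positive (years), events 0/1, sample ids unique.
#'
#' @param path File path.
#' @return A tibble with validated survival columns.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  core <- as_survival_tbl(df)
  extra <- df[, setdiff(names(df), c("sample_id", "time", "event")), drop = FALSE]
  dplyr::bind_cols(core, extra)
}

#' Read a table of IHC pixel-bin counts
#'
#' CSV with columns `sample_id`, `marker`, `n0`, `n1`, `n2`, `n3`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_pixel_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "marker", "n0", "n1", "n2", "n3")
  if (!all(needed %in% names(df))) {
    abort(sprintf("%s: need columns %s.", path, paste(needed, collapse = ", ")))
  }
  check_pixel_counts(df$n0, df$n1, df$n2, df$n3)
  as_tibble(df)
}
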