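#' Immune/stromal infiltrate scores and tumour purity
#'
#' Scores each sample for an immune and a stromal gene program with
#' [sample_enrichment_scores()], sums them into a combined non-tumour score,
#' and maps the combined score onto a tumour purity in \[0, 1\] with a
#' strictly decreasing map. The default map is an affine rescaling
#' calibrated on the cohort's observed combined-score range (the most
#' infiltrated sample gets purity 0, the least purity 1); a custom
#' calibration can be plugged in via `purity_map`.
#'
#' @param x Expression matrix (genes x samples, log2) or gene-column data
#'   frame.
#' @param immune_set,stromal_set Character vectors of gene ids; each must
#'   share at least 2 genes with the matrix.
#' @param purity_map Optional function mapping the combined-score vector to
#'   purities in \[0, 1\] (must be decreasing in the score).
#' @return A tibble: `sample_id`, `immune_score`, `stromal_score`,
#'   `combined_score`, `purity`.
#' @export
infiltrate_scores <- function(x, immune_set, stromal_set, purity_map = NULL) {
  m <- as_expr_matrix(x)
  sets <- list(immune = unique(immune_set), stromal = unique(stromal_set))
  if (length(intersect(sets$immune, rownames(m))) < 2 ||
      length(intersect(sets$stromal, rownames(m))) < 2) {
    abort("Immune and stromal sets must each share at least 2 genes with the matrix.")
  }
  sc <- sample_enrichment_scores(m, sets)
  combined <- sc["immune", ] + sc["stromal", ]
  purity <- if (is.null(purity_map)) {
    rng <- range(combined)
    if (diff(rng) == 0) {
      warn("Combined infiltrate score constant across cohort; purity set to 0.5.")
      rep(0.5, length(combined))
    } else {
      (rng[2] - combined) / (rng[2] - rng[1])
    }
  } else {
    p <- purity_map(combined)
    if (any(p < -1e-9 | p > 1 + 1e-9)) abort("`purity_map` must return values in [0, 1].")
    pmin(pmax(p, 0), 1)
  }
  tibble(
    sample_id = colnames(m),
    immune_score = as.numeric(sc["immune", ]),
    stromal_score = as.numeric(sc["stromal", ]),
    combined_score = as.numeric(combined),
    purity = as.numeric(purity)
  )
}

#' Cell-type deconvolution by non-negative least squares
#'
#' Estimates the relative composition of each bulk sample over the columns
#' of a reference signature matrix (linear-scale mean expression profiles of
#' purified cell types). Log2 input is linearised by `2^x` before fitting;
#' each sample is regressed on the shared signature genes by non-negative
#' least squares and the coefficients are normalised to sum to one.
#' Normalisation makes the fractions invariant to any positive rescaling of
#' a sample. A sample whose coefficients are all zero gets uniform fractions
#' and a `degenerate` flag.
#'
#' @param x Expression matrix (genes x samples) or gene-column data frame.
#' @param reference Genes x cell-types numeric matrix (linear scale,
#'   non-negative, unique cell-type column names), or gene-column data frame.
#' @param log2_input Is `x` on the log2 scale (default `TRUE`)? If so it is
#'   linearised by `2^x` first.
#' @return A tibble of class `deconv_result`: `sample_id`, one fraction
#'   column per cell type (rows sum to 1), and `degenerate`.
#' @export
deconvolve <- function(x, reference, log2_input = TRUE) {
  m <- as_expr_matrix(x)
  ref <- as_expr_matrix(reference, "reference")
  if (any(ref < 0)) abort("Reference profiles must be non-negative (linear scale).")
  if (ncol(ref) < 2) abort("Reference needs at least 2 cell types.")
  shared <- intersect(rownames(ref), rownames(m))
  if (length(shared) < ncol(ref)) {
    abort(sprintf("Only %d reference gene(s) shared with the matrix; need at least %d (one per cell type).",
                  length(shared), ncol(ref)))
  }
  A <- ref[shared, , drop = FALSE]
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    dropped <- colnames(A)[qr_A$pivot[(qr_A$rank + 1):ncol(A)]]
    abort(sprintf("Reference is rank-deficient; collinear column(s): %s.",
                  paste(dropped, collapse = ", ")))
  }
  y_all <- if (log2_input) 2^m[shared, , drop = FALSE] else m[shared, , drop = FALSE]

  res <- purrr::map_dfr(seq_len(ncol(y_all)), function(j) {
    coef <- pracma::lsqnonneg(A, y_all[, j])$x
    degenerate <- sum(coef) <= 0
    frac <- if (degenerate) rep(1 / ncol(A), ncol(A)) else coef / sum(coef)
    out <- as_tibble(as.list(setNames(frac, colnames(A))))
    dplyr::bind_cols(tibble(sample_id = colnames(y_all)[j]), out,
                     tibble(degenerate = degenerate))
  })
  class(res) <- c("deconv_result", class(res))
  attr(res, "cell_types") <- colnames(A)
  attr(res, "n_shared_genes") <- length(shared)
  res
}

#' Correct relative cell fractions by tumour purity
#'
#' Converts the relative composition of the non-tumour compartment into
#' absolute fractions of the whole sample: each relative fraction is
#' multiplied by the non-tumour fraction `(1 - purity)`, so the absolute
#' fractions sum to `1 - purity` and, together with the tumour compartment,
#' account for the whole sample.
#'
#' @param fractions A `deconv_result` (or tibble with `sample_id` plus one
#'   column per cell type).
#' @param purity Data frame with `sample_id`, `purity` (e.g. from
#'   [infiltrate_scores()]), or a numeric vector named by sample, values in
#'   \[0, 1\].
#' @return A tibble like `fractions` with absolute fractions and an added
#'   `nontumor_fraction` column.
#' @export
purity_correct <- function(fractions, purity) {
  cell_types <- attr(fractions, "cell_types") %||%
    setdiff(names(fractions), c("sample_id", "degenerate"))
  if (is.data.frame(purity)) {
    if (!all(c("sample_id", "purity") %in% names(purity))) {
      abort("`purity` data frame needs columns sample_id and purity.")
    }
    pv <- setNames(purity$purity, purity$sample_id)
  } else if (is.numeric(purity) && !is.null(names(purity))) {
    pv <- purity
  } else {
    abort("`purity` must be a data frame (sample_id, purity) or a named numeric vector.")
  }
  if (!all(fractions$sample_id %in% names(pv))) abort("Missing purity for some samples.")
  pv <- unname(pv[fractions$sample_id])
  if (any(pv < 0 | pv > 1)) abort("Purity must lie in [0, 1].")
  out <- fractions
  for (ct in cell_types) out[[ct]] <- out[[ct]] * (1 - pv)
  out$nontumor_fraction <- 1 - pv
  out
}

#' Correlate cell-type fractions with a marker
#'
#' Per cell type, the correlation (Pearson or Spearman) between the
#' per-sample fraction and a continuous marker, with the two-sided P-value.
#'
#' @param fractions A `deconv_result` or tibble with `sample_id` plus
#'   cell-type columns.
#' @param marker Data frame with `sample_id` and a `value` column, or a
#'   numeric vector named by sample.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble: `cell_type`, `estimate`, `p_value`, `n`.
#' @export
marker_fraction_correlation <- function(fractions, marker,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cell_types <- attr(fractions, "cell_types") %||%
    setdiff(names(fractions), c("sample_id", "degenerate", "nontumor_fraction"))
  if (is.data.frame(marker)) {
    if (!all(c("sample_id", "value") %in% names(marker))) {
      abort("`marker` data frame needs columns sample_id and value.")
    }
    mv <- setNames(marker$value, marker$sample_id)
  } else if (is.numeric(marker) && !is.null(names(marker))) {
    mv <- marker
  } else {
    abort("`marker` must be a data frame (sample_id, value) or a named numeric vector.")
  }
  shared <- intersect(fractions$sample_id, names(mv))
  if (length(shared) < 3) abort("Need at least 3 paired observations.")
  mv <- mv[shared]
  if (length(unique(mv)) < 2) abort("Marker is constant across the paired samples.")
  f <- fractions[match(shared, fractions$sample_id), ]
  purrr::map_dfr(cell_types, function(ct) {
    v <- f[[ct]]
    if (length(unique(v)) < 2) {
      return(tibble(cell_type = ct, estimate = NA_real_, p_value = NA_real_,
                    n = length(shared)))
    }
    ct_res <- suppressWarnings(cor.test(v, mv, method = method))
    tibble(cell_type = ct, estimate = unname(ct_res$estimate),
           p_value = ct_res$p.value, n = length(shared))
  })
}

#' Long-format view of deconvolution fractions
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `cell_type`, `fraction`.
#' @export
tidy.deconv_result <- function(x, ...) {
  cell_types <- attr(x, "cell_types")
  tidyr::pivot_longer(
    dplyr::select(x, dplyr::all_of(c("sample_id", cell_types))),
    dplyr::all_of(cell_types),
    names_to = "cell_type", values_to = "fraction"
  )
}

#' Stacked-bar plot of per-sample cell-type fractions
#'
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deconv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
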