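#' Expression-matrix filtering and collapsing
#'
#' Pre-processing steps applied to a summarised, normalised gene-by-sample
#' log2 expression matrix before differential expression and signature work:
#'
#' * `detection_filter()` removes genes that fail the detection call
#'   (detection P at or above `alpha`) in **every** sample; a gene detected in
#'   a single sample is retained.
#' * `collapse_genes()` collapses multiple array rows (e.g. transcript
#'   clusters) mapping to the same gene, keeping the row with the highest
#'   mean intensity.
#' * `reference_gene_filter()` keeps genes whose median intensity **and**
#'   standard deviation across samples both exceed those of a reference gene
#'   (the reference itself is retained). This is the pre-filter used before
#'   clustering, DE and signature construction, anchoring the analysis to
#'   genes at least as well measured and as variable as the marker
#'   transcript.
#'
#' @param x Expression input: numeric matrix (genes x samples, rownames =
#'   gene ids) or data frame with a gene column first.
#' @param detect_p Matrix of detection P-values aligned with `x` (same
#'   dimensions and order).
#' @param alpha Detection threshold (default 0.05).
#' @return A filtered genes x samples matrix.
#' @export
detection_filter <- function(x, detect_p, alpha = 0.05) {
  m <- as_expr_matrix(x)
  dp <- if (is.data.frame(detect_p)) as_expr_matrix(detect_p, "detect_p") else detect_p
  if (!identical(dim(dp), dim(m))) abort("`detect_p` must match the expression matrix dimensions.")
  undetected_everywhere <- rowSums(dp < alpha) == 0
  m[!undetected_everywhere, , drop = FALSE]
}

#' @rdname detection_filter
#' @param mapping Data frame with columns `row_id`, `gene_id` covering every
#'   row of `x` (named vector `row_id -> gene_id` also accepted).
#' @export
collapse_genes <- function(x, mapping) {
  m <- as_expr_matrix(x)
  if (is.data.frame(mapping)) {
    if (!all(c("row_id", "gene_id") %in% names(mapping))) {
      abort("`mapping` needs columns row_id and gene_id.")
    }
    map <- setNames(as.character(mapping$gene_id), as.character(mapping$row_id))
  } else if (is.character(mapping) && !is.null(names(mapping))) {
    map <- mapping
  } else {
    abort("`mapping` must be a data frame (row_id, gene_id) or a named character vector.")
  }
  if (length(map) == 0) abort("Empty mapping.")
  missing_rows <- setdiff(rownames(m), names(map))
  if (length(missing_rows) > 0) {
    abort(sprintf("Mapping does not cover %d row(s), e.g. %s.", length(missing_rows), missing_rows[1]))
  }
  gene <- unname(map[rownames(m)])
  means <- rowMeans(m)
  # For each gene keep the row with the highest mean intensity.
  keep <- tapply(seq_len(nrow(m)), gene, function(idx) idx[which.max(means[idx])])
  keep <- unlist(keep)
  out <- m[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out)), , drop = FALSE]
}

#' @rdname detection_filter
#' @param reference_gene Identifier of the reference gene (must be a row of `x`).
#' @export
reference_gene_filter <- function(x, reference_gene) {
  m <- as_expr_matrix(x)
  if (!reference_gene %in% rownames(m)) {
    abort(sprintf("Reference gene `%s` not present in the matrix.", reference_gene))
  }
  med <- apply(m, 1, median)
  sds <- apply(m, 1, sd)
  keep <- (med > med[reference_gene] & sds > sds[reference_gene]) |
    rownames(m) == reference_gene
  m[keep, , drop = FALSE]
}

#' Moderated two-group differential expression
#'
#' Per-gene two-group comparison on a log2 expression matrix with
#' empirical-Bayes variance moderation: residual variances are shrunk toward
#' a common prior estimated by moment matching of the log residual
#' variances (fitting a scaled F/chi-square model via digamma/trigamma
#' moments), giving posterior variances
#' \eqn{s^2_{post} = (d_0 s_0^2 + d s^2) / (d_0 + d)} and moderated
#' t-statistics on \eqn{d_0 + d} degrees of freedom. P-values are two-sided;
#' FDR is Benjamini-Hochberg. The log fold change convention is
#' hi-group mean minus lo-group mean (log2 scale).
#'
#' @param x Expression matrix (genes x samples, log2 scale) or gene-column
#'   data frame.
#' @param groups Hi/lo assignment: data frame (`sample_id`, `label`) or named
#'   character vector of `"hi"`/`"lo"`. Samples absent from `groups` are
#'   dropped. At least two samples per group.
#' @param prior_df Optional override of the prior degrees of freedom
#'   \eqn{d_0}; `NULL` (default) estimates it from the data, `0` gives
#'   ordinary two-sample equal-variance t-statistics, `Inf` full shrinkage
#'   to the common variance.
#' @return A tibble of class `de_result`, one row per gene: `gene`, `logFC`,
#'   `t`, `p_value`, `fdr`, sorted by `p_value`. Attributes `prior_df` and
#'   `prior_var` record the fitted prior.
#' @export
moderated_de <- function(x, groups, prior_df = NULL) {
  m <- as_expr_matrix(x)
  g <- as_label_vector(groups, arg = "groups")
  g <- g[names(g) %in% colnames(m)]
  m <- m[, names(g), drop = FALSE]
  n_hi <- sum(g == "hi")
  n_lo <- sum(g == "lo")
  if (n_hi < 2 || n_lo < 2) abort("Need at least two samples per group.")
  hi <- g == "hi"

  mean_hi <- rowMeans(m[, hi, drop = FALSE])
  mean_lo <- rowMeans(m[, !hi, drop = FALSE])
  logfc <- mean_hi - mean_lo
  ss_hi <- rowSums((m[, hi, drop = FALSE] - mean_hi)^2)
  ss_lo <- rowSums((m[, !hi, drop = FALSE] - mean_lo)^2)
  df_resid <- n_hi + n_lo - 2
  s2 <- (ss_hi + ss_lo) / df_resid

  if (is.null(prior_df)) {
    fit <- fit_f_dist(s2, df_resid)
  } else if (prior_df == 0) {
    fit <- list(df_prior = 0, var_prior = NA_real_)
  } else if (is.infinite(prior_df)) {
    fit <- list(df_prior = Inf, var_prior = mean(s2))
  } else {
    # Fixed d0: estimate s0^2 by the same moment equation with d0 held.
    fit <- fit_f_dist(s2, df_resid)
    fit$df_prior <- prior_df
  }

  if (fit$df_prior == 0) {
    s2_post <- s2
    df_total <- df_resid
  } else if (is.infinite(fit$df_prior)) {
    s2_post <- rep(fit$var_prior, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (fit$df_prior * fit$var_prior + df_resid * s2) / (fit$df_prior + df_resid)
    df_total <- fit$df_prior + df_resid
  }
  se2 <- s2_post * (1 / n_hi + 1 / n_lo)
  tstat <- ifelse(se2 > 0, logfc / sqrt(se2), ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * pt(-abs(tstat), df = df_total)

  out <- tibble(
    gene = rownames(m), logFC = unname(logfc), t = unname(tstat),
    p_value = unname(p), fdr = unname(p.adjust(p, method = "BH"))
  )
  out <- dplyr::arrange(out, .data$p_value, .data$gene)
  class(out) <- c("de_result", class(out))
  attr(out, "prior_df") <- fit$df_prior
  attr(out, "prior_var") <- fit$var_prior
  attr(out, "n_hi") <- n_hi
  attr(out, "n_lo") <- n_lo
  out
}

# Moment-matching fit of the scaled-F model for residual variances
# (method of moments on log s^2 using digamma/trigamma, with an inverse
# trigamma solved by Newton iteration). Genes with zero residual variance are
# floored at a tiny positive value for the log; with moderation they still
# receive finite posterior variances.
fit_f_dist <- function(s2, df) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  df_prior <- 2 * trigamma_inverse(evar)
  var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(x) = y by Newton iteration on a monotone decreasing function.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Select differentially expressed genes at fixed thresholds
#'
#' @param de A `de_result` from [moderated_de()].
#' @param fdr_max Keep genes with `fdr` strictly below this.
#' @param abs_lfc_min Keep genes with `|logFC|` at or above this.
#' @param direction `"both"` or `"up"` (positive logFC only, i.e.
#'   hi-group-upregulated).
#' @return Character vector of gene identifiers (possibly empty).
#' @export
select_degs <- function(de, fdr_max, abs_lfc_min, direction = c("both", "up")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(de), all(c("gene", "logFC", "fdr") %in% names(de)))
  keep <- de$fdr < fdr_max & abs(de$logFC) >= abs_lfc_min
  if (direction == "up") keep <- keep & de$logFC > 0
  de$gene[keep]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a hit list within
#' a fixed gene universe: the P-value of observing at least the seen overlap
#' when drawing `|hits|` genes from the universe. Sets are intersected with
#' the universe first; sets outside the size bounds are dropped (the
#' published analysis excluded sets of more than 500 or fewer than 5 genes).
#'
#' @param hits Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of all genes eligible for selection.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param p_cutoff Sets with `p_value` strictly below this are flagged
#'   `enriched` (default 0.001).
#' @param min_size,max_size Set-size bounds applied after intersection with
#'   the universe (defaults 5 and 500).
#' @return A tibble: `set`, `set_size`, `overlap`, `expected`, `p_value`,
#'   `enriched`, sorted by `p_value`.
#' @export
hypergeometric_ora <- function(hits, universe, sets, p_cutoff = 0.001,
                               min_size = 5, max_size = 500) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe)) abort("`hits` must be a subset of `universe`.")
  if (!is.list(sets) || is.null(names(sets))) abort("`sets` must be a named list of gene vectors.")
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- purrr::imap(sets, function(genes, nm) {
    in_univ <- intersect(unique(genes), universe)
    k <- length(in_univ)
    if (k < min_size || k > max_size) return(NULL)
    ov <- length(intersect(in_univ, hits))
    p <- phyper(ov - 1, k, n_univ - k, n_hits, lower.tail = FALSE)
    tibble(set = nm, set_size = k, overlap = ov,
           expected = n_hits * k / n_univ, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("No gene set within the size bounds overlaps the universe.")
  out$enriched <- out$p_value < p_cutoff
  dplyr::arrange(out, .data$p_value, .data$set)
}
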