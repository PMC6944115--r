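#' Sample-wise gene-set enrichment scores
#'
#' Rank-based single-sample enrichment scoring. Each gene's expression is
#' first rank-transformed **across samples**, so a gene's statistic in a
#' sample reflects how high that sample sits in the gene's cohort-wide
#' distribution (this makes the score invariant to any strictly monotone
#' per-gene transformation). For each sample, genes are then ordered by
#' decreasing rank statistic and a weighted Kolmogorov-Smirnov-like running
#' sum is walked down the list: genes inside the set add their rank weight
#' (normalised over the set), genes outside subtract a uniform step. The
#' score is the signed sum of the two extrema — maximum positive deviation
#' plus maximum negative deviation — which lives in \[-1, 1\] by
#' construction, so a fixed dichotomisation cutoff (e.g. -0.05 for signature
#' groups) is meaningful across cohorts.
#'
#' Sets are intersected with the matrix; sets retaining fewer than
#' `min_set_size` genes are dropped with a warning (an error if all are).
#'
#' @param x Expression matrix (genes x samples) or gene-column data frame.
#' @param sets Named list of gene-id vectors.
#' @param min_set_size Minimum genes a set must retain in the matrix
#'   (default 2).
#' @return A sets x samples numeric matrix of class `enrichment_scores`,
#'   with attribute `set_sizes` (genes retained per set).
#' @export
sample_enrichment_scores <- function(x, sets, min_set_size = 2) {
  m <- as_expr_matrix(x)
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a list with unique names.")
  }
  kept <- purrr::map(sets, ~ intersect(unique(.x), rownames(m)))
  sizes <- lengths(kept)
  bad <- sizes < min_set_size | sizes >= nrow(m)
  if (any(bad)) {
    warn(sprintf("Dropping %d set(s) with fewer than %d matrix genes (or covering the whole matrix): %s.",
                 sum(bad), min_set_size, paste(names(kept)[bad], collapse = ", ")))
    kept <- kept[!bad]
  }
  if (length(kept) == 0) abort("No gene set retains enough genes in the matrix.")

  n_genes <- nrow(m)
  n_samples <- ncol(m)
  # Across-sample rank of each gene's expression (ties averaged), centred so
  # the statistic is symmetric: z in [-(n-1)/2, (n-1)/2]. A sample sitting
  # high in a gene's cohort-wide distribution gets a large positive z.
  R <- t(apply(m, 1, rank))
  if (n_samples == 1) R <- matrix(R, ncol = 1, dimnames = dimnames(m))
  Z <- R - (n_samples + 1) / 2

  scores <- matrix(0, nrow = length(kept), ncol = n_samples,
                   dimnames = list(names(kept), colnames(m)))
  set_idx <- purrr::map(kept, ~ match(.x, rownames(m)))
  for (j in seq_len(n_samples)) {
    # Genes ordered by decreasing centred rank statistic; ties broken by row
    # order for determinism. Walk weight is |z| (tau = 1).
    ord <- order(-Z[, j], seq_len(n_genes))
    w <- abs(Z[ord, j])
    in_set_pos <- match(seq_len(n_genes), ord) # position of each gene in the walk
    for (s in seq_along(set_idx)) {
      idx <- set_idx[[s]]
      member <- logical(n_genes)
      member[in_set_pos[idx]] <- TRUE
      wm <- w * member
      pos_step <- if (sum(wm) > 0) wm / sum(wm) else member / sum(member)
      neg_step <- (!member) / (n_genes - length(idx))
      walk <- cumsum(pos_step - neg_step)
      scores[s, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  structure(scores, class = c("enrichment_scores", "matrix", "array"),
            set_sizes = lengths(kept))
}

#' Pre-filter a matrix against a signature's measurement floor
#'
#' Before scoring, genes measured less reliably and less variably than every
#' signature gene are removed: a gene is excluded when both its median
#' intensity and its standard deviation fall below the signature genes'
#' minima. Signature genes themselves are always retained.
#'
#' @param x Expression matrix or gene-column data frame.
#' @param signature_genes Character vector of signature gene ids (at least
#'   one must be present in the matrix).
#' @return The filtered genes x samples matrix.
#' @export
signature_prefilter <- function(x, signature_genes) {
  m <- as_expr_matrix(x)
  sig <- intersect(unique(signature_genes), rownames(m))
  if (length(sig) == 0) abort("No signature gene present in the matrix.")
  med <- apply(m, 1, median)
  sds <- apply(m, 1, sd)
  floor_med <- min(med[sig])
  floor_sd <- min(sds[sig])
  keep <- !(med < floor_med & sds < floor_sd) | rownames(m) %in% sig
  m[keep, , drop = FALSE]
}

#' Molecular subtype assignment from enrichment scores
#'
#' Assigns each sample the label of its highest-scoring subtype signature;
#' samples whose top two scores differ by less than `tie_margin` are labelled
#' `"nd"` (not determined).
#'
#' @param scores An `enrichment_scores` matrix (subtype sets x samples).
#' @param tie_margin Minimum lead of the top score (default 0.01).
#' @return A tibble: `sample_id`, `label`, `best_score`, `margin`.
#' @export
classify_subtype <- function(scores, tie_margin = 0.01) {
  if (!is.matrix(scores)) abort("`scores` must be a sets x samples matrix.")
  if (nrow(scores) < 2) abort("Need at least two subtype sets.")
  purrr::map_dfr(seq_len(ncol(scores)), function(j) {
    v <- scores[, j]
    ord <- order(-v)
    margin <- v[ord[1]] - v[ord[2]]
    tibble(
      sample_id = colnames(scores)[j],
      label = if (margin < tie_margin) "nd" else rownames(scores)[ord[1]],
      best_score = unname(v[ord[1]]),
      margin = unname(margin)
    )
  })
}

#' Correlation-distance hierarchical clustering of samples
#'
#' Agglomerative clustering with Pearson distance (1 minus the Pearson
#' correlation between sample expression profiles) and average (UPGMA)
#' linkage. Genes with zero variance across samples carry no correlation
#' information and are dropped with a warning.
#'
#' @param x Expression matrix (genes x samples) or gene-column data frame.
#' @return An `stats::hclust` object over samples.
#' @export
correlation_cluster <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 3) abort("Need at least 3 samples to cluster.")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(sprintf("Dropping %d zero-variance gene(s) before correlation.", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("Fewer than 2 informative genes left after dropping zero-variance rows.")
  d <- as.dist(1 - cor(m))
  hclust(d, method = "average")
}

#' Long-format view of an enrichment score matrix
#'
#' @param x An `enrichment_scores` matrix.
#' @param ... Unused.
#' @return A tibble with `set`, `sample_id`, `score`.
#' @export
tidy.enrichment_scores <- function(x, ...) {
  m <- unclass(x)
  tibble(
    set = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    score = as.vector(m)
  )
}

#' Heatmap-style plot of sample enrichment scores
#'
#' @param object An `enrichment_scores` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$set, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
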