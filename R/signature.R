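#' Construct a prognostic gene signature from a marker-high program
#'
#' Second-round signature construction: starting from a DEG universe (the
#' matrix passed in, typically already restricted to first-round DEGs or to
#' the reference-filtered gene space), the two-group moderated analysis is
#' re-run with **all** samples — including any that were ambiguous in the
#' first round — and a grid of (minimum logFC, maximum FDR) thresholds is
#' searched. Each grid point defines a candidate signature (the upregulated
#' genes passing it); every sample is scored for that candidate with
#' [sample_enrichment_scores()], scores are dichotomised at
#' `enrichment_cutoff` (default -0.05, the published value), and the
#' candidate is judged by the two-sided Fisher exact P of the
#' (enriched/under-represented x short/long survivor) table at the fixed
#' `survival_cutoff`, censored samples below the cutoff excluded. The
#' candidate minimising that separation P wins; ties go to the smaller
#' signature.
#'
#' @param x Expression matrix (genes x samples, log2) defining the DEG
#'   universe for the second-round analysis.
#' @param groups Hi/lo labels (data frame `sample_id`,`label` or named
#'   vector) covering the scored samples, ambiguous samples re-included.
#' @param survival Data frame of survival records (`sample_id`, `time`,
#'   `event`).
#' @param survival_cutoff Short/long survivor cutoff in years (for the
#'   original cohort, the longest survival of the marker-high group).
#' @param grid Data frame with columns `logfc_min`, `fdr_max`; the default
#'   grid is anchored at the published second-round thresholds
#'   (logFC > 1.12, FDR < 0.022).
#' @param enrichment_cutoff Score dichotomisation cutoff (default -0.05).
#' @param scoring_x Optional separate matrix to score samples on (defaults
#'   to `x`).
#' @return An object of class `signature_result`: `genes`,
#'   `thresholds_used`, `separation_p`, `enrichment_cutoff`, per-sample
#'   `scores`, the `de` table and the full grid `trace`.
#' @export
build_signature <- function(x, groups, survival, survival_cutoff,
                            grid = default_signature_grid(),
                            enrichment_cutoff = -0.05,
                            scoring_x = NULL) {
  m <- as_expr_matrix(x)
  surv <- as_survival_tbl(survival)
  if (!is.data.frame(grid) || !all(c("logfc_min", "fdr_max") %in% names(grid))) {
    abort("`grid` needs columns logfc_min and fdr_max.")
  }
  if (!is_scalar_number(survival_cutoff) || survival_cutoff <= 0) {
    abort("`survival_cutoff` must be a positive number of years.")
  }
  score_m <- if (is.null(scoring_x)) m else as_expr_matrix(scoring_x, "scoring_x")
  surv <- surv[surv$sample_id %in% colnames(score_m), ]
  if (nrow(surv) == 0) abort("No survival record matches a scored sample.")

  de <- moderated_de(m, groups)

  trace <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    lfc <- grid$logfc_min[i]
    fdr <- grid$fdr_max[i]
    genes <- de$gene[de$logFC > lfc & de$fdr < fdr]
    if (length(genes) < 2) {
      return(tibble(logfc_min = lfc, fdr_max = fdr, n_genes = length(genes),
                    separation_p = NA_real_))
    }
    sc <- tryCatch(
      suppressWarnings(sample_enrichment_scores(score_m, list(candidate = genes))),
      error = function(e) NULL
    )
    if (is.null(sc) || !"candidate" %in% rownames(sc)) {
      return(tibble(logfc_min = lfc, fdr_max = fdr, n_genes = length(genes),
                    separation_p = NA_real_))
    }
    p <- signature_separation_p(sc["candidate", surv$sample_id], surv,
                                survival_cutoff, enrichment_cutoff)
    tibble(logfc_min = lfc, fdr_max = fdr, n_genes = length(genes), separation_p = p)
  })
  ok <- which(!is.na(trace$separation_p))
  if (length(ok) == 0) abort("Every grid point yields an empty candidate signature.")
  best <- ok[order(trace$separation_p[ok], trace$n_genes[ok], ok)][1]

  genes <- de$gene[de$logFC > trace$logfc_min[best] & de$fdr < trace$fdr_max[best]]
  sc <- suppressWarnings(sample_enrichment_scores(score_m, list(signature = genes)))
  scores <- tibble(
    sample_id = colnames(sc),
    score = as.numeric(sc["signature", ]),
    enriched = as.numeric(sc["signature", ]) > enrichment_cutoff
  )
  structure(
    list(
      genes = genes,
      thresholds_used = c(logfc_min = trace$logfc_min[best], fdr_max = trace$fdr_max[best]),
      separation_p = trace$separation_p[best],
      enrichment_cutoff = enrichment_cutoff,
      survival_cutoff = survival_cutoff,
      scores = scores, de = de, trace = trace
    ),
    class = "signature_result"
  )
}

#' @rdname build_signature
#' @export
default_signature_grid <- function() {
  # The four combinations of the first-round (logFC 0.89, FDR 0.015) and
  # second-round (logFC 1.12, FDR 0.022) selection thresholds.
  tidyr::expand_grid(
    logfc_min = c(0.89, 1.12),
    fdr_max = c(0.015, 0.022)
  )
}

# Fisher P of the enriched/under-represented x short/long table at a fixed
# survival cutoff, censored-below-cutoff samples excluded.
signature_separation_p <- function(score, surv, survival_cutoff, enrichment_cutoff) {
  hi <- score > enrichment_cutoff
  d <- tibble(sample_id = surv$sample_id, time = surv$time, event = surv$event)
  fisher_quadrant(d, hi, survival_cutoff)$p
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result: %d genes (logFC > %.3g, FDR < %.3g)>\n",
              length(x$genes), x$thresholds_used[["logfc_min"]],
              x$thresholds_used[["fdr_max"]]))
  cat(sprintf("  separation Fisher P: %.4g at survival cutoff %.3g y, score cutoff %.3g\n",
              x$separation_p, x$survival_cutoff, x$enrichment_cutoff))
  cat(sprintf("  enriched samples: %d / %d\n", sum(x$scores$enriched), nrow(x$scores)))
  invisible(x)
}

#' Per-sample scores of a constructed signature
#'
#' @param x A `signature_result`.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `score`, `enriched`.
#' @export
tidy.signature_result <- function(x, ...) x$scores

#' One-row summary of a constructed signature
#'
#' @param x A `signature_result`.
#' @param ... Unused.
#' @return A one-row tibble with thresholds, size and separation P.
#' @export
glance.signature_result <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    logfc_min = x$thresholds_used[["logfc_min"]],
    fdr_max = x$thresholds_used[["fdr_max"]],
    separation_p = x$separation_p,
    enrichment_cutoff = x$enrichment_cutoff,
    survival_cutoff = x$survival_cutoff,
    n_enriched = sum(x$scores$enriched)
  )
}
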