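#' Dual expression/survival cutoff search minimising Fisher's exact P
#'
#' Implements the two-cutoff stratification rule used to define marker-high
#' groups that exclude long survivors. Every admissible expression cutoff
#' (midpoints between consecutive distinct marker values; both groups at
#' least `min_group_fraction` of the cohort and at least 2 samples) is
#' scanned. For each candidate the survival-time cutoff is set to the longest
#' observed survival of the marker-high group, a 2x2 table of
#' (hi/lo x short/long survivor) is built — censored samples with follow-up
#' shorter than the survival cutoff are excluded from the table, since their
#' long-survivor status is unknown — and the candidate minimising the
#' two-sided Fisher exact P is returned. Ties are broken by the larger
#' absolute difference in median marker value between groups, then by the
#' more balanced split.
#'
#' The minimised P-value is selection-biased (a minimum over many tests) and
#' is reported as such; no multiplicity correction is applied, but see the
#' calibration notes in the package vignette.
#'
#' @param data Data frame with one row per sample: marker value plus survival.
#' @param marker Column name of the continuous marker.
#' @param sample_id,time,event Column names for identifiers, follow-up time
#'   (years) and event status (1 = dead, 0 = censored).
#' @param min_group_fraction Minimum fraction of the cohort on each side of
#'   the cutoff (default 0.1).
#' @return An object of class `strat_result`: chosen cutoffs, per-sample
#'   labels, contingency table, P-values, excluded censored samples and the
#'   full scan trace. See [tidy.strat_result()], [glance.strat_result()],
#'   [autoplot.strat_result()].
#' @export
dual_cutoff_fisher_scan <- function(data, marker, sample_id = "sample_id",
                                    time = "time", event = "event",
                                    min_group_fraction = 0.1) {
  d <- strat_input(data, marker, sample_id, time, event)
  if (nrow(d) < 6) abort("Need at least 6 samples with marker and survival.")
  cuts <- candidate_cutoffs(d$marker, nrow(d), min_group_fraction)

  trace <- purrr::map_dfr(cuts, function(cc) {
    hi <- d$marker > cc
    s_cut <- max(d$time[hi])
    ft <- fisher_quadrant(d, hi, s_cut)
    # Tie-break medians are taken over the samples that actually enter the
    # Fisher table: censored samples below the survival cutoff carry no
    # short/long information, so they should not influence the choice
    # between splits whose evidence is identical.
    keep <- !ft$excluded
    med_diff <- if (any(hi & keep) && any(!hi & keep)) {
      abs(median(d$marker[hi & keep]) - median(d$marker[!hi & keep]))
    } else {
      -Inf
    }
    tibble(
      expression_cutoff = cc,
      n_hi = sum(hi), n_lo = sum(!hi),
      survival_cutoff = s_cut,
      p_fisher = ft$p,
      median_diff = med_diff,
      imbalance = abs(sum(hi) - sum(!hi))
    )
  })
  best <- select_min_p(trace$p_fisher, trace$median_diff, trace$imbalance)
  cc <- trace$expression_cutoff[best]
  hi <- d$marker > cc
  s_cut <- trace$survival_cutoff[best]
  ft <- fisher_quadrant(d, hi, s_cut)
  lr <- logrank_stat(d$time, d$event, hi)

  new_strat_result(
    method = "dual_fisher", marker_name = marker, data = d, hi = hi,
    expression_cutoff = cc, survival_cutoff = s_cut,
    table = ft$table, p_fisher = ft$p, p_logrank = lr$p,
    excluded_censored = d$sample_id[ft$excluded],
    trace = trace,
    constraints = list(min_group_fraction = min_group_fraction)
  )
}

#' Constrained log-rank cutoff scan
#'
#' Scans every admissible marker split and, for each, computes the two-group
#' log-rank P, the group-size imbalance, and the absolute difference in
#' Kaplan-Meier median survival (restricted-mean difference when a median is
#' undefined). The published rule — lowest P while equilibrating group sizes
#' and maximising the survival difference — is concretised as a rank
#' composite: `rank(P) + balance_weight * rank(imbalance) -
#' median_diff_weight * rank(|median difference|)`, lower is better, ranks
#' taken over the candidate splits. Weights are configurable and echoed in
#' the result.
#'
#' @inheritParams dual_cutoff_fisher_scan
#' @param balance_weight,median_diff_weight Non-negative weights of the two
#'   secondary criteria (defaults 1 and 1).
#' @return A `strat_result` with `p_logrank` for the chosen split and the
#'   full scan trace (every candidate with its P, imbalance, median
#'   difference and composite score). The chosen minimum-P is
#'   selection-biased; see Details of [dual_cutoff_fisher_scan()].
#' @export
logrank_cutoff_scan <- function(data, marker, sample_id = "sample_id",
                                time = "time", event = "event",
                                min_group_fraction = 0.1,
                                balance_weight = 1, median_diff_weight = 1) {
  d <- strat_input(data, marker, sample_id, time, event)
  if (nrow(d) < 6) abort("Need at least 6 samples with marker and survival.")
  if (sum(d$event) == 0) abort("No events: log-rank scan undefined.")
  stopifnot(balance_weight >= 0, median_diff_weight >= 0)
  cuts <- candidate_cutoffs(d$marker, nrow(d), min_group_fraction)

  trace <- purrr::map_dfr(cuts, function(cc) {
    hi <- d$marker > cc
    lr <- logrank_stat(d$time, d$event, hi)
    km_hi <- km_estimate(d[hi, ])
    km_lo <- km_estimate(d[!hi, ])
    med_hi <- median_survival(km_hi)
    med_lo <- median_survival(km_lo)
    surv_diff <- if (is.na(med_hi) || is.na(med_lo)) {
      abs(km_restricted_mean(km_hi) - km_restricted_mean(km_lo))
    } else {
      abs(med_hi - med_lo)
    }
    tibble(
      expression_cutoff = cc, n_hi = sum(hi), n_lo = sum(!hi),
      p_logrank = lr$p, imbalance = abs(sum(hi) - sum(!hi)) / nrow(d),
      surv_diff = surv_diff
    )
  })
  trace$score <- rank(trace$p_logrank) +
    balance_weight * rank(trace$imbalance) -
    median_diff_weight * rank(trace$surv_diff)
  ord <- order(trace$score, trace$p_logrank, trace$imbalance, trace$expression_cutoff)
  best <- ord[1]
  cc <- trace$expression_cutoff[best]
  hi <- d$marker > cc

  new_strat_result(
    method = "logrank_scan", marker_name = marker, data = d, hi = hi,
    expression_cutoff = cc, survival_cutoff = NA_real_,
    table = NULL, p_fisher = NA_real_, p_logrank = trace$p_logrank[best],
    excluded_censored = character(0), trace = trace,
    constraints = list(
      min_group_fraction = min_group_fraction,
      balance_weight = balance_weight, median_diff_weight = median_diff_weight
    )
  )
}

#' Survival-time cutoff minimising Fisher's exact P for fixed groups
#'
#' Given an existing hi/lo partition (e.g. a signature-enrichment
#' dichotomy), scans the observed survival times as candidate short/long
#' cutoffs, builds the (hi/lo x short/long) table at each — excluding
#' censored samples with follow-up below the cutoff — and returns the cutoff
#' minimising the two-sided Fisher P. Ties go to the smallest cutoff.
#'
#' @param data Data frame with sample ids, group labels and survival.
#' @param group Column with `"hi"`/`"lo"` labels.
#' @inheritParams dual_cutoff_fisher_scan
#' @return A list with `cutoff`, `table`, `p_fisher` and the scan `trace`.
#' @export
survival_time_cutoff_scan <- function(data, group, sample_id = "sample_id",
                                      time = "time", event = "event") {
  d <- as_survival_tbl(data, sample_id, time, event)
  lab <- as.character(data[[group]])
  if (!all(lab %in% c("hi", "lo"))) abort("`group` must contain only \"hi\"/\"lo\".")
  if (length(unique(lab)) < 2) abort("Both groups must be non-empty.")
  d$hi <- lab == "hi"
  cand <- sort(unique(d$time))
  if (length(cand) < 2) abort("Need at least two distinct survival times to scan.")
  trace <- purrr::map_dfr(cand, function(s) {
    ft <- fisher_quadrant(d, d$hi, s)
    tibble(survival_cutoff = s, p_fisher = ft$p, n_excluded = sum(ft$excluded))
  })
  best <- which.min(trace$p_fisher)
  s <- trace$survival_cutoff[best]
  ft <- fisher_quadrant(d, d$hi, s)
  list(cutoff = s, table = ft$table, p_fisher = ft$p, trace = trace)
}

#' Quadrant cross-tabulation of two hi/lo factors
#'
#' Cross-tabulates the samples labelled under both factors and reports the
#' 2x2 counts, the two-sided Fisher exact P, and the conditional percentages
#' (share of A-high that is B-high and vice versa).
#'
#' @param labels_a,labels_b Data frames with columns `sample_id`, `label`
#'   (`"hi"`/`"lo"`), or named `"hi"`/`"lo"` character vectors.
#' @param names Length-2 character vector naming the two factors (used in
#'   the table dimnames).
#' @return A list of class `quadrant_table`: `table` (rows = factor A hi/lo,
#'   columns = factor B hi/lo), `p_fisher`, `n_shared`, and `percentages`.
#' @export
quadrant_table <- function(labels_a, labels_b, names = c("A", "B")) {
  a <- as_label_vector(labels_a, arg = "labels_a")
  b <- as_label_vector(labels_b, arg = "labels_b")
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) abort("No samples labelled under both factors.")
  fa <- factor(a[shared], levels = c("hi", "lo"))
  fb <- factor(b[shared], levels = c("hi", "lo"))
  tab <- table(fa, fb)
  dimnames(tab) <- setNames(list(c("hi", "lo"), c("hi", "lo")), names)
  m <- as.matrix(unclass(tab))
  pct <- tibble(
    description = c(
      sprintf("%% of %s-hi that are %s-hi", names[1], names[2]),
      sprintf("%% of %s-hi that are %s-hi", names[2], names[1])
    ),
    value = c(100 * m[1, 1] / sum(m[1, ]), 100 * m[1, 1] / sum(m[, 1]))
  )
  structure(
    list(table = m, p_fisher = fisher_exact_two_sided(m),
         n_shared = length(shared), percentages = pct, factor_names = names),
    class = "quadrant_table"
  )
}

# ---- internals --------------------------------------------------------------

strat_input <- function(data, marker, sample_id, time, event) {
  d <- as_survival_tbl(data, sample_id, time, event)
  if (!marker %in% names(data)) abort(sprintf("Marker column `%s` not found.", marker))
  d$marker <- as.numeric(data[[marker]])
  d <- d[complete.cases(d), ]
  if (nrow(d) == 0) abort("No samples with both marker and survival.")
  if (length(unique(d$marker)) < 2) abort("No valid split: marker is constant across samples.")
  d
}

# Midpoints between consecutive distinct sorted marker values, restricted to
# splits with both groups >= max(2, ceiling(min_group_fraction * n)).
candidate_cutoffs <- function(marker, n, min_group_fraction) {
  if (!is_scalar_number(min_group_fraction) || min_group_fraction <= 0 || min_group_fraction > 0.5) {
    abort("`min_group_fraction` must be in (0, 0.5].")
  }
  v <- sort(unique(marker))
  mids <- (v[-1] + v[-length(v)]) / 2
  min_n <- max(2, ceiling(min_group_fraction * n))
  keep <- vapply(mids, function(cc) {
    nh <- sum(marker > cc)
    nh >= min_n && (n - nh) >= min_n
  }, logical(1))
  cuts <- mids[keep]
  if (length(cuts) == 0) abort("No admissible split under the group-size constraint.")
  cuts
}

# Build the (hi/lo x short/long) table at survival cutoff s_cut.
# Long survivor: time strictly greater than the cutoff. Censored samples with
# time strictly below the cutoff are excluded (status unknowable).
fisher_quadrant <- function(d, hi, s_cut) {
  excluded <- d$event == 0 & d$time < s_cut
  keep <- !excluded
  long <- d$time > s_cut
  tab <- matrix(
    c(sum(keep & hi & !long), sum(keep & hi & long),
      sum(keep & !hi & !long), sum(keep & !hi & long)),
    nrow = 2, byrow = TRUE,
    dimnames = list(group = c("hi", "lo"), survival = c("short", "long"))
  )
  list(table = tab, p = fisher_exact_two_sided(tab), excluded = excluded)
}

# Minimum-P selection with deterministic tie-breaking: candidates whose P is
# within relative 1e-9 of the minimum are tied; among them prefer the larger
# median marker difference, then the smaller imbalance, then the first.
select_min_p <- function(p, median_diff, imbalance) {
  p_min <- min(p)
  tied <- which(p <= p_min + 1e-9 * max(p_min, .Machine$double.eps) + 1e-15)
  tied <- tied[order(-median_diff[tied], imbalance[tied], tied)]
  tied[1]
}

new_strat_result <- function(method, marker_name, data, hi, expression_cutoff,
                             survival_cutoff, table, p_fisher, p_logrank,
                             excluded_censored, trace, constraints) {
  labels <- tibble(
    sample_id = data$sample_id,
    marker_value = data$marker,
    time = data$time,
    event = data$event,
    label = ifelse(hi, "hi", "lo")
  )
  structure(
    list(
      method = method, marker = marker_name,
      expression_cutoff = expression_cutoff, survival_cutoff = survival_cutoff,
      labels = labels, table = table, p_fisher = p_fisher, p_logrank = p_logrank,
      n_hi = sum(hi), n_lo = sum(!hi), excluded_censored = excluded_censored,
      trace = trace, constraints = constraints,
      selection_biased = TRUE
    ),
    class = "strat_result"
  )
}

#' @export
print.strat_result <- function(x, ...) {
  cat(sprintf("<strat_result: %s scan on marker `%s`>\n", x$method, x$marker))
  cat(sprintf("  expression cutoff: %.4g  (hi n=%d, lo n=%d)\n",
              x$expression_cutoff, x$n_hi, x$n_lo))
  if (!is.na(x$survival_cutoff)) {
    cat(sprintf("  survival cutoff:   %.4g years (%d censored sample(s) below it excluded)\n",
                x$survival_cutoff, length(x$excluded_censored)))
  }
  if (!is.na(x$p_fisher)) cat(sprintf("  Fisher exact P:    %.4g (minimised over %d candidate splits; selection-biased)\n",
                                      x$p_fisher, nrow(x$trace)))
  if (!is.na(x$p_logrank)) cat(sprintf("  log-rank P:        %.4g\n", x$p_logrank))
  invisible(x)
}

#' Per-sample labels of a stratification result
#'
#' @param x A `strat_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `marker_value`, `time`, `event`,
#'   `label`, and `excluded` (censored below the survival cutoff, hence left
#'   out of the Fisher table).
#' @export
tidy.strat_result <- function(x, ...) {
  dplyr::mutate(x$labels, excluded = .data$sample_id %in% x$excluded_censored)
}

#' One-row summary of a stratification result
#'
#' @param x A `strat_result`.
#' @param ... Unused.
#' @return A one-row tibble with the cutoffs, group sizes and P-values.
#' @export
glance.strat_result <- function(x, ...) {
  tibble(
    method = x$method, marker = x$marker,
    expression_cutoff = x$expression_cutoff, survival_cutoff = x$survival_cutoff,
    n_hi = x$n_hi, n_lo = x$n_lo,
    n_excluded_censored = length(x$excluded_censored),
    p_fisher = x$p_fisher, p_logrank = x$p_logrank,
    n_candidates = nrow(x$trace), selection_biased = x$selection_biased
  )
}

#' Marker-versus-survival quadrant plot of a stratification result
#'
#' Reproduces the standard presentation: marker value against survival time,
#' points coloured by group and shaped by event status, with the expression
#' cutoff as a vertical line and (when defined) the survival cutoff as a
#' horizontal line.
#'
#' @param object A `strat_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strat_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_value, y = .data$time,
                                        colour = .data$label,
                                        shape = factor(.data$event))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$expression_cutoff, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`0` = 1, `1` = 16), name = "event") +
    ggplot2::labs(x = object$marker, y = "Survival (years)", colour = "group") +
    ggplot2::theme_minimal()
  if (!is.na(object$survival_cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = object$survival_cutoff, linetype = 3)
  }
  p
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat(sprintf("<quadrant_table: %s x %s, n=%d shared samples>\n",
              x$factor_names[1], x$factor_names[2], x$n_shared))
  print(x$table)
  cat(sprintf("  Fisher exact P: %.4g\n", x$p_fisher))
  for (i in seq_len(nrow(x$percentages))) {
    cat(sprintf("  %s: %.1f%%\n", x$percentages$description[i], x$percentages$value[i]))
  }
  invisible(x)
}

#' @export
tidy.quadrant_table <- function(x, ...) {
  m <- x$table
  tibble(
    !!x$factor_names[1] := rep(rownames(m), each = 2),
    !!x$factor_names[2] := rep(colnames(m), times = 2),
    n = as.vector(t(m))
  )
}
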