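#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the distinct event times of a cohort, with \eqn{d_i} deaths among
#' \eqn{n_i} at risk. Censored observations tied with an event time are
#' treated as occurring just after the events (the standard convention).
#'
#' @param data Data frame of survival records.
#' @param time,event Column names for follow-up time (years, positive) and
#'   event status (1 = dead, 0 = censored).
#' @return A tibble of class `km_curve` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`. `survival` is
#'   the right-continuous step value at (and after) that time.
#' @seealso [median_survival()], [logrank_test()]
#' @export
km_estimate <- function(data, time = "time", event = "event") {
  d <- as_survival_tbl_loose(data, time, event)
  ut <- sort(unique(d$time))
  n <- nrow(d)
  n_risk <- vapply(ut, function(t) sum(d$time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(d$time == t & d$event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(d$time == t & d$event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(
    time = ut, n_risk = as.integer(n_risk), n_event = as.integer(n_event),
    n_censor = as.integer(n_censor), survival = surv
  )
  class(out) <- c("km_curve", class(out))
  attr(out, "n") <- n
  out
}

# Relaxed coercion used where sample ids are not needed.
as_survival_tbl_loose <- function(data, time = "time", event = "event") {
  if (!is.data.frame(data) || nrow(data) == 0) abort("Need a non-empty data frame of survival records.")
  if (!all(c(time, event) %in% names(data))) {
    abort(sprintf("Missing survival column(s): %s.", paste(setdiff(c(time, event), names(data)), collapse = ", ")))
  }
  out <- tibble(time = as.numeric(data[[time]]), event = as.numeric(data[[event]]))
  if (anyNA(out$time) || any(out$time <= 0)) abort("Survival times must be positive and non-missing.")
  if (!all(out$event %in% c(0, 1))) abort("Event status must be 0 (censored) or 1 (dead).")
  out
}

#' Survival probability from a fitted curve
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities (1 before the first
#'   observed time).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest event time at which the estimated survival drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5 (e.g. heavy censoring).
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @return A single numeric, or `NA_real_` when undefined.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- curve$time[curve$n_event > 0 & curve$survival <= 0.5 + 1e-12]
  if (length(hit) == 0) NA_real_ else min(hit)
}

# Restricted mean survival up to the largest observed time: area under the
# KM step function. Fallback summary when the median is undefined.
km_restricted_mean <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  times <- c(0, curve$time)
  surv <- c(1, curve$survival)
  sum(diff(times) * surv[-length(surv)])
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom, with tied event
#' times handled by the hypergeometric variance formula.
#'
#' @param data Data frame of survival records for both groups.
#' @param group Column name holding the two group labels.
#' @inheritParams km_estimate
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`, `n_event`.
#' @export
logrank_test <- function(data, group, time = "time", event = "event") {
  d <- as_survival_tbl_loose(data, time, event)
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  if (min(table(g)) < 1) abort("Both groups must be non-empty.")
  res <- logrank_stat(d$time, d$event, g == levels(g)[1])
  tibble(
    statistic = res$statistic, df = 1L, p_value = res$p,
    n = nrow(d), n_event = sum(d$event)
  )
}

# Core log-rank computation shared with the cutoff scans. `in_a` is a logical
# marking membership of group A. Returns observed-minus-expected tally,
# variance, chi-square and p.
logrank_stat <- function(time, event, in_a) {
  if (sum(event) == 0) abort("Log-rank statistic undefined: no events in either group.")
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & in_a)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & in_a)
    o_minus_e <- o_minus_e + (d1j - dj * n1j / nj)
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  if (v <= 0) {
    # Degenerate layout (e.g. all events in one group after the other left
    # the risk set with no overlap): no information, report a null result.
    if (abs(o_minus_e) > 1e-12) abort("Log-rank variance is zero but observed != expected; degenerate input.")
    return(list(statistic = 0, p = 1, o_minus_e = 0, var = 0))
  }
  chi2 <- o_minus_e^2 / v
  list(statistic = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), o_minus_e = o_minus_e, var = v)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided P by the minimum-likelihood rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (the convention of
#' `stats::fisher.test`, which this wraps). Degenerate margins (an empty row
#' or column) carry no information and return 1.
#'
#' @param x A 2x2 matrix/table of counts, or the count `a` with `b`, `c`, `d`
#'   supplied separately (row-wise: `a`,`b` / `c`,`d`).
#' @param b,c,d Optional remaining cells when `x` is given as a scalar.
#' @return The two-sided P-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 2, 30, 27), nrow = 2)) # 0.0604
#' @export
fisher_exact_two_sided <- function(x, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(x) || is.table(x)) {
    as.matrix(x)
  } else {
    matrix(c(x, c, b, d), nrow = 2)
  }
  if (!identical(dim(m), c(2L, 2L))) abort("Need a 2x2 table.")
  if (anyNA(m) || any(m < 0) || any(m != round(m))) abort("Cells must be non-negative integers.")
  if (sum(m) == 0) abort("Empty table.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Pearson chi-square test on an r x c table
#'
#' Without continuity correction; companion to [fisher_exact_two_sided()] for
#' quadrant tables with more than two groups.
#'
#' @param x Matrix/table of counts.
#' @return Two-sided P-value.
#' @export
pearson_chisq <- function(x) {
  m <- as.matrix(x)
  if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}

#' Nonparametric comparison of a value across groups
#'
#' Two groups: two-sided Mann-Whitney (Wilcoxon rank-sum) test. Three or
#' more: Kruskal-Wallis omnibus test followed by Dunn's pairwise z-tests on
#' mean ranks (tie-corrected), with Benjamini-Hochberg adjusted P-values.
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names.
#' @param method `"auto"` picks by the number of groups; or force
#'   `"mann_whitney"` / `"kruskal_dunn"`.
#' @return A tibble with one row per comparison: `comparison`, `method`,
#'   `statistic`, `p_value`, and `p_adj` for Dunn rows.
#' @export
group_compare <- function(data, value, group, method = c("auto", "mann_whitney", "kruskal_dunn")) {
  method <- match.arg(method)
  v <- as.numeric(data[[value]])
  g <- as.factor(as.character(data[[group]]))
  if (anyNA(v)) abort("Missing values in `value`.")
  sizes <- table(g)
  if (length(sizes) < 2) abort("Need at least two groups.")
  if (any(sizes < 1)) abort("Every group needs at least one observation.")
  if (method == "auto") method <- if (length(sizes) == 2) "mann_whitney" else "kruskal_dunn"

  if (method == "mann_whitney") {
    if (length(sizes) != 2) abort("Mann-Whitney requires exactly two groups.")
    lv <- levels(g)
    wt <- suppressWarnings(wilcox.test(v[g == lv[1]], v[g == lv[2]], exact = FALSE, correct = TRUE))
    return(tibble(
      comparison = paste(lv, collapse = " vs "), method = "mann_whitney",
      statistic = unname(wt$statistic), p_value = wt$p.value, p_adj = NA_real_
    ))
  }

  kw <- kruskal.test(v, g)
  r <- rank(v)
  n <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  dunn <- purrr::map_dfr(pairs, function(p) {
    ni <- sizes[[p[1]]]; nj <- sizes[[p[2]]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
    tibble(
      comparison = paste(p, collapse = " vs "), method = "dunn",
      statistic = z, p_value = 2 * pnorm(-abs(z))
    )
  })
  dunn$p_adj <- p.adjust(dunn$p_value, method = "BH")
  dplyr::bind_rows(
    tibble(
      comparison = "omnibus", method = "kruskal_wallis",
      statistic = unname(kw$statistic), p_value = kw$p.value, p_adj = NA_real_
    ),
    dunn
  )
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Survival probability") +
    ggplot2::theme_minimal()
}
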