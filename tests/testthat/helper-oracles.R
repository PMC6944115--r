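# Independent brute-force oracles used to pin down expected values. These are
# deliberately written as plain enumerations, sharing no code path with the
# package implementations they check.

# Two-sided Fisher exact P by full hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule, ties within 1e-7).
oracle_fisher2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[ord[i]] * n / i)
    adj[ord[i]] <- running_min
  }
  adj
}

# Upper-tail hypergeometric P by summing binomial-coefficient terms.
oracle_hyper_upper <- function(overlap, set_size, universe_size, n_hits) {
  ks <- overlap:min(set_size, n_hits)
  sum(vapply(ks, function(k) {
    exp(lchoose(set_size, k) + lchoose(universe_size - set_size, n_hits - k) -
          lchoose(universe_size, n_hits))
  }, numeric(1)))
}

# Brute-force dual expression/survival cutoff search: enumerate every
# midpoint split meeting the size constraint, derive the survival cutoff as
# the longest hi-group time, build the table excluding censored-below, take
# the enumerated Fisher P, and apply the documented tie rules.
oracle_dual_scan <- function(d, min_group_fraction = 0.1) {
  n <- nrow(d)
  min_n <- max(2, ceiling(min_group_fraction * n))
  v <- sort(unique(d$marker))
  best <- NULL
  for (i in seq_len(length(v) - 1)) {
    cc <- (v[i] + v[i + 1]) / 2
    hi <- d$marker > cc
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    s_cut <- max(d$time[hi])
    keep <- !(d$event == 0 & d$time < s_cut)
    long <- d$time > s_cut
    tab <- matrix(c(sum(keep & hi & !long), sum(keep & hi & long),
                    sum(keep & !hi & !long), sum(keep & !hi & long)),
                  nrow = 2, byrow = TRUE)
    p <- oracle_fisher2x2(tab)
    md <- if (any(hi & keep) && any(!hi & keep)) {
      abs(median(d$marker[hi & keep]) - median(d$marker[!hi & keep]))
    } else {
      -Inf
    }
    cand <- list(cutoff = cc, p = p, median_diff = md,
                 imbalance = abs(sum(hi) - sum(!hi)), hi = hi)
    if (is.null(best)) {
      best <- cand
    } else {
      tol <- 1e-9 * max(best$p, .Machine$double.eps) + 1e-15
      if (cand$p < best$p - tol) {
        best <- cand
      } else if (abs(cand$p - best$p) <= tol) {
        if (cand$median_diff > best$median_diff ||
            (cand$median_diff == best$median_diff && cand$imbalance < best$imbalance)) {
          best <- cand
        }
      }
    }
  }
  best
}

# Brute-force survival-time cutoff scan for fixed hi/lo groups.
oracle_survival_scan <- function(d, hi) {
  best <- NULL
  for (s in sort(unique(d$time))) {
    keep <- !(d$event == 0 & d$time < s)
    long <- d$time > s
    tab <- matrix(c(sum(keep & hi & !long), sum(keep & hi & long),
                    sum(keep & !hi & !long), sum(keep & !hi & long)),
                  nrow = 2, byrow = TRUE)
    p <- oracle_fisher2x2(tab)
    if (is.null(best) || p < best$p) best <- list(cutoff = s, p = p)
  }
  best
}

# Plain UPGMA on a distance matrix: returns successive merge heights.
oracle_upgma_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- mean(D[clusters[[i]], clusters[[j]]])
          if (dd < best_d) { best_d <- dd; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Random survival cohort with marker for oracle comparisons.
random_small_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("X%02d", seq_len(n)),
    marker = round(runif(n, 0, 100), 1),
    time = round(rexp(n, 0.5) + 0.01, 3),
    event = rbinom(n, 1, 0.8)
  )
}

# Join a generated cohort's clinical table with its marker values.
cohort_marker_data <- function(co) {
  dplyr::inner_join(co$clinical, co$marker[, c("sample_id", "value")],
                    by = "sample_id")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
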