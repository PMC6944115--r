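test_that("dual cutoff scan equals hand enumeration on a small toy", {
  # n = 8, five admissible splits at min_group_fraction 0.25 (min group 2)
  d <- data.frame(
    sample_id = paste0("s", 1:8),
    marker = c(10, 20, 30, 40, 50, 60, 70, 80),
    time = c(4.0, 3.5, 0.4, 3.0, 0.6, 0.9, 0.5, 0.7),
    event = c(1, 0, 1, 1, 1, 1, 1, 1)
  )
  res <- dual_cutoff_fisher_scan(d, marker = "marker", min_group_fraction = 0.25)
  ora <- oracle_dual_scan(d, min_group_fraction = 0.25)
  expect_equal(res$expression_cutoff, ora$cutoff)
  expect_equal(res$p_fisher, ora$p, tolerance = 1e-12)
  expect_equal(nrow(res$trace), 5)
  # chosen P is the scan minimum
  expect_true(all(res$p_fisher <= res$trace$p_fisher + 1e-12))
})

test_that("dual cutoff scan equals brute force on random small cohorts", {
  for (i in 1:40) {
    d <- random_small_cohort(n = sample(10:30, 1), seed = 500 + i)
    res <- dual_cutoff_fisher_scan(d, marker = "marker", min_group_fraction = 0.1)
    ora <- oracle_dual_scan(d, min_group_fraction = 0.1)
    expect_equal(res$expression_cutoff, ora$cutoff, info = paste("cohort", i))
    expect_equal(res$p_fisher, ora$p, tolerance = 1e-9, info = paste("cohort", i))
  }
})

test_that("stratification labels respect the ordering invariant", {
  for (i in 1:10) {
    d <- random_small_cohort(n = 24, seed = 900 + i)
    res <- dual_cutoff_fisher_scan(d, marker = "marker")
    lab <- tidy(res)
    expect_lt(max(lab$marker_value[lab$label == "lo"]),
              min(lab$marker_value[lab$label == "hi"]))
    expect_equal(res$n_hi + res$n_lo, nrow(d))
    # excluded samples are censored below the survival cutoff
    exc <- lab[lab$excluded, ]
    expect_true(all(exc$event == 0 & exc$time < res$survival_cutoff))
  }
})

test_that("scan labels are invariant under strictly monotone marker transforms", {
  d <- random_small_cohort(n = 26, seed = 77)
  r1 <- dual_cutoff_fisher_scan(d, marker = "marker")
  d2 <- d
  d2$marker <- exp(d$marker / 20)
  r2 <- dual_cutoff_fisher_scan(d2, marker = "marker")
  expect_equal(tidy(r1)$label, tidy(r2)$label)
  expect_equal(r1$p_fisher, r2$p_fisher)
  r3 <- logrank_cutoff_scan(d, marker = "marker")
  r4 <- logrank_cutoff_scan(d2, marker = "marker")
  expect_equal(tidy(r3)$label, tidy(r4)$label)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(sample_id = paste0("s", 1:8), marker = rep(5, 8),
                  time = 1:8, event = 1)
  expect_error(dual_cutoff_fisher_scan(d, marker = "marker"), "constant")
  d2 <- random_small_cohort(8, seed = 1)
  expect_error(dual_cutoff_fisher_scan(d2, marker = "marker",
                                       min_group_fraction = 0.5 + 1e-9),
               "min_group_fraction")
  d3 <- d2
  d3$event <- 0
  expect_error(logrank_cutoff_scan(d3, marker = "marker"), "No events")
})

test_that("planted cohorts are recovered exactly (spot check)", {
  co <- generate_cohort(cohort_config(seed = 42))
  res <- dual_cutoff_fisher_scan(cohort_marker_data(co), marker = "value")
  lab <- tidy(res)
  expect_setequal(lab$sample_id[lab$label == "hi"], co$truth$hi_samples)
  expect_lte(res$survival_cutoff, co$truth$config$survival_cutoff_true)
})

test_that("log-rank scan returns a lone admissible split and recovers planted thresholds", {
  # exactly one admissible split under a tight size constraint
  d <- data.frame(sample_id = paste0("s", 1:10), marker = c(rep(1, 5), rep(2, 5)),
                  time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), event = 1)
  res <- logrank_cutoff_scan(d, marker = "marker", min_group_fraction = 0.5)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$expression_cutoff, 1.5)

  # hazard ratio 4 at a known marker threshold: minimum-P cutpoint location
  # converges slowly (cube-root asymptotics), so exact recovery is checked in
  # bands: most replicates land within 2 rank positions, nearly all within 5
  dist <- integer(0)
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    set.seed(4000 + i)
    n <- 60
    hi <- rep(c(TRUE, FALSE), each = n / 2)
    d <- data.frame(
      sample_id = sprintf("r%02d", 1:n),
      marker = ifelse(hi, runif(n, 51, 100), runif(n, 0, 50)),
      time = rexp(n, rate = ifelse(hi, 2, 0.5)),
      event = 1
    )
    res <- logrank_cutoff_scan(d, marker = "marker")
    planted_rank <- sum(d$marker <= 50)
    chosen_rank <- sum(d$marker <= res$expression_cutoff)
    dist <- c(dist, abs(chosen_rank - planted_rank))
  }
  expect_gte(mean(dist <= 2), 0.6)
  expect_gte(mean(dist <= 5), 0.9)
})

test_that("survival-time cutoff scan equals brute force and handles separation", {
  # perfect separation: hi all short, lo all long
  d <- data.frame(sample_id = paste0("s", 1:10),
                  group = rep(c("hi", "lo"), each = 5),
                  time = c(0.5, 0.8, 1.1, 1.4, 1.9, 2.5, 3, 3.5, 4, 5),
                  event = 1)
  res <- survival_time_cutoff_scan(d, "group")
  expect_gte(res$cutoff, 1.9)
  expect_lt(res$cutoff, 2.5)
  expect_equal(res$p_fisher, min(res$trace$p_fisher))

  for (i in 1:30) {
    d <- random_small_cohort(12, seed = 700 + i)
    d$group <- ifelse(d$marker > median(d$marker), "hi", "lo")
    res <- survival_time_cutoff_scan(d, "group")
    ora <- oracle_survival_scan(d, d$group == "hi")
    expect_equal(res$p_fisher, ora$p, tolerance = 1e-9, info = paste("toy", i))
  }

  d_one <- data.frame(sample_id = c("a", "b"), group = c("hi", "lo"),
                      time = c(1, 1), event = c(1, 1))
  expect_error(survival_time_cutoff_scan(d_one, "group"), "distinct")
})

test_that("identical survival in both groups yields uninformative scans", {
  d <- data.frame(sample_id = paste0("s", 1:12),
                  group = rep(c("hi", "lo"), 6),
                  time = rep(c(1, 2, 3, 4, 5, 6), each = 2), event = 1)
  res <- survival_time_cutoff_scan(d, "group")
  expect_gte(res$p_fisher, 0.4)
})

test_that("quadrant tables cross-tabulate shared samples with Fisher P", {
  set.seed(55)
  ids <- sprintf("q%02d", 1:20)
  a <- tibble::tibble(sample_id = ids, label = sample(c("hi", "lo"), 20, replace = TRUE))
  b <- tibble::tibble(sample_id = ids, label = sample(c("hi", "lo"), 20, replace = TRUE))
  qt <- quadrant_table(a, b, names = c("F1", "F2"))
  expect_equal(sum(qt$table), 20)
  expect_equal(qt$p_fisher, fisher_exact_two_sided(qt$table))
  expect_equal(qt$p_fisher, oracle_fisher2x2(qt$table), tolerance = 1e-12)

  # all-hi degenerate table
  all_hi <- tibble::tibble(sample_id = ids, label = "hi")
  expect_equal(quadrant_table(all_hi, all_hi)$p_fisher, 1)
  # disjoint sample sets
  b2 <- tibble::tibble(sample_id = paste0("z", 1:5), label = "hi")
  expect_error(quadrant_table(a, b2), "No samples")
})
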