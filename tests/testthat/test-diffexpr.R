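make_expr <- function(n_genes, n_samples, seed = 1, mean = 7, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

test_that("detection filter drops only genes undetected everywhere", {
  m <- make_expr(4, 3)
  dp <- matrix(c(0.5, 0.5, 0.5,   # undetected everywhere -> out
                 0.01, 0.9, 0.9,  # detected once -> kept
                 0.01, 0.01, 0.01,
                 0.05, 0.05, 0.05), # exactly at alpha everywhere -> out
               nrow = 4, byrow = TRUE, dimnames = dimnames(m))
  out <- detection_filter(m, dp, alpha = 0.05)
  expect_setequal(rownames(out), c("g0002", "g0003"))
  expect_equal(nrow(detection_filter(m, dp, alpha = 1)), 4)
  expect_error(detection_filter(m, dp[1:3, ]), "dimensions")
})

test_that("collapse_genes keeps the highest-mean row per gene", {
  m <- make_expr(10, 4, seed = 3)
  map <- setNames(c("A", "A", "B", "B", "B", "C", "D", "E", "C", "F"), rownames(m))
  out <- collapse_genes(m, map)
  expect_equal(nrow(out), 6)
  # brute-force max-mean selection
  for (g in unique(map)) {
    rows <- names(map)[map == g]
    best <- rows[which.max(rowMeans(m[rows, , drop = FALSE]))]
    expect_equal(out[g, ], m[best, ], ignore_attr = TRUE)
  }
  # one row per gene is the identity
  ident <- collapse_genes(m, setNames(rownames(m), rownames(m)))
  expect_equal(ident[rownames(m), ], m)
  expect_error(collapse_genes(m, map[1:5]), "cover")
})

test_that("reference gene filter keeps genes above the reference floor", {
  m <- matrix(
    c(rep(10, 4),            # high median, but var 0
      10, 12, 8, 11,         # high median, high sd
      1, 1.2, 0.8, 1.1,      # low median, low sd
      5, 6, 4, 5.5,          # the reference
      5.1, 9, 2, 7,          # median above, sd above
      4, 4.5, 3.5, 4.2),     # below reference median
    nrow = 6, byrow = TRUE,
    dimnames = list(c("flat", "good", "low", "REF", "good2", "dim"),
                    paste0("s", 1:4))
  )
  out <- reference_gene_filter(m, "REF")
  expect_setequal(rownames(out), c("good", "good2", "REF"))
  expect_error(reference_gene_filter(m, "missing"), "not present")
})

test_that("moderated DE handles degenerate genes and recovers planted shifts", {
  m <- make_expr(200, 10, seed = 5)
  grp <- setNames(rep(c("hi", "lo"), each = 5), colnames(m))
  m["g0001", ] <- 4                    # identical in both groups
  m["g0002", ] <- rep(c(6, 4), each = 5) # exact shift 2, zero within-group var
  de <- moderated_de(m, grp)
  g1 <- de[de$gene == "g0001", ]
  expect_equal(g1$logFC, 0)
  expect_equal(g1$p_value, 1)
  g2 <- de[de$gene == "g0002", ]
  expect_equal(g2$logFC, 2)
  expect_equal(g2$fdr, min(de$fdr))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_error(moderated_de(m[, 1:6], setNames(c("hi", rep("lo", 5)), colnames(m)[1:6])),
               "two samples per group")
})

test_that("prior df 0 reduces to ordinary equal-variance t-statistics", {
  m <- make_expr(50, 12, seed = 6)
  grp <- setNames(rep(c("hi", "lo"), each = 6), colnames(m))
  de0 <- moderated_de(m, grp, prior_df = 0)
  for (g in c("g0001", "g0025", "g0050")) {
    tt <- t.test(m[g, 1:6], m[g, 7:12], var.equal = TRUE)
    expect_equal(de0$t[de0$gene == g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de0$p_value[de0$gene == g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  m <- make_expr(500, 12, seed = 7)
  # heteroscedastic genes so the prior df is finite and informative
  set.seed(17)
  m <- m * runif(500, 0.3, 3)
  m[1:20, 1:6] <- m[1:20, 1:6] + 1
  grp <- setNames(rep(c("hi", "lo"), each = 6), colnames(m))
  de <- moderated_de(m, grp)
  fit <- limma::eBayes(limma::lmFit(m, cbind(int = 1, hi = as.numeric(grp == "hi"))))
  expect_true(is.finite(attr(de, "prior_df")))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[de$gene, "hi"]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[de$gene, "hi"]), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(5:60, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DEG selection applies both thresholds and the direction flag", {
  de <- tibble::tibble(
    gene = paste0("g", 1:5),
    logFC = c(2, -2, 0.5, 1.5, 1.0),
    t = 0, p_value = c(0.001, 0.001, 0.5, 0.01, 0.2),
    fdr = c(0.005, 0.005, 0.6, 0.03, 0.3)
  )
  expect_setequal(select_degs(de, 1, 0), de$gene)
  expect_equal(select_degs(de, 0, Inf), character(0))
  expect_setequal(select_degs(de, 0.05, 1.5), c("g1", "g2", "g4")) # threshold is inclusive
  expect_setequal(select_degs(de, 0.05, 1.5, direction = "up"), c("g1", "g4"))
  expect_setequal(select_degs(de, 0.05, 1.6), c("g1", "g2"))
})

test_that("hypergeometric ORA matches closed forms and enumeration", {
  universe <- paste0("u", 1:20)
  sets <- list(inside = universe[1:5], outside = paste0("x", 1:6))
  res <- hypergeometric_ora(universe[1:5], universe, sets["inside"],
                            min_size = 2, max_size = 500)
  expect_equal(res$p_value, 1 / choose(20, 5))
  # hits = whole universe: overlap is certain
  res_all <- hypergeometric_ora(universe, universe, sets["inside"], min_size = 2)
  expect_equal(res_all$p_value, 1)
  # disjoint set: upper tail at overlap 0 is 1
  sets2 <- list(far = universe[10:14])
  expect_equal(hypergeometric_ora(universe[1:5], universe, sets2, min_size = 2)$p_value,
               oracle_hyper_upper(0, 5, 20, 5))
  expect_error(hypergeometric_ora(c("nope"), universe, sets), "subset")

  set.seed(9)
  for (i in 1:30) {
    n_univ <- sample(10:25, 1)
    uni <- paste0("v", seq_len(n_univ))
    hits <- sample(uni, sample(2:(n_univ - 1), 1))
    st <- list(s = sample(uni, sample(2:n_univ, 1)))
    res <- hypergeometric_ora(hits, uni, st, min_size = 1, max_size = 500)
    expect_equal(res$p_value,
                 oracle_hyper_upper(res$overlap, res$set_size, n_univ, length(hits)),
                 tolerance = 1e-12)
  }
})
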