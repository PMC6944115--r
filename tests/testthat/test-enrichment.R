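rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 7, 1), nrow = n_genes,
         dimnames = list(sprintf("e%04d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_samples))))
}

test_that("a sample's own top genes give it the maximal positive score", {
  m <- rand_expr(600, 25, seed = 41)
  j <- 7
  top <- rownames(m)[order(-m[, j])][1:20]
  sc <- sample_enrichment_scores(m, list(top = top))
  expect_gt(sc["top", j], 0)
  expect_equal(unname(which.max(sc["top", ])), j)
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("scores are invariant to strictly monotone per-gene transforms", {
  m <- rand_expr(300, 15, seed = 42)
  sets <- list(a = rownames(m)[1:25], b = rownames(m)[100:140])
  s1 <- sample_enrichment_scores(m, sets)
  s2 <- sample_enrichment_scores(2^m, sets)          # same monotone map per gene
  m3 <- m
  m3[1:150, ] <- m3[1:150, ]^3                        # different map per gene block
  s3 <- sample_enrichment_scores(m3, sets)
  expect_equal(unclass(s1), unclass(s2))
  expect_equal(unclass(s1), unclass(s3))
})

test_that("adding a constant to one sample leaves correlation distances unchanged", {
  m <- rand_expr(200, 12, seed = 43)
  h1 <- correlation_cluster(m)
  m2 <- m
  m2[, 3] <- m2[, 3] + 5
  h2 <- correlation_cluster(m2)
  expect_equal(h2$height, h1$height)
  expect_equal(h2$merge, h1$merge)
})

test_that("up-shifting a signature in one sample strictly increases its score", {
  m <- rand_expr(400, 20, seed = 44)
  sig <- rownames(m)[31:60]
  s0 <- sample_enrichment_scores(m, list(sig = sig))
  set.seed(45)
  for (i in 1:15) {
    j <- sample(20, 1)
    m2 <- m
    m2[sig, j] <- m2[sig, j] + 2
    s1 <- sample_enrichment_scores(m2, list(sig = sig))
    expect_gt(s1["sig", j], s0["sig", j])
  }
})

test_that("random sets score near zero on random data", {
  m <- rand_expr(500, 20, seed = 46)
  set.seed(47)
  sets <- purrr::map(1:40, ~ sample(rownames(m), 20))
  names(sets) <- paste0("r", 1:40)
  sc <- sample_enrichment_scores(m, sets)
  expect_true(all(abs(rowMeans(sc)) < 0.1))
})

test_that("undersized sets are dropped, empty collections rejected", {
  m <- rand_expr(50, 8, seed = 48)
  expect_warning(
    sc <- sample_enrichment_scores(m, list(ok = rownames(m)[1:5], tiny = "e0001")),
    "Dropping"
  )
  expect_equal(rownames(sc), "ok")
  expect_error(
    suppressWarnings(sample_enrichment_scores(m, list(tiny = "e0001"))),
    "No gene set"
  )
})

test_that("signature prefilter removes genes below the signature floor", {
  m <- matrix(c(rep(c(10, 11, 9, 10.5), 2),       # sig1, sig2 alike
                1, 1.1, 0.9, 1,                   # below both floors -> out
                12, 12.1, 11.9, 12,               # median above -> kept
                1, 9, 2, 8),                      # sd above -> kept
              nrow = 5, byrow = TRUE,
              dimnames = list(c("sig1", "sig2", "dim", "bright", "wild"),
                              paste0("s", 1:4)))
  out <- signature_prefilter(m, c("sig1", "sig2"))
  expect_setequal(rownames(out), c("sig1", "sig2", "bright", "wild"))
})

test_that("subtype calls take the arg-max set with an nd tie band", {
  sc <- matrix(c(0.8, 0.05, 0.3,
                 0.1, 0.06, -0.2,
                 -0.5, 0.01, 0.2),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("ME", "CL", "PN"), c("x1", "x2", "x3")))
  class(sc) <- c("enrichment_scores", "matrix", "array")
  res <- classify_subtype(sc, tie_margin = 0.01)
  expect_equal(res$label, c("ME", "nd", "ME"))
  # agreement with arg-max wherever no tie applies
  no_tie <- res$margin >= 0.01
  expect_equal(res$label[no_tie],
               rownames(sc)[apply(sc[, no_tie, drop = FALSE], 2, which.max)])
})

test_that("samples with a shifted program are classified into it", {
  m <- rand_expr(300, 10, seed = 49)
  sets <- list(ME = rownames(m)[1:30], PN = rownames(m)[31:60])
  m[sets$ME, 1:5] <- m[sets$ME, 1:5] + 2
  m[sets$PN, 6:10] <- m[sets$PN, 6:10] + 2
  res <- classify_subtype(sample_enrichment_scores(m, sets))
  expect_equal(res$label, rep(c("ME", "PN"), each = 5))
})

test_that("correlation clustering follows hand UPGMA on Pearson distances", {
  m <- rand_expr(40, 4, seed = 50)
  m[, 2] <- m[, 1]                 # identical pair merges first at height 0
  hc <- correlation_cluster(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_true(all(diff(hc$height) >= -1e-12))
  D <- 1 - cor(m)
  expect_equal(hc$height, oracle_upgma_heights(D), tolerance = 1e-12)
  # a sample and its negation sit at distance 2
  m2 <- rand_expr(40, 3, seed = 51)
  m2[, 2] <- -m2[, 1]
  expect_equal(max(1 - cor(m2)), 2, tolerance = 1e-12)
  # zero-variance gene dropped with a warning
  m3 <- rand_expr(10, 4, seed = 52)
  m3[1, ] <- 3
  expect_warning(correlation_cluster(m3), "zero-variance")
})
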