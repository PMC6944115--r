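test_that("exact mixtures are recovered to numerical precision", {
  ref <- generate_reference_matrix(3, n_marker_genes = 10, n_shared_genes = 5, seed = 61)
  mix <- ref %*% c(0.6, 0.4, 0)
  m <- matrix(log2(pmax(mix, 1e-9)), ncol = 1,
              dimnames = list(rownames(ref), "mix1"))
  fr <- deconvolve(m, ref)
  expect_equal(unlist(fr[1, attr(fr, "cell_types")]),
               c(CT01 = 0.6, CT02 = 0.4, CT03 = 0), tolerance = 1e-6)
  # a single reference column maps to fraction 1
  m2 <- matrix(log2(pmax(ref[, 2], 1e-9)), ncol = 1,
               dimnames = list(rownames(ref), "pure"))
  fr2 <- deconvolve(m2, ref)
  expect_equal(fr2$CT02, 1, tolerance = 1e-9)
})

test_that("fractions are invariant to positive rescaling of a sample", {
  ref <- generate_reference_matrix(4, seed = 62)
  mx <- generate_mixtures(ref, n = 5, noise_sd = 0, seed = 63)
  f1 <- deconvolve(mx$expression, ref)
  f2 <- deconvolve(mx$expression + 3, ref) # x8 on the linear scale
  cts <- attr(f1, "cell_types")
  expect_equal(as.matrix(f1[, cts]), as.matrix(f2[, cts]), tolerance = 1e-9)
})

test_that("noisy mixtures are recovered within the expected error", {
  ref <- generate_reference_matrix(5, seed = 64)
  mx <- generate_mixtures(ref, n = 50, noise_sd = 0.1, seed = 65)
  fr <- deconvolve(mx$expression, ref)
  err <- mean(abs(as.matrix(fr[, attr(fr, "cell_types")]) - t(mx$weights)))
  expect_lte(err, 0.05)
})

test_that("a rank-deficient reference is rejected naming the collinear column", {
  ref <- generate_reference_matrix(3, seed = 66)
  bad <- cbind(ref, CT_dup = 2 * ref[, 1])
  m <- matrix(log2(pmax(ref[, 1], 1e-9)), ncol = 1,
              dimnames = list(rownames(ref), "s"))
  expect_error(deconvolve(m, bad), "rank-deficient")
  expect_error(deconvolve(m, ref[, 1, drop = FALSE]), "at least 2")
})

test_that("purity correction rescales to the non-tumour compartment", {
  fr <- tibble::tibble(sample_id = c("a", "b"), CT01 = c(0.5, 0.2), CT02 = c(0.5, 0.8))
  attr(fr, "cell_types") <- c("CT01", "CT02")
  pur <- tibble::tibble(sample_id = c("a", "b"), purity = c(0.7, 1))
  out <- purity_correct(fr, pur)
  expect_equal(out$CT01, c(0.15, 0))
  expect_equal(out$CT02, c(0.15, 0))
  expect_equal(out$nontumor_fraction, c(0.3, 0))
  # conservation: absolute fractions plus purity account for the sample
  expect_equal(out$CT01 + out$CT02 + pur$purity, c(1, 1))
  # purity 0: absolute equals relative
  out0 <- purity_correct(fr, tibble::tibble(sample_id = c("a", "b"), purity = c(0, 0)))
  expect_equal(out0$CT01, fr$CT01)
  expect_error(purity_correct(fr, tibble::tibble(sample_id = c("a", "b"), purity = c(1.2, 0))),
               "\\[0, 1\\]")
})

test_that("infiltrate scores track planted mixing and flag pure tumours", {
  set.seed(67)
  n <- 20
  imm <- sprintf("IM%02d", 1:10)
  stro <- sprintf("ST%02d", 1:6)
  bg <- sprintf("BG%03d", 1:200)
  mixing <- seq(0, 0.9, length.out = n) # planted infiltrate fraction; sample 1 pure
  base <- rbind(
    matrix(rnorm(10 * n, 5, 0), nrow = 10) + 4 * outer(rep(1, 10), mixing),
    matrix(rnorm(6 * n, 5, 0), nrow = 6) + 4 * outer(rep(1, 6), mixing),
    matrix(rnorm(200 * n, 7, 1), nrow = 200)
  )
  dimnames(base) <- list(c(imm, stro, bg), sprintf("p%02d", 1:n))
  inf <- infiltrate_scores(base, imm, stro)
  expect_equal(inf$combined_score, inf$immune_score + inf$stromal_score)
  # purity decreasing in the planted mixing fraction; the rank statistic
  # carries a small interleaving noise from the background genes, so the
  # ordering is checked in rank terms
  expect_lte(cor(inf$purity, mixing, method = "spearman"), -0.97)
  expect_gte(inf$purity[1], 0.9)
  expect_equal(min(inf$purity), inf$purity[n])
  # with measurement noise the ordering still holds in rank terms
  m2 <- base
  m2[c(imm, stro), ] <- m2[c(imm, stro), ] + rnorm(16 * n, sd = 0.3)
  inf2 <- infiltrate_scores(m2, imm, stro)
  expect_lte(cor(inf2$purity, mixing, method = "spearman"), -0.9)
  expect_error(infiltrate_scores(base, c("nope1", "nope2"), stro), "at least 2")
})

test_that("marker-fraction correlations recover planted relations", {
  fr <- tibble::tibble(sample_id = sprintf("m%02d", 1:30))
  set.seed(68)
  mk <- setNames(runif(30, 0, 300), fr$sample_id)
  fr$CT01 <- unname(mk) / 300                             # r = 1
  fr$CT02 <- -unname(mk)                                  # r = -1
  fr$CT03 <- 0.002 * unname(mk) + rnorm(30, sd = 0.1)     # planted r ~ 0.87
  attr(fr, "cell_types") <- c("CT01", "CT02", "CT03")
  res <- marker_fraction_correlation(fr, mk)
  expect_equal(res$estimate[res$cell_type == "CT01"], 1, tolerance = 1e-12)
  expect_equal(res$estimate[res$cell_type == "CT02"], -1, tolerance = 1e-12)
  planted_r <- cor(0.002 * unname(mk), unname(mk)) # = 1; realised with noise
  expect_equal(res$estimate[res$cell_type == "CT03"],
               cor(fr$CT03, unname(mk)), tolerance = 1e-12)
  expect_gt(res$estimate[res$cell_type == "CT03"], 0.75)
  expect_error(marker_fraction_correlation(fr[1:2, ], mk[1:2]), "at least 3")
})

test_that("purity-corrected fractions recover the planted marker association", {
  hits <- 0
  for (sd in 1:5) {
    co <- generate_cohort(cohort_config(n_samples = 30, seed = 100 + sd))
    fr <- deconvolve(co$mixture, co$reference)
    pur <- tibble::tibble(sample_id = names(co$truth$purity),
                          purity = unname(co$truth$purity))
    fr_abs <- purity_correct(fr, pur)
    mk <- setNames(co$marker$value, co$marker$sample_id)
    res <- marker_fraction_correlation(fr_abs, mk)
    # CT01 carries the planted marker-linked tilt
    r1 <- res$estimate[res$cell_type == "CT01"]
    if (r1 > 0 && r1 == max(res$estimate)) hits <- hits + 1
  }
  expect_equal(hits, 5)
})
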