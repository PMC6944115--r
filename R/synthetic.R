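#' Configuration for a synthetic stratification cohort
#'
#' Bundles and validates the generator parameters. The defaults emulate the
#' structure of the motivating cohort: ~76 samples of which ~30% form a
#' marker-high subgroup with no survivor past 1.8 years, a marker-low
#' remainder whose exponential survival leaves roughly 28% of patients alive
#' past that cutoff, H-score marker values on \[0, 300\], a planted
#' 30-gene upregulated program in the high group, and an immune admixture
#' whose non-tumour fraction correlates with the marker.
#'
#' @param n_samples Cohort size (default 76).
#' @param hi_fraction Fraction of marker-high samples (default 0.3); the
#'   planted high group has `round(hi_fraction * n_samples)` members.
#' @param survival_cutoff_true Survival truncation of the high group in
#'   years (default 1.8): no high sample survives past it.
#' @param hazard_hi,hazard_lo Exponential hazards (per year) of the two
#'   groups (defaults 1.2 and 0.7; the low-group default leaves
#'   `exp(-0.7 * 1.8) = 28%` of low samples alive past the cutoff).
#' @param censor_rate Probability a sample is censored, uniformly before its
#'   event (default 0.15).
#' @param n_genes Background transcriptome size (default 500).
#' @param n_signature_genes Planted upregulated program size (default 30).
#' @param signature_effect_log2 Planted log2 effect in the high group
#'   (default 1.5).
#' @param noise_sd Per-gene Gaussian noise on the log2 scale (default 0.5).
#' @param n_cell_types Reference cell types for the admixture (default 5).
#' @param purity_range Per-sample tumour purity range (default 0.4-0.95).
#' @param marker_infiltrate_corr Latent correlation between marker and
#'   non-tumour fraction (default 0.7).
#' @param seed Integer RNG seed; the whole cohort is deterministic given it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 76, hi_fraction = 0.3,
                          survival_cutoff_true = 1.8,
                          hazard_hi = 1.2, hazard_lo = 0.7,
                          censor_rate = 0.15,
                          n_genes = 500, n_signature_genes = 30,
                          signature_effect_log2 = 1.5, noise_sd = 0.5,
                          n_cell_types = 5, purity_range = c(0.4, 0.95),
                          marker_infiltrate_corr = 0.7, seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), hi_fraction = hi_fraction,
    survival_cutoff_true = survival_cutoff_true,
    hazard_hi = hazard_hi, hazard_lo = hazard_lo, censor_rate = censor_rate,
    n_genes = as.integer(n_genes), n_signature_genes = as.integer(n_signature_genes),
    signature_effect_log2 = signature_effect_log2, noise_sd = noise_sd,
    n_cell_types = as.integer(n_cell_types), purity_range = purity_range,
    marker_infiltrate_corr = marker_infiltrate_corr, seed = as.integer(seed)
  )
  n_hi <- round(cfg$hi_fraction * cfg$n_samples)
  if (cfg$n_samples < 6) abort("Need at least 6 samples.")
  if (n_hi < 2 || cfg$n_samples - n_hi < 2) {
    abort("Infeasible config: each planted group needs at least 2 samples.")
  }
  if (cfg$hazard_hi <= 0 || cfg$hazard_lo <= 0) abort("Hazards must be positive.")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  if (cfg$survival_cutoff_true <= 0) abort("`survival_cutoff_true` must be positive.")
  if (length(cfg$purity_range) != 2 || any(cfg$purity_range < 0 | cfg$purity_range > 1) ||
      diff(cfg$purity_range) <= 0) {
    abort("`purity_range` must be an increasing pair in [0, 1].")
  }
  if (abs(cfg$marker_infiltrate_corr) > 1) abort("`marker_infiltrate_corr` must be in [-1, 1].")
  if (cfg$n_signature_genes > cfg$n_genes) abort("More signature genes than genes.")
  if (cfg$n_cell_types < 2) abort("Need at least 2 cell types.")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces every input the pipeline consumes, deterministically from the
#' config seed:
#'
#' * **clinical**: survival times (high group truncated-exponential below
#'   `survival_cutoff_true` via inverse-CDF sampling, so the group contains
#'   no survivor past the cutoff; low group untruncated), independent
#'   censoring at a Uniform(0, T) time with probability `censor_rate`, and
#'   two binary covariates;
#' * **marker**: H-scores with separated supports (low group on 20-150,
#'   high on 180-300). Within the low group the sample with the longest
#'   observed survival receives the largest low marker value; this is the
#'   identifiability condition of the planted split — absorbing that sample
#'   into the high group raises the derived survival cutoff past every long
#'   survivor and collapses the Fisher table, so the planted partition is
#'   the minimum-P split (see the methods vignette);
#' * **pixel_counts**: intensity-bin counts (1000 pixels/sample) that
#'   reproduce each marker H-score through [hscore()] to within 0.5 units;
#' * **expression**: log2 background with a planted upregulated program of
#'   `n_signature_genes` genes in the high group, a `MARKER1` transcript
#'   tracking the marker, and immune/stromal gene blocks whose level
#'   increases with the non-tumour fraction;
#' * **mixture**: log2 bulk profiles over the reference-signature genes,
#'   built as purity x tumour background + (1 - purity) x reference
#'   composition, for the deconvolution stage;
#' * **truth**: every planted parameter (high set, signature genes, purity,
#'   composition, achieved censoring rate, ...).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `clinical`,
#'   `marker`, `pixel_counts`, `expression`, `mixture`, `reference`,
#'   `immune_set`, `stromal_set`, and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_hi <- round(config$hi_fraction * n)
  ids <- sprintf("S%03d", seq_len(n))
  hi <- c(rep(TRUE, n_hi), rep(FALSE, n - n_hi))

  # Survival: truncated exponential for the high group (inverse CDF), free
  # exponential for the low group.
  cutoff <- config$survival_cutoff_true
  u <- runif(n_hi)
  t_hi <- -log(1 - u * (1 - exp(-config$hazard_hi * cutoff))) / config$hazard_hi
  t_lo <- rexp(n - n_hi, rate = config$hazard_lo)
  t_true <- c(t_hi, t_lo)
  censored <- runif(n) < config$censor_rate
  time <- ifelse(censored, runif(n) * t_true, t_true)
  time <- pmax(time, 1e-4)
  event <- as.numeric(!censored)

  # Marker with separated supports; the low sample with the longest observed
  # time anchors the top of the low range (identifiability of the split).
  marker <- numeric(n)
  marker[hi] <- runif(n_hi, 180, 300)
  marker[!hi] <- runif(n - n_hi, 20, 150)
  # Identifiability anchors: in each group, the sample with the longest
  # observed time carries the group's largest marker value, so the planted
  # partition is the minimum-P split (any absorption past the low anchor
  # drags the derived survival cutoff past every long survivor; any interior
  # trim keeps the high anchor and thus the survival cutoff).
  lo_idx <- which(!hi)
  anchor <- lo_idx[which.max(time[lo_idx])]
  top_lo <- lo_idx[which.max(marker[lo_idx])]
  marker[c(anchor, top_lo)] <- marker[c(top_lo, anchor)]
  hi_idx <- which(hi)
  anchor_hi <- hi_idx[which.max(time[hi_idx])]
  top_hi <- hi_idx[which.max(marker[hi_idx])]
  marker[c(anchor_hi, top_hi)] <- marker[c(top_hi, anchor_hi)]

  pixel_counts <- purrr::map_dfr(seq_len(n), function(i) {
    cnt <- hscore_to_bins(marker[i], total = 1000)
    tibble(sample_id = ids[i], marker = "MARKER1",
           n0 = cnt[1], n1 = cnt[2], n2 = cnt[3], n3 = cnt[4])
  })

  # Purity / non-tumour fraction, latently correlated with the marker.
  r <- config$marker_infiltrate_corr
  z <- r * as.numeric(scale(marker)) + sqrt(max(0, 1 - r^2)) * rnorm(n)
  nontumor_range <- 1 - rev(config$purity_range)
  nontumor <- nontumor_range[1] + diff(nontumor_range) * pnorm(z)
  purity <- 1 - nontumor

  # Tumour transcriptome with the planted program and infiltrate-tracking
  # immune/stromal blocks.
  gene_ids <- c("MARKER1", sprintf("G%04d", seq_len(config$n_genes - 1)))
  sig_genes <- sample(setdiff(gene_ids, "MARKER1"), config$n_signature_genes)
  base_mean <- runif(config$n_genes, 4, 10)
  expr <- matrix(rnorm(config$n_genes * n, mean = base_mean, sd = config$noise_sd),
                 nrow = config$n_genes, dimnames = list(gene_ids, ids))
  expr[sig_genes, hi] <- expr[sig_genes, hi] + config$signature_effect_log2
  # The marker transcript tracks the protein but is kept modest in level and
  # spread so it works as the reference-gene filter floor.
  expr["MARKER1", ] <- 4.5 + 1.0 * (marker - min(marker)) / diff(range(marker)) +
    rnorm(n, sd = config$noise_sd / 2)
  immune_set <- sprintf("IMM%02d", 1:20)
  stromal_set <- sprintf("STR%02d", 1:10)
  imm_base <- runif(length(immune_set), 5, 7)
  str_base <- runif(length(stromal_set), 5, 7)
  imm_block <- outer(imm_base, rep(1, n)) + 2 * outer(rep(1, length(immune_set)), nontumor) +
    matrix(rnorm(length(immune_set) * n, sd = config$noise_sd), nrow = length(immune_set))
  str_block <- outer(str_base, rep(1, n)) + 1.5 * outer(rep(1, length(stromal_set)), nontumor) +
    matrix(rnorm(length(stromal_set) * n, sd = config$noise_sd), nrow = length(stromal_set))
  dimnames(imm_block) <- list(immune_set, ids)
  dimnames(str_block) <- list(stromal_set, ids)
  expr <- rbind(expr, imm_block, str_block)

  # Bulk mixtures over the reference genes for the deconvolution stage.
  reference <- generate_reference_matrix(
    n_cell_types = config$n_cell_types, seed = config$seed + 1L
  )
  base_w <- rexp(config$n_cell_types) + 0.2
  tilt <- outer(c(1.5, rep(0, config$n_cell_types - 1)), as.numeric(scale(marker)))
  comp <- base_w * exp(tilt)
  comp <- sweep(comp, 2, colSums(comp), "/")
  dimnames(comp) <- list(colnames(reference), ids)
  tumor_profile <- runif(nrow(reference), 5, 30)
  mixture_lin <- tumor_profile %o% purity + (reference %*% comp) %*% diag(nontumor)
  mixture_lin <- mixture_lin * exp(matrix(rnorm(length(mixture_lin), sd = 0.05),
                                          nrow = nrow(mixture_lin)))
  colnames(mixture_lin) <- ids
  mixture <- log2(mixture_lin)

  clinical <- tibble(
    sample_id = ids, time = time, event = event,
    idh1 = rbinom(n, 1, 0.16), ctx = rbinom(n, 1, 0.6)
  )
  marker_tbl <- tibble(sample_id = ids, value = marker, marker = "MARKER1",
                       kind = "hscore")[, c("sample_id", "marker", "kind", "value")]
  truth <- list(
    config = unclass(config),
    hi_samples = ids[hi],
    n_hi = n_hi,
    anchor_sample = ids[anchor],
    expression_cutoff_range = c(max(marker[!hi]), min(marker[hi])),
    signature_genes = sort(sig_genes),
    immune_set = immune_set, stromal_set = stromal_set,
    purity = setNames(purity, ids),
    nontumor_fraction = setNames(nontumor, ids),
    composition = comp,
    achieved_censor_rate = mean(event == 0),
    true_times = setNames(t_true, ids)
  )
  structure(
    list(clinical = clinical, marker = marker_tbl, pixel_counts = pixel_counts,
         expression = expr, mixture = mixture, reference = reference,
         immune_set = immune_set, stromal_set = stromal_set, truth = truth),
    class = "synthetic_cohort"
  )
}

# Intensity-bin counts whose H-score reproduces `h`: the target mean
# intensity h/100 is split between its two neighbouring classes.
hscore_to_bins <- function(h, total = 1000) {
  stopifnot(h >= 0, h <= 300)
  x <- h / 100
  i <- min(floor(x), 2)
  frac <- x - i
  p <- numeric(4)
  p[i + 1] <- 1 - frac
  p[i + 2] <- frac
  cnt <- round(total * p)
  cnt[i + 1] <- cnt[i + 1] + (total - sum(cnt))
  as.integer(cnt)
}

#' Reference signature matrix for deconvolution tests
#'
#' Builds a well-conditioned non-negative genes x cell-types matrix: each
#' type gets a block of private marker genes expressed high in that type and
#' near zero elsewhere, plus a block of shared moderately expressed genes.
#'
#' @param n_cell_types Number of cell types (default 5).
#' @param n_marker_genes Private marker genes per type (default 30).
#' @param n_shared_genes Shared background genes (default 20).
#' @param seed RNG seed.
#' @return A numeric matrix with cell types as columns; attributes
#'   `marker_genes` (list per type) and `condition_number`.
#' @export
generate_reference_matrix <- function(n_cell_types = 5, n_marker_genes = 30,
                                      n_shared_genes = 20, seed = 1) {
  if (n_cell_types < 2) abort("Need at least 2 cell types.")
  set.seed(seed)
  types <- sprintf("CT%02d", seq_len(n_cell_types))
  n_genes <- n_cell_types * n_marker_genes + n_shared_genes
  genes <- sprintf("REF%04d", seq_len(n_genes))
  ref <- matrix(runif(n_genes * n_cell_types, 0, 15), nrow = n_genes,
                dimnames = list(genes, types))
  marker_genes <- list()
  for (k in seq_len(n_cell_types)) {
    idx <- ((k - 1) * n_marker_genes + 1):(k * n_marker_genes)
    ref[idx, ] <- runif(length(idx) * n_cell_types, 0, 5)
    ref[idx, k] <- runif(length(idx), 300, 800)
    marker_genes[[types[k]]] <- genes[idx]
  }
  if (n_shared_genes > 0) {
    idx <- (n_cell_types * n_marker_genes + 1):n_genes
    ref[idx, ] <- runif(length(idx) * n_cell_types, 40, 120)
  }
  structure(ref, marker_genes = marker_genes, condition_number = kappa(ref))
}

#' Random mixtures of reference profiles
#'
#' Convenience generator for deconvolution recovery experiments: draws
#' random simplex weights per mixture, forms the linear combinations of the
#' reference columns and optionally applies multiplicative log-normal noise.
#'
#' @param reference A reference matrix (see [generate_reference_matrix()]).
#' @param n Number of mixtures (default 50).
#' @param noise_sd Standard deviation of the log-normal multiplicative
#'   noise on the linear scale (default 0, noiseless).
#' @param seed RNG seed.
#' @return A list: `expression` (log2 genes x mixtures matrix) and
#'   `weights` (cell types x mixtures, columns sum to 1).
#' @export
generate_mixtures <- function(reference, n = 50, noise_sd = 0, seed = 1) {
  set.seed(seed)
  k <- ncol(reference)
  w <- matrix(rexp(k * n), nrow = k)
  w <- sweep(w, 2, colSums(w), "/")
  dimnames(w) <- list(colnames(reference), sprintf("MIX%03d", seq_len(n)))
  y <- reference %*% w
  if (noise_sd > 0) {
    y <- y * exp(matrix(rnorm(length(y), sd = noise_sd), nrow = nrow(y)))
  }
  y <- pmax(y, 1e-9)
  colnames(y) <- colnames(w)
  list(expression = log2(y), weights = w)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `clinical.csv`, `marker.csv`, `pixel_counts.csv`,
#' `expression.tsv`, `mixture.tsv`, `reference.tsv` and `truth.json` into
#' `dir`. Re-running with the same config produces byte-identical files.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(cohort$marker, file.path(dir, "marker.csv"))
  readr::write_csv(cohort$pixel_counts, file.path(dir, "pixel_counts.csv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression(cohort$mixture, file.path(dir, "mixture.tsv"))
  write_expression(cohort$reference, file.path(dir, "reference.tsv"))
  truth <- cohort$truth
  truth$composition <- as.data.frame(truth$composition)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
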