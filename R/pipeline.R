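#' Run the marker-stratification workflow end to end
#'
#' Ties the stages together in dependency order: IHC scoring (when pixel
#' counts are supplied), survival-driven marker stratification, moderated
#' differential expression on the reference-filtered transcriptome,
#' signature construction, optional gene-set enrichment/subtype scoring and
#' optional purity-corrected deconvolution. Every stage's parameters, the
#' seed, and the effective configuration are echoed into the output
#' directory together with a manifest of MD5 checksums, so a run is
#' reproducible from its own outputs.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   * `clinical` (path, required), `expression` (path, required),
#'   * one of `marker` (path to a scored marker CSV with columns
#'     `sample_id`, `marker`, `value`) or `pixel_counts` (path; H-scores are
#'     computed),
#'   * optional `gmt` (subtype/collection sets), `reference` (deconvolution
#'     signature matrix TSV), `immune_set`/`stromal_set` (set names inside
#'     the GMT used for infiltrate scoring),
#'   * `out_dir` (required), `seed` (default 1), and a `params` list
#'     overriding stage defaults (`marker_name`, `method` =
#'     `"dual_fisher"`/`"logrank_scan"`, `min_group_fraction`,
#'     `reference_gene`, `deg_fdr_max`, `deg_lfc_min`,
#'     `enrichment_cutoff`).
#' @return The output directory path, invisibly. Outputs: `labels.csv`,
#'   `stratification.json`, `de.tsv`, `signature.json`, `signature.gmt`,
#'   optionally `enrichment_scores.tsv`, `subtypes.csv`, `fractions.csv`,
#'   `infiltrate.csv`, `correlations.csv`, plus `config.yaml` and
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  defaults <- list(
    seed = 1L,
    params = list(
      marker_name = NULL, method = "dual_fisher", min_group_fraction = 0.1,
      reference_gene = NULL, deg_fdr_max = 0.015, deg_lfc_min = 0.89,
      enrichment_cutoff = -0.05
    )
  )
  config$params <- modifyList(defaults$params, config$params %||% list())
  config$seed <- config$seed %||% defaults$seed

  for (req in c("clinical", "expression", "out_dir")) {
    if (is.null(config[[req]])) abort(sprintf("Config is missing `%s`.", req))
  }
  if (is.null(config$marker) && is.null(config$pixel_counts)) {
    abort("Config needs `marker` or `pixel_counts`.")
  }
  # Validate every input path before any stage runs.
  paths <- purrr::compact(config[c("clinical", "expression", "marker",
                                   "pixel_counts", "gmt", "reference")])
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(sprintf("Missing input file(s): %s.",
                  paste(sprintf("%s (%s)", unlist(missing), names(missing)), collapse = ", ")))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  clinical <- stage("read_clinical", function() read_clinical(config$clinical))
  expr <- stage("read_expression", function() read_expression(config$expression))

  marker_tbl <- stage("marker", function() {
    if (!is.null(config$marker)) {
      df <- readr::read_csv(config$marker, show_col_types = FALSE, progress = FALSE)
      if (!all(c("sample_id", "marker", "value") %in% names(df))) {
        abort("Marker CSV needs columns sample_id, marker, value.")
      }
      as_tibble(df)
    } else {
      counts <- read_pixel_counts(config$pixel_counts)
      ihc_scores(counts, kinds = "hscore")
    }
  })
  marker_name <- config$params$marker_name %||% marker_tbl$marker[1]
  marker_tbl <- marker_tbl[marker_tbl$marker == marker_name, ]
  if (nrow(marker_tbl) == 0) abort(sprintf("No rows for marker `%s`.", marker_name))

  strat <- stage("stratification", function() {
    d <- dplyr::inner_join(clinical, marker_tbl[, c("sample_id", "value")],
                           by = "sample_id")
    if (config$params$method == "dual_fisher") {
      dual_cutoff_fisher_scan(d, marker = "value",
                              min_group_fraction = config$params$min_group_fraction)
    } else {
      logrank_cutoff_scan(d, marker = "value",
                          min_group_fraction = config$params$min_group_fraction)
    }
  })
  labels <- tidy(strat)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"))
  jsonlite::write_json(
    c(glance(strat), list(trace = strat$trace,
                          table = as.data.frame(strat$table))),
    file.path(out_dir, "stratification.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  de_expr <- stage("reference_filter", function() {
    rg <- config$params$reference_gene
    if (is.null(rg)) expr else reference_gene_filter(expr, rg)
  })
  groups <- setNames(labels$label, labels$sample_id)
  de <- stage("moderated_de", function() moderated_de(de_expr, groups))
  readr::write_delim(de, file.path(out_dir, "de.tsv"), delim = "\t")

  sig <- stage("signature", function() {
    degs <- select_degs(de, config$params$deg_fdr_max, config$params$deg_lfc_min)
    if (length(degs) < 2) abort("Fewer than 2 first-round DEGs at the configured thresholds.")
    surv_cut <- if (!is.na(strat$survival_cutoff)) {
      strat$survival_cutoff
    } else {
      hi_ids <- labels$sample_id[labels$label == "hi"]
      max(clinical$time[clinical$sample_id %in% hi_ids])
    }
    build_signature(de_expr[degs, , drop = FALSE], groups, clinical, surv_cut,
                    enrichment_cutoff = config$params$enrichment_cutoff,
                    scoring_x = de_expr)
  })
  jsonlite::write_json(
    list(genes = sig$genes, thresholds_used = as.list(sig$thresholds_used),
         separation_p = sig$separation_p,
         enrichment_cutoff = sig$enrichment_cutoff,
         survival_cutoff = sig$survival_cutoff, scores = sig$scores),
    file.path(out_dir, "signature.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_gmt(list(signature = sig$genes), file.path(out_dir, "signature.gmt"))

  if (!is.null(config$gmt)) {
    stage("enrichment", function() {
      sets <- read_gmt(config$gmt)
      sc <- suppressWarnings(sample_enrichment_scores(expr, sets))
      readr::write_delim(
        dplyr::bind_cols(tibble(set = rownames(sc)), as_tibble(unclass(sc))),
        file.path(out_dir, "enrichment_scores.tsv"), delim = "\t"
      )
      readr::write_csv(classify_subtype(sc), file.path(out_dir, "subtypes.csv"))
    })
  }

  if (!is.null(config$reference)) {
    stage("deconvolution", function() {
      ref <- read_expression(config$reference)
      imm <- config$immune_set %||% "immune"
      str <- config$stromal_set %||% "stromal"
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else list()
      if (all(c(imm, str) %in% names(sets))) {
        inf <- infiltrate_scores(expr, sets[[imm]], sets[[str]])
        readr::write_csv(inf, file.path(out_dir, "infiltrate.csv"))
        fr <- deconvolve(expr, ref)
        fr_abs <- purity_correct(fr, inf)
        readr::write_csv(fr_abs, file.path(out_dir, "fractions.csv"))
        mk <- setNames(marker_tbl$value, marker_tbl$sample_id)
        readr::write_csv(marker_fraction_correlation(fr_abs, mk),
                         file.path(out_dir, "correlations.csv"))
      } else {
        fr <- deconvolve(expr, ref)
        readr::write_csv(fr, file.path(out_dir, "fractions.csv"))
      }
    })
  }

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  # Result files only: the config echo embeds the output path itself, so it
  # would make otherwise-identical runs hash differently.
  outputs <- setdiff(list.files(out_dir), c("manifest.json", "config.yaml"))
  manifest <- list(
    seed = config$seed,
    files = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$files) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
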