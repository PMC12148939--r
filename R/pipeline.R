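#' Read and validate a pipeline configuration
#'
#' YAML configuration with a `scenario` block (synthetic data: `type` one of
#' `"neutral"`, `"planted_classes"`, `"background_private"`, plus its
#' parameters) or an `inputs` block (paths: `sync`, `traits`, `design`,
#' optional `gff3`), a `thresholds` block (`q_detect`, `q_class`,
#' `offset_quantile`) and a master `seed`.  Thresholds are validated before
#' any computation.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config$thresholds <- config$thresholds %||% list()
  th <- config$thresholds
  config$thresholds$q_detect <- th$q_detect %||% 1e-4
  config$thresholds$q_class <- th$q_class %||% 1e-2
  config$thresholds$offset_quantile <- th$offset_quantile %||% 0.001
  config$seed <- config$seed %||% 1
  config$proxy_offset <- config$proxy_offset %||% 3
  with(config$thresholds, {
    if (q_detect <= 0 || q_detect >= 0.5) abort("`q_detect` must be in (0, 0.5)")
    if (q_class <= 0 || q_class >= 0.5) abort("`q_class` must be in (0, 0.5)")
    if (offset_quantile <= 0 || offset_quantile >= 1) {
      abort("`offset_quantile` must be in (0, 1)")
    }
  })
  if (is.null(config$scenario) && is.null(config$inputs)) {
    abort("config needs a `scenario` or an `inputs` block")
  }
  config
}

pipeline_stage <- function(name, quiet, code) {
  t0 <- Sys.time()
  if (!quiet) message("[", name, "] ...")
  out <- tryCatch(force(code), error = function(e) {
    abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> drift-null scan -> pleiotropy classification (and
#' gene mapping when an annotation is given) -> change-vector geometry at
#' the phenotypic and genomic level -> reference-anchored offsets.  All
#' stage tables are written as TSV and a machine-readable `summary.json`
#' collects per-line Ne, candidate and class counts, regime-level geometry
#' summaries and the offset correlations.  Re-running with the same
#' configuration and seed reproduces the outputs byte-identically.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the main stage objects and the summary.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  exp <- pipeline_stage("data", quiet, {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      args <- sc[setdiff(names(sc), "type")]
      args$seed <- args$seed %||% config$seed
      switch(sc$type %||% "neutral",
             neutral = do.call(scenario_neutral, args),
             planted_classes = do.call(scenario_planted_classes, args),
             background_private = do.call(scenario_background_private, args),
             abort(paste("unknown scenario type:", sc$type)))
    } else {
      inp <- config$inputs
      design <- readr::read_tsv(inp$design, show_col_types = FALSE)
      class(design) <- c("er_design", class(design))
      snp <- sync_frequencies(read_sync(inp$sync), design)
      traits <- read_trait_table(inp$traits)
      structure(list(snp = snp, traits = traits, design = design),
                class = "er_experiment")
    }
  })

  scan <- pipeline_stage("detect", quiet, {
    drift_scan(exp, q_detect = th$q_detect, q_class = th$q_class,
               proxy_offset = config$proxy_offset)
  })

  calls <- pipeline_stage("classify", quiet, {
    classify_snps(scan, th$q_class)
  })
  gene_sets <- NULL
  if (!is.null(config$inputs$gff3)) {
    gene_sets <- pipeline_stage("genes", quiet, {
      genes <- read_gene_annotation(config$inputs$gff3)
      map_snps_to_genes(left_join(calls, scan$loci, by = "locus"), genes)
    })
  }

  geom <- pipeline_stage("geometry", quiet, {
    scaled <- mean_scale_traits(exp$traits)
    cv_p <- change_vectors(scaled, exp$design)
    cv_g <- genomic_change_vectors(scan)
    list(
      angles_pheno = pairwise_angles(cv_p),
      divergence_pheno = divergence_pairs(cv_p),
      rates_pheno = evolutionary_rates(cv_p),
      angles_genomic = pairwise_angles(cv_g, correct = FALSE),
      divergence_genomic = divergence_pairs(cv_g, correct = FALSE),
      rates_genomic = evolutionary_rates(cv_g)
    )
  })

  off <- pipeline_stage("offsets", quiet, {
    ot <- offset_table(exp, scan, quantile_fraction = th$offset_quantile)
    list(table = ot, correlation = offset_correlation(ot))
  })

  pipeline_stage("write", quiet, {
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
    w(exp$design, "design.tsv")
    w(scan$records, "scan_records.tsv")
    w(scan$ne, "ne_estimates.tsv")
    w(calls, "snp_classes.tsv")
    if (!is.null(gene_sets)) w(gene_sets, "gene_sets.tsv")
    for (nm in names(geom)) w(geom[[nm]], paste0(nm, ".tsv"))
    w(off$table, "offsets.tsv")

    summary <- list(
      seed = config$seed,
      thresholds = th,
      ne = scan$ne[, c("line_id", "ne")],
      candidate_counts = glance(scan)[, c("line_id", "n_detect", "n_class")],
      class_counts = calls |>
        filter(.data$class != "none") |>
        dplyr::count(.data$background, .data$class),
      mean_angle = geom$angles_pheno |>
        filter(!is.na(.data$theta), .data$regime_a == .data$regime_b) |>
        group_by(regime = .data$regime_a) |>
        summarise(mean_theta = mean(.data$theta)),
      offset_correlation = glance(off$correlation),
      ancova = off$correlation$ancova
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    summary
  }) -> summary

  invisible(list(experiment = exp, scan = scan, calls = calls,
                 gene_sets = gene_sets, geometry = geom, offsets = off,
                 summary = summary, out_dir = out_dir))
}
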