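#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> model -> NPC -> overlap ->
#' enrichment pipeline with the canonical defaults: expression selection at
#' global p <= 0.001 and FDR <= 0.1, methylation at global p <= 0.001 and
#' FDR <= 0.2, a strict 1 Mb cis window, correlation screening at
#' |rho| > 0.5 and p < 0.05, and gene-set sizes within [20, 200].
#'
#' @param seed Master seed for every stage.
#' @param B Number of NPC permutations.
#' @param moderate Moderate variances inside NPC.
#' @param weights Liptak weights (NULL = equal).
#' @param expr_p_max,expr_q_max Expression selection thresholds.
#' @param meth_p_max,meth_q_max Methylation selection thresholds.
#' @param max_dist Cis window in bases (strict).
#' @param rho_min,p_max_corr Correlation screening thresholds.
#' @param set_min,set_max Gene-set size bounds.
#' @param simulate List of arguments forwarded to [simulate_study()]
#'   (the synthetic study specification).
#' @param gene_sets Optional path to a GMT file for the enrichment stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, B = 1000, moderate = FALSE,
                            weights = NULL,
                            expr_p_max = 0.001, expr_q_max = 0.1,
                            meth_p_max = 0.001, meth_q_max = 0.2,
                            max_dist = 1e6, rho_min = 0.5, p_max_corr = 0.05,
                            set_min = 20, set_max = 200,
                            simulate = list(), gene_sets = NULL) {
  cfg <- as.list(environment())
  thresholds <- c(cfg$expr_p_max, cfg$expr_q_max, cfg$meth_p_max,
                  cfg$meth_q_max, cfg$p_max_corr)
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must lie in (0, 1]", class = "npcomb_config_error")
  }
  if (B < 1) abort("B must be >= 1", class = "npcomb_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "npcomb_config_error")
  }
  do.call(pipeline_config, raw)
}

.config_hash <- function(config) {
  rlang::hash(config[sort(names(config))])
}

#' Run the full NPC analysis pipeline
#'
#' Executes simulate -> NPC (expression) -> NPC (methylation) -> direction
#' groups -> cis overlap -> enrichment, writing per-stage TSVs (each with a
#' config-hash comment header), a JSON run manifest and a log file into
#' `out_dir`. Re-running with the same configuration reproduces the outputs
#' byte-identically. A stage failure aborts with an error naming the stage
#' and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(unclass(config))
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      writeLines(log_lines, log_path)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "npcomb_stage_failure", stage = name)
    })
  }
  cmt <- paste("config_hash:", hash)

  study <- stage("simulate", {
    st <- do.call(simulate_study,
                  c(config$simulate, list(seed = config$seed)))
    write_design_tsv(st$design, file.path(out_dir, "design.tsv"))
    write_annotations_tsv(st$annotations,
                          file.path(out_dir, "annotations.tsv"))
    for (d in names(st$expression)) {
      write_matrix_tsv(st$expression[[d]]$values,
                       file.path(out_dir, paste0("expression_", d, ".tsv")),
                       comment = cmt)
      write_matrix_tsv(st$methylation[[d]]$values,
                       file.path(out_dir, paste0("methylation_", d, ".tsv")),
                       comment = cmt)
    }
    say("simulate: %d samples, %d genes, %d probes", nrow(st$design),
        nrow(st$expression[[1]]$values), nrow(st$methylation[[1]]$values))
    st
  })

  npc_expr <- stage("npc_expression", {
    res <- npc_global(study$expression, study$design, B = config$B,
                      seed = config$seed, moderate = config$moderate,
                      weights = config$weights)
    .write_tsv_commented(tidy(res),
                         file.path(out_dir, "npc_expression.tsv"), cmt)
    res
  })
  sel_genes <- select_features(npc_expr, config$expr_p_max, config$expr_q_max)
  say("npc_expression: %d / %d genes selected (p <= %g, q <= %g)",
      length(sel_genes), nrow(npc_expr$table), config$expr_p_max,
      config$expr_q_max)

  npc_meth <- stage("npc_methylation", {
    res <- npc_global(study$methylation, study$design, B = config$B,
                      seed = config$seed + 1L, moderate = config$moderate,
                      weights = config$weights)
    .write_tsv_commented(tidy(res),
                         file.path(out_dir, "npc_methylation.tsv"), cmt)
    res
  })
  sel_probes <- select_features(npc_meth, config$meth_p_max,
                                config$meth_q_max)
  say("npc_methylation: %d / %d probes selected (p <= %g, q <= %g)",
      length(sel_probes), nrow(npc_meth$table), config$meth_p_max,
      config$meth_q_max)

  groups <- stage("direction_groups", {
    tt <- purrr::imap(study$expression, function(ds, d) {
      fits <- fit_feature_models(ds, build_design_matrix(
        dplyr::filter(study$design, .data$dataset_id == d)))
      dplyr::bind_rows(contrast_t_statistics(fits, "HC-RR"),
                       contrast_t_statistics(fits, "RR-SP")) |>
        dplyr::mutate(dataset_id = d)
    }) |> dplyr::bind_rows()
    g <- assign_expression_groups(
      dplyr::filter(tt, .data$feature_id %in% sel_genes))
    .write_tsv_commented(g, file.path(out_dir, "direction_groups.tsv"), cmt)
    g
  })

  overlap <- stage("overlap", {
    pairs <- pair_within_distance(sel_genes, sel_probes, study$annotations,
                                  config$max_dist)
    corr <- correlate_pairs(pairs, study$expression, study$methylation,
                            study$design)
    hits <- rank_and_intersect(corr, config$rho_min, config$p_max_corr)
    .write_tsv_commented(corr, file.path(out_dir, "pair_correlations.tsv"),
                         cmt)
    .write_tsv_commented(hits, file.path(out_dir, "pairs_intersect.tsv"),
                         cmt)
    say("overlap: %d pairs within %g bases, %d intersected",
        nrow(pairs), config$max_dist, nrow(hits))
    list(pairs = pairs, correlations = corr, intersect = hits)
  })

  enrich <- stage("enrichment", {
    if (is.null(config$gene_sets)) {
      say("enrichment: no gene sets configured, stage skipped")
      NULL
    } else {
      sets <- read_gmt(config$gene_sets)
      universe <- npc_expr$table$feature_id
      coll <- filter_sets(sets, universe, config$set_min, config$set_max)
      scores <- setNames(npc_expr$table$global_p, universe)
      res <- rank_set_test(scores, coll)
      .write_tsv_commented(res, file.path(out_dir, "enrichment.tsv"), cmt)
      say("enrichment: %d sets tested, %d at q < 0.1", nrow(res),
          sum(res$q < 0.1))
      res
    }
  })

  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    B = config$B,
    package_version = as.character(utils::packageVersion("npcomb")),
    n_samples = nrow(study$design),
    feature_counts = list(
      genes_analyzed = nrow(npc_expr$table),
      genes_selected = length(sel_genes),
      genes_unselected = nrow(npc_expr$table) - length(sel_genes),
      probes_analyzed = nrow(npc_meth$table),
      probes_selected = length(sel_probes),
      probes_unselected = nrow(npc_meth$table) - length(sel_probes),
      pairs_within_window = nrow(overlap$pairs),
      pairs_intersected = nrow(overlap$intersect),
      sets_tested = if (is.null(enrich)) 0L else nrow(enrich)
    ),
    selected_genes = sel_genes,
    selected_probes = sel_probes,
    direction_groups = as.list(table(groups$pattern_group))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(manifest)
}
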