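#' Resolve a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list with two blocks:
#' `inputs` (paths: `transcriptome`, `proteome`, `phospho`, `kb_edges`,
#' `kb_sites`, `kb_roles`, optional `markers`, optional `col_map`) and
#' `params` (`source`, plus optional overrides of the documented
#' defaults).  Every default is materialized into the returned object so
#' the run manifest is self-describing.
#'
#' @param config YAML path or list.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(fdr_diff = 0.1, fdr_activity = 0.05, n_perm = 1000,
                   seed = 1L, min_targets = 3, max_len = 4, lambda = 0.1,
                   engine = "auto", source_state = -1L)
  params <- modifyList(defaults, config$params %||% list())
  if (is.null(params[["source"]])) sc_abort("config params$source is mandatory")
  inputs <- config$inputs %||% list()
  for (need in c("transcriptome", "proteome", "phospho", "kb_edges")) {
    if (is.null(inputs[[need]])) sc_abort("config inputs$%s is mandatory", need)
  }
  structure(list(inputs = inputs, params = params), class = "run_config")
}

#' Run the four-step modeling pipeline end to end
#'
#' Differential statistics on all three omics layers, phospho-by-protein
#' normalization, activity inference, naive-network construction,
#' two-run sign-consistent optimization, and (when a marker table is
#' configured) the phenotype readout.  Every intermediate artifact is
#' written into `outdir` together with a machine-readable JSON manifest
#' (input hashes, resolved parameters, package version) and a short
#' human-readable summary.
#'
#' @param config A [read_run_config()] input (path or list).
#' @param outdir Output directory; must be empty unless `force = TRUE`.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list with `activities`, `naive`, `model`,
#'   `phenotype` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  cfg <- read_run_config(config)
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    sc_abort("output directory %s is not empty (use force = TRUE)", outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pr <- cfg$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sc_abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  tabs <- stage("read", list(
    transcriptome = read_measurement_table(cfg$inputs$transcriptome,
                                           "transcript", cfg$inputs$col_map),
    proteome = read_measurement_table(cfg$inputs$proteome, "protein",
                                      cfg$inputs$col_map),
    phospho = read_measurement_table(cfg$inputs$phospho, "phosphosite",
                                     cfg$inputs$col_map)))
  kb <- stage("read", load_causal_kb(cfg$inputs$kb_edges, cfg$inputs$kb_sites,
                                     cfg$inputs$kb_roles))

  tabs <- stage("differential_stats", lapply(tabs, function(t) {
    if (all(c("reps_control", "reps_treated") %in% names(t))) {
      differential_stats(t, fdr_threshold = pr$fdr_diff)
    } else t
  }))
  for (nm in names(tabs)) {
    write_measurement_table(tabs[[nm]], file.path(outdir, paste0(nm, "_stats.tsv")))
  }

  acts <- stage("activity", activity_table(
    kb, transcriptome = tabs$transcriptome, proteome = tabs$proteome,
    phospho = tabs$phospho, n_perm = pr$n_perm, seed = pr$seed,
    min_targets = pr$min_targets, fdr_threshold = pr$fdr_activity))
  readr::write_tsv(tibble::as_tibble(acts), file.path(outdir, "activities.tsv"),
                   progress = FALSE)

  naive <- stage("network", {
    n <- build_naive_network(kb, pr$source, regulators = acts, tfs = acts,
                             max_len = pr$max_len)
    annotate_states(n, acts, source_state = pr$source_state)
  })
  write_sif(naive, file.path(outdir, "naive_network.sif"))
  write_node_attributes(naive, file.path(outdir, "naive_nodes.tsv"))

  model <- stage("optimize", two_run_optimize(
    kb, pr$source, acts, source_state = pr$source_state,
    max_len = pr$max_len, lambda = pr$lambda, engine = pr$engine,
    seed = pr$seed))
  write_sif(model, file.path(outdir, "model.sif"))
  write_node_attributes(model, file.path(outdir, "model_nodes.tsv"))

  phen <- NULL
  if (!is.null(cfg$inputs$markers)) {
    phen <- stage("phenotype", score_markers(
      model, kb, read_phenotype_markers(cfg$inputs$markers)))
    readr::write_tsv(
      dplyr::mutate(phen$marker_states,
                    regulators = vapply(.data$regulators, paste,
                                        character(1), collapse = ";")),
      file.path(outdir, "phenotype_markers.tsv"), progress = FALSE)
    readr::write_tsv(phen$phenotype_scores,
                     file.path(outdir, "phenotype_scores.tsv"), progress = FALSE)
  }

  manifest <- list(
    package = "signalcarver",
    version = as.character(utils::packageVersion("signalcarver")),
    inputs = lapply(cfg$inputs[!vapply(cfg$inputs, is.null, TRUE)],
                    function(p) if (is.character(p) && file.exists(p))
                      unname(tools::md5sum(p)) else p),
    params = pr,
    n_significant_activities = sum(acts$significant),
    model_nodes = nrow(model$nodes),
    model_edges = nrow(model$edges))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(
    sprintf("signalcarver run: source=%s state=%+d", pr$source, pr$source_state),
    sprintf("significant activities: %d / %d scored", sum(acts$significant),
            nrow(acts)),
    sprintf("optimized model: %d nodes, %d edges", nrow(model$nodes),
            nrow(model$edges))),
    file.path(outdir, "summary.txt"))
  invisible(list(activities = acts, naive = naive, model = model,
                 phenotype = phen, manifest = manifest))
}

#' Compare the results of two pipeline runs
#'
#' The paired-condition driver: activity-profile correlation, optimized
#' model comparison and (when both runs scored markers) the phenotype
#' contrast.
#'
#' @param a,b Result lists returned by [run_pipeline()].
#' @return List with `activities` ([compare_activity_profiles()]),
#'   `models` ([compare_models()]), `phenotypes`
#'   ([contrast_phenotypes()] or `NULL`).
#' @export
compare_conditions <- function(a, b) {
  list(activities = compare_activity_profiles(a$activities, b$activities),
       models = compare_models(a$model, b$model),
       phenotypes = if (!is.null(a$phenotype) && !is.null(b$phenotype)) {
         contrast_phenotypes(a$phenotype, b$phenotype)
       })
}
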