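# End-to-end driver: compile -> screen-merge -> enrich -> assemble ->
# annotate -> calibrate -> export. Every stage writes its intermediate with
# a stable name; reruns with an identical config are byte-identical.

#' Build a pipeline configuration
#'
#' @param ligands path to the raw ligand CSV (`name,smiles,class,role`).
#' @param predictions_dir directory of per-ligand prediction CSVs named
#'   `<ligand_id>.csv`.
#' @param ppi path of the causal-PPI TSV.
#' @param gmt path of the pathway gene-set GMT.
#' @param disease_pathway pathway id to filter to (must be in the GMT).
#' @param adme,locations_primary,locations_fallback,functions,docking
#'   optional annotation/calibration input paths.
#' @param alpha enrichment significance threshold.
#' @param exhaustive hydrolyze glycosides to completion.
#' @param k_hard,k_prob,sd_type calibration parameters
#'   ([confidence_model()]).
#' @param cutoffs,prob_thresholds optional explicit calibration overrides.
#' @param seed layout/fixture seed.
#' @param fixture optional list of [fixture_spec()] arguments; when present
#'   the bundle is generated under `<out_dir>/inputs` and used as the input
#'   set.
#' @return a `pcpinet_config` list.
#' @export
pipeline_config <- function(ligands = NULL, predictions_dir = NULL,
                            ppi = NULL, gmt = NULL, disease_pathway = NULL,
                            adme = NULL, locations_primary = NULL,
                            locations_fallback = NULL, functions = NULL,
                            docking = NULL, alpha = 0.05, exhaustive = TRUE,
                            k_hard = 3, k_prob = 1, sd_type = "population",
                            cutoffs = NULL, prob_thresholds = NULL,
                            seed = 1, fixture = NULL) {
  structure(list(
    ligands = ligands, predictions_dir = predictions_dir, ppi = ppi,
    gmt = gmt, disease_pathway = disease_pathway, adme = adme,
    locations_primary = locations_primary,
    locations_fallback = locations_fallback, functions = functions,
    docking = docking, alpha = alpha, exhaustive = exhaustive,
    k_hard = k_hard, k_prob = k_prob, sd_type = sd_type,
    cutoffs = cutoffs, prob_thresholds = prob_thresholds, seed = seed,
    fixture = fixture), class = "pcpinet_config")
}

#' Read a pipeline configuration from YAML
#' @param file YAML path whose keys mirror [pipeline_config()] arguments.
#' @return a `pcpinet_config`.
#' @export
read_pipeline_config <- function(file) {
  if (!file.exists(file)) stop_config("config file not found: %s", file)
  raw <- yaml::read_yaml(file)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  # resolve relative input paths against the config file's directory
  base <- dirname(normalizePath(file))
  pathkeys <- c("ligands", "predictions_dir", "ppi", "gmt", "adme",
                "locations_primary", "locations_fallback", "functions",
                "docking")
  for (k in intersect(pathkeys, names(raw))) {
    if (!is.null(raw[[k]]) && !grepl("^/", raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

.require_inputs <- function(config) {
  req <- c("ligands", "predictions_dir", "ppi", "gmt")
  for (k in req) {
    if (is.null(config[[k]])) {
      stop_config("config is missing required input '%s'", k)
    }
    if (!file.exists(config[[k]])) {
      stop_config("input '%s' not found: %s", k, config[[k]])
    }
  }
  if (is.null(config$disease_pathway)) {
    stop_config("config must name a disease_pathway")
  }
  opt <- c("adme", "locations_primary", "locations_fallback", "functions",
           "docking")
  for (k in opt) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop_config("input '%s' not found: %s", k, config[[k]])
    }
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes all stages and writes every intermediate and export under
#' `out_dir` with stable names, plus `run_manifest.json` (parameters, seed,
#' per-stage record counts) and `run.log`. Output is a pure function of
#' config + inputs: rerunning with an identical config is byte-identical.
#'
#' @param config a `pcpinet_config` or the path of a YAML config.
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @param log_level "debug", "info" or "warn".
#' @return invisible list with the key in-memory artifacts (`registry`,
#'   `network`, `model`, `simplified`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, log_level = "info") {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pcpinet_config")) {
    stop_config("config must be a pcpinet_config or a YAML path")
  }
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  old <- options(pcpinet.log_level = log_level, pcpinet.log_file = logfile)
  on.exit(options(old))

  if (!is.null(config$fixture)) {
    fixdir <- file.path(out_dir, "inputs")
    log_info("stage fixture: generating synthetic input bundle")
    spec <- do.call(fixture_spec, c(config$fixture,
                                    if (is.null(config$fixture$seed)) {
                                      list(seed = config$seed)
                                    }))
    generate_fixture_bundle(spec, fixdir)
    config$ligands <- file.path(fixdir, "ligands.csv")
    config$predictions_dir <- file.path(fixdir, "predictions")
    config$ppi <- file.path(fixdir, "ppi.tsv")
    config$gmt <- file.path(fixdir, "pathways.gmt")
    config$adme <- file.path(fixdir, "adme.csv")
    config$locations_primary <- file.path(fixdir, "locations_primary.csv")
    config$locations_fallback <- file.path(fixdir, "locations_fallback.csv")
    config$functions <- file.path(fixdir, "functions.csv")
    config$docking <- file.path(fixdir, "docking.csv")
    if (is.null(config$disease_pathway)) config$disease_pathway <- "FX05210"
  }
  .require_inputs(config)
  counts <- list()

  # stage 1: compile
  log_info("stage compile: building ligand registry")
  registry <- build_registry(config$ligands, exhaustive = config$exhaustive)
  write_registry(registry, file.path(out_dir, "registry.csv"),
                 file.path(out_dir, "relations.csv"))
  counts$registry_records <- nrow(registry$registry)
  counts$glycoside_relations <- nrow(registry$relations)

  # stage 2: screen-merge
  log_info("stage screen-merge: reading reverse-screening predictions")
  pcpis <- list()
  for (id in registry$registry$ligand_id) {
    f <- file.path(config$predictions_dir, paste0(id, ".csv"))
    if (!file.exists(f)) {
      log_warn("no prediction file for ligand '%s'", id)
      next
    }
    pcpis[[id]] <- read_target_predictions(f, id)
  }
  complete <- do.call(rbind, c(pcpis, list(make.row.names = FALSE)))
  if (is.null(complete) || nrow(complete) == 0) {
    stop_input("no predictions with nonzero probability were read")
  }
  write_pcpi_table(complete, file.path(out_dir, "complete_pcpis.csv"))
  counts$complete_pcpis <- nrow(complete)

  # stage 3: enrich
  log_info("stage enrich: pathway over-representation")
  sets <- read_gmt(config$gmt)
  enr <- overrepresentation_test(unique(complete$protein), sets,
                                 alpha = config$alpha, keep_all = TRUE)
  write_enrichment(enr[enr$adjusted_p <= config$alpha, , drop = FALSE],
                   file.path(out_dir, "enrichment.csv"))
  if (!config$disease_pathway %in% names(sets)) {
    stop_config("disease pathway '%s' is not in the GMT",
                config$disease_pathway)
  }
  row <- enr[enr$pathway_id == config$disease_pathway, ]
  overlap <- strsplit(row$overlap, ";", fixed = TRUE)[[1]]
  log_info("disease pathway %s: adjusted p = %.4g, overlap %d protein(s)",
           config$disease_pathway, row$adjusted_p, length(overlap))
  disease <- filter_to_pathway(complete, sets[[config$disease_pathway]],
                               overlap)
  write_pcpi_table(disease, file.path(out_dir, "disease_pcpis.csv"))
  counts$disease_pcpis <- nrow(disease)
  counts$disease_targets <- length(overlap)

  # stage 4: assemble
  log_info("stage assemble: joining PCPIs, PPIs and glycoside relations")
  ppis <- read_ppi_table(config$ppi)
  network <- assemble_network(disease, ppis, registry$relations, registry)
  network <- clean_network(network)
  counts$nodes <- nrow(network$nodes)
  counts$edges <- nrow(network$edges)

  # stage 5: annotate
  log_info("stage annotate: locations, pharmacokinetics, function")
  primary <- if (!is.null(config$locations_primary)) {
    read_protein_map(config$locations_primary)
  } else character(0)
  fallback <- if (!is.null(config$locations_fallback)) {
    read_protein_map(config$locations_fallback)
  } else NULL
  network <- assign_protein_locations(network, primary, fallback)
  network <- assign_ligand_locations(network)
  if (!is.null(config$adme)) {
    pk <- read_adme_table(config$adme, registry)
    network <- annotate_pharmacokinetics(network, pk)
  }
  fnmap <- if (!is.null(config$functions)) {
    read_protein_map(config$functions, value_col = "function")
  } else character(0)
  network <- annotate_protein_function(network, fnmap)
  write_network(network, file.path(out_dir, "network_nodes.csv"),
                file.path(out_dir, "network_edges.csv"))

  # stage 6: calibrate
  model <- NULL
  simplified <- NULL
  if (!is.null(config$docking)) {
    log_info("stage calibrate: docking-confidence model")
    dockings <- read_docking_table(config$docking)
    model <- confidence_model(dockings, k_hard = config$k_hard,
                              k_prob = config$k_prob,
                              sd_type = config$sd_type,
                              cutoffs = config$cutoffs,
                              prob_thresholds = config$prob_thresholds)
    write_classified_interactions(model,
                                  file.path(out_dir,
                                            "classified_interactions.csv"))
    write_confidence_config(model,
                            file.path(out_dir, "confidence_model.txt"))
    counts$docked <- model$n
    simplified <- extract_high_confidence_subnetwork(network, model = model)
    write_network(simplified, file.path(out_dir, "simplified_nodes.csv"),
                  file.path(out_dir, "simplified_edges.csv"))
    counts$simplified_nodes <- nrow(simplified$nodes)
    counts$simplified_edges <- nrow(simplified$edges)
  }

  # stage 7: export
  log_info("stage export: styled graph files")
  export_network(network, out_dir, seed = config$seed)
  if (!is.null(simplified) && nrow(simplified$nodes) > 0) {
    export_network(simplified, out_dir, seed = config$seed,
                   basename = "simplified")
  }

  manifest <- list(
    package = "pcpinet",
    version = as.character(utils::packageVersion("pcpinet")),
    seed = config$seed,
    parameters = list(alpha = config$alpha, exhaustive = config$exhaustive,
                      k_hard = config$k_hard, k_prob = config$k_prob,
                      sd_type = config$sd_type,
                      disease_pathway = config$disease_pathway),
    counts = counts,
    model = if (!is.null(model)) as.list(coef(model))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_info("pipeline complete: %d nodes, %d edges", counts$nodes,
           counts$edges)
  invisible(list(registry = registry, network = network, model = model,
                 simplified = simplified, manifest = manifest))
}
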