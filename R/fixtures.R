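# Deterministic synthetic input bundles with known ground truth.
#
# Glycosides are constructed programmatically by attaching a glucopyranose
# unit to the leading hydroxyl of a known aglycone scaffold, so the expected
# hydrolysis products are exact by construction. The bundle emulates the
# table dialects of the external tools the pipeline ingests; it tests
# plumbing and calibration math, not chemistry or biology realism.

# Aglycone scaffold library. SMILES of glycosylatable scaffolds start with
# the hydroxyl oxygen the sugar is attached to; ring numbers stay below 9 so
# the glucose template (ring digit 9) never collides.
.scaffolds <- data.frame(
  name = c("saligenin", "gallic acid", "caffeic acid", "ferulic acid",
           "vanillic acid", "p-coumaric acid", "quercetin", "luteolin",
           "apigenin", "kaempferol", "naringenin", "kuguacin-like triterpenoid",
           "ellagic acid", "oleic acid"),
  smiles = c(
    "Oc1ccccc1CO",
    "Oc1cc(C(=O)O)cc(O)c1O",
    "Oc1ccc(C=CC(=O)O)cc1O",
    "Oc1ccc(C=CC(=O)O)cc1OC",
    "Oc1ccc(C(=O)O)cc1OC",
    "Oc1ccc(C=CC(=O)O)cc1",
    "Oc1ccc(C2=C(O)C(=O)c3c(O)cc(O)cc3O2)cc1O",
    "Oc1ccc(C2=CC(=O)c3c(O)cc(O)cc3O2)cc1O",
    "Oc1ccc(C2=CC(=O)c3c(O)cc(O)cc3O2)cc1",
    "Oc1ccc(C2=C(O)C(=O)c3c(O)cc(O)cc3O2)cc1",
    "Oc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1",
    "OC1CCC2(C)C(CCC3(C)C2CCC3C(C)O)C1",
    "Oc1cc2c(=O)oc3c(O)c(O)cc4c(=O)oc(c1O)c2c34",
    "CCCCCCCCC=CCCCCCCCC(=O)O"),
  class = c("simple phenol", "phenolic acid", "phenolic acid",
            "phenolic acid", "phenolic acid", "phenolic acid", "flavonoid",
            "flavonoid", "flavonoid", "flavonoid", "flavonoid",
            "triterpenoid", "phenolic acid", "fatty acid"),
  glycosylatable = c(rep(TRUE, 13), FALSE),
  stringsAsFactors = FALSE
)

.controls <- data.frame(
  name = c("sorafenib", "vemurafenib", "alprazolam"),
  smiles = c(
    "CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1",
    "CCCS(=O)(=O)Nc1ccc(F)c(C(=O)c2c[nH]c3ncc(-c4ccc(Cl)cc4)cc23)c1F",
    "Cc1nnc2CN=C(c3ccccc3)c3cc(Cl)ccc3-n12"),
  class = "drug-control",
  role = c("positive-control", "positive-control", "negative-control"),
  stringsAsFactors = FALSE
)

.disease_gene_pool <- c("EGFR", "BRAF", "RAF1", "MAP2K2", "CTNNB1", "GSK3B",
                        "AKT1", "PIK3CA", "MTOR", "BCL2", "TP53", "TGFBR2",
                        "ARAF", "MAPK1", "MAPK3", "KRAS", "CCND1", "CASP3")
.decoy_genes <- c("GABRA1", "CYP3A4", "ABCB1", "HDAC1", "JAK2", "NOTCH1")

# Annotated-but-untargeted genes padding the enrichment background, the way
# a genome-wide annotation background dwarfs any real target list.
.background_genes <- sprintf("SYNBG%02d", 1:60)

.function_map_fixture <- c(
  EGFR = "oncogene", BRAF = "oncogene", CTNNB1 = "oncogene",
  PIK3CA = "oncogene", AKT1 = "oncogene", KRAS = "oncogene",
  TP53 = "tumor suppressor", GSK3B = "tumor suppressor",
  TGFBR2 = "tumor suppressor")

#' Attach a glucose unit to a scaffold's leading hydroxyl
#'
#' The scaffold SMILES must start with the attachment hydroxyl oxygen;
#' hydrolysis of the result regenerates the scaffold exactly.
#'
#' @param smiles scaffold SMILES starting with "O".
#' @param ring_digit SMILES ring-closure digit for the sugar ring.
#' @return glycoside SMILES.
#' @export
glycosylate <- function(smiles, ring_digit = 9) {
  if (!startsWith(smiles, "O")) {
    stop_input("scaffold SMILES must start with the attachment hydroxyl")
  }
  paste0("OCC", ring_digit, "OC(", smiles, ")C(O)C(O)C", ring_digit, "O")
}

# Run code with a fixed seed, restoring global RNG state afterwards.
.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture bundle
#'
#' @param seed integer; all randomness in the bundle derives from it.
#' @param n_ligands number of phytochemical input rows (glycosides included;
#'   one row is always the pre-listed aglycone of the first glycoside).
#' @param n_glycosides how many of the rows are constructed glucosides.
#' @param n_proteins size of the synthetic disease pathway gene set.
#' @param n_pathways number of gene sets in the GMT (disease set included).
#' @param pcpi_density per-(ligand, disease gene) probability of a predicted
#'   interaction; decoy genes are hit at a third of this rate.
#' @param prob1_fraction fraction of predictions assigned probability
#'   exactly 1 (database-recorded structures).
#' @param docking_group_params list with numeric `c(mean, sd)` for the
#'   `prob1`, `medium` and `low` docking-energy groups (kcal/mol).
#' @param n_docking integer `c(medium, low)`: how many non-probability-1
#'   interactions to dock per intended group.
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42, n_ligands = 12, n_glycosides = 4,
                         n_proteins = 12, n_pathways = 4,
                         pcpi_density = 0.45, prob1_fraction = 0.15,
                         docking_group_params = list(
                           prob1 = c(mean = -8.6, sd = 0.5),
                           medium = c(mean = -8.0, sd = 0.2),
                           low = c(mean = -5.6, sd = 0.6)),
                         n_docking = c(medium = 10, low = 10)) {
  glyc_ok <- sum(.scaffolds$glycosylatable)
  if (n_glycosides < 1 || n_glycosides > glyc_ok) {
    stop_spec("n_glycosides must be in [1, %d]", glyc_ok)
  }
  if (n_ligands < n_glycosides + 1 || n_ligands - 1 > nrow(.scaffolds)) {
    stop_spec("n_ligands must be in [n_glycosides + 1, %d]",
              nrow(.scaffolds) + 1)
  }
  if (n_proteins < 4 || n_proteins > length(.disease_gene_pool)) {
    stop_spec("n_proteins must be in [4, %d]", length(.disease_gene_pool))
  }
  if (n_pathways < 1) stop_spec("n_pathways must be >= 1")
  if (!(pcpi_density > 0 && pcpi_density <= 1)) {
    stop_spec("pcpi_density must be in (0, 1]")
  }
  if (prob1_fraction < 0 || prob1_fraction > 1) {
    stop_spec("prob1_fraction must be in [0, 1]")
  }
  for (g in c("prob1", "medium", "low")) {
    p <- docking_group_params[[g]]
    if (is.null(p) || length(p) != 2 || p[2] < 0) {
      stop_spec("docking_group_params$%s must be c(mean, sd) with sd >= 0", g)
    }
  }
  structure(list(seed = seed, n_ligands = n_ligands,
                 n_glycosides = n_glycosides, n_proteins = n_proteins,
                 n_pathways = n_pathways, pcpi_density = pcpi_density,
                 prob1_fraction = prob1_fraction,
                 docking_group_params = docking_group_params,
                 n_docking = n_docking), class = "fixture_spec")
}

#' Generate a complete synthetic input bundle
#'
#' Writes every input table the pipeline consumes (ligand CSV, per-ligand
#' prediction CSVs, causal-PPI TSV, GMT, ADME CSV, location and function
#' CSVs, docking CSV) plus `manifest.json` recording the ground truth the
#' bundle was built to satisfy: expected aglycone structures, record counts
#' at each stage, post-clean network composition, and the docking-energy
#' cutoffs implied by the drawn probability-1 energies. Byte-identical for
#' a given spec.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created).
#' @return the manifest, invisibly.
#' @export
generate_fixture_bundle <- function(spec, dir) {
  if (!inherits(spec, "fixture_spec")) spec <- do.call(fixture_spec, spec)
  dir.create(file.path(dir, "predictions"), recursive = TRUE,
             showWarnings = FALSE)
  .with_seed(spec$seed, .generate_bundle_impl(spec, dir))
}

.generate_bundle_impl <- function(spec, dir) {
  G <- spec$n_glycosides
  glyc_idx <- which(.scaffolds$glycosylatable)[seq_len(G)]

  # --- ligand table ------------------------------------------------------
  gly <- data.frame(
    name = paste(.scaffolds$name[glyc_idx], "glucoside"),
    smiles = vapply(.scaffolds$smiles[glyc_idx], glycosylate, character(1)),
    class = paste(.scaffolds$class[glyc_idx], "glycoside"),
    role = "phytochemical", stringsAsFactors = FALSE)
  prelisted <- data.frame(
    name = .scaffolds$name[glyc_idx[1]],
    smiles = .scaffolds$smiles[glyc_idx[1]],
    class = .scaffolds$class[glyc_idx[1]],
    role = "phytochemical", stringsAsFactors = FALSE)
  n_plain <- spec$n_ligands - G - 1
  plain_idx <- setdiff(seq_len(nrow(.scaffolds)), glyc_idx)[seq_len(n_plain)]
  plain <- data.frame(
    name = .scaffolds$name[plain_idx],
    smiles = .scaffolds$smiles[plain_idx],
    class = .scaffolds$class[plain_idx],
    role = "phytochemical", stringsAsFactors = FALSE)
  ligands <- rbind(gly, prelisted, plain, .controls)
  utils::write.csv(ligands, file.path(dir, "ligands.csv"), row.names = FALSE)

  # expected registry: the prelisted aglycone merges; the other G - 1
  # aglycones are novel records
  agl_names <- paste(gly$name, "aglycone")
  agl_smiles <- canonicalize_structure(.scaffolds$smiles[glyc_idx])
  expected_aglycones <- data.frame(parent = gly$name, smiles = agl_smiles,
                                   stringsAsFactors = FALSE)
  reg_names <- c(ligands$name, agl_names[-1])
  reg_ids <- .slugify(reg_names)
  lig_roles <- stats::setNames(
    c(ligands$role, rep("phytochemical", G - 1)), reg_ids)
  # ids of glycosides and their aglycone records (for relations bookkeeping)
  gly_ids <- reg_ids[seq_len(G)]
  agl_ids <- c(reg_ids[G + 1], .slugify(agl_names[-1]))

  # --- proteins and gene sets -------------------------------------------
  disease_genes <- .disease_gene_pool[seq_len(spec$n_proteins)]
  universe <- c(.disease_gene_pool[seq_len(min(spec$n_proteins + 4,
                                               length(.disease_gene_pool)))],
                .decoy_genes)
  sets <- list(list(pathway_id = "FX05210",
                    description = "Synthetic colorectal cancer pathway",
                    genes = disease_genes))
  for (i in seq_len(spec$n_pathways - 1)) {
    sets[[i + 1]] <- list(
      pathway_id = sprintf("FX%05d", i),
      description = sprintf("Synthetic pathway %d", i),
      genes = sort(c(sample(universe, sample(4:6, 1)),
                     sample(.background_genes, sample(6:10, 1)))))
  }
  # guarantee the background covers the targetable universe plus the
  # untargeted padding genes
  sets[[length(sets) + 1]] <- list(pathway_id = "FX00000",
                                   description = "Synthetic background set",
                                   genes = c(universe, .background_genes))
  write_gmt(sets, file.path(dir, "pathways.gmt"))

  # --- per-ligand predictions -------------------------------------------
  draw_prob <- function(n) {
    p1 <- stats::runif(n) < spec$prob1_fraction
    p <- round(stats::runif(n, 0.02, 0.8), 4)
    ifelse(p1, 1, p)
  }
  pcpi <- list()
  for (id in reg_ids) {
    role <- lig_roles[[id]]
    if (role == "negative-control") {
      tgt <- sample(.decoy_genes, 3)
      prob <- round(stats::runif(3, 0.02, 0.3), 4)
    } else {
      hit_d <- disease_genes[stats::runif(length(disease_genes)) <
                               spec$pcpi_density]
      if (length(hit_d) == 0) hit_d <- sample(disease_genes, 1)
      hit_x <- .decoy_genes[stats::runif(length(.decoy_genes)) <
                              spec$pcpi_density / 3]
      tgt <- c(hit_d, hit_x)
      prob <- if (role == "positive-control" && id == "sorafenib") {
        rep(1, length(tgt))
      } else draw_prob(length(tgt))
    }
    pcpi[[id]] <- data.frame(ligand_id = id, protein = tgt,
                             probability = prob, stringsAsFactors = FALSE)
  }
  # inject one duplicate prediction (lower probability) for the first
  # glycoside's first disease target: survives parsing, is removed by clean()
  dup_row <- pcpi[[gly_ids[1]]][1, ]
  dup_row$probability <- round(dup_row$probability / 2, 4)
  pcpi[[gly_ids[1]]] <- rbind(pcpi[[gly_ids[1]]], dup_row)

  for (id in reg_ids) {
    df <- pcpi[[id]]
    out <- data.frame(
      "Target" = paste(df$protein, "(synthetic target)"),
      "Common name" = df$protein,
      "Uniprot ID" = sprintf("P%05d", match(df$protein, universe)),
      "Target Class" = "Kinase",
      "Probability*" = df$probability,
      check.names = FALSE, stringsAsFactors = FALSE)
    # one zero-probability row per file; dropped on read
    out <- rbind(out, data.frame(
      "Target" = "ZERO (synthetic target)", "Common name" = "ZEROGENE",
      "Uniprot ID" = "P99999", "Target Class" = "Other",
      "Probability*" = 0, check.names = FALSE))
    utils::write.csv(out, file.path(dir, "predictions",
                                    paste0(id, ".csv")), row.names = FALSE)
  }
  all_pcpi <- do.call(rbind, pcpi)
  n_complete <- nrow(all_pcpi)
  overlap <- sort(intersect(unique(all_pcpi$protein), disease_genes))
  disease_pcpi <- all_pcpi[all_pcpi$protein %in% overlap, ]
  lig_nodes <- unique(disease_pcpi$ligand_id)
  prot_nodes <- sort(unique(disease_pcpi$protein))
  pair_key <- paste(disease_pcpi$ligand_id, disease_pcpi$protein)
  n_lp_edges <- length(unique(pair_key))
  control_ids <- names(lig_roles)[grepl("control", lig_roles)]
  uniq <- !duplicated(pair_key)
  n_dpi <- sum(disease_pcpi$ligand_id[uniq] %in% control_ids)
  n_pcpi_edges <- n_lp_edges - n_dpi

  # --- PPIs --------------------------------------------------------------
  k <- length(prot_nodes)
  pairs <- expand.grid(a = prot_nodes, b = prot_nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  n_within <- min(nrow(pairs), ceiling(1.2 * k))
  sel <- pairs[sample(nrow(pairs), n_within), ]
  effects <- sample(c("up-regulates activity", "down-regulates activity",
                      "binds"), n_within, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
  ppi <- data.frame(ENTITYA = sel$a, TYPEA = "protein", ENTITYB = sel$b,
                    TYPEB = "protein", EFFECT = effects,
                    MECHANISM = "synthetic", PMID = "00000000",
                    stringsAsFactors = FALSE)
  n_up <- sum(grepl("up-regulates", effects))
  n_down <- sum(grepl("down-regulates", effects))
  n_other <- n_within - n_up - n_down
  extra <- data.frame(
    ENTITYA = c(sample(.decoy_genes, 2), prot_nodes[1], ppi$ENTITYA[1],
                "SYNCHEM1"),
    TYPEA = c("protein", "protein", "protein", "protein", "chemical"),
    ENTITYB = c(prot_nodes[c(1, 2)], prot_nodes[1], ppi$ENTITYB[1],
                prot_nodes[2]),
    TYPEB = "protein",
    EFFECT = c("up-regulates", "down-regulates", "up-regulates",
               ppi$EFFECT[1], "up-regulates"),
    MECHANISM = "synthetic", PMID = "00000000", stringsAsFactors = FALSE)
  ppi_out <- rbind(ppi, extra)
  utils::write.table(ppi_out, file.path(dir, "ppi.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- ADME, locations, functions ---------------------------------------
  ba_levels <- c(0.11, 0.17, 0.55, 0.56, 0.85)
  is_glyc_rec <- reg_ids %in% gly_ids
  adme <- data.frame(
    Molecule = reg_names,
    "Bioavailability Score" = sample(ba_levels, length(reg_ids),
                                     replace = TRUE),
    "GI absorption" = ifelse(is_glyc_rec, "Low",
                             sample(c("High", "Low"), length(reg_ids),
                                    replace = TRUE, prob = c(0.75, 0.25))),
    "Consensus Log P" = round(stats::runif(length(reg_ids), -0.5, 5.5), 2),
    check.names = FALSE, stringsAsFactors = FALSE)
  # exercise case-insensitive matching and the missing-PK warning path
  adme$Molecule[1] <- toupper(adme$Molecule[1])
  adme <- adme[-nrow(adme), ]
  utils::write.csv(adme, file.path(dir, "adme.csv"), row.names = FALSE)

  comp_pool <- c("nucleus", "cytoplasm", "plasma membrane", "mitochondrion",
                 "extracellular", "endoplasmic reticulum")
  comp_w <- c(0.25, 0.3, 0.25, 0.1, 0.05, 0.05)
  prot_comp <- sample(comp_pool, length(prot_nodes), replace = TRUE,
                      prob = comp_w)
  n_primary <- ceiling(0.75 * length(prot_nodes))
  primary <- data.frame(protein = prot_nodes[seq_len(n_primary)],
                        compartment = prot_comp[seq_len(n_primary)],
                        stringsAsFactors = FALSE)
  rest <- setdiff(seq_along(prot_nodes), seq_len(n_primary))
  unmapped <- if (length(rest) >= 2) rest[length(rest)] else integer(0)
  fb_idx <- setdiff(rest, unmapped)
  fallback <- data.frame(protein = prot_nodes[fb_idx],
                         compartment = prot_comp[fb_idx],
                         stringsAsFactors = FALSE)
  if (nrow(fallback) > 0) {
    fallback$compartment[1] <- paste(fallback$compartment[1],
                                     "cytoplasm", sep = "; ")
  }
  utils::write.csv(primary, file.path(dir, "locations_primary.csv"),
                   row.names = FALSE)
  utils::write.csv(fallback, file.path(dir, "locations_fallback.csv"),
                   row.names = FALSE)
  fn <- .function_map_fixture[names(.function_map_fixture) %in% prot_nodes]
  utils::write.csv(data.frame(protein = names(fn), "function" = unname(fn),
                              check.names = FALSE),
                   file.path(dir, "functions.csv"), row.names = FALSE)

  # --- docking -----------------------------------------------------------
  dp <- spec$docking_group_params
  uniq_pcpi <- disease_pcpi[uniq, ]
  p1_rows <- uniq_pcpi[uniq_pcpi$probability == 1, ]
  # probability-1 rows necessarily classify at or above their own minimum
  # (the soft cutoff), i.e. into the medium class; cap them so that class
  # stays dominated by ordinary low-probability interactions and the
  # derived probability regions are well ordered
  p1_rows <- p1_rows[seq_len(min(6, nrow(p1_rows))), ]
  rest_rows <- uniq_pcpi[uniq_pcpi$probability < 1, ]
  # dock the lowest-probability interactions, alternating ranks between the
  # low and medium groups so their probability distributions overlap
  ord <- order(rest_rows$probability)
  low_pos <- ord[seq(1, length(ord), by = 2)]
  med_pos <- ord[seq(2, length(ord), by = 2)]
  n_med <- min(spec$n_docking[["medium"]], length(med_pos))
  n_low <- min(spec$n_docking[["low"]], length(low_pos))
  med_rows <- rest_rows[med_pos[seq_len(n_med)], ]
  low_rows <- rest_rows[low_pos[seq_len(n_low)], ]
  e1 <- stats::rnorm(nrow(p1_rows), dp$prob1[1], dp$prob1[2])
  soft <- min(e1)
  hard <- mean(e1) + 3 * .sd_fun(e1, "population")
  # medium/low energies are drawn from their configured normals truncated
  # to the band the probability-1 cutoffs define, so the intended group is
  # the classified group (degenerate soft == hard leaves no medium band;
  # the untruncated draw is used then)
  rtnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
    if (n == 0) return(numeric(0))
    if (sd == 0) return(rep(mean, n))
    pa <- stats::pnorm(a, mean, sd); pb <- stats::pnorm(b, mean, sd)
    if (pb - pa < 1e-9) return(stats::rnorm(n, mean, sd))
    stats::qnorm(stats::runif(n, pa, pb), mean, sd)
  }
  em <- rtnorm(nrow(med_rows), dp$medium[1], dp$medium[2],
               a = soft, b = hard - 1e-9)
  el <- rtnorm(nrow(low_rows), dp$low[1], dp$low[2], a = hard)
  docking <- rbind(
    data.frame(ligand_id = p1_rows$ligand_id, protein = p1_rows$protein,
               energy = e1, probability = p1_rows$probability),
    data.frame(ligand_id = med_rows$ligand_id, protein = med_rows$protein,
               energy = em, probability = med_rows$probability),
    data.frame(ligand_id = low_rows$ligand_id, protein = low_rows$protein,
               energy = el, probability = low_rows$probability))
  .write_csv_precise(docking, file.path(dir, "docking.csv"))

  manifest <- list(
    spec = unclass(spec),
    expected = list(
      aglycones = expected_aglycones,
      n_registry_records = length(reg_ids),
      n_relations = G,
      relation_pairs = data.frame(parent_id = gly_ids, child_id = agl_ids,
                                  stringsAsFactors = FALSE),
      n_complete_pcpis = n_complete,
      disease_pathway_id = "FX05210",
      overlap = overlap,
      n_disease_pcpis = nrow(disease_pcpi),
      n_ligand_nodes = length(lig_nodes),
      n_protein_nodes = length(prot_nodes),
      n_nodes = length(lig_nodes) + length(prot_nodes),
      n_pcpi_edges = n_pcpi_edges,
      n_dpi_edges = n_dpi,
      n_ppi_edges = n_within,
      n_ppi_up = n_up, n_ppi_down = n_down, n_ppi_other = n_other,
      n_relation_edges = G,
      n_edges = n_lp_edges + n_within + G,
      soft_cutoff = soft,
      hard_cutoff = hard,
      analytic_cutoffs = list(
        soft_asymptotic = unname(dp$prob1[1]),
        hard_asymptotic = unname(dp$prob1[1] + 3 * dp$prob1[2]))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}
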