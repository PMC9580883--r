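# Shared fixtures, built in code.

# Reference molecules (SMILES drawn independently of the hydrolysis code).
SALICIN <- "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O"
SALIGENIN <- "OCc1ccccc1O"
GLUCOSE <- "OCC1OC(O)C(O)C(O)C1O"
QUERCETIN <- "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12"
PHENOL <- "Oc1ccccc1"

# Heavy-atom counts from the molecular formulas (independent oracle):
# salicin C13H18O7, saligenin C7H8O2, glucose C6H12O6, phenol C6H6O.
HEAVY <- c(salicin = 20L, saligenin = 9L, glucose = 12L, phenol = 7L)

# A minimal raw ligand table: one glycoside, its aglycone pre-listed, one
# plain flavonoid, one positive control.
toy_ligand_table <- function() {
  data.frame(
    name = c("salicin", "saligenin", "quercetin", "drugA"),
    smiles = c(SALICIN, SALIGENIN, QUERCETIN, "CCN(CC)CCO"),
    class = c("phenolic glycoside", "simple phenol", "flavonoid",
              "drug-control"),
    role = c("phytochemical", "phytochemical", "phytochemical",
             "positive-control"),
    stringsAsFactors = FALSE
  )
}

# Hand-enumerated assembly fixture: 5 ligands, 4 proteins, 6 PCPIs (one
# ligand with none surviving), 3 PPIs (one with an endpoint outside the
# disease targets), 1 glycoside relation.
toy_assembly_inputs <- function() {
  pcpis <- data.frame(
    ligand_id = c("l1", "l1", "l2", "l3", "l4", "l5"),
    protein = c("PA", "PB", "PB", "PC", "PD", "PA"),
    probability = c(1, 0.5, 0.3, 0.8, 0.2, 0.6),
    stringsAsFactors = FALSE
  )
  ppis <- data.frame(
    source = c("PA", "PB", "PA"),
    target = c("PB", "PC", "PX"),   # PA->PX has an endpoint outside
    effect = c("up-regulates", "down-regulates", "up-regulates"),
    provenance = "test", stringsAsFactors = FALSE
  )
  relations <- data.frame(parent_id = "l1", child_id = "l2",
                          stringsAsFactors = FALSE)
  registry <- structure(list(
    registry = data.frame(
      ligand_id = paste0("l", 1:5),
      name = paste0("ligand ", 1:5),
      smiles = NA_character_,
      ligand_class = c("phenolic glycoside", "simple phenol", "flavonoid",
                       "flavonoid", "drug-control"),
      role = c(rep("phytochemical", 4), "positive-control"),
      parent_id = c(NA, "l1", NA, NA, NA),
      synonyms = "", stringsAsFactors = FALSE),
    relations = relations), class = "ligand_registry")
  list(pcpis = pcpis, ppis = ppis, relations = relations,
       registry = registry)
}

# Expected composition of the toy network (by hand):
#   ligand nodes l1..l5 (all have >= 1 PCPI), protein nodes PA..PD -> 9
#   edges: 6 ligand->protein (l5 is a control -> DPI), 2 PPIs kept
#   (PA->PB, PB->PC; PA->PX dropped), 1 relation edge -> 9 edges.
TOY_N_NODES <- 9L
TOY_N_EDGES <- 9L

# Generate one shared fixture bundle per test run (cached).
.fixture_cache <- new.env(parent = emptyenv())
fixture_bundle_cached <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("pcpinet_fixture_", seed))
    unlink(dir, recursive = TRUE)
    spec <- fixture_spec(seed = seed)
    suppressMessages(generate_fixture_bundle(spec, dir))
    .fixture_cache[[key]] <- dir
  }
  .fixture_cache[[key]]
}

read_manifest <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "manifest.json"))
}

# One shared full pipeline run on the fixture bundle (cached).
pipeline_run_cached <- function(seed = 42) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    out <- file.path(tempdir(), paste0("pcpinet_run_", seed))
    unlink(out, recursive = TRUE)
    cfg <- pipeline_config(fixture = list(seed = seed),
                           disease_pathway = "FX05210", seed = seed)
    res <- suppressMessages(suppressWarnings(
      run_pipeline(cfg, out, log_level = "warn")))
    .fixture_cache[[key]] <- list(dir = out, res = res)
  }
  .fixture_cache[[key]]
}
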