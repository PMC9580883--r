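# Dialect parsing and table round trips.

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("zero-probability predictions are dropped on read", {
  f <- write_lines_tmp(c(
    "Target,Common name,Uniprot ID,Probability*",
    "epidermal growth factor receptor,EGFR,P00533,1.0",
    "serine/threonine-protein kinase B-raf,BRAF,P15056,0.4",
    "some target,AKT1,P31749,0.0",
    "another target,MTOR,P42345,0.0",
    "third target,GSK3B,P49841,0.2"))
  recs <- suppressMessages(read_target_predictions(f, "lig1"))
  expect_identical(nrow(recs), 3L)
  expect_true(all(recs$probability > 0))
  expect_identical(recs$protein, c("EGFR", "BRAF", "GSK3B"))
  expect_identical(recs$ligand_id, rep("lig1", 3))
})

test_that("prediction dialect variants parse identically via header aliasing", {
  rows <- c("EGFR,P00533,0.5", "BRAF,P15056,0.25")
  f1 <- write_lines_tmp(c("Common name,Uniprot ID,Probability*", rows))
  f2 <- write_lines_tmp(c("common_name,uniprot_id,Probability", rows))
  r1 <- read_target_predictions(f1, "x")
  r2 <- read_target_predictions(f2, "x")
  expect_identical(r1, r2)
})

test_that("header-only prediction files yield an empty record list with a warning", {
  f <- write_lines_tmp("Common name,Uniprot ID,Probability*")
  expect_message(recs <- read_target_predictions(f, "x"), "header-only")
  expect_identical(nrow(recs), 0L)
})

test_that("prediction dialect and value errors are classed", {
  f <- write_lines_tmp(c("Common name,Uniprot ID", "EGFR,P00533"))
  expect_error(read_target_predictions(f, "x"), "probability",
               class = "pcpinet_dialect_error")
  f2 <- write_lines_tmp(c("Common name,Probability*", "EGFR,1.7"))
  expect_error(read_target_predictions(f2, "x"), "row 1",
               class = "pcpinet_value_error")
})

test_that("PPI effects map to signed categories and non-proteins are dropped", {
  f <- write_lines_tmp(c(
    "ENTITYA\tTYPEA\tENTITYB\tTYPEB\tEFFECT",
    "EGFR\tprotein\tMAPK1\tprotein\tup-regulates activity",
    "TP53\tprotein\tBCL2\tprotein\tdown-regulates quantity by repression",
    "AKT1\tprotein\tGSK3B\tprotein\tbinds",
    "aspirin\tchemical\tEGFR\tprotein\tup-regulates"), ext = ".tsv")
  recs <- suppressMessages(read_ppi_table(f))
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$effect,
                   c("up-regulates", "down-regulates", "other"))
  # self-loops are allowed at parse time
  f2 <- write_lines_tmp(c("ENTITYA\tTYPEA\tENTITYB\tTYPEB\tEFFECT",
                          "EGFR\tprotein\tEGFR\tprotein\tbinds"),
                        ext = ".tsv")
  expect_identical(nrow(read_ppi_table(f2)), 1L)
  # empty file
  f3 <- write_lines_tmp("ENTITYA\tTYPEA\tENTITYB\tTYPEB\tEFFECT",
                        ext = ".tsv")
  expect_identical(nrow(read_ppi_table(f3)), 0L)
  # missing column
  f4 <- write_lines_tmp("ENTITYA\tENTITYB", ext = ".tsv")
  expect_error(read_ppi_table(f4), class = "pcpinet_dialect_error")
})

test_that("ADME tables parse, deduplicate, and validate GI categories", {
  f <- write_lines_tmp(c(
    "Molecule,Bioavailability Score,GI absorption,Consensus Log P",
    "mol1,0.55,High,1.8",
    "mol1,0.55,High,1.8",
    "mol2,0.17,low,-0.4"))
  recs <- read_adme_table(f)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$gi_absorption, c("high", "low"))
  expect_identical(recs$bioavailability, c(0.55, 0.17))
  expect_identical(recs$logp, c(1.8, -0.4))
  f2 <- write_lines_tmp(c(
    "Molecule,Bioavailability Score,GI absorption,Consensus Log P",
    "mol1,0.55,Medium,1.8"))
  expect_error(read_adme_table(f2), "Medium",
               class = "pcpinet_value_error")
})

test_that("ADME names resolve to registry ids case-insensitively, unresolved kept", {
  reg <- suppressMessages(build_registry(toy_ligand_table()))
  f <- write_lines_tmp(c(
    "Molecule,Bioavailability Score,GI absorption,Consensus Log P",
    "SALICIN,0.55,Low,-1.2",
    "notamolecule,0.17,High,2.0"))
  expect_message(recs <- read_adme_table(f, reg), "not resolvable")
  expect_identical(recs$ligand_id, c("salicin", NA))
  expect_identical(nrow(recs), 2L)
})

test_that("every table type round-trips read -> write -> read identically", {
  # predictions
  f <- write_lines_tmp(c("Common name,Uniprot ID,Probability*",
                         "EGFR,P00533,0.123456789012345",
                         "BRAF,P15056,1"))
  r1 <- read_target_predictions(f, "x")
  out <- tempfile(fileext = ".csv")
  write_pcpi_table(r1, out)
  r2 <- read_pcpi_table(out)
  expect_equal(r2, r1)
  expect_identical(r2$probability, r1$probability)  # no rounding on ingest
  # PPIs
  fp <- write_lines_tmp(c(
    "ENTITYA\tTYPEA\tENTITYB\tTYPEB\tEFFECT",
    "EGFR\tprotein\tMAPK1\tprotein\tup-regulates activity",
    "AKT1\tprotein\tGSK3B\tprotein\tbinds"), ext = ".tsv")
  p1 <- read_ppi_table(fp)
  outp <- tempfile(fileext = ".tsv")
  write_ppi_table(p1, outp)
  p2 <- read_ppi_table(outp)
  expect_identical(p2[c("source", "target", "effect", "provenance")],
                   p1[c("source", "target", "effect", "provenance")])
  # docking
  d1 <- data.frame(ligand_id = c("a", "b"), protein = c("EGFR", "MTOR"),
                   energy = c(-7.8123456789, -6.4), probability = c(1, 0.07),
                   stringsAsFactors = FALSE)
  outd <- tempfile(fileext = ".csv")
  write_docking_table(d1, outd)
  expect_identical(read_docking_table(outd), d1)
  # ADME
  a1 <- data.frame(name = c("m1", "m2"), bioavailability = c(0.55, 0.11),
                   gi_absorption = c("high", "low"), logp = c(1.23, -0.5),
                   stringsAsFactors = FALSE)
  outa <- tempfile(fileext = ".csv")
  write_adme_table(a1, outa)
  a2 <- read_adme_table(outa)
  expect_identical(a2[c("name", "bioavailability", "gi_absorption", "logp")],
                   a1)
  # GMT
  sets <- list(list(pathway_id = "P1", description = "first",
                    genes = c("EGFR", "BRAF")),
               list(pathway_id = "P2", description = "second",
                    genes = c("TP53", "MTOR", "AKT1")))
  outg <- tempfile(fileext = ".gmt")
  write_gmt(sets, outg)
  expect_identical(unname(read_gmt(outg)), sets)
})

test_that("docking tables validate energies and probabilities", {
  f <- write_lines_tmp(c("ligand_id,protein,energy,probability",
                         "a,EGFR,-7.0,0"))
  expect_error(read_docking_table(f), class = "pcpinet_value_error")
  f2 <- write_lines_tmp(c("ligand_id,protein,energy,probability",
                          "a,EGFR,notanumber,0.5"))
  expect_error(read_docking_table(f2), class = "pcpinet_value_error")
})

test_that("protein maps take the first of multi-valued entries", {
  f <- write_lines_tmp(c("protein,compartment",
                         "EGFR,plasma membrane",
                         "GSK3B,cytoplasm; nucleus"))
  m <- suppressMessages(read_protein_map(f))
  expect_identical(unname(m["GSK3B"]), "cytoplasm")
  expect_identical(unname(m["EGFR"]), "plasma membrane")
})

test_that("the shipped sample dialect files parse", {
  ext <- system.file("extdata", package = "pcpinet")
  pr <- suppressMessages(read_target_predictions(
    file.path(ext, "sample_predictions.csv"), "quercetin"))
  expect_identical(nrow(pr), 2L)  # the zero-probability row is dropped
  expect_identical(nrow(read_ppi_table(file.path(ext, "sample_ppi.tsv"))), 3L)
  expect_identical(nrow(read_adme_table(file.path(ext, "sample_adme.csv"))), 2L)
  expect_identical(nrow(read_docking_table(file.path(ext, "sample_docking.csv"))), 2L)
  gmt <- read_gmt(file.path(ext, "sample_pathways.gmt"))
  expect_identical(gmt[[1]]$pathway_id, "hsa05210")
  expect_length(read_protein_map(file.path(ext, "sample_locations.csv")), 3L)
})
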