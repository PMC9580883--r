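# pcpinet

Network-pharmacology pipeline for predicting and visualizing the cellular
action of a medicinal plant against a disease.

Phytochemicals rarely act as magic bullets: a plant extract is a mixture of
small molecules, each predicted (by reverse screening) to interact with many
protein targets, each carrying a probability score. `pcpinet` turns those
per-molecule prediction tables into a single annotated phytochemical–protein
interaction (PCPI) network for a chosen disease, and calibrates how much to
trust each predicted edge against molecular-docking energies. It is written
for natural-products and chemical-biology researchers who have ligand lists,
reverse-screening exports, a causal PPI table and pathway gene sets, and
want a reproducible desk pipeline from those inputs to a styled, viewable
network.

## What it computes

1. **Ligand registry with simulated metabolism** — SMILES are
   canonicalized, duplicate structures merged, and O-glycosides hydrolyzed
   *in silico*: every bond between a saccharide-ring anomeric carbon and an
   exocyclic oxygen leading to a carbon outside the ring is cleaved, each
   fragment capped with hydroxyl (one water per bond, so
   heavy atoms(products) = heavy atoms(parent) + bonds cleaved). Aglycones
   are registered with parentage; sugar fragments are discarded.
2. **Screening ingestion and disease filtering** — per-ligand prediction
   CSVs are merged (zero-probability rows dropped); targets are tested for
   pathway over-representation with the one-sided hypergeometric upper
   tail, P(X ≥ k) with X ~ Hypergeom(N, K, n), Benjamini–Hochberg adjusted;
   the chosen disease pathway's overlap filters the PCPIs.
3. **Network assembly** — typed directed edges: ligand→protein PCPI/DPI
   with probability, signed protein→protein (up-/down-regulation),
   glycoside→aglycone; PPIs join only between disease targets; duplicate
   edges and self-loops removed.
4. **Annotation** — subcellular compartments (primary map, fallback map,
   four-tier ligand priority rule: nucleus > mitochondrion > plasma
   membrane > cytoplasm), pharmacokinetics (Abbott bioavailability, GI
   absorption, log P), protein function classes.
5. **Confidence calibration** — among docked interactions with prediction
   probability 1, soft cutoff = min energy and hard cutoff =
   mean + 3·SD; docking classes high (E < soft), medium (soft ≤ E < hard),
   low (E ≥ hard); probability regions high (P > mean(P|low) + SD) and
   low (P ≤ mean(P|medium) − SD); a simplified network keeps edges that
   dock high or have P = 1.
6. **Export** — style-mapped GraphML / JSON / CSV with a deterministic
   compartment-box cell layout and a plain-text legend.

A seeded fixture generator (`generate_fixture_bundle()`) emulates every
input dialect with exact ground truth, so the whole pipeline runs and is
tested without any external service.

## Worked example

```r
library(pcpinet)

# hydrolyze salicin: one O-glycosidic bond, saligenin + glucose
hydrolyze_glycosides("OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O")
#> $parent
#> [1] "OCC1OC(Oc2ccccc2CO)C(C(C1O)O)O"
#> $bonds_cleaved
#> [1] 1
#> $products
#>                 smiles     kind count
#> 1          OCc1ccccc1O aglycone     1
#> 2 OCC1OC(O)C(C(C1O)O)O    sugar     1
```

The aglycone is saligenin and the sugar is glucose, in canonical SMILES;
products sum to 21 heavy atoms = 20 (salicin) + 1 cleaved bond's water
oxygen.

```r
reg <- build_registry(data.frame(
  name  = c("salicin", "quercetin"),
  smiles = c("OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O",
             "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12"),
  class = c("phenolic glycoside", "flavonoid"),
  role  = "phytochemical"))
reg
#> Ligand registry: 3 records (1 with a glycoside parent), 1 glycoside-aglycone relation(s)
#>   flavonoid                    1
#>   phenolic aglycone            1
#>   phenolic glycoside           1
```

Two input rows became three records: the salicin aglycone was registered
automatically with `parent_id = "salicin"` and one glycoside–aglycone
relation. Quercetin has no sugar unit and is untouched.

Full pipeline on a synthetic bundle:

```r
cfg <- pipeline_config(fixture = list(seed = 7),
                       disease_pathway = "FX05210", seed = 7)
res <- run_pipeline(cfg, "out")
res$network
#> Network: 29 nodes, 107 interactions
#>  nodes by kind:  ligand=17, protein=12
#>  edges by type:  DPI=12, glycoside-aglycone=4, PCPI=76, PPI-down=6, PPI-other=6, PPI-up=3
res$model
#> Docking-confidence calibration model
#>   soft cutoff: -8.988 kcal/mol (high docking confidence below)
#>   hard cutoff: -7.388 kcal/mol (low docking confidence at/above)
#>   probability thresholds: high > 0.6968, low <= 0.4778
#>   fitted on 20 docking record(s); k_hard = 3, k_prob = 1, population SD
```

`out/` then contains every intermediate (`registry.csv`,
`complete_pcpis.csv`, `disease_pcpis.csv`, `network_*.csv`,
`classified_interactions.csv`, `simplified_*.csv`), the styled exports
(`network.graphml`, `network.json`, legend) and `run_manifest.json`;
rerunning the same config reproduces the directory byte for byte. The
command-line wrapper `inst/cli/pcpinet` exposes `run` and `make-fixture`.

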