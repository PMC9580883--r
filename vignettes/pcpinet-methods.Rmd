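---
title: "Methods: predicting and visualizing phytochemical-protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and visualizing phytochemical-protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpinet)
```

# The problem

Medicinal plants act through many small molecules hitting many protein
targets at once. Reverse screening predicts, for each phytochemical, a list
of candidate protein targets with a probability score; network pharmacology
assembles these phytochemical-protein interactions (PCPIs) together with
known protein-protein interactions (PPIs) into a single directed network for
a chosen disease. `pcpinet` implements that workflow end to end: ligand
compilation with simulated metabolism, ingestion of reverse-screening and
causal-PPI tables, disease-pathway filtering, annotated network assembly,
docking-based confidence calibration, and styled graph export.

Every stage is exposed as ordinary functions; `run_pipeline()` drives them
in sequence and writes each intermediate with a stable name.

# Ligand registry and simulated metabolism

Ingested glycosides are hydrolyzed in the gut, so the aglycone — not the
parent glycoside — is often the circulating species. The registry therefore
simulates metabolism by cleaving O-glycosidic bonds *in silico*.

The structural rule: a **saccharide ring** is a 5- or 6-membered ring with
exactly one ring oxygen, all other ring atoms carbon, and at least two ring
carbons bearing hydroxyl or hydroxymethyl substituents (hydroxyl means a
degree-one oxygen attached by a single bond, so carbonyl oxygens never
count). The **anomeric carbon** is a saturated ring carbon adjacent to the
ring oxygen; restricting to saturated carbons keeps aromatic oxygen
heterocycles such as chromones and furans from matching, which matters
because flavonoids — a dominant phytochemical class — are built on a
chromen-4-one core. An **O-glycosidic bond** joins the anomeric carbon to an
exocyclic oxygen whose other neighbour is a carbon outside that ring (any
carbon: chained di-glycosides are covered, and exhaustive cleavage then
peels sugars off one layer at a time). C- and N-glycosides are deliberately
not cleaved; their bonds survive digestion.

Cleavage removes the anomeric C–O bond and caps the anomeric carbon with a
new hydroxyl: the bridging oxygen stays with the partner fragment, which is
the chemically correct direction (salicin yields saligenin and glucose, not
an aryl-ether fragment). Each cleavage adds exactly one oxygen, giving the
testable mass balance

> heavy atoms(products) = heavy atoms(parent) + bonds cleaved.

Fragments whose every ring atom belongs to a saccharide ring are sugars and
are discarded; everything else is registered as an aglycone with
`parent_id` pointing at the glycoside. By default hydrolysis is exhaustive
(partial hydrolysis products are not registered; the `exhaustive` flag
exposes single-pass behaviour for callers who want intermediates).

Stereochemistry is preserved through cleavage where the structure encodes
it; the anomeric centre of the capped sugar is left unspecified because
hydrolysis racemizes it. SMILES parsing and canonicalization are delegated
to OpenBabel (through ChemmineR/ChemmineOB); the pattern rule, ring
perception for saccharide detection, and the cleavage itself operate on the
molecular graph in package code.

On duplicate structures (identical canonical SMILES) the first-seen name is
primary and later names become synonyms; ligand ids are slugified names
with numeric suffixes on collision.

# Table dialects

The parsers accept the CSV/TSV dialects of the upstream tools through
header alias tables (e.g. the prediction probability column may be
`Probability*` or `Probability`), matched exactly after whitespace
stripping, case-insensitively. Encoding is UTF-8 and the decimal separator
is `.`. Numbers are never rounded on ingest, and the package's own writers
emit numerics with 17 significant digits so read–write–read round trips are
bit-exact. Prediction rows with probability zero are dropped (the tools
emit them for molecules with no informative similarity); causal-PPI rows
are kept only when both entities are proteins, with effect strings mapped
to `up-regulates` / `down-regulates` / `other`. Ligand names in ADME tables
resolve to registry ids by exact case-insensitive match on primary names
then synonyms — no fuzzy matching, because a silent mis-join is worse than
a logged gap.

# Disease-pathway filtering

Over-representation of each pathway gene set among the predicted targets
is tested with the one-sided upper-tail hypergeometric distribution
(`phyper`), i.e. the probability of drawing at least the observed overlap
when `|targets|` genes are drawn from the background without replacement.
P-values are adjusted across gene sets with the Benjamini–Hochberg step-up
(`p.adjust`). The default significance threshold is `alpha = 0.05`; the
default background is the union of all genes in the supplied GMT, and gene
symbols are upper-cased before comparison. An alternative proprietary
multiple-testing correction used by some web enrichment services is not
fully specified for re-implementation, so BH — the field standard — is
used instead; this is a documented divergence that changes adjusted
p-values but not the overlap sets used downstream.

The disease pathway is an explicit user choice (`disease_pathway` in the
config). Its overlap — pathway genes intersected with the predicted
targets — filters the complete PCPI list down to disease-specific PCPIs;
ligands with no surviving record drop out of all later stages.

# Network assembly and cleaning

Ligand nodes are created for every ligand with at least one disease PCPI,
protein nodes for every disease target. Ligand-to-protein edges are typed
`DPI` for control drugs and `PCPI` otherwise and carry the prediction
probability. PPI edges are kept only when **both** endpoints are disease
targets (the disease targets act as the join clause on both sides;
intermediates are not pulled in). Glycoside-aglycone edges run parent to
child and require both ligands in the network.

`clean_network()` removes self-loops and duplicate `(source, target,
edge_type)` edges, keeping the highest probability (ties: first
encountered) — duplicates arise when the same interaction is predicted for
several reasons, and the strongest evidence is preserved. Cleaning is
idempotent. `network_summary()` partitions nodes by kind and class and
edges by type; the partitions always sum to the totals.

# Annotation

Protein compartments come from a primary (fractionation-style) table, then
a fallback (curated-annotation) table, then `"other"` with a warning;
compartment vocabulary is normalized through a synonym map
(`Cytosol -> cytoplasm`, `PM -> plasma membrane`, ...) and multi-valued
entries take their first value. Ligands are placed by the four-tier
priority rule over their own targets' compartments — nucleus, then
mitochondrion, then plasma membrane, then cytoplasm; a ligand whose targets
all lie outside those tiers takes the plurality compartment among its
targets with alphabetical tie-break (the priority rule is silent on this
case; plurality with a deterministic tie-break is the design choice).
Pharmacokinetic columns (Abbott bioavailability score in [0,1], categorical
GI absorption, log P — the base-10 octanol/water partition coefficient,
consumed as data and never computed) attach to ligand nodes; protein
function classes (oncogene / tumor suppressor / other, defaulting to
other) attach to protein nodes.

# Docking-confidence calibration

Docked interactions with prediction probability exactly 1 correspond to
structures already recorded in the bioactivity database behind the reverse
screen — the closest thing to ground truth available. Calibration uses
them as anchors:

* **soft cutoff** — the most negative docking energy among probability-1
  interactions; energies below it are *high* docking confidence;
* **hard cutoff** — the upper bound of the mean ± `k_hard`·SD band of the
  probability-1 energies (`k_hard = 3`, the 99.7% band under normality);
  energies at or above it are *low*, between the cutoffs *medium*.

Probability-confidence regions then come from the docking classes: the
high-probability threshold is the upper bound (mean + `k_prob`·SD,
`k_prob = 1`, the 68% band) of the low-docking-class probabilities, and the
low-probability threshold is the lower bound of the medium-class mean.
"k standard deviations" uses the population SD (divide by n) by default
because the 68% band is equated with one standard deviation; the sample SD
is available via `sd_type = "sample"`. Degenerate groups (SD 0) collapse
the band to the mean.

Published inequalities for these classes are strict on both sides, leaving
boundary values undefined; the package assigns boundaries to the weaker
class (energy at the soft cutoff is medium, at the hard cutoff low; a
probability exactly at a threshold falls in the lower region) —
conservative triage. Both calibration steps can be bypassed with explicit
values (`cutoffs`, `prob_thresholds`), which is how published thresholds
are reproduced without the underlying docking table. Whether the original
bands used SD or SEM, population or sample SD, is not stated anywhere
authoritative; both conventions are offered and neither is asserted.

`confidence_model()` returns a classed object with `print`, `summary`,
`coef` and `predict` methods. The simplified high-confidence subnetwork
keeps ligand-protein edges that dock with high confidence **or** carry
probability 1, the nodes incident to them, PPIs among surviving proteins,
and glycoside edges among surviving ligands; it is structurally a subgraph
of its input.

# Visual channels and layout

Edge width maps prediction probability linearly (range default 1–8);
edge colour maps interaction type (PCPI/DPI blue, PPI up-regulation green,
PPI down-regulation red, glycoside-aglycone dark green and dashed,
other-PPI neutral grey — "other" effects are retained even though the
published legend covers only up/down). Ligands are circles coloured by
class; proteins are pink squares. Node opacity maps log P linearly over the
network's observed range (more lipophilic = more opaque); node size maps GI
absorption (high large, low small); border colour maps the Abbott score
into three bins (default edges 0.35 and 0.7 — the published account
distinguishes "high or medium" bioavailability without numeric edges, so
the bins are package defaults and fully configurable); label colour maps
protein function. Missing PK attributes map to the channel minimum and are
flagged in `vis_pk_missing`. Concrete widths, opacities and the class
palette are package defaults: the source material fixes the channel
assignments, not the numbers.

The cell-template layout is a simple compartment-box scheme standing in
for interactive layout plug-ins: each compartment owns a rectangle
(extracellular band, plasma-membrane band, cytoplasm/nucleus/mitochondrion
boxes, an "other" band; extra compartments get bands appended), and nodes
are placed on a jittered grid strictly inside their rectangle —
deterministic given the seed, with a guaranteed minimum pairwise
separation. Dashes are encoded as a `line_style` attribute because not all
formats render them natively. Exports: GraphML with typed attribute keys
(well-formed, namespaced, round-trippable through `read_graphml()`),
an elements-style JSON loadable by web graph viewers, node/edge CSVs, and
a plain-text legend.

# The synthetic fixture generator

`generate_fixture_bundle()` writes a complete, internally consistent input
bundle — ligand CSV, per-ligand prediction CSVs in the reverse-screening
dialect, causal-PPI TSV, GMT, ADME CSV, location and function CSVs, docking
CSV — plus a ground-truth manifest. Everything derives from one seed; the
bundle is byte-identical across runs.

What it emulates, and how the ground truth is exact:

* Glycosides are built by attaching a glucopyranose unit to the leading
  hydroxyl of a known aglycone scaffold, so the expected hydrolysis
  products are known *by construction*, not by running the hydrolysis
  code. One aglycone is always pre-listed to exercise the merge path.
* Predictions hit disease-pathway genes at `pcpi_density` (default 0.45)
  and decoy genes at a third of that, with `prob1_fraction` (default 0.15)
  of predictions at probability exactly 1 — mirroring how
  database-recorded structures come back with probability 1. Zero-probability
  rows are planted to exercise the read-side filter. The GMT carries a
  large annotated-but-untargeted background gene pool, the way a
  genome-wide annotation background dwarfs any real target list; this is
  what makes the designated disease pathway genuinely enriched.
* The PPI table plants a self-loop, an exact duplicate, rows to proteins
  outside the disease targets, and a chemical-entity row — each exercising
  one documented cleaning/joining rule, each accounted for in the manifest
  counts.
* Docking energies: the probability-1 group is drawn from its configured
  normal (default mean −8.6, SD 0.5 kcal/mol, a realistic strong-binder
  range); the manifest records the cutoffs implied by the drawn energies
  exactly. Medium- and low-group energies are drawn from their configured
  normals truncated to the bands those cutoffs define, so intended and
  classified groups coincide. Docked non-probability-1 interactions are
  taken from the low-probability end of the PCPI list, alternating ranks
  between the groups: the two probability distributions then overlap with
  medium slightly higher, which is the regime the probability-confidence
  regions are defined for. Probability-1 rows are capped at six so they
  stay a minority of the medium class — they necessarily classify at or
  above their own minimum energy, and letting them dominate would push the
  medium-class mean toward 1 and invert the region thresholds.

What it does **not** emulate: realistic chemistry (scaffolds are small
phenolics/flavonoids regardless of the class label), realistic biology
(gene sets and PPIs are sampled, not curated), correlated noise, or the
scale of real screens (a real compilation runs to hundreds of ligands and
thousands of predictions). Passing tests on fixtures therefore demonstrate
that the plumbing, joins, counts and calibration math are exact — not that
predictions on real data are accurate.

# Numerical and design choices

* Degenerate inputs: a single probability-1 docking record gives
  soft = hard; SD-0 groups collapse bands to means; empty medium or low
  docking classes are a calibration error that names the explicit-override
  escape hatch.
* Determinism: all randomness (layout jitter, fixture sampling) flows
  through locally seeded RNG with the caller's RNG state restored; log
  lines carry no timestamps, so a pipeline output directory is
  byte-identical across reruns of the same config.
* Tie-breaks: duplicate-edge resolution prefers the first encountered at
  equal probability; plurality compartment ties break alphabetically;
  layout orders nodes by id before placement.
* The command-line wrapper (`inst/cli/pcpinet`) exposes the composite
  drivers (`run`, `make-fixture`); the per-stage operations are the
  exported R functions themselves rather than one subcommand each.
* Problem sizes in the test suite (12-ligand, 12-protein fixtures;
  backgrounds of at most 20 genes for the exhaustive enrichment oracle)
  are chosen so every oracle can be enumerated exactly; the pipeline
  scales to realistically sized tables without modification.

# Known limitations

* Only O-glycosidic bonds are cleaved; other phase-I/II metabolism
  (oxidation, conjugation, ester hydrolysis) is out of scope.
* The saccharide pattern targets pyranose/furanose rings with free
  hydroxyls; heavily derivatized sugars (peracetylated, deoxy at every
  position) will not match.
* Headline counts from any real study (numbers of phytochemicals,
  predictions, enriched targets) depend on the versions of the external
  services that produced the inputs and are not reproducible from scratch;
  the package reproduces the *procedure* and verifies it on synthetic
  bundles with exact ground truth.
* Enrichment adjusted p-values differ from services using proprietary
  corrections (BH is used here); overlap sets are unaffected.
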