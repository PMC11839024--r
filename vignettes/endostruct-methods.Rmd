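---
title: "Methods: building an organelle structural interactome from cross-linking and co-fractionation evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building an organelle structural interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endostruct)
```

## The problem

Early/sorting endosomes carry several hundred resident and transiently
associated proteins, many of which interact only on the organelle membrane
and are lost by conventional affinity purification. Two organelle-level
proteomic readouts recover this interaction landscape: cross-linking mass
spectrometry (XL-MS), which identifies residue pairs close enough in space
to be joined by a chemical linker, and blue-native co-fractionation (BN-MS),
in which intact complexes co-migrate through a native gel so that subunits
share elution profiles across fractions. `endostruct` implements the
informatic half of such a study: scoring which proteins belong to the
organelle, filtering both evidence streams, integrating them into a network,
validating structural models of protein pairs and trios against cross-link
distance constraints, and scanning disease variants against predicted
interfaces.

## Meta-analysis of the organelle proteome

Three per-protein metrics predict endosomal localization:

1. **dataset presence** — the number of independent published organelle
   proteomics studies identifying the protein;
2. **organelle-IP abundance** — log-scale abundance in an
   endosome-immunoprecipitation experiment;
3. **reference interactions** — the count of reported interactions with
   well-known endosomal proteins.

Each metric is evaluated by ROC against a curated reference list, with a
binomial logistic regression as the predictor (`metric_roc()`); since the
logistic transform of one metric is monotone, the curve equals the ROC of
the raw metric, and separation warnings from the fit are immaterial. The
headline statistic is the partial AUC over the 0–10% false-positive range,
reported both raw (maximum 0.10) and normalized.

The combined score is the **summation of the three metrics**
(`combine_scores()`). Whether the metrics should be standardized before
summation was an open design choice: summing raw values lets whichever
metric has the largest numeric range dominate, so the default
rank-normalizes each metric to [0, 1] first, preserving the summation
semantics while making units commensurable; `standardize = FALSE` recovers
the raw sum. Missing IP abundance is imputed as the observed minimum —
absence of detection is treated as "not detected", the conservative choice
for an abundance metric — and the imputation count is messaged.

`call_endosomal()` thresholds the combined score at a 10% false-positive
rate among the reference negatives. Because no curated negative set exists,
negatives are defined as proteins *not* on the reference list — an
approximation that makes the realized FP rate conservative. The threshold
is the smallest distinct observed score whose FP rate does not exceed the
budget, which maximizes the number of called proteins subject to the bound;
ties at the threshold are included. Proteins on an exclusion list (e.g. a
mitochondrial catalogue) are never called regardless of score.

## Co-fractionation filtering

Elution profiles (48 fractions, fraction 1 = highest apparent mass) are
normalized per replicate (`normalize_profile()`, sum or max mode;
idempotent; all-zero profiles are flagged and excluded). The consensus
profile is the mean of the replicates after outlier handling
(`consensus_profile()`): the wording "excluding outliers as the most
dissimilar to the median" is ambiguous between dropping a *replicate* and a
*fraction*; the default drops the replicate whose Pearson correlation with
the per-fraction median profile is lowest, when that correlation falls
below a floor (default 0.5 — an uncorrelated or anti-correlated replicate
is an outlier; a merely noisy one is not). The fraction-level reading is
available via `mode = "fraction"`.

Candidate pairs pass `filter_bn_candidates()` when the per-replicate
co-elution score is at least **0.7 in at least 2 replicates**, the parent
complex has at most **25 proteins**, and the complex peak elutes at an
apparent mass of at least **67 kDa**. The mass rule needs a
fraction-to-mass calibration; `bn_calibration()` supplies a log-linear
ladder (5000 → 10 kDa across 48 fractions) standing in for the spiked
native-marker table of a real experiment. When no external co-elution
classifier score is supplied, `score_coelution_pairs()` uses `max(0, r)` of
replicate profiles — a documented stand-in on the same [0, 1] scale, not a
re-implementation of a random-forest co-elution classifier. The filter is
monotone in every replicate score, which the test suite verifies by random
perturbation.

## Cross-link tables

`dedup_crosslinks()` canonicalizes residue-pair links (sorted accessions;
sorted positions within a protein) so duplicate collapse is deterministic
and order-invariant, keeps the best search score per unique link, counts
replicates, and removes links with score ≤ 40 (the floor is strict: a
score of exactly 40 fails). `topology_check()` classifies each link by
membrane topology: cytosolic residues must pair with cytosolic, and
lumenal with extracellular (grouped as non-cytosolic); residues inside a
transmembrane segment take the class of the nearest flanking segment,
because linker-reactive lysines at TM borders are accessible from the
flanking compartment; residues in no segment are unannotated and excluded
from the consistency percentage. `collapse_to_pairs()` reduces links to
protein-pair edges with cross-link counts, recording intra-protein links
as self-evidence rather than hetero edges. `map_secondary_chemistry()`
maps acid–acid and acid–Lys links onto the Lys–Lys-defined interaction
set, expanding each link through peptide-ambiguity groups so one link may
annotate several interactions.

## Network integration

`build_network()` merges the two evidence streams into one undirected
simple graph, removing a blocklist (native-gel marker proteins, the
purification handle, ubiquitin, keratins). `endosome_center_filter()`
retains the endosomal proteins, their direct interactors, and second-order
interactors connected to **at least one direct interactor by cross-link
and/or two direct interactors by BN**; the alternative reading of the BN
clause (one edge passing in two replicates) is available via
`bn_rule = "two_replicates"`. Exclusively-nuclear proteins are removed as
doubtful connectivity. `core_component()` extracts the largest connected
component with deterministic tie-breaking (node count, then edge count,
then smallest member accession).

`network_stats()` reports the mean unweighted shortest path over connected
pairs and a power-law goodness of fit: the R² of the least-squares line on
log degree versus log frequency (degrees ≥ 1, empty bins dropped), with a
maximum-likelihood exponent fit behind `powerlaw_method = "mle"`. The
simple histogram fit is sensitive to sparse tail bins, so R² values depend
on graph size and density; the tests therefore compare scale-free against
Erdős–Rényi graphs rather than asserting one universal constant.
Communities come from Girvan–Newman edge-betweenness clustering cut at
maximum modularity; community counts are algorithm- and tie-break-sensitive,
so they are reported, not matched against an external reference value.
`rewire_null()` draws degree-preserving randomizations (double-edge swaps
rejecting loops and multi-edges, 100 permutations by default), each from
its own seeded substream. `complex_coherence()` compares within-complex
path distances and per-protein same-complex neighbor fractions against the
rewired nulls, with the empirical p-value `(1 + #{null ≥ obs}) / (n + 1)`,
bounded below by 1/101 at 100 permutations. `enumerate_3cliques()` lists
all triangles with at least one cross-link-supported edge — the input set
for trimeric structure prediction.

## Structural validation

Models are Cα-level: `structure_model` objects carry per-chain coordinates,
per-residue confidence (pLDDT; `NA` for experimental structures), and a
chain→accession map with sequence offsets, so every public coordinate is a
1-based full-length position. `evaluate_crosslinks()` classifies each link
as `within` / `exceeded` / `unstructured` / `unmapped` — an exhaustive,
mutually exclusive partition. The confidence gate requires **both residues'
pLDDT strictly above 70**; experimental structures (no pLDDT) skip the
gate. Distance ceilings are a chemistry × model-source matrix
(`distance_threshold()`): 35 Å for standard predictions and PDB structures,
30 Å for link-assisted predictions whose models already saw the links; the
acid–acid chemistry has no separately stated ceiling on standard models and
defaults to 35 Å with a config override. The boundary is inclusive: a link
at exactly the ceiling is within range.

`classify_prediction()` triages a prediction: `low-confidence` when the
SPOC classifier score is ≤ 0.33 (strict floor); otherwise `supported` when
more than 50% of distance-evaluable interprotein links are within range,
`unstructured-only` when every link falls in unstructured or unmapped
regions, `violated` otherwise. Records without a SPOC score are flagged
`unscored` unless an explicit ipTM floor is supplied — there is no
defensible default ipTM cut. `trimer_quality()` accepts a three-protein
model when at least two of its three pairwise interface-average scores are
strictly above 0.5; the exact definition of that per-interface statistic is
upstream of this package, so it is consumed as an input column.

Interface contacts default to Cα–Cα ≤ 8 Å (`contact_residues()`): models
here are Cα-only, so an all-atom criterion cannot be the default.
`variant_interface_scan()` marks a variant as near-interface when a contact
residue on the same protein lies within 2 positions *in sequence* — a
deliberately sequence-based window, since variant coordinates are sequence
positions. `export_pseudobonds()` writes viewer-ready link lines colored by
distance status.

## The synthetic world

`synthetic_world()` generates every input with ground truth attached:

* a presence/absence matrix over 16 studies with endosomal proteins
  detected at sensitivity 0.5 against a 0.05 background — chosen to mimic
  the observed spread where well-known endosomal proteins appear in a
  handful of 16 heterogeneous datasets while background proteins appear in
  at most one or two; 400 proteins at 20% endosomal keeps every test fast
  while leaving both classes large;
* complexes of 4 proteins with Gaussian elution peaks (SD 2 fractions) in
  the high-mass half of the gel and multiplicative log-normal noise
  (CV 0.1 by default; 0 for exactness tests);
* a scale-free (preferential-attachment) protein-pair cross-link network
  over 150 proteins, hub-enriched for endosomal accessions;
* an ideal-helix two-chain model (rise 1.5 Å, 100°/residue — sufficient
  geometry for distance tests, no physics) with a short second chain so the
  interface is local and far-from-interface positions exist; cross-links
  planted from true ≤ 35 Å contacts plus uniform decoys from longer pairs;
  variants planted inside and outside the 2-residue interface window.

All generators draw from named substreams of one master seed, so adding a
generator never perturbs another and regeneration is bit-identical. What
the generators do **not** emulate: mass-spectral noise and FDR structure,
peptide-level ambiguity, protein abundance bias in cross-link detection,
fraction-to-fraction carryover in the gel, and the conformational
heterogeneity of real predicted models. Passing tests therefore demonstrate
the correctness of the filters, counts, and geometry — not the biological
error rates of a real experiment.

## Numerical choices and problem sizes

Coordinates are held at 0.001 Å precision so structure files round-trip
exactly through the PDB format. Distance and score boundaries follow the
stated strict/inclusive semantics above. Empty denominators (no evaluable
links, no annotated pairs) yield `NA`, never 0. The test suite runs the
rewiring null at 100 permutations on a 500-node graph, the clique oracle on
50 graphs of up to 50 nodes, and the meta-analysis FP-budget check over 20
seeded worlds of 400 proteins — sizes chosen so the whole suite completes
in well under a minute while every check remains exact rather than sampled.

## Known limitations

* The co-elution score stand-in (`max(0, r)`) is cruder than a trained
  classifier; with noisy real data its 0.7 floor has a different operating
  point than an external random-forest score.
* Negative-class definition for the FP threshold treats all non-reference
  proteins as negatives; true-but-unlisted endosomal proteins inflate the
  apparent FP rate, making the call conservative.
* Power-law R² from a histogram least-squares fit is a descriptive
  statistic, not a model test; use the MLE mode for inference.
* Community counts depend on tie-breaking in the betweenness hierarchy and
  should be compared qualitatively between runs, not as exact integers.
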