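---
title: "orfpipe: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orfpipe: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfpipe)
```

orfpipe models the informatics of a cloned-ORF collection: enzyme
annotation by sequence similarity, subcellular localization,
cloning-primer design and structural verification from sequencing
reads. This vignette describes each model, every default parameter,
and the design decisions that shaped the implementation. All examples
run on the package's own synthetic-data generator.

## Local alignment and E-values

All sequence comparison is exhaustive Smith–Waterman local alignment
with affine gap penalties, provided by `local_align()` and the
scoring schemes of `scoring_scheme()`:

- protein: BLOSUM62, gap open −11 / extend −1, λ = 0.267, K = 0.041;
- nucleotide: match +1 / mismatch −2 (N never matches), gap open −5 /
  extend −2, λ = 1.28, K = 0.46.

A gap of length L costs |open| + L·|extend|. E-values use the
Karlin–Altschul form E = K·m·n·exp(−λS); this is an ungapped-style
approximation, and every downstream decision thresholds E or the
alignment's identity/coverage rather than interpreting E absolutely.
Percent identity is identities divided by alignment columns (gap
columns included); coverage is the aligned span over the sequence
length (`length_coverage()`).

The dynamic program is delegated to
`Biostrings::pairwiseAlignment(type = "local")`. The package's test
suite pins the contract — optimal scores are verified against a
brute-force enumeration of all alignments of all substring pairs on
small instances — so the backend is interchangeable. One consequence
worth knowing: among *co-optimal* alignments the engine's traceback
picks one deterministically, but not necessarily the one a different
engine would pick; the package guarantees determinism and score
optimality, and its thresholds operate on score, identity and
coverage, which are insensitive to the choice among co-optimal paths
in practice.

```{r alignment}
a <- seq_set(c(p1 = "MKVLAAGHKWEDQRR"), "protein")
b <- seq_set(c(p2 = "GGMKVLAAGHKWEDY"), "protein")
local_align(a, b)
```

## Enzyme annotation

`annotate_enzymes()` implements a two-stage transfer:

1. **Reciprocal best hits.** An ORF receives the EC numbers of a
   database protein when each is the other's best-scoring hit with
   E ≤ 1e-3 in both directions (`reciprocal_best_hits()`). Score
   ties break toward the lexicographically smallest id, so results
   do not depend on input order.
2. **Paralog propagation.** The full proteome is clustered by single
   linkage: an edge joins two proteins when their optimal local
   alignment reaches ≥35% identity and covers ≥70% of *both*
   sequence lengths; clusters are the connected components
   (`cluster_paralogs()`, via igraph, relabelled by smallest member
   for order invariance). Unannotated members of a cluster with at
   least one direct hit receive the union of the cluster's direct EC
   sets, provenance `paralog_propagated`; clusters whose direct
   members disagree are flagged `ambiguous_cluster` rather than
   suppressed. Single linkage chains deliberately: two sequences
   below threshold between themselves still cluster through an
   above-threshold intermediate.

The coverage cutoff is applied to both sequences by default
(`coverage_mode = "both"`); `"shorter"` relaxes it to the shorter
sequence — a choice exposed because annotation-transfer pipelines
differ on this point and the stricter reading is the safer default
for propagating enzyme function.

```{r ec}
cfg <- simulation_config(seed = 1, n_families = 4L,
                         members_per_family = 3L, n_decoys = 3L,
                         ancestor_length = c(120L, 200L))
db <- simulate_enzyme_db(cfg)
prot <- simulate_proteome(db, cfg)
ann <- annotate_enzymes(prot$proteome, db$db)
table(ann$assignments$provenance)
```

## Localization

`predict_localization()` scores each protein against two labelled
reference sets — a plant and an animal lineage — with k-nearest
neighbors (k = 32) and converts neighbor counts to probabilities
P(cᵢ) = N(cᵢ)/k over ten compartments (`COMPARTMENTS`: chlo, cyto,
cysk, er, extr, mito, nucl, pero, plas, vacu). Per lineage, a protein
is binned to a compartment only when strictly more than 50% of its
neighbors share it, otherwise to `"other"`. The two lineages are then
consolidated at an 85% cutoff on the top probability: both qualify →
the higher confidence wins, ties to plant; one qualifies → that
lineage; neither → `"other"` with `lineage_used = "none"`.

The features are the 20 amino-acid frequencies plus log sequence
length — a deliberate stand-in for the richer sorting-signal features
of trained predictors. The module's contract is the neighbor-count
probability arithmetic and the binning/consolidation rules, not the
feature engineering; the reference sets are an injection point for
real labelled data. Distance ties at the k-th neighbor break by
reference id, so predictions are deterministic.

```{r loc}
sim <- simulate_compartment_refs(simulation_config(seed = 2))
res <- predict_localization(sim$queries[1:5], sim$plant, sim$animal)
res$consolidated
```

## Primer design

`design_orf_primers()` produces one Gateway-tailed pair per CDS. The
forward gene-specific part is a CDS prefix starting exactly at the A
of the ATG; the reverse part is the reverse complement of the CDS
suffix ending at the last base before the stop codon. Each part is
grown from 18 to at most 30 nt and the *shortest* length whose
melting temperature falls in [55, 65] °C wins; attB1.1 / attB2.1
tails are prepended (overridable). If no length qualifies the design
fails with an error naming the ORF; `design_primer_set()` collects
such failures per row instead of stopping. High-GC CDSs (the
generator's default regime is 64% GC) can exceed 65 °C already at
18 nt — a real failure mode that is reported, not hidden.

Tm uses the unified nearest-neighbor thermodynamic model (Allawi &
SantaLucia 1997): Tm = 1000·ΔH / (ΔS + R·ln Cₜ) − 273.15 with
duplex-initiation terms per terminal base, total strand concentration
500 nM, and the entropy salt correction 0.368·(N−1)·ln[Na⁺] at 50 mM
Na⁺. The implementation matches an independent reference
implementation to ~1e-5 °C (values frozen in the tests). The Wallace
2(A+T)+4(G+C) rule is available as `method = "wallace"`. Note that
nearest-neighbor Tm is not monotone in primer length — appending an
AT-rich base can lower it — which is why the search simply scans
lengths in order.

```{r primers}
cds <- reverse_translate(seq_set(c(orf1 = random_protein(150)), "protein"),
                         gc_content = 0.5, seed = 3)
design_orf_primers(cds)[c("forward_full", "reverse_full",
                          "forward_tm", "reverse_tm")]
```

## Verification from shotgun reads

`verify_references()` implements a fixed calculus:

1. `trim_reads()` removes vector and adapter contamination and drops
   reads shorter than 20 nt. A qualifying contaminant match needs
   ≥90% identity over ≥10 nt at a read end *and* must include the
   contaminant terminus facing the read interior (anchored, the way
   adapter trimmers work); the best-scoring qualifying match clips
   first, repeating until stable. Anchoring matters: the attB1.1 and
   attB2.1 tails are near-duplicates of each other, and unanchored
   greedy clipping can cut one base into the insert or fire on
   chance internal look-alikes.
2. `map_reads()` aligns each read (both strands) against the
   references and keeps hits with ≥40 nt aligned span on the read
   and ≥90% identity; reads may map to several paralogous
   references. A k-mer prescreen (k = 12, both strands) skips
   references sharing no exact k-mer with a read; it is a
   performance shortcut, tested to leave the mapping output
   unchanged, and `prefilter_k = NULL` disables it.
3. `coverage_profile()` counts per-base depth;
   `classify_verification()` calls a reference **verified** when
   strictly more than 98% of its length is covered, **unsupported**
   below 20%, **partial** between, and bins coverage into
   [95,100], [50,95), [20,50), [0,20).

Coverage is computed from read mappings directly rather than from an
intermediate assembly: per-base reference coverage is the quantity
the verification rule is defined on, so assembly would only add a
failure mode.

## Paired end reads (OSTs)

ORF sequence tags — one read from each end of a clone — verify clone
structure in `verify_ost_set()`. After trimming, `assemble_ends()`
merges the forward read with the reverse-complemented reverse read
when they overlap by ≥20 columns at ≥95% identity in
suffix-to-prefix geometry (forward read wins disagreements). An end
is verified when a read (or the contig) aligns at ≥95% identity
covering the terminal base; `full_length_contig` additionally
requires a contig at ≥98% identity over ≥98% of the reference. A
clone truncated at one end therefore fails exactly that end — the
property the synthetic generator's truncation truth is tested
against.

## Synthetic data

`simulate_all()` writes a complete ground-truthed input set. Design
points:

- **Determinism.** One global seed expands into fixed per-stage child
  seeds (offsets 1–6), so any stage regenerates identically in
  isolation; `with_seed` scoping restores the caller's RNG state.
  Identical config + seed reproduces every file byte for byte, and a
  manifest records the config plus an FNV-1a checksum per file.
- **Proteome.** Families are point-mutant clouds (no indels, so
  identity is analytic) around database ancestors at a target
  within-family identity (default 0.80, 20 families × 5 members,
  plus 20 decoys of 150–600 aa).
- **Compartment references.** Each compartment draws a Dirichlet
  (α = 0.5) amino-acid composition, blended toward uniform by
  1 − `composition_bias`; plant and animal lineages mix in
  independent perturbations (rate 0.1). At `composition_bias = 0`
  compartments are indistinguishable — the knob that lets tests
  assert accuracy degrades to chance.
- **Coding sequences.** Reverse translation samples synonymous
  codons with weights exp(θ·gc(codon)), θ calibrated per protein
  (uniroot) so the expected GC equals the target (default 0.64,
  clamped to the achievable range). Translation inverts it exactly.
- **Reads.** Shotgun reads come from repeated random fragmentation
  of the tailed amplicon (B1 tail + CDS + reverse-complemented B2
  tail), which guarantees terminal coverage at depth; depth has a
  low-expression tail and a zero-read fraction; substitution errors
  default to 1% per base. End reads (600 nt, error-free by default)
  carry vector + tail contamination, with 5% of clones truncated by
  20–100 nt at one end.

Problem sizes in the shipped defaults (120-ORF proteome, 500
reference proteins per lineage, ~thousands of reads) are the
package's own choices, set to exercise every stage in seconds to
minutes on one core.

## Pipeline

`run_pipeline(pipeline_config(seed = ...), out_dir)` executes
simulate → annotate → localize → primers → verify → ost, each stage
toggleable, writing per-stage TSVs, a run log (version, configuration
fingerprint, seed, explicit non-default overrides) and
`summary.json`. `score_run()` joins the outputs back to the truth
tables: EC recovery, decoy false-annotations, held-out localization
accuracy, verification rates, and agreement of OST end verification
with the planted truncations. Orchestration is deliberately plain
functions plus a thin `Rscript` entry point (`scripts/acceptance.R`)
rather than an installed executable — the natural command-line
surface of an R package.

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 7L)
run_pipeline(cfg, "run_out")
score_run("run_out")
```

## Default constants

| Parameter | Default |
|---|---|
| RBH E-value cutoff | 1e-3 |
| Clustering identity / coverage | 0.35 / 0.70 (both sequences) |
| k (nearest neighbors) | 32 |
| Primary bin threshold | > 0.5 |
| Consolidation cutoff | ≥ 0.85 (ties → plant) |
| Mapping overlap / identity | ≥ 40 nt / ≥ 0.90 |
| Verified coverage | > 98% |
| Coverage bins | [95,100], [50,95), [20,50), [0,20) |
| Minimum read length after trimming | 20 nt |
| Primer Tm window / length range | 55–65 °C / 18–30 nt |
| Protein scoring | BLOSUM62, −11/−1, λ 0.267, K 0.041 |
| Nucleotide scoring | +1/−2, −5/−2, λ 1.28, K 0.46 |

These constants are asserted verbatim by the acceptance tests, so a
change to any of them is a deliberate, visible act.
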