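---
title: "Methods: provenance-explicit multilocus phylogenomics with phylocrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provenance-explicit multilocus phylogenomics with phylocrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocrate)
```

## The container model

A `pc_project` holds an entire multilocus experiment: locus definitions,
sequence records, alignments (raw and trimmed), trees, supermatrix recipes
and realizations, per-locus statistics, and the provenance ledger. All
verbs that change the project take it as their first argument and return
the updated copy; side results (counts, filter reports, newly built
objects) ride along as the `"result"` attribute, read with `op_result()`.
R's copy-on-modify semantics make `fetch()`ed objects independent copies
for free.

Identifiers are designed to stay meaningful to a human while remaining
collision-free:

* **records**: `<locus>_<accession-or-source>_f<serial>`, with the serial
  assigned at read time;
* **process ids**: a zero-padded serial plus the operation name, e.g.
  `0007_align`. Timestamps live inside the ledger entry, not the id, so a
  replayed analysis produces the same ids;
* **derived objects** (alignments, trimmed alignments, trees) are suffixed
  with the process id that made them (`coi@0007_align`), which also
  disambiguates the same locus aligned twice under different settings.

Locus names and aliases are folded case-insensitively with underscores,
hyphens, dots and spaces removed, because database gene naming is
inconsistent (`cox1`, `COX-1` and `COI` should land in one bin). Folding is
applied when loci are declared (collisions are an error naming both loci)
and whenever user input names a locus. A record belongs to exactly one
locus; overlapping features that would justify dual membership are rare and
their support would complicate every downstream occupancy computation, so
the restriction is deliberate.

Each OTU (tree tip) is the value of one metadata field per record. The
field is a project-level setting, `otu_field`, defaulting to `"organism"`,
since that is the qualifier GenBank records reliably carry; any other
metadata column (say, a population label) can serve instead.

## Statistics

Five families are computed per locus by `compute_locus_stats()`:

* **Column entropy** (bits): SE = −Σ p·log₂ p over the frequencies of
  unambiguous, non-gap residues in the column. Gap characters are `-`, `?`
  and `.`; ambiguity codes (N, X, IUPAC degenerates) are also excluded from
  the frequencies, generalizing "ignore gaps" to "ignore uninformative
  symbols". A column with no informative residue has **missing** entropy
  (`NA`), never 0 — an all-gap column is not evidence of conservation. Log
  base 2 is conventional; any base preserves the ordering the gradient
  machinery uses. Bounds: 0 ≤ SE ≤ 2 for DNA, ≤ log₂ 20 for protein.
* **Gap score**: fraction of rows with a non-gap character; 1 means
  gap-free. This orientation matches gap-threshold trimming, which keeps
  columns whose score is at least the threshold.
* **Conservation**: frequency of the modal unambiguous residue among
  unambiguous residues. Published conservation scores sometimes weight by
  a similarity matrix; the identity-based score was chosen because it is
  deterministic, parameter-free and monotone in what the gradient sorting
  needs. It is a documented substitute, not a reimplementation of any
  specific matrix-weighted score.
* **Length**: ungapped residue count; ambiguity codes count (they are real
  sequenced positions).
* **GC content**: (G+C)/(A+C+G+T) on the ungapped sequence, ambiguity
  codes excluded from numerator and denominator. The same function backs
  GC-based filtering, so filters and statistics can never disagree.

Summaries use linear interpolation between order statistics
(`quantile(type = 7)`), chosen because it is R's default and fully
specified, making summaries bit-reproducible: for values 1…100 the 25th
percentile is 25.75, the median 50.5, the 75th percentile 75.25. Whiskers
follow the 1.5·IQR rule, and collapse to the median when the box has null
range (a whisker has no meaning without a box).

## Slicing and sliding along a gradient

`sort_loci()` orders the selected loci by a summary (median, p25 or p75) of
a statistic; ties break lexicographically on the locus name so the order is
total and deterministic. `slice_loci()` selects the loci whose summary lies
in a closed interval; an empty selection is an error that reports the
observed range rather than silently building an empty supermatrix.

`slide_loci()` cuts windows at offsets k·step for k = 0 … ⌊(n−w)/s⌋, each
containing exactly `width` loci. A trailing remainder that cannot fill a
window is dropped: windows are compared against each other downstream, and
equal-sized supermatrices are the only fair comparison. (An end-anchored
final window — guaranteeing the very lowest-ranked loci appear — would be a
reasonable alternative; strict offsets were chosen because the window count
then follows the closed formula above, which the tests verify against
explicit enumeration.)

## Supermatrices

A `concatenation()` is a declarative recipe: ordered loci, the OTU field,
and occupancy rules. `build_supermatrix()` realizes it: one aligned
sequence per OTU per locus, partitions recorded as 1-based inclusive
intervals (the PHYLIP/RAxML convention), and an OTU×locus occupancy table.

* When an OTU has several records for a locus, the longest ungapped
  sequence is used, ties broken by lexicographic record id — deterministic
  and information-favoring.
* Missing cells are filled with `?`, distinguishing "locus absent for this
  OTU" from alignment gaps `-`.
* `rules = "complete"` requires every OTU to carry every locus, producing a
  zero-missing-data matrix; arbitrary `otus_must_have` / `min_loci_per_otu`
  rules cover intermediate designs.
* Building prefers the trimmed alignment when one exists (trimming is
  requested deliberately, so using it downstream is the least surprising
  default); `use_trimmed = FALSE` overrides.

## Stages and adapters

The native stages exist so the full pipeline runs and is testable with no
external binaries: pass-through alignment registration for already-aligned
input, a gap-threshold trimmer (keep columns with non-gap fraction ≥ gt;
gt = 0 is the identity, gt = 1 keeps only gap-free columns, and kept-column
sets are monotone in gt), and neighbor joining on p or JC69 distances.
Distances use pairwise deletion of gap/ambiguous sites; JC69 is undefined
at p ≥ 3/4 and the offending pair is named. Negative NJ branch lengths are
clamped to zero with the deficit moved to the sibling branch, the standard
repair that preserves path lengths through the parent. Protein data uses
the p distance only.

Real aligners and tree builders plug in as adapters: a shell command
template with `{in}`, `{out}` and `{params}` placeholders plus a version
probe. The probe runs before anything is written, so a missing executable
errors before any mutation; the probed version string is stored in the
ledger entry, which is how tool versions reach the report.

## Tree distances

All metrics work on the bipartition (split) representation, which is
invariant under re-rooting; inputs are unrooted first and multifurcations
are allowed.

* **Robinson–Foulds**: count of non-trivial splits present in exactly one
  tree; ≤ 2(n−3) for binary trees.
* **Branch score**: √Σ(b₁−b₂)² over the union of splits, absent splits
  contributing 0. Pendant branches are included by default
  (`include_pendant = TRUE`) since the metric is defined over all branches;
  the flag restricts to internal branches when topology-adjacent length
  structure is the question.
* **Standardized branch score**: each tree is first divided by its total
  length, so trees differing only by a uniform rate scale compare as
  identical. Total tree length is the simplest reading of "standardizing
  the evolutionary rate"; the normalizer is an explicit strategy point
  (`rescale_to_unit_length()`) should another convention be preferred.

The implementation extracts splits by postorder accumulation over the edge
matrix. The test suite checks all three metrics against two independent
routes: a naive recursive enumerator written separately in the tests, and
phangorn's `RF.dist`/`KF.dist`.

## Provenance layer

Serialization is a single file: one header line carrying a format tag and
the md5 of the body, then a JSON body holding every field — sequence rows,
Newick strings, statistics arrays, the full ledger. An open format was
preferred over language-native object pickling because the file then
remains readable with any JSON parser, without this package or even R.
Loading verifies the checksum first; corrupt or truncated files fail with
an integrity error and no partial object.

Checkpoints are content-addressed: the id is the md5 of the serialized
body, so an unchanged project checkpoints to the same id (a no-op) and the
store deduplicates states. The chain is linear and append-only
(`objects/<hash>.json` + `chain.jsonl`); restoring an old checkpoint
recovers every intermediate object and the ledger prefix, and toggling
forward again is always possible. Forks are represented inside the project
as alternative objects (distinguished by their process-id suffixes) rather
than as store branches, which keeps the history trivially navigable.
Ledger timestamps are data (they were true when written) and serialize with
everything else; determinism claims are therefore about re-serializing the
same state, and the report's `Generated:` header is the only line excluded
from its determinism comparison.

The archive bundles the serialized project, FASTA alignments, Newick and
PhyloXML trees, supermatrices with partition and occupancy files, the
report, the checkpoint listing and an md5 manifest into one zip; extracting
it and loading `project.json` reproduces the project exactly.

## Synthetic data

`synth_dataset()` draws, per column, a dominant residue and then per-row
residues that equal it with probability 1 − 3d/4 (d the locus diversity in
[0, 1]); d = 0 gives invariant columns, d = 1 uniform ones, and expected
entropy is strictly increasing in d. Diversity above 1 would demand more
than the 2-bit DNA ceiling and is an error. Defaults emulate the
use-case scale: 465 loci × 26 taxa, 300 bp, full occupancy, a strictly
decreasing gradient.

What the generator does *not* emulate matters for interpreting green
tests: columns are i.i.d. (no among-site rate correlation), rows are
exchangeable (no phylogenetic structure), and sequences come pre-aligned
without indels. Passing tests therefore demonstrate the correctness of the
statistics, sorting, windowing, concatenation and provenance machinery —
not that any inference on real, indel-rich, phylogenetically structured
data is well calibrated. `synth_trees()` similarly provides random binary
trees with a divergence knob (leaf relocations; 0 = identical copies) for
exercising the distance machinery, not realistic tree shapes.

## Problem sizes and numerical notes

The test suite runs the full gradient pipeline at the use-case scale
(465 × 26 × 300, seconds to a minute) and fuzzes the rest at small sizes:
200+ random tree pairs with 4–8 taxa for the distance oracles, 10–30 loci
for gradient recovery (10 well-separated diversity levels at 500 bp are
recovered in exactly the generated order under a fixed seed; 465
near-adjacent levels are recovered at rank correlation ≈ 0.999, which is
why the acceptance script reports the correlation at full scale).
Floating-point details: `−Σ p log₂ p` is normalized to drop IEEE negative
zero so serialized output is byte-stable; branch-score comparisons use
1e-9 absolute tolerance; Newick branch lengths serialize at 12 significant
digits, which makes re-serialization a fixed point.

## Known limitations

* GenBank parsing covers the flat-file subset the harvest needs (simple,
  `join` and `complement` locations, quoted multi-line qualifiers); exotic
  location operators (`order`, cross-entry references) are not interpreted
  beyond their ranges.
* No NEXUS writer; trace (ab1) files must be converted to FASTA upstream.
* The container is whole-in-memory by design — datasets far beyond the
  hundreds-of-loci scale would need a different storage model.
* Native tree building is distance-based NJ only; likelihood or Bayesian
  inference is adapter territory.
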