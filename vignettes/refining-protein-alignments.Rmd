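---
title: "Refining protein multiple sequence alignments with msaRefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining protein multiple sequence alignments with msaRefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaRefine)
```

## The problem and the approach

A protein multiple sequence alignment (MSA) produced by any of the
standard aligners is rarely uniformly good: the conserved central
portion of a protein family is usually recoverable, but local gap
placement within it is often suboptimal, and the terminal regions are
intrinsically unreliable. `msaRefine` is a *post-processor*: it takes an
existing alignment and improves gap placement locally, never touching
residue content or row order.

The workflow has two levels.

**Segmentation.** Columns containing a residue in every row (gap-free
columns) mark the trustworthy central region. The input is cut at its
first and last gap-free columns: everything before the first becomes the
*head*, everything after the last the *tail*, and the span between them
(inclusive) the *target*. Head and tail pass through verbatim — in
poorly alignable terminal regions a realignment is as likely to destroy
signal as to add it — and only the target is refined.

**Vertical iterative realignment** of the target:

1. Strip all gaps and re-align the bare sequences with an inner MSA
   engine; reorder the result to the input's row order.
2. If the result is column-for-column identical to the input (including
   all-gap column placement), the region has converged: return it.
3. Otherwise map both alignments positionally — gaps label 0, the
   *k*-th residue of a row labels *k* — and match columns whose label
   vectors are identical (all-gap columns never match, since an all-zero
   vector would match ambiguously). Maximal runs of matches advancing by
   +1 in both coordinates, of length at least `minAnchorLen` (default
   2), become *unchanged anchors*; the spans between them become
   *changed region pairs*: the same residues, gapped differently.
4. Anchors are kept verbatim from the input. For each changed pair both
   fragments are scored with the sum-of-pairs objective below; the
   higher-scoring side wins, ties keeping the input's version, and the
   winner is itself refined recursively.
5. The refined pieces are concatenated in order.

The objective for an *M*-row, *N*-column fragment is the sum-of-pairs
(SP) score: per column, the sum of `score(i, j)` over all ordered pairs
of distinct rows, summed over the *N* columns. `score(i, j)` is a
substitution-matrix entry when both characters are residues, `aaGap`
when exactly one is a gap, and `gapGap` when both are. Counting ordered
pairs doubles every unordered pair; the doubling rescales all scores by
2 and cannot change any comparison, and it is kept because it is the
form in which the column score is conventionally written. All scores are
integers, so ties are exact, never a floating-point artifact.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| substitution matrix | BLOSUM62 | residue-residue scores; PAM250 bundled, any NCBI-format file accepted |
| `aaGap` | −6 | residue-vs-gap score (score units of the matrix) |
| `gapGap` | 0 | gap-vs-gap score |
| `minAnchorLen` | 2 | minimum unchanged-anchor run length (columns) |
| `maxDepth` | 10 | recursion depth backstop |
| `noConservedPolicy` | `"all"` | input with no gap-free column: refine it whole (`all`) or return it untouched (`skip`) |
| backend | `muscle5` | inner MSA engine (`muscle5`, `fftnsi`, `builtin`, or a custom command/function) |

BLOSUM62 with `aaGap = -6` and `gapGap = 0` is the recommended default
configuration: across the standard protein benchmark collections the
refinement's accuracy stabilizes once the residue-gap penalty reaches
about −6, and BLOSUM62 matches or beats PAM250 throughout, while a
gap-gap score of 0 keeps existing gap structure cost-neutral so that
arbitration is driven by residue placement. `minAnchorLen = 2` demands
two consecutive identical columns before trusting a region as unchanged;
a single identical column is too weak an anchor. Matrices are taken from
`Biostrings` (`scoringMatrix("BLOSUM62")`); letters a matrix lacks
(U, O, and J in some matrices) are scored through its `X` wildcard row,
the conventional treatment for rare/ambiguous residues.

## Inner aligner backends

The engine used in step 1 is pluggable. `muscle5` (default) and
`fftnsi` shell out to `muscle`/`mafft` through configurable command
templates with `{in}`/`{out}` placeholders, temporary FASTA files and a
per-call timeout (600 s). The `builtin` backend is a deterministic
center-star progressive aligner: the center sequence maximizes the
summed pairwise global-alignment score (ties to the lowest input
index), each other sequence is aligned to the center by
Needleman–Wunsch under the objective's matrix with a flat
per-character gap cost of |`aaGap`| (the pairwise dynamic program is
`Biostrings::pairwiseAlignment` with zero gap-opening cost), and the
pairwise alignments are merged on the center's coordinates with the
usual "once a gap, always a gap" rule. The builtin backend exists so
that tests, examples and the reproduction script run with no external
binary and are bit-reproducible; it is *not* claimed to match a
dedicated MSA tool's alignment quality. Reproducibility claims are
scoped to it — external tools are invoked as-is, with no attempt at
seed control. A third backend kind wraps an arbitrary R function, which
the test suite uses for adversarial engines.

Whatever the backend, its output is checked before use: it must contain
exactly the submitted ids, and stripping its gaps must reproduce the
submitted sequences. Degenerate inputs never reach the engine: empty
sequences are withheld and re-inserted as all-gap rows, a single
non-empty sequence is returned as-is, and an all-empty set yields a
width-0 alignment.

## Numerical and structural choices

**Coordinates.** All column spans are 1-based and closed, the
R/Bioconductor convention; a span with `end = start - 1` is empty.

**Anchor soundness.** Two screens are applied to candidate anchors
before partitioning, both necessary for correctness on adversarial
engine output. First, a matched column pins down, for every row with a
residue in it, how many residues of that row precede it — but for rows
*gapped* in the anchor column (label 0) it pins down nothing, so the
two alignments can agree on the column yet disagree on how many
residues of a gapped row lie before it; such an anchor would put
different residues into its flanking changed regions. Anchors are
therefore required to agree with per-row cumulative residue counts at
their boundary. Second, two anchor runs whose columns share no row
carry no mutual order constraint and can cross (forward in one
alignment, backward in the other); a jointly increasing subset
maximizing the number of anchored columns is selected by a small
dynamic program. Columns excluded by either screen simply fall into
changed regions and remain subject to arbitration. On realistic engine
output both screens are almost always no-ops.

**Termination.** The only natural exit of the iteration is the engine
reproducing its input. An engine that keeps proposing a rejected
alternative would recurse forever, so two guards are added: a changed
pair spanning the entire current input whose input side wins is
returned without recursion (the recursive call would be the identical
computation), and recursion depth is capped at `maxDepth` (default 10),
returning the current best fragment and noting the event in the report.
Changed fragments with fewer than two non-empty rows are passed through
without an engine call — there is nothing to align.

**Segmentation boundary cases.** The cut-point columns themselves
belong to the target region, keeping the outermost gap-free columns
available as anchors; head and tail are then purely pre-/post-conserved
flanks. An input with *no* gap-free column has no defined cut points;
by default the whole alignment becomes the target (`"all"`), on the
view that the worst alignments have the most to gain, with `"skip"`
available for a strictly conservative run. This fallback is a policy
choice of this package, not part of the method's definition.

**Evaluation.** `qScore` is the fraction of reference-aligned residue
pairs reproduced by the test alignment; `tcScore` the fraction of
reference columns whose (annotated) residues are reunited in a single
test column. Reference alignments in the benchmark tradition mark
unreliable positions in lowercase; lowercase positions are excluded
from both numerator and denominator, following the benchmark suites'
documented convention. A reference with nothing to score yields 0 with
a warning rather than an error. In `tcScore`, a column's lowercase
residues are exempted from the reunification requirement, and a column
whose only annotated content is a single residue counts as reproduced.

## The synthetic family generator

Real benchmark references (BAliBASE, OXBench, PREFAB, SABmark) are
external curated data; the package instead ships a generator whose
output has the one structural property the method relies on: a
conserved, gap-free central core flanked by more variable regions.
`generateFamily()` samples an ancestor uniformly over the 20 standard
residues and evolves each descendant independently with per-site
substitutions and geometric-length insertions/deletions; the middle
40–60% of ancestor positions are exempt from indels, so the true
alignment always has a gap-free central block. Insertions are private
to their sequence and occupy their own columns — no homology is claimed
between independent insertions. `degradeAlignment()` then produces an
imperfect "initial alignment" by locally swapping gaps with adjacent
residues, never touching the first/last gap-free columns.

Defaults — 8 sequences, ancestor length 200, substitution rate 0.10,
indel rate 0.03, mean indel length 1.5 — describe a moderately diverged
protein family (roughly 80–90% pairwise identity, a handful of short
indels per sequence): divergent enough that gap placement is
non-trivial, conserved enough that a reference-free refinement can
plausibly recover the truth. What the fixtures deliberately do *not*
emulate: domain shuffling, long low-complexity insertions, alignable
homologous insertions shared by subsets of sequences, and realistic
site-rate heterogeneity. Passing the fixture-scale tests therefore
shows the machinery is correct and non-destructive under the stated
model, not that the accuracy gains transfer to any particular real
family — for that, the tool should be run against curated references
with a production engine (MUSCLE5) as the backend.

The package's tests and the reproduction script use these problem
sizes: fuzzed structural checks on up to 10 sequences × 80 columns;
region-detection and scoring oracles on hundreds of random cases up to
6 × 12; and the accuracy study on 20 seeded families of 8 × 200
degraded by 30 gap shifts, where refinement with the builtin backend
must not reduce median Q or TC. All are deliberately small enough to
run in minutes on one CPU while still exercising every code path.

## Known limitations

- One target region only: the method refines a single central span, by
  design; alignments with several conserved blocks separated by long
  gappy stretches are handled, but the whole stretch between the first
  and last gap-free column is treated as one region.
- The SP objective has flat per-character gap penalties; there is no
  affine gap-open/extend model and no sequence weighting, so families
  with heavily duplicated subgroups can bias the arbitration.
- The builtin center-star backend is a correctness-and-reproducibility
  device; for production refinement use MUSCLE5 or MAFFT.
- With an external engine, improvements are bounded by that engine's
  quality on the stripped sequence set; the method guards against
  *accepting* a worse region (by SP score), not against an engine that
  fails outright.
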