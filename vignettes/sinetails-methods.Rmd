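---
title: "SINE tail classification: model, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SINE tail classification: model, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinetails)
```

## The problem

SINE retrotransposons integrate with a 3′ poly(A) tail. After insertion the
tail keeps mutating: slippage expands adenine-plus-one-base microsatellites
(AT-, AC- and AG-series motifs of length 2–5), so tail structure carries a
record of post-insertion evolution. `sinetails` extracts tails from
RepeatMasker annotations, classifies their structure, dates the insertions,
and compares tails across genome assemblies. This vignette documents the
model behind each stage, every tunable parameter, and the design decisions
that were genuinely open.

All internal coordinates are 0-based half-open; conversion to and from
1-based inclusive conventions happens only at parse/write boundaries
(RepeatMasker `.out`, GFF3). Sequences are uppercase `ACGTN`; `N` matches
no motif base and breaks adenine runs.

## Tail extraction

The body→tail boundary is marked by a short *cutoff motif* (a
subfamily-specific 8–20 bp sequence at the 3′ end of the element body).
Matching is hierarchical:

1. an **exact** pass over the subfamily's motifs, then the global (`*`)
   motifs, in library order;
2. a **single-substitution** pass (Hamming distance ≤ 1) in the same order.

An exact match of a lower-priority motif therefore beats a mismatched match
of a higher-priority one: the pass, not the motif, is the outer loop,
because a mutated copy of the right motif is less trustworthy than a
perfect copy of any boundary marker. Within one motif, the occurrence whose
end lies closest to the element's 3′ end wins — tails are terminal, and a
spurious internal copy of the motif must not truncate the body. Everything
downstream of the match is the tail; its length is uncapped.

Elements with no recognisable cutoff receive their terminal
`fallback_length` bases (default 30, configurable to 20/40) as the tail,
flagged `method = "fallback"`. Fallback tails are classified like any
other tail by default; the alternative reading in which such elements are
assigned directly to "Other" is available as `strict_other = TRUE` in
`sine_tail_scan()`. We default to classifying them because the fallback
window is explicitly designed to capture the tail, and discarding it would
silently conflate "no boundary found" with "no structure present".

## The classification rule system

`classify_tail()` is a total, deterministic cascade:

1. **A-rich** — the longest continuous adenine run has length ≥
   `arich_min_run` (default 5) *and* covers ≥ `arich_min_coverage`
   (default 0.70) of the tail. We read "70% continuous adenine" as
   *longest-run coverage*, not total A content: the canonical second
   A-rich worked example (a 19-bp run in a 27-bp tail, 70.4%) passes under
   this reading and fails under a naive total-content reading applied to
   its run. The total-content interpretation remains available
   (`arich_total_a = TRUE`).
2. **Single motif `(m)n`** — for each of the twelve AN-series motifs, the
   maximal number of adjacent, non-overlapping tandem copies anywhere in
   the tail (any phase) is computed. A motif qualifies when
   (a) its copy count reaches `min_consecutive[motif length]`
   (defaults: 5-mers 2, 4-mers 3, 3-mers 3, 2-mers 3), and
   (b) the run starts within the first `max_run_start_frac` (default 0.5)
   of the tail. Among qualifiers, the largest tandem-run span in bp wins;
   ties prefer the longer motif, then the leftmost run.
3. **Series composite** — a series (AT, AC or AG) qualifies when at least
   `composite_min_distinct` (default 2) of its motif types are present
   *standalone* — i.e. through at least one occurrence not wholly embedded
   in an occurrence of a longer same-series motif — and occurrences of the
   series' motifs cover ≥ `composite_min_coverage` (default 0.5) of the
   tail. Among qualifying series the one covering more bp wins (ties:
   AT, AC, AG order).
4. **Other** — everything else, including empty tails.

### Why these defaults

The published rule table prints "2 or more times in a row" for 4-mers and
3-mers, but its own worked examples contradict that value: the
AT-composite example contains an `AAAT` tandem of 2 and the AC-composite
example an `AAC` tandem of 3, so verbatim thresholds reclassify both as
single-motif tails. Similarly, counting a motif as "present" through
occurrences embedded in longer motifs (every `AC` inside an `AAC`) would
turn one of the printed Other examples into a composite. The defaults above
are the calibration under which **all twenty printed example tails (16
categories, a second A-rich example, three Other examples) reproduce their
own row label**, which we treat as the binding specification of the
system's intent:

* 4-mer and 3-mer minimum copy counts raised from 2 to 3;
* the **junction-anchor rule** (`max_run_start_frac = 0.5`): the winning
  tandem run must begin in the 5′ half of the tail. Tail microsatellites
  expand outward from the poly(A) seed at the body–tail junction, so a
  repeat confined to the distal 3′ end of an otherwise heterogeneous tail
  describes a late, local event rather than the tail's architecture. This
  single rule is what separates the printed `(AAG)n` example (tandem run
  anchored 4/14 into the tail) from the printed AC-composite example
  (equally long `AAC` run, but anchored 20/30 into the tail);
* standalone-occurrence counting and the 50% series-coverage floor for
  composites, so that an isolated `AAC` plus its embedded `AC` in an
  otherwise unstructured tail does not fabricate a composite.

Every printed per-row criterion remains reachable through
`classifier_config()`; the package does not hard-code the calibration.

Two useful invariants hold by construction and are enforced by tests:
classification is total and deterministic over the 17 labels; and the
A-rich decision never depends on the motif thresholds, so sensitivity
analyses of `min_consecutive` can only exchange structured labels and
Other, never A-rich.

## Insertion dating

Ages derive from the RepeatMasker divergence of the *complete element
including the tail* (we do not recompute divergence from alignments):
*K* = −0.75 ln(1 − 4*D*/3), age = *K*/(2μ), with μ = 2.3 × 10⁻⁹
substitutions/site/year. The *K*/(2μ) form is the source convention and the
default; the more common transposable-element convention *K*/μ is a
configuration switch (`clock_params(age_formula = "k-over-mu")`). The
transform saturates at *D* = 0.75; saturated elements are flagged and
excluded from dating rather than clamped, since a clamped age would be
arbitrarily model-dependent. Ages bin into half-open 5-My intervals
[L, L+5) so no age lands in two bins; ages ≥ 85 My fall into an `85+`
overflow bin excluded from composition tables.

```{r}
jc_distance(0.10)          # 0.1073 substitutions/site
age_from_k(jc_distance(0.10))  # ~23.3 My under the default clock
```

## Genomic context

The *tail* interval (not the whole element) is intersected with gene
features. A tail overlaps a class when they share ≥ 1 bp (the standard
interval-intersection default; the source specifies none). Class
memberships are non-exclusive — a tail inside a coding exon counts in
gene, exon and CDS simultaneously, which is the only reading under which
published per-class totals can exceed the classified total — and an
additional single label per tail uses the priority CDS > 5′UTR > 3′UTR >
exon > intron > intergenic. Introns are derived once, as per-gene gaps
between exons; intergenic regions as the complement of gene spans within
chromosome bounds; intersection never re-derives them.

## Cross-assembly comparison

Tail loci are lifted into other assemblies by walking PAF cigars
(`M`/`I`/`D`); a locus is unmapped when either endpoint falls in a deleted
block, outside every alignment, or the endpoints map through different
alignment records. Per-locus sequences are then aligned to the reference
tail with an exact affine-gap Needleman–Wunsch/Gotoh aligner
(match +2, mismatch −2, gap open −4, gap extend −1; a gap of length L
costs open + L·extend; traceback ties prefer diagonal, then a gap in the
second sequence), replacing a heuristic multiple aligner: for ≤ 10
sequences of ≤ a few hundred bp, the exact pairwise star layout is
deterministic and dependency-free.

Call precedence formalises what was a manual inspection step and is
therefore a definition, not a reconstruction: an assembly that is unmapped
or aligns < 50% of the reference tail (`presence_min_frac`, exposed)
yields `presence_absence`; otherwise any net indel ≥ 1 bp yields
`length_variant` (with signed per-assembly deltas); otherwise differing
tail categories yield `composition_change`; otherwise `identical`. The
precedence gives each locus exactly one primary call.

## Coding impact

mRNAs are rebuilt from exon coordinates (reverse-complemented for minus
strand transcripts), with insertion edits applied in reference coordinates
before splicing. The longest ORF is searched in all six frames even though
the transcript strand is known — fidelity to the stated procedure, and a
cheap guard against mis-annotated strands. Identity between reference and
variant proteins is identities over alignment columns *including gaps*;
the alternative shorter-sequence denominator is not used (the choice is
documented because published identity figures rarely state theirs). An
internal stop in the variant is reported through the shorter protein, not
treated as an error. Frameshift is declared exactly when the inserted
length is not a multiple of 3. NMD and splice-site disruption are outside
the model; conclusions are genomic, not proteomic.

## The synthetic-fixture generator

`plant_genome()` emulates the pipeline's input universe: a random
background genome (GC 0.42, pig-like; the value only affects realism, not
correctness), planted elements built from deterministic synthetic
subfamily consensus bodies ending in known cutoff motifs, substitution-only
divergence (uniform over the three alternatives), and tails constructed by
`make_tail()` to classify as a requested category. Mutations are applied to
the body (and optionally the cutoff), never the tail, and no indels are
introduced, so the true boundary and category stay well defined; indels
enter only as explicit assembly edits in `make_variant_assembly()`, which
emits exact cigars. Annotated divergence is the realised Hamming divergence
of the emitted element, so the dating stage sees exactly the divergence
that exists.

What passing tests on these fixtures shows: the extraction, classification,
dating, intersection, liftover and calling machinery is internally correct
and self-consistent. What it does not show: robustness to real
RepeatMasker boundary noise, tail indels, nested/fragmented elements, or
biological cutoff libraries — the shipped cutoff library is synthetic, and
real analyses must supply their own.

Problem sizes in the test suite are chosen for a laptop-scale run:
end-to-end recovery uses 200 planted elements on a 90-kb genome (100%
category recovery at zero divergence, ≥ 95% at 5% divergence with intact
cutoffs), oracle comparisons use 1-kb interval fixtures and 300-nt ORF
fixtures, and alignment cross-checks use sequences of 20–60 bp.

## Known limitations

* The classification calibration is validated against the twenty printed
  example tails; the original precedence when several motifs qualify is
  not independently recoverable, so other rule systems could reproduce the
  same examples.
* Divergence-based ages inherit RepeatMasker's consensus choice and assume
  neutral, clock-like evolution of the whole element including the tail.
* Liftover requires cigar-bearing PAF records and maps endpoints only; it
  does not split loci across alignment breakpoints.
* The comparative module's 50% presence threshold is a formalisation with
  no published counterpart; sensitivity to it should be checked on real
  data.
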