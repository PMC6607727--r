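---
title: "Genome-wide pre-miRNA hairpin discovery: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide pre-miRNA hairpin discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premirscan)
```

# The problem and the procedure

Plant microRNA precursors (pre-miRNAs) are short hairpin-forming RNAs
scattered through the noncoding portion of a genome. Template-free,
genome-wide identification does not start from known miRNA families or
expression libraries; it scans *all* noncoding sequence for
hairpin-competent fragments and then applies structural criteria to the
folded candidates. `premirscan` implements that scan as a chain of small,
individually testable stages:

1. **Region extraction.** Intergenic space is the per-scaffold complement
   of the union of gene spans; intronic space is the per-gene gaps between
   the union of a gene's exons. Every base is exonic, intronic or
   intergenic exactly once under this convention, which is what makes the
   downstream per-class accounting well defined when genes overlap.
2. **Windowing.** Each noncoding region is chopped into 120-nt windows
   overlapping by 20 nt (step 100). When the last full step leaves a
   residue, one extra window is taken *backwards* from the region end, so
   every base of a region at least as long as the window is covered; the
   backward window is deduplicated when it coincides with a regular start.
3. **Hairpin screening.** Each window is folded (both strands; the
   better-scoring strand is kept) and scored by four indicator rules
   (below). Passing windows that overlap by at least one base are merged
   transitively into *predicted loci*; windows that merely touch
   end-to-start are not merged (half-open convention). An optional
   rRNA/tRNA exclusion removes windows matching a structural-RNA set by a
   seeded, ungapped 16-mer-anchored match at ≥ 90% identity over ≥ 60 nt.
4. **Duplex extraction.** Each locus is folded and its stem-loops are
   walked; the miRNA duplex is the longest contiguous pair-window whose
   induced arms satisfy: both strands > 15 nt, per-event bulge asymmetry
   ≤ 2 nt, total mismatch ≤ 4 nt. Loci with no qualifying window are
   re-examined after symmetric end extension in 5-nt increments up to
   20 nt. Each duplex yields exactly two putative matures (5p, 3p).
5. **Validation and annotation.** Predicted loci are matched to reference
   pre-miRNA sets (same scaffold, > 60% overlap of the reference, ≤ 2
   substitutions in the overlap) and the recovery count is assessed with
   an exact hypergeometric test; matures gain expression support from
   small-RNA reads (100% coverage, ≤ 3 substitutions, ≥ 10 reads) or
   total-RNA alignments (≥ 60% coverage, ≥ 10 reads), conservation calls
   against a plant mature catalog (full coverage, ≤ 3 substitutions),
   per-region-class population densities (count per gigabase), and
   consensus target predictions from one penalty scorer run under two
   presets.

# The folding model

Screening and extraction both consume secondary structures through a
single deterministic contract. The built-in folder maximises an additive
score over nested stem-loop chains:

* pair weights GC = 3, AU = 2, GU = 1;
* `stack_bonus` = 1 for each pair stacked directly on the previous pair;
* `hairpin_penalty` = 8 for closing a hairpin loop;
* interior loops and bulges cost `interior_open + interior_per_nt × gap`
  (2 + 1.5/nt), with the total gap capped at 30 nt;
* hairpin loops keep at least `min_loop` = 3 unpaired bases;
* multiloops and pseudoknots are outside the model.

The loop penalties are the load-bearing part. Under plain pair-count
maximisation, a genomic window happily pairs a real stem's bases with
scattered flanking partners of equal pair weight — two half-pairings beat
one stem pair — and chains unrelated short helices into arbitrarily long
"stems". Penalising every loop opening (and pricing larger gaps
progressively) restores the qualitative behaviour of thermodynamic
folders: a long contiguous helix pays its hairpin penalty once and earns
stacking rewards throughout, while opportunistic pairings must keep
opening loops they cannot pay for. The weights are unitless scores, not
free energies; their *ratios* (stack ≈ pair weight, hairpin ≈ 2–3 stacked
pairs, interior ≳ one GC pair) mirror the ratios of nearest-neighbour
parameters and were fixed once from pilot folds of random sequence before
the test suite was frozen.

Determinism is part of the contract: the traceback prefers pairing over
leaving a base unpaired, takes the smallest optimal partner, prefers a
stacked continuation inside a helix, and resolves interior-loop ties by
increasing total gap. Published structures from an external engine can be
injected bit-exactly through the dot-bracket backend
(`fold_config(backend = "external")`), so the extraction criteria can be
applied to any folder's output.

Degenerate inputs: sequences shorter than 10 nt and non-IUPAC letters are
errors; `U` is mapped to `T` internally; `N` never pairs.

# Screening rules

`screen_rules()` scores a window as the mean of four indicators, and the
default threshold 1 (the strictest cut-off) requires all of them:

| rule | default | rationale |
|---|---|---|
| paired fraction | ≥ 0.40 | a pre-miRNA window is mostly helical |
| longest stem | ≥ 16 pairs | must be able to host a > 15-nt duplex strand |
| single loop | = 1 | the dominant stem is a clean stem-loop |
| contiguous helix run | ≥ 12 pairs | the discriminative rule (below) |

The first three rules barely discriminate: under any folder that rewards
pairing, most random 120-mers pair more than 40% of their bases and chain
small helices past 16 pairs. What random sequence almost never does is
stack more than ~10 pairs *without interruption*, while genuine miRNA
duplexes keep a long clean helical core. The contiguous-run rule
therefore carries the specificity (a few percent of random windows pass
it). The screen is deliberately a transparent stand-in for an external
machine-learned classifier; externally computed scores can be substituted
per fragment (`screen_fragments_external()`), preserving the pipeline
shape while leaving the classifier pluggable.

# Duplex criteria accounting

The three thresholds (> 15 nt strands, ≤ 2 nt asymmetric bulge, ≤ 4 nt
mismatch) are stated in the field without an accounting rule, so the
package declares one: walking consecutive pairs outermost to innermost,
an internal loop with `a` unpaired bases on the 5′ arm and `b` on the 3′
arm contributes `min(a, b)` to the mismatch total; when `a ≠ b` the event
is a bulge with asymmetry `|a − b|`, bounded per event (a `"total"` mode
bounds the summed asymmetry instead). Arm lengths are the induced spans,
interior unpaired bases included. Among qualifying windows the longest
(most pairs) wins; ties resolve towards the loop. An exhaustive
enumeration of every contiguous pair-window, written as an independent
oracle, backs this in the tests.

Strand handling: the forward strand is extracted first and the reverse
complement is consulted only when the forward fold yields no qualifying
duplex. This keeps minus-strand precursors findable without letting an
opportunistic reverse-strand structure override a forward hit; reverse
coordinates are mapped back to forward space. The 3p mature is reported
as the reverse-strand reading 5′→3′ (biological convention;
`threep_revcomp = FALSE` gives the forward substring).

# The hypergeometric overlap test

Validation against a reference set of `k` known pre-miRNAs among `N`
investigated fragments, with `n` predicted loci drawn and `X` references
recovered, uses the exact hypergeometric law. Both `P(x = X)` (the point
probability) and `P(x ≥ X)` (the upper tail) are always reported:
published per-study tables of this form print the *point* probability
(the tail is strictly larger; for the weakest study in the reproduced
table the point value is 0.213 while the genuine tail is 0.325), and the
significance verdict at 0.05 holds under either reading for the studies
that are significant at all. Computation goes through R's `dhyper` /
`phyper` (log-space internally), exact at the `N ≈ 8.3 × 10⁶` scale; the
tests cross-check it by enumerating every draw for small populations.
Whether `n` should be the passed-fragment count or the merged locus count
is genuinely ambiguous in this family of analyses; `overlap_significance`
takes `n` explicitly, and the pipeline uses the passed-fragment count
while reporting both counts in its summary.

The same kernel drives the GO-term enrichment (`hypergeom_enrichment`),
one-sided upper tail, uncorrected by default (Benjamini–Hochberg behind a
flag), and the tests assert the two entry points agree on identical
inputs.

# Population density and network analyses

Density is `count × 10⁹ / region length` (miRNAs per gigabase). The genic
length defaults to the plain sum of gene-span lengths — the literal
published rule — which double-counts overlapping genes; the function
warns loudly in that case and offers a merged-interval (`"union"`) mode.
A locus is genic when its midpoint falls in a gene span.

Target prediction scores every ungapped antisense placement (perfect
complement 0, G:U wobble 0.5, mismatch 1, positions 2–13 of the mature
doubled), keeps sites under a cutoff, and intersects two presets
(cutoffs 3 and 4) standing in for two independent predictors; only
consistent pairs survive. Binding groups take the lowest and highest
deciles of transcripts ranked by distinct bound matures (ties broken
lexically; decile size `floor(0.1 n)`, at least 1). Degree classes close
the conventionally open boundaries: 15 falls in the first bin
([1, 15]) and 81 in the last ([81, ∞)).

# The synthetic genome generator

`simulate_genome()` produces the full input suite — genome FASTA-ready
sequence, gene models with introns, planted hairpins, reference sets,
conserved catalogs, reads, term maps — with a truth table, all
deterministic under one seed. It emulates the *statistical shape* the
pipeline assumes, not real genomes: i.i.d. background at a configurable
GC (0.36 default, a plant-like value), evenly slotted non-overlapping
genes, and hairpins whose duplexes are known by construction.

A planted stem is a random 5′ arm (18–24 nt), an inert loop (4–15 nt)
and the arm's reverse complement carrying the prescribed events:
mismatch columns set to A on both arms (A:A cannot pair), bulge events
inserting C bases on one arm (asymmetry 1–2). Decoys violate the
criteria by design — 5–6 mismatches placed so that *every* pair-window
with > 15-nt arms contains more than 4 of them, or one central bulge of
asymmetry 3–4 with neither side long enough to host a qualifying window —
and must never be recovered.

Three generator guarantees make the recovery property a test of the
*method* rather than of placement luck, and are deliberate design
choices:

* **Screenability.** Mismatch counts are capped at `arm − 16` so every
  non-decoy stem keeps ≥ 16 paired columns, and events are confined to
  columns [5, arm − 12], leaving a ≥ 12-pair clean helix core next to the
  loop (the screen's contiguous-run rule) while keeping every event far
  enough from the helix ends that bridging it is always worthwhile for
  the folder.
* **Inert surroundings.** Loops and the 12-nt flanking buffers are
  homopolymers from {A, C} chosen against the adjacent pair, and the two
  buffers share one letter, so no pair with both ends within stem-walk
  range of the stem can form across them: planted arms can never extend
  outward, whatever the genomic context.
* **Verified placement.** Every candidate hairpin is folded in isolation
  and accepted only if extraction returns exactly the planted arms
  (decoys: nothing); at placement time the containing 120-nt scanning
  window of the actual genome draft is folded again and the same check is
  repeated, with the position resampled on failure. Stems are also placed
  wholly inside at least one scanning window of their region's grid —
  stems straddling beyond every window by more than the 20-nt end
  extension are unrecoverable under the windowing scheme by construction,
  a known limitation of fixed-window scans.

What passing the synthetic tests does *not* show: behaviour on real
repeat structure, GC landscapes, isoform-rich annotations, sequencing
biases of real small-RNA libraries, or the accuracy of any particular
external screening classifier. The generator's background is i.i.d.
rather than Markov; screening specificity against composition-matched
sequence is exercised separately through dinucleotide shuffles in the
test suite.

# Problem sizes and reproducibility

The default simulation (200 kb over two scaffolds, 20 genes, 30 planted
hairpins, 20% decoys) is the package's standard study condition: large
enough that the windowing, merging and density bookkeeping are exercised
on dozens of regions, small enough that the complete pipeline folds every
window in well under a minute. The test suite runs the full pipeline on
this default and on a 60-kb single-scaffold variant; the duplex oracle is
exercised on 1,000+ random stems; windowing laws are enumerated for every
region length from 120 to 2,000 nt. All randomness flows through explicit
seeds, RNG state is restored after every generator call, and pipeline
reruns are byte-identical.

# Known limitations

* The folding model is a scoring heuristic, not a thermodynamic model: no
  nearest-neighbour parameters, no multiloops, no suboptimal structures.
  The published analyses this pipeline mirrors used two thermodynamic
  engines and noted their disagreement; here engine variability is out of
  scope and the extraction criteria are the object of study.
* One duplex is reported per locus and one mature per arm, although long
  stems could in principle host more than one product per arm; stems long
  enough are visible in the duplex table (`n_pairs`).
* Read alignment is consumed as a minimal interval table (or the built-in
  exact matcher for synthetic reads); no SAM/BAM ingestion, no gapped
  alignment, no multi-mapping model.
* The target scorer is one penalty scheme under two presets; absolute
  interaction counts are scheme-dependent and not comparable across
  scoring schemes.
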