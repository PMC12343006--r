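---
title: "Detecting within-gene exon duplications: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-gene exon duplications: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind `exdup`, the parameters that matter,
the numerical choices made where the design was genuinely open, what the
synthetic-genome simulator does and does not emulate, and the package's
known limitations.

## The detection problem

A protein-coding exon duplicated within its parent gene can survive in two
states: as a second annotated coding exon, or as an unannotated, possibly
degenerate copy inside an intron. Detecting both requires two complementary
searches: a *global* one over pairs of annotated exons (sensitive to
full-exon copies of similar length) and a *local*, translated one of each
exon against its entire gene, introns included (sensitive to partial,
boundary-crossing and intronic copies). Everything downstream —
classification, reconciliation, family construction — exists to organize
the redundant, overlapping matches these searches produce into
interpretable duplication events.

## Intervals and clustering

All coordinates are 1-based, inclusive, genomic, and never strand-flipped;
strand is applied only when sequence is extracted. Similarity of two closed
intervals is their intersection length divided by the length of the longer
interval ("minimum interval overlap ratio"): identical intervals score 1,
disjoint ones 0, and a short interval nested in a long one scores low —
which is what makes the measure suitable for deciding whether two exon
annotations are variants of the same exon rather than merely touching.

Clustering of intervals (used for representative-exon selection, target
reconciliation, and tandemness) is a deterministic single-linkage sweep:
intervals are sorted by (start, end) and each interval joins the open
cluster when its overlap ratio with the most recently added member is
*strictly* greater than the cutoff. Two consequences are used as behavioural
anchors and are tested: at cutoff 1 every interval is its own cluster
(strict inequality), and at cutoff 0 any chain of overlapping intervals
merges, after which the shortest-member representatives are provably
pairwise non-overlapping. Sorting first makes the partition invariant to
input order. The sweep links only consecutive sorted intervals; a long
interval can span a later cluster without merging it. This is a deliberate
trade of completeness for determinism and is equivalent to the transitive
closure of the consecutive-pair overlap relation (the test suite checks
this equivalence against a brute-force closure oracle on random inputs).

Ties for "shortest member" are broken by (start, end) order; duplicate
exon coordinates across transcripts are collapsed before clustering.

## The searches

**Local.** Each representative exon is translated once, in its annotated
frame (the GFF `phase` when available, otherwise the frame minimizing stop
codons), and aligned by Smith–Waterman (BLOSUM62, gap open 11, extend 1)
against all six translation frames of the gene. Querying the exon in its
coding frame only — rather than all three — is a numerical choice: the
six subject frames already reach frame-shifted and inverted copies, and the
extra query frames only rediscover the same genomic hit at three times the
cost. Additional copies beyond the best one are recovered by masking each
found subject region with `X` and re-aligning, up to `max_hsps` times.
E-values use Karlin–Altschul statistics, `E = K m n exp(-λS)` with the
standard gapped BLOSUM62 constants (λ = 0.267, K = 0.041) and the *pairwise*
search space — query length × gene length in residues — because every
search here is a one-exon-vs-one-gene comparison, not a database scan.
Overlapping hits of the same query found through different frame
combinations are collapsed to the most significant one.

A tblastx-compatible executable can replace the builtin aligner
(`search_params(backend = "external")`); on exact copies the two backends
report the same target interval up to codon-boundary jitter (≤ 3 nt), which
is asserted in the tests whenever a `tblastx` binary is on the PATH.

**Global.** Exon pairs enter only if shorter/longer length > `pair_ratio`
(strict, so a ratio exactly at the cutoff is excluded). Peptides are
globally aligned; *identity* is identical columns over columns aligned in
both sequences, and *aligned fraction* is columns aligned in both over
total alignment columns. The aligned-fraction definition was open (longer
sequence, shorter sequence, or alignment length are all defensible
denominators); alignment length was chosen because it penalizes terminal
overhangs symmetrically. Matches are reciprocal by construction.

## Classification, reconciliation, promotion

Matches are classified against the union of all transcripts' CDS intervals
(not only representatives) and the intron space, in the precedence order
full-length > partial > inter-boundary > intronic, evaluated with the same
coverage threshold `query_coverage` (t~e~) used at emission:

* full-length: query coverage and coverage of some annotated exon both ≥ t~e~;
* partial: the target lies inside an annotated exon or engulfs one, and
  exactly one of the two coverages reaches t~e~;
* inter-boundary: query coverage reached, every overlapped exon covered
  below t~e~, target spans exon and intron sequence;
* intronic: at least t~e~ of the *target* lies in intron space (the
  target-fraction reading of "aligns to an intronic region").

When a target overlaps several exons, the binding exon for the
inter-boundary decision is the one with the greatest overlap. Lowering t~e~
can only add full-length classifications, a monotonicity that is tested on
a fixture of truncated duplicates.

Reconciliation clusters target intervals at `target_overlap`; clusters in
which *every* match is full-length snap to the annotated exon with the
highest overlap ratio to the cluster footprint (ties: shortest exon), other
clusters inherit the target of the most significant member — lowest
E-value, then largest aligned query fraction, then earliest coordinates
("most significant" was undefined and needed a total order). The reading
frame of each reconciled target is the frame whose translation aligns to
the query peptide with the highest identity, ties to the lowest frame.
Reconciliation is idempotent.

A local *partial* match whose query coincides with one endpoint of a
retained global match and whose target is contained in (or engulfs) the
other endpoint's exon is promoted to full-length. Containment — overlap
over the shorter interval — is used here rather than the minimum overlap
ratio, because a genuinely partial target can never reach a high minimum
ratio against the full exon; requiring it would make promotion vacuous.

## Expansions, tandemness, interdependence

Vertices are representative exons and reconciled targets compared by exact
coordinates, so a target snapped to an annotated exon merges with that
exon's vertex — this is what collapses a reciprocal full-length pair into
one connected component. Local matches contribute directed edges, global
matches bidirectional ones; expansions are the connected components of the
undirected projection, excluding isolated vertices. An expansion of size
*k* is read as *k* − 1 duplication events, which assumes no multi-exon
duplication unit.

Tandemness (full-length expansions only) clusters all coding exons at
cutoff 0 and asks whether consecutive duplicates, in coordinate order, fall
in consecutive clusters. Transcript membership of a duplicate uses an
overlap ratio ≥ 0.9 against the transcript's CDS intervals rather than
exact equality, tolerating minor isoform boundary variants; the threshold
is a configurable argument. Interdependence follows the obligate /
exclusive / flexible scheme, with the `optional_` prefix when some
transcript lacks the whole group, sub-classified over the transcripts that
contain at least one member. For groups larger than two the same
definitions are applied to the restricted transcript set; this extension
beyond the two-duplicate case is a package decision, and the classifier is
verified to be total and exclusive over the exhaustive enumeration of
membership patterns for up to four transcripts.

## The simulator and what passing tests mean

`simulate_genome()` builds genes from random open-reading-frame exons
(whole codons, no internal stops; 102–300 nt by default) separated by
random introns with canonical `GT..AG` ends (200–1000 nt), on one plus-strand
chromosome with 500-nt spacers. Planted events copy a source exon of the
same gene, mutate it, and insert it into an intron: full-length events
become annotated CDS exons (phase 0; present in all transcripts or a random
subset covering at least one), intronic events sit mid-intron with at least
50 nt of intact intron on each side, which avoids creating accidental
boundary-spanning truth events. One event per intron keeps truth intervals
unambiguous.

The default mutation process is a uniform (JC69-style) substitution model:
each site differs from the source with probability ¾(1 − e^(−4d/3)) at
distance *d* expected substitutions per site, giving a closed-form identity
expectation used as the test oracle. Copies destined to be *annotated* are
additionally conditioned on containing no in-frame stop codon — a CDS
annotation with internal stops would be malformed input, not a harder test
case; the conditioning measurably affects only the handful of sites
involved, and the identity oracle is therefore checked on the unconstrained
intronic copies.

Two properties of this design deserve emphasis:

* Real exon divergence involves indels, splice-site drift, codon usage and
  selection; the default simulator has none of these, so recovery rates on
  it measure alignment-and-bookkeeping correctness, not performance on real
  genomes.
* Under an unconstrained substitution model the signal saturates quickly:
  by d = 1.0 the expected nucleotide identity of a planted copy is ~0.45
  (protein identity ~0.2, barely above the random background of 0.25/0.15),
  and by d = 2.0 nucleotide identity is ~0.30. The acceptance experiment
  shows exactly this: recovery is complete at d = 0.2, partial at d = 0.5,
  and zero at d ≥ 1.0 with the default thresholds — no similarity-based
  detector could do otherwise, because the planted signal is statistically
  indistinguishable from background at those distances. Duplicated exons
  that *remain coding* in real genomes diverge mostly synonymously and stay
  detectable far longer; the simulator exposes this regime through the
  `omega` option of `simulation_config()`, a codon-aware purifying-selection
  mode (synonymous substitutions always accepted, nonsynonymous with
  probability `omega`) intended for sensitivity analysis. The package
  default remains the unconstrained model.

## Problem sizes and runtime choices

The shipped validation uses ~55–60 genes with 4–6 exons each and 100 + 100
planted events over distances {0.2, 0.5, 1.0, 1.5, 2.0} — large enough for
20 events per distance stratum while a full run stays in the minutes range
on a single core. The property suites use 1000 random interval sets
(n ≤ 50) for the clustering oracle and 500 random graphs (≤ 20 vertices)
for the component oracle.

## Known limitations

* The search space is always a single gene; cross-gene paralogy and
  genome-wide repeats are out of scope, as are trans-splicing, fuzzy
  coordinates and feature types beyond gene/mRNA/transcript/CDS.
* No HSP chaining: query coverage is evaluated per alignment, so a copy
  split by a large insertion may fail the coverage gate even though its
  pieces are individually found.
* One long target spanning several annotated exons is never split into
  multiple events (the k − 1 event count assumes single-exon units).
* The relational store is a directory of TSV tables with a JSON manifest;
  it is self-describing and versioned, but it is not a server-backed
  database and makes no compatibility promise to any other tool's schema.
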