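---
title: "Annotating duplicated teleost IGH loci: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating duplicated teleost IGH loci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighloci)
```

## The problem

Teleost immunoglobulin heavy-chain (IGH) loci can be organized as tandem,
recently duplicated "zones": each zone carries its own D and JH segment
clusters and constant-region (Cμ, Cδ, TM) exons, with VH segment arrays
lying between zones. Medaka chromosome 8 is the motivating case: five such
zones, one of them disorganized, one inverted, with inter-zone sequence
identity high enough that homologous exon copies differ at only a handful
of nucleotides. Annotating such a locus, and deciding which zone a given
cDNA (EST) was transcribed from, is what this package does. Every stage is
exercised against a synthetic locus with planted truth, so the pipeline is
testable at desk scale without any external data.

## Gene-segment discovery rules

**RSS model.** A recombination signal sequence is heptamer + spacer +
nonamer, the heptamer always coding-proximal. The nonamer consensus is
`TATTATTGT` with at most 2 mismatches by default (1 or 2 are the
conventional tolerances for this motif). The heptamer consensus is the
canonical vertebrate `CACAGTG` with at most 1 mismatch; note that the
heptamer sequence and its tolerance are a package choice — only the
nonamer is pinned down hard by convention in this locus style — so both
are exposed as parameters of `rss_model()`. Spacers are 12 or 23 bp with a
default slack of ±1 bp to tolerate indels (`spacer_slack = 0` gives the
strict exact-spacer reading). N never matches anything, which is the
conservative choice for gap-ridden assemblies. Scanning
(`scan_rss()`) is exhaustive over positions, spacer lengths and both
strands; overlapping hits are all reported and callers tie-break.

**VH** (`call_vh()`): a stop-free open reading frame of 240–360 nt
(typical teleost VH exon length; configurable), the splice-acceptor
dinucleotide `AG` immediately 5′ of the exon start, and a 23-spacer RSS
whose heptamer begins within 0–10 nt of the exon 3′ end. The full leader
exon is not modeled; the acceptor dinucleotide alone implements the
"splice sites flanking open reading frames" criterion. Overlapping
candidates resolve by fewest RSS mismatches, then leftmost start, then
longest exon. The default search strand is "+": translocon-style VH
arrays sit in forward orientation upstream of the constant-region zones,
and inversions in loci of this architecture affect D/Cδ blocks;
`strand = "both"` is available.

**D** (`call_d()`): an interval of 5–40 nt flanked by 12-spacer RSSs on
both sides (the 12/23 rule places the 12s on D). Because the flanking
arrangement reads identically on both strands, a D cassette is
strand-symmetric by construction: forward and reverse scans find the same
interval, and the call is reported once on "+". An inverted D is therefore
only distinguishable by its context, not by the cassette itself.

**JH** (`call_jh()`): candidate loci are found by windowed-identity
homology to reference JH sequences at window 30 nt and 60% match, then
verified by the ungapped identity over the full reference length along the
seed diagonal (a single 30-nt window at 60% has a non-negligible match
rate on random sequence; the seed-then-verify pattern removes that noise
without touching the stated thresholds). The 5′ boundary goes immediately
after the heptamer of the nearest upstream 23-RSS within 60 nt; the 3′
boundary immediately before the first `GTA` within 30 nt after the
homology run — the `GT` being the splice donor, so the exon ends at the
first G. Candidates missing either anchor are kept and flagged
`boundary_uncertain` rather than dropped. When one locus is hit in both
orientations (this genuinely happens when a reference is quasi-palindromic
— ~60% identical to its own reverse complement), the calls are resolved to
one per locus: anchored beats unanchored, then fewest RSS mismatches.

**Self-audit.** After calling, every emitted call is re-verified by direct
string inspection (acceptors present, frames stop-free, RSS flanks
re-scan); a violation is treated as a package defect, not a data problem.

## Dot plots and duplication detection

`dot_matches()` reports a cell (i, j) exactly when the 30-nt windows at i
and j agree at or above the identity threshold. The threshold is applied
as an integer match count `ceiling(window × identity)` — 26/30 at 85%,
18/30 at 60% — which removes floating-point ambiguity. The inner loop is
O(nm) C++ (per-diagonal sliding window), which is what keeps exhaustive
matching practical at locus scale. `merge_diagonals()` joins cells on a
common diagonal into runs; `max_gap = 0` (strictly contiguous) is the
default since run merging is a formalization of reading runs off a plot,
not a tuned step. `detect_duplications()` runs both orientations at
window 30 / 85% identity and drops the trivial main diagonal for
self-comparison; inverted duplications appear as reverse-orientation runs.

## CH exon mapping, naming, zones

`map_ch_exons()` seeds candidate loci with dot-plot cells at window 30 /
60%, verifies each candidate by full-reference-length diagonal identity at
≥ 0.70 (below the few-percent inter-zone divergence so duplicated copies
are found, far above random), and snaps boundaries to the nearest splice
contexts within 6 nt (`AG` before the start, `GT` after the end; `AC`/`CT`
on the forward strand for inverted copies). All copies of a label are
reported — repeated exons are the point of this locus architecture.

`name_exon_orthology()` names an exon by its best global alignment
(match +1, mismatch −1, linear gap −2) against labeled references,
reporting the score margin over the best competing label; a zero margin
yields "ambiguous". Orthology-based naming, rather than positional
numbering, is what keeps labels meaningful when exons are repeated,
missing, or out of canonical order.

`partition_zones()` opens a zone boundary at every VH call and at every
gap > 15 kb between consecutive non-VH annotations (intra-zone distances
in this architecture are a few kb; 15 kb is comfortably beyond them).
Each VH-free run containing at least one CH exon is a zone. A zone lacking
both a complete Cμ1–Cμ4 set and a complete Cδ chain is flagged
non-functional — a deliberate formalization of the qualitative judgment
one makes about a disorganized zone, and documented as a heuristic.

During orchestration (`run_annotate()`), calls are integrated by evidence
strength. A VH call, which rests on pattern evidence alone, yields to any
overlapping JH, D or exon annotation, which carry homology or dual-RSS
anchoring — this matters in practice, because an inverted JH cassette
presents a forward-strand VH-style 23-RSS and a chance stop-free ORF next
to it completes the VH pattern. Symmetrically, an unanchored
(`boundary_uncertain`) JH candidate lying inside a homology-mapped exon is
dropped: a 48-nt stretch of a CH exon can clear 60% identity to a JH
reference by chance, and the duplicated architecture then replicates that
false candidate into every zone. Anchored JH calls are never dropped.

## Transcript classification

`chain_exons()` places every exon copy in the EST by substitution-only
approximate matching (per-link identity ≥ 0.90; same-species copies of
genomic exons justify the high threshold) and selects the colinear,
non-overlapping chain maximizing matched bases by dynamic programming.
An unmatched prefix of ≥ 50 nt before the first CH exon is tested for VH
content with an ORF rule — any stop-free frame ≥ 150 nt ending within
90 nt of the junction — because EST VH regions are rearranged and will not
match germline VH intervals. Exon-0 usage is read off the chain.

`assign_zone()` counts, for each chained exon, mismatches to every zone's
copy and sums per zone; the best zone wins only if it beats the runner-up
by at least one nucleotide (a diagnostic site), otherwise the vote is
"ambiguous". Aggregating across all chained exons (rather than a single
exon) uses all available diagnostic sites; with planted-identical copies
the vote is ambiguous by construction — the behavior expected of Cδ copies
too similar to distinguish.

`classify_isoform()` applies ordered rules: sterile (no VH, or stops in
all frames before the last chained exon), then short transmembrane IgM
(Cμ1–Cμ2 spliced to TM1–TM2), secreted IgM (Cμ1–Cμ4, no TM), chimeric
transmembrane IgD (Cμ1, then Cδ exons — no Cδ5 required — ending TM1–TM2),
else unclassified. `orf_stop_analysis()` and `protein_features()`
(cysteines; N-X-S/T sequons with X ≠ P) support the chain-feature
readouts, and `predict_amplicon()` reproduces the RT-PCR design step in
silico (all forward/reverse-complement primer placements within a
mismatch budget, product measured 5′ end to 5′ end).

## The synthetic locus: what it emulates, and what it does not

`simulate_locus()` builds a master zone — D cassettes (12-RSS both
flanks), JH cassettes (upstream 23-RSS, terminal `GTA`), a 100-bp exon 0
with a planted stop in each reading frame, Cμ1–Cμ4 (Cμ4 carrying the
60-nt secretory tail), one TM1/TM2 pair and the Cδ1–4, 6, 7 chain —
then derives each zone from it by substitution. The default layout is the
five-zone architecture: zones 1, 2, 4 organized, zone 3 disorganized
(a random minority of CH exons, no D/JH; exon 0 retained), zone 5
organized but inverted in place; exon 0 in zones 1–3 only; ten VH
cassettes in each inter-zone array. Zone counts, exon sets, inversion and
disorganization are all per-configuration.

Choices worth knowing about:

* **Divergence is pairwise.** `zone_divergence = 0.02` means two zone
  copies are expected to differ at ~2% of unprotected positions; each copy
  draws substitutions at half that rate from the master. Substitutions
  never touch protected motif positions (RSS elements, splice contexts,
  `GTA`, exon-0 stop triplets) — those mutate only at
  `motif_mutation_rate`, default 0 — and are codon-aware inside exon
  reading frames so no planted exon acquires a stop.
* **One TM pair per zone.** Both membrane IgM (Cμ2→TM1) and chimeric IgD
  (Cδ7→TM1) splice to the same planted TM pair. Real loci carry separate
  μ and δ TM exons; collapsing them keeps every label's copy count at one
  per zone, which keeps zone voting well-defined. The secretory tail is
  the 3′ 60 nt of the Cμ4 exon rather than a separate exon, as in
  teleost secreted IgM.
* **Junctions model productive rearrangement.** V(D)J joining trims 0–5 nt
  per end and adds 0–8 non-templated nucleotides per junction, resampled
  until the rearranged prefix is a multiple of 3 and stop-free in the V
  frame. Master JH segments are generated stop-free in all three frames so
  the resampling always terminates. Sterile transcripts are exon 0 + Cμ
  chains (zones with exon 0) or VH-less Cμ chains.
* **A VH "stop wall".** Each VH cassette is preceded by a 12-nt sequence
  carrying a stop in every frame, so the planted exon start is the
  unique AG-anchored candidate — the synthetic analog of the leader
  intron's stop-rich context.

What the generator does **not** emulate: indels, transition/transversion
bias, repeat families, sequencing-read noise models, per-zone Cδ
asymmetries (configurable but not default), and separate μ/δ TM exons.
Passing tests therefore demonstrate the discovery rules and the
classification logic under substitution-style divergence — not robustness
to structural variation or to alignment through indels, which this
package deliberately does not attempt (its matching is ungapped
throughout, like the dot-plot tool it formalizes).

## Numerical and degenerate-input choices

Identity thresholds are integer match counts (no float comparisons).
Sequences shorter than a window give an empty match set with a warning.
A motif longer than its sequence scans to an empty result, not an error.
Zero segment calls is a valid outcome everywhere; only missing reference
sets are hard errors. Boundary snapping prefers the smallest shift and
breaks ties leftward. Duplicate FASTA ids and non-IUPAC characters are
hard errors naming the offender; `U` is silently converted to `T`.
Internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive, written and re-read through `rtracklayer`.

## Problem sizes

The default desk-scale study uses a ~47-kb locus (five zones of ~6 kb,
five 10-cassette VH arrays) and 500 error-free transcripts at the mix
IGM_SEC 0.45, IGM_TM_SHORT 0.25, IGD_TM_CHIMERIC 0.15, STERILE 0.15 —
proportions read off the observed EST class distribution, with the sterile
share at the ~15% reported for this locus. Oracle-equivalence checks run
the brute-force enumerations on 200 nt–5 kb instances. These sizes keep a
full run (simulate → annotate → classify → summarize) within a few
minutes on one core while leaving every rule exercised, including the
inverted and disorganized zones.

## Known limitations

* Ungapped matching throughout: an indel inside an exon copy breaks its
  link rather than shifting it.
* The functional-zone flag and the VH-over-other-call conflict rule are
  heuristics; both are surfaced in the outputs (`functional`, dropped-call
  counts) rather than hidden.
* D-segment strand is not identifiable from the cassette alone.
* Zones are reported per input sequence and never merged across
  sequences; resolving zone structure across assembly gaps is out of
  scope.
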