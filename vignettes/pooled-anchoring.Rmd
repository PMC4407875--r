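---
title: "Anchoring a physical map from sequenced 3-D BAC pools: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring a physical map from sequenced 3-D BAC pools: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolanchor)
```

# The model

A minimum tiling path (MTP) of a BAC physical map is re-arrayed into
`n_plates` 384-well plates and pooled three ways: plate pools (all 384
clones of one plate), row pools (all clones of one row across plates)
and column pools (all clones of one column across plates). On the
default ten-plate geometry this gives 50 pools of 384, 240 and 160
clones, and the map from a well to its pool triple is a bijection:
`pools_to_well()` inverts `clone_to_pools()` exactly, which the test
suite verifies by exhaustive enumeration over all 3,840 wells.

Each pool is shotgun-sequenced. For a marker sequence $m$ of length
$L_m$ and pool $q$, the *covered region* $C_{mq}$ is breadth of
coverage: the number of reference positions of $m$ covered by at least
one retained read. Pool $q$ is called positive for $m$ when
$C_{mq}/L_m \ge t$; the threshold is inclusive ("at least"), default
$t = 0.8$. Positivity per pool, not read counts, is the entire signal —
the method is deliberately robust to uneven sequencing within a pool.

Deconvolution converts a marker's positive-pool signature into clones
via a fixed cascade (repetitive filter → missing-dimension check →
1-1-1 direct assignment → shared-contig resolution → end-clone
fingerprint resolution → no_clone_overlap). Two points where the
procedure is genuinely open, and the choices made here:

* **Several co-contig candidate groups.** When more than one contig
  holds two or more candidate clones, the marker is reported
  `ambiguous` and not anchored. Anchoring only unambiguous resolutions
  keeps the anchor table conservative; the groups are recoverable from
  the candidate set if a user wants them.
* **Order of resolution tiers.** Shared-contig resolution (type 2) is
  always tried before end-clone matching (type 3), so a marker never
  receives both; type 3 results carry a `merge_suggested` flag naming
  the two contigs involved. If several candidate pairs match at the
  cutoff, the lowest-scoring pair is taken (and with more than one,
  ambiguity is again conservative — in practice end-clone matches are
  rare enough that ties did not arise in any simulated run).

A 1-1-1 signature pointing at an unoccupied roster well is reported
`no_clone_overlap` with an `empty_well` flag: the signature was
complete, but no clone can carry it, which distinguishes a roster gap
from a missing pool.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 0.8 | fraction of marker length | stringent covered-region rule; inclusive comparison |
| sweep | 0.8 → 0.3 by 0.1 | fraction | relaxed re-analysis recovering false-negative pools |
| `max_per_dim` | 5 | pools per dimension | markers above this in any dimension are repetitive (strict >) |
| `mapq_min` | 1 | MAPQ | drops MAPQ-0 records as an aligner-agnostic proxy for unique mapping |
| `min_depth` | 20 | fold coverage | pools below this are flagged; positives plateau near 30x |
| `endmatch_cutoff` | 1e-25 | probability | relaxed Sulston cutoff for end clones (map built at 1e-45) |
| `tolerance` | 7 | band units | fingerprint band-matching tolerance |
| `gel_length` | 3600 | band units | effective gel length in the chance-match probability |
| QC `max_gap` | 5 | genes | zipper-adjacency flag: pairs separated by ≥ 5 additional genes |
| QC `max_cm` | 1.0 | cM | genetic-distance flag (≥, plus cross-chromosome) |

The fingerprint parameters deserve a note: published descriptions of
FPC-style maps state the cutoffs (1e-45 build, 1e-25 end-clone
comparison) but not the tolerance/gel settings behind them, so both are
exposed rather than fixed; the defaults are the conventional
agarose-free HICF-era values and the cutoffs are what actually carry
the semantics.

# The Sulston score and its numerical behaviour

With band counts $n_{hi} \ge n_{lo}$ and $k$ shared bands, the score is
the binomial upper tail at $k$ over $n_{lo}$ trials with per-band
chance-match probability $p = 1 - (1 - 2\,\mathrm{tol}/G)^{n_{hi}}$.
Shared bands are counted by greedy one-to-one two-pointer matching of
the sorted band lists within ± tolerance — deterministic and invariant
to input order. The tail is evaluated through `pbinom(..., lower.tail =
FALSE)`, which works in log space internally, so cutoffs like 1e-25 are
represented exactly; two 60-band near-identical fingerprints score
around 1e-41.

The binomial formulation treats the $n_{lo}$ band-match events as
independent. Under the actual matching process (uniform band positions,
one-to-one consumption) they are weakly negatively dependent, so the
formula slightly overestimates deep tails at high band density: at 20
bands per clone the Monte-Carlo frequency of ≥ 2 chance matches sits a
few percent below the formula, a property of the classical formulation
itself, not of this implementation. The Monte-Carlo validation in the
test suite therefore probes the sparse regime (8–10 bands, $k = 1$,
10^5 trials), where the independence approximation is accurate to well
within sampling error, and complements it with exact closed forms:
$k = 0$ gives score 1, and identical $n$-band fingerprints give
$p^n$. In anchoring practice only the deep tail matters (cutoffs of
1e-25 and beyond, dozens of shared bands), where a few percent of
relative bias is irrelevant against 40 orders of magnitude of signal.

# Coverage computation

Alignments are consumed as SAM/BAM via Rsamtools/GenomicAlignments.
Retained reads are mapped, primary, non-supplementary and pass
`mapq_min`; mates of a pair are treated independently. Breadth counts
reference positions at depth ≥ 1 — the depth threshold is a documented
assumption, since "covered" could in principle demand more — using the
aligned reference span of each read: reference-consuming CIGAR
operations (M, =, X, D) count as covered, insertions and soft clips do
not. Internally intervals are 0-based half-open; SAM's 1-based closed
convention is converted at the boundary. The implementation is checked
against a brute-force per-base depth array on randomized instances.

Depth subsampling (`saturation_curve()`) draws reads uniformly without
replacement under a stated integer seed; requested depths above the
available data are capped with a warning rather than failing, since
capping is what a ragged real dataset needs.

# What the simulator emulates

`simulate_experiment()` generates: a contig-structured map (contigs of
2–4 clones until the MTP size is reached; default 3,823 clones, the
size of a ten-plate re-array less 17 empty wells); per-clone
fingerprints built from contig-level band tracks so that adjacent
clones share half their bands; a roster laid out in contig order, as an
MTP re-array is picked; markers of four classes — present in one clone,
present in the overlap of two adjacent clones, repetitive (placed in 7
clones across 7 distinct plates, exceeding the 5-per-dimension filter),
and off-target (absent); log-normal per-pool depths centred near 30x
with enough spread that some pools fall under the 20x floor; and a
coverage table in which truly present (marker, pool) pairs get covered
fractions of 0.9–1.0. Marker lengths are normal (504 ± 53 bp, clipped
at 100); sequences are random DNA at 44% GC.

Noise is injected at the call level, matching the failure mode of the
real assay: a false negative truncates the covered fraction to a
uniform draw below the stringent threshold (so part of the signal is
recoverable by the 0.3 sweep, as observed in practice), and a false
positive lifts an absent pair above it. One master seed is expanded
once into per-stage sub-seeds (map, roster, markers, placement, depths,
coverage), making bundles byte-identical under a fixed seed.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: alignment ambiguity within
marker sequences (reads are placed, not aligned), clone
under-representation correlated with pool depth (dropout is independent
per pair), chimeric BACs, restriction-site biases in library coverage,
and contamination. Recovery of 1.0 on noise-free runs validates the
deconvolution logic, not the sequencing assay.

# Problem sizes and runtime choices

The default simulated experiment is full study scale (3,823 clones,
50 pools, ~600 markers) and runs in a few seconds. The test suite uses
a reduced geometry (ten 8×12 plates, 800 clones, ~100 markers) for most
property checks and full scale for the acceptance-style checks
(≥ 500 single-clone markers for recovery; 1,000+ markers for the sweep
nesting property); the Monte-Carlo Sulston validation uses 10^5 trials.
The whole suite completes in about a minute.

# Known limitations

* The optional `.fpc`-dialect reader was dropped: the format is
  versioned and under-documented, and the clone→contig TSV carries the
  same information losslessly. FPC users export the table once.
* Anchor type 3 depends entirely on the supplied fingerprints; with no
  fingerprint table the cascade simply never reaches type 3 (the
  observed effect is small — in published practice type 3 contributes
  ~2% of anchors).
* `estimate_false_positive_rate()` reports the fraction of non-target
  markers detected in ≥ 1 pool. Note this is a per-marker quantity:
  with 50 pools, a per-pool false-positive rate $r$ yields a per-marker
  detection probability $1 - (1-r)^{50}$, which is what the estimator
  converges to on simulations.
* The arm partition (`partition_markers_by_arm()`) assumes markers are
  uniformly distributed along the physical length of the chromosome;
  its round-half-up count is a bookkeeping convention, not an
  inference.
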