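---
title: "Detecting and designing engineered balancer rearrangements from split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and designing engineered balancer rearrangements from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancerSV)
```

# Scope and model

`balancerSV` verifies engineered chromosome-scale rearrangements —
inversions, reciprocal translocations and the deletions, insertions and
duplications that can accompany imperfect repair — from short single-end
sequencing, and designs the CRISPR reagents (sgRNA sites, two-arm
chimeric targeting vectors) that program such rearrangements. The
evidence model is purely split-read plus read-depth: no read pairs, no
assembly, no genotype likelihoods.

A rearrangement junction leaves a precise signature in a primary
mapping: a read crossing the junction aligns by one side only, the other
side remaining as a soft clip. The pipeline rediscovers the clipped
side's true origin by exact 16-mer seeding and local realignment, joins
the two placements into a split read (SR), and reduces SR clusters to
variant calls.

## Split-read geometry

Each SR carries two placements, the anchor and the realigned clip,
ordered 5'→3' within the (stored-orientation) read. Internally every
placement end is reduced to a breakpoint end `(linkage group, position,
side)`, where `side = left` means the read approaches the junction from
lower coordinates. This formalism makes the five SR categories exact
set-theoretic statements:

| category | geometry |
|---|---|
| deletion | same group, one `left` end at *x*, one `right` end at *y*, *x* < *y* |
| insertion | same, but *x* > *y* (the read jumps backwards) |
| inversion | same group, both ends `left`, or both `right` |
| translocation | different groups, one `left` + one `right` |
| translocational inversion | different groups, equal sides |

An SR and its reverse complement describe the same junction; both
classification and clustering are invariant under that flip. A
chromosome-scale inversion produces two reciprocal inversion-type
clusters at the same coordinate pair (left-left and right-right); a
reciprocal translocation two translocation-type clusters with swapped
sides. Matching those pairs yields the balancer calls.

## Depth model

Coverage is `mean(raw read length) × reads / reference length`; clipped
bases count toward read length because the quantity describes the
library, not the mapping. Per-base depth counts only aligned (M) bases.
Bases with depth strictly greater than 1 form the mapped mask; there,
normalized depth ND = depth / coverage, and the case/control ND ratio
(DR) estimates relative copy number: DR ≈ 1 copy-neutral, ≈ 0.5
hemizygous loss, ≈ 2 duplication. Candidate regions are summarized by
the arithmetic mean of per-base DR (the obvious alternatives — median,
trimmed mean — differ negligibly at the coverages involved; the mean is
the simplest to reason about and is what the filters' thresholds are
calibrated against).

# Tunable parameters

All defaults live in `detect_config()` and are surfaced by the CLI.

| parameter | default | meaning / rationale |
|---|---|---|
| `min_clip` | 20 bp | clips must be *strictly* longer to be realigned; shorter tails are too seed-poor (only `L − 15` sixteen-mers) |
| `kmer` | 16 bp | exact-seed length; on a ~10^8 bp genome a random 16-mer recurs ~a handful of times, so seeding stays near-unique while guaranteeing a hit for any exactly occurring clip ≥ 16 bp |
| `match, mismatch, gap` | +2, −1, −2 | Smith–Waterman unit scores; gaps are linear (a single per-base penalty, no affine opening cost) |
| `min_score` | 32 | a realignment must be worth at least one perfect 16-mer |
| `margin` | 20 bp | realignment window = seed position ± (clip length + margin), so the optimal placement of a true-locus clip always fits |
| `tol` | 10 bp | clustering, control matching and pair bracketing tolerance; junction coordinates jitter by repair micro-indels and realignment end effects |
| `min_del_sr` | 3 | deletion clusters need **more than 2** supporting reads |
| `min_complex_reads` | 10 | complex (paired-cluster) candidates with fewer than ten reads are removed |
| `depth_mapped_min` | 1 | mapped regions require depth **greater than 1** |
| `dr_del, dr_dup, dr_mult` | 0.75, 1.75, 2.5 | DR thresholds: deletion removal, duplication, multiplication |
| `local_max_span` | 1 kb | inversion cluster pairs spanning less are reported as local variants, larger ones as breakpoint pairs |

The support thresholds are deliberately implemented with strict
inequalities exactly as stated above ("more than 2", "greater than 1");
both readings ("≥ 2", "≥ 1") are plausible editorial intentions, so the
thresholds are configuration, not constants, and the strict reading is
the default.

# The simulator

`sim_config()` → `simulate_genome()` → `apply_rearrangements()` →
`simulate_reads()` → `emulate_mapping()` generates everything the
detector consumes, deterministically from one master seed
(hierarchically split per stage, so case, control and junction-repair
randomness are independent).

What it emulates:

* i.i.d. genomes at a configurable GC fraction (default 0.36, a
  nematode-like value);
* reads of ~140 bp (discrete-uniform ±10), uniform starts, either
  strand, per-base substitution errors (default 0.5%) and 1 bp indel
  errors (default 0.05%) — plausible short-read error magnitudes chosen
  once as configuration, not claims about any particular instrument;
* junction micro-indels (optional): each engineered junction may gain or
  lose up to `microindel_max` bases, modelling end-joining repair;
* mapper behaviour at breakpoints: a read is placed by its **longer**
  colinear piece with the remainder soft-clipped, and dropped as
  unmapped when that piece is under 20 bp. The min-seed of 20 mirrors
  the downstream clip threshold so both sides of a junction are
  observable. Sequencing indels appear as I/D CIGAR operations.

What it does not emulate: homopolymer/flow-space error chemistry,
GC-coverage bias, chimeric library artifacts, multi-mapping ambiguity in
repeats, and real mapper heuristics. Consequently, passing recovery
tests demonstrates the *algorithmic* correctness of clip harvesting,
seeding, realignment, classification and filtering — not robustness to
every real-data artifact. The truth-aware mapper emulation stands in for
an external primary mapper; it is the one component that could mask
mapper-specific failure modes, which is why the realignment stage is
additionally pinned to independent oracles (naive search, brute-force
dynamic programming) rather than only to simulations.

Insertions support `copy_from` semantics (a copied, optionally
inverted, segment inserted elsewhere) in addition to novel sequence. A
novel insertion's clips match nothing and legitimately produce no SR —
only its depth signature remains — whereas a copied insertion produces
the documented paired deletion+insertion-type SR signature around its
source region. This distinction is intrinsic to split-read evidence,
not a simulator shortcut.

# Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; SAM I/O
  converts at the boundary.
* **Tie-breaks** in realignment: highest score, then smallest distance
  between candidate region and anchor (different linkage group =
  infinite), then lexicographically smaller group name, then smaller
  coordinate — fully deterministic.
* **Colinear realignments** (same group, same sense, zero gap) are
  discarded at SR construction: they are just the read rejoining its own
  locus, not evidence of a junction. Seed hits inside the anchor are
  allowed earlier; this rule is where they die.
* **Cluster positions** are medians of member junction coordinates,
  rounded to integers.
* **Local versus chromosome-scale inversions** share one SR signature
  (two reciprocal clusters). `run_detect()` splits them by
  `local_max_span` (default 1 kb): below, the event is reported as a
  local inversion / inverted insertion (a region-style candidate subject
  to the 10-read complex filter); at or above, as a copy-neutral
  breakpoint pair exempt from depth filters. One signature, one
  threshold, no double reporting.
* **Paired-candidate bracketing** requires the two clusters to share one
  junction end (within `tol`, opposite sides) with the two remaining
  ends bracketing a region wider than `tol` on one group. A residual gap
  of 1–`tol` bases between the shared ends is additionally emitted as a
  deletion candidate (the "gap near the border" rule); it is emitted as
  an extra candidate rather than re-labelling its parent, keeping the
  parent call intact.
* **Reciprocal-translocation vectors** are constructed by analogy with
  the inversion rule (the worked description available covers only the
  inversion case); the choice is pinned by an exact duality test —
  vector sequence ≡ rearranged genome read across the junction — for
  both event types.
* **Cas9 cleavage** uses the canonical SpCas9 blunt cut 3 bp PAM-proximal
  ("within 3 bp of PAM"); the offset is a parameter of
  `predict_cleavage()`.
* **Fisher's exact test** is computed by direct hypergeometric
  enumeration (two-sided, probability-mass criterion with a 1e-7
  relative tolerance, matching the standard convention), and is checked
  exhaustively against `stats::fisher.test`.
* **Degenerate inputs**: N bases are excluded from queries and never
  match in scanning or alignment scoring; empty candidate sets write
  valid header-only reports; regions with no jointly mapped base get
  `DR unavailable` and are kept flagged rather than silently filtered.
* **Printed-percentage ambiguity**: screening efficiency ratios are
  returned raw plus both two-decimal renderings (rounded and truncated)
  because published tables of this quantity are not consistently
  rounded; tests assert only renderings that are unambiguous.

# Problem sizes used in the test suite

The suite favours many small, seeded simulations: unit fixtures use
2–30 kb genomes; the recovery experiment (`recovery_experiment()`) runs
20 replicates of a 100 kb two-group genome (60 + 40 kb) carrying one
5–50 kb inversion and one reciprocal translocation at coverage 20 with
0.5% substitution errors and 50%-probability micro-indels up to 10 bp,
plus an independent control-versus-control null per replicate. These
sizes exercise every code path (including both sequencing orientations
of every junction at ~20 supporting reads) while keeping each replicate
a few seconds of work; recovery at these scales is the package's
regression bar, restated by `scripts/acceptance.R`.

# Known limitations

* Single-end evidence only; no discordant-pair signal, so dispersed
  duplications without a breakpoint-spanning read are invisible to the
  SR stage (the DR stage may still flag them).
* Exact seeding cannot place a clip whose every 16-mer carries an error;
  at 0.5% substitution this loss is negligible, but highly degraded
  clips fail quietly.
* Repeats longer than a clip make realignment ambiguous; the
  nearest-to-anchor tie-break is a heuristic, not a guarantee.
* The control subtraction matches SRs at `tol`; a true variant shared by
  case and control (e.g. a background polymorphism) is deliberately
  removed — the tool verifies *engineered* differences against a
  matched control.
* VCF output uses symbolic SV records plus BND pairs for
  interchromosomal junctions; it records calls, not genotypes.
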