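---
title: "Model-guided coronary tree correction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided coronary tree correction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catimprove)
```

## The problem

A coronary artery tree (CAT) extracted automatically from CCTA is a forest of
centerline pathlines rooted at the left and right coronary ostia. Extraction
errors fall into a few recurring classes: structure disconnected from the
ostia, branches that run on into veins (too long, or leaving the parent at an
implausible angle), branches cut short by gaps in the vesselness response,
and whole branches missed. `catimprove` corrects these guided by an
anatomical statistical model, monitored by a quality score so that no
correction step can silently make the extraction worse.

## The anatomical statistical model

The model (one per dominance type, RD and LD; balanced anatomy is treated as
RD, the most prevalent type) stores the AHA segment topology as a label
forest with three roots — the proximal RCA, the left main (LM), and the
proximal LCX — plus per label an importance weight in [0, 1] and an expected
length range in mm, and four global constraints: maximum pathline length
(250 mm, longer than any anatomical ostium-to-leaf path), maximum bifurcation
angle (120°), minimum pathline length (1 mm), and the weight threshold (0.4)
above which an absent label counts as a probable missed extraction rather
than a normal anatomical variant.

Shipped defaults give main-branch segments and the posterior descending
artery (PDA) weight 1.0, first-order side branches (D1, OM1, RPLB/LPLB) 0.6,
and second-order ones (D2, OM2) 0.3, so that only the absence of important
labels triggers a search. Length ranges are per-label anatomically plausible
values (e.g. LM 5–15 mm, proximal RCA 15–35 mm); a label that omits its range
in a user config falls back to 10–50 mm. Two points matter for these
defaults. First, the mechanism (range check, weight threshold) is the
contribution; the numbers are config inputs and fully overridable. Second,
the ranges are chosen so the labeling heuristic below is unambiguous on
phantoms: side-branch maxima stay below the main-chain remainder beyond their
attachment, otherwise a "longest path" main branch could legitimately run
through a side branch.

## Baseline labeling and dominance

The labeling method this package calls is deliberately a deterministic
baseline behind a pluggable surface (`assign_labels()`), because a
production-grade anatomical labeler is a project of its own. The RCA main
branch is the longest ostium-to-leaf pathline chain of the right tree; on the
left, the root pathline is the LM and the two longest chains through distinct
LM children become the LAD and LCX, disambiguated by projecting each chain's
mean direction onto a configurable anterior axis (the LAD is the more
anterior/apical branch; the phantom generator and the default axis agree on
`(0, -1, 0)`). Main chains take their proximal/mid/distal segment labels
sequentially along the chain; chain pathlines beyond the distal label fall
into the side pool. Side branches are matched to the model's side labels of
the segment they attach to, in attachment order. Unmatched structure stays
unlabeled — and is exactly what the score's spurious-structure penalty sees.

Dominance follows from the PDA: labeled under the RD model, a present RPDA
means right dominance; otherwise a present LPDA under the LD model means left
dominance; with neither, the tree is provisionally RD and the controller
re-checks after improvement. When the provisional RD search for an RPDA
fails, the controller explicitly hypothesizes LD and searches for the LPDA
before settling — without this, a left-dominant case whose PDA was lost by
the extraction could never recover it.

A consequence of order-based side matching worth knowing: if a non-final side
slot (say RPDA, with RPLB behind it) is missing, the matcher first shifts the
later branch onto the empty slot. The finding list then reports the *last*
slot missing, the extension recovers the lost branch, and the next labeling
pass puts every branch back on its own slot. The intermediate labels are
wrong; the fixed point is right.

## The quality score

The score (formula version `wcov-1`, frozen in `quality_score()`) is

$$S = 100\,\max\!\Big(0, \min\!\Big(1, \frac{\sum_l w_l c_l}{\sum_l w_l} - P\Big)\Big)$$

with $c_l = 0$ for an absent label, 1 for a present label with total length
inside its range, and a linear, clamped discount for length violations
($L/L_{\min}$ when short, $1 - (L - L_{\max})/L_{\max}$ when long). The
penalty $P$ adds $0.5\,U/(U + T)$ for unlabeled pathline length $U$ against
labeled length $T$, plus 0.05 per labeled segment violating the angle
maximum. The properties the pipeline relies on, all covered by tests: the
score lives in [0, 100]; it is 100 exactly for a model-identical tree; adding
a missing in-range label never lowers it; removing unlabeled spurious
structure never lowers it (this is what lets deletion operations *raise* the
score). The penalty weights 0.5 and 0.05 are design constants: large enough
that a tree half-buried in unlabeled structure loses tens of points, small
enough that no single spurious branch can mask a recovered label.

## Improvement operations

**Coarse improvement** applies three ordered rules to all vessels: orphans
removed; overlong pathlines pruned to the global maximum and sub-millimetre
pathlines removed (exactly 1 mm is kept — thresholds act on strict
inequality); side branches at angles strictly above 120° removed. Removing a
pathline cascades to its descendants. The pass is idempotent, and its
postconditions are assertable on any output tree.

Bifurcation angles compare the parent's blood-flow direction with the branch
direction, both estimated as chords over 3 mm of arc around the attachment
point. The 3 mm arc is a design choice (the alternative, point tangents, is
noisy at 0.25–0.5 mm voxel scales); it is fixed, documented, and makes angle
computation deterministic for a given tree.

**Deletion** truncates a too-long labeled segment where it starts exceeding
its maximum length, and removes bad-angle labeled segments entirely; angles
are recomputed afterwards because earlier operations may have changed the
topology.

**Extension** bridges to unconnected vessel-like structure in the binary
volume. Start points follow three rules: high-curvature points on the parent
label (absent side branch), on the whole extracted main branch (absent main
segment — its identification is unreliable precisely when a segment is
missing), or the single end point of a too-short segment. "High curvature"
means discrete Menger curvature above 0.1 mm⁻¹ on a 1 mm resampling — about a
6° direction change per millimetre — plus pathline-junction bends evaluated
on a parent-attachment-child stencil. The search then grows a radius from
2 mm in 1 mm steps to the 15 mm maximum (which also bounds the occlusion gap
length the method can bridge); at the first radius containing foreground
voxels not covered by the current tree, the 26-connected component of the
closest hit is traced from its entry voxel to its graph-farthest voxel and
attached through a straight connector at the nearest start point. Ties are
broken by lexicographic voxel index, keeping the whole pipeline
deterministic.

Two numerical details here came out of failure analysis. Traced voxel-centre
paths overestimate arc length (a straight oblique vessel rasterizes into a
staircase up to ~30 % longer), which made freshly recovered branches read as
"too long"; traced paths are therefore smoothed with three passes of an
endpoint-preserving (¼, ½, ¼) kernel before attachment. And rasterization
leaves one-or-two-voxel crumbs near junctions that are pointless to attach
(and were immediately re-deleted, producing an attach/delete oscillation);
components whose traced path is shorter than 1 mm are skipped during search.

## The controller

Each iteration runs: the coarse pass (as a single scored operation); recovery
of absent main branches; dominance determination with PDA repair under the
selected model; then the sub-tree traversal RCA → LAD → LCX, each sub-tree
root label to leaf label, where a main segment with a present child is
skipped in favour of the child (its proximal boundary is an arbitrary
division, so only the deepest present segment's length is meaningful).

Every operation passes through the score state machine: $S_\Delta > 0$ keep;
$T_{S\Delta} \le S_\Delta \le 0$ keep with debt; $S_\Delta < T_{S\Delta}$
revert to the stored snapshot and skip that finding for the rest of the run.
$\Sigma S_\Delta$ is a running sum over all kept operations (positive deltas
repay earlier debt; there is no reset), and the process stops when it falls
below $T_{S\Delta}$, when an iteration leaves the score unchanged, or at the
iteration cap (default 10, guarding against over-extraction). The final
extraction is the stored snapshot with the highest score — which is also why
the final score can never be below the initial one, on any input. Equality of
floating-point score deltas is tested at 1e-9. The default
$T_{S\Delta} = -2$ trades tolerance for transiently harmful operations
against protection from vein take-up; it is a config input.

Determinism is a contract: identical inputs and parameters give identical
trees and logs, and `replay_improvement()` re-applies the kept operations of
a log to the initial tree and reproduces the final tree byte-for-byte under
canonical serialization.

## The phantom generator

The generator emulates the three inputs the correction needs: a ground-truth
labeled tree following the model topology, a binary vesselness volume, and a
degraded "initial extraction".

Geometry: ostia 70 mm apart; each main branch is a chain of piecewise
straight segments with deliberate 12–20° bends at junctions and side-branch
origins — real vessels change direction at bifurcations, and these bends are
what gives curvature-based start-point selection real anchors. Segment
lengths are drawn uniformly within the model ranges (5 % inset), side
branches leave at 25–60°, and all draws come from one seeded generator, so
generation is reproducible. The volume is auto-sized to the tree with a 3 mm
margin at a default spacing of 0.5 mm isotropic (anisotropic spacings are
supported throughout; clinical CCTA is ~0.3 × 0.3 × 0.25 mm — tests use the
coarser default to keep volumes small). Rasterization samples each edge at
0.35 of the smallest spacing, which guarantees a 26-connected skeleton
covering every tree vertex.

Degradations model the observed failure classes: full or fractional pruning
of labeled segments (tree only — the volume keeps the continuous skeleton,
which is the precondition for full recovery); gaps cut from the volume along
a labeled span; floating fragments; vein-like branches attached at >120°;
sub-millimetre stubs; overlong tails pushing a label past its maximum.

What the phantoms deliberately do not model: image noise and vesselness
false positives, lumen calibre, motion artifacts, anatomical anomalies
(e.g. absent LM), and curved rather than piecewise-straight vessels. Passing
the suite therefore demonstrates the correction logic — detection, operation
ordering, stopping behaviour, exact recovery given continuous evidence — not
robustness to raw clinical segmentations.

## Problem sizes and known limitations

The test suite and the acceptance script run phantoms of ~270 mm total tree
length in auto-fitted volumes of roughly 170³ voxels; the randomized
robustness suite uses 50 phantoms across both dominance types, and the
recovery experiment 5 right-dominant phantoms (seeds 1–5), matching the scale
of the artificial-pruning experiment the method is designed around.

Limitations worth knowing before use on real data: the baseline labeler
assigns one label per pathline, so a recovered pathline spanning two
anatomical segments is labeled as one and may be truncated at that label's
maximum; side-slot matching is by attachment order, so intermediate labelings
during recovery can be wrong (the fixed point is correct); extension can in
principle attach vein structure that the score tolerates within
$T_{S\Delta}$ — the paper-level remedy, manual review of low-scoring cases,
applies here too; and only gaps up to the 15 mm maximum searching distance
can be bridged.
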