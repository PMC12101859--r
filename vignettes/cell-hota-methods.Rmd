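---
title: "Cell-HOTA: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-HOTA: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhota)
```

## The problem

Tracking metrics for general multi-object tracking treat object identities
as immutable. Cells divide: a single identity legitimately becomes two, and
the annotated frame of that division is often a judgement call — in a
mother-machine movie the constriction of a dividing bacterium spans several
frames, any of which a human might label as "the" division. Cell-HOTA
extends Higher Order Tracking Accuracy with a division term and, optionally,
a one-frame tolerance on division timing, so that trackers are scored on the
coherence of the lineage rather than on reproducing an annotator's exact
frame choice.

## The procedure

For a ground-truth and a tracker sequence (`cell_sequence` objects holding
label masks and a CTC-style track table), `evaluate_tracking()` performs,
at every threshold α in the grid:

1. **Similarity.** Exact pixel-set Jaccard (IOU) for every overlapping
   (ground truth, tracker) detection pair, per frame. Masks are compared on
   identical grids; there is no resampling, so every IOU is a ratio of pixel
   counts.
2. **Matching.** Within each frame, a Hungarian assignment over the pairs
   with IOU strictly greater than α. The assignment weight is
   `1 + (align + 1e-6·iou) / (4·max(n_gt, n_res))`, where `align` is a
   whole-track alignment score (frames the two tracks overlap, divided by
   frames either exists). The constant 1 makes the objective lexicographic:
   the matching maximises the number of true positives first; among
   matchings of equal size it prefers globally consistent track pairings,
   then higher IOU, with a deterministic tie-break toward low label pairs.
   Matching is redone independently at every α, so strict thresholds never
   inherit permissive pairings.
3. **Division classification.** A tracker division is a true positive
   (TPD) if its two daughters match the two daughters of a ground-truth
   division in the frame where both appear, the parents match in the frame
   before, and the mean daughter IOU exceeds α. Competing pairings at one
   frame are resolved greedily by mean daughter IOU (ties: lowest parent
   labels). Everything unpaired is an FPD (tracker side) or FND (ground
   truth side).
4. **Flexible divisions** (default on). Unpaired divisions exactly one
   frame apart are rescued when parents match before the earlier division
   and daughters match at the later one. The shifted frame is then rescored
   as if the division had been on time: for an early division the two
   tracker daughters are merged into one object and compared against the
   still-undivided ground-truth cell (one TP if the merged IOU beats α);
   for a late division the two ground-truth daughters are merged against
   the single tracker cell and the merged IOU is counted **twice**, once
   per ground-truth cell. The association list is rewired the same way, so
   each track pair's frame counts look exactly as they would for an on-time
   division. This makes the score of a one-frame-shifted division *equal*
   to the clean score, not merely close — a property the test suite asserts
   exactly.
5. **Scores.** `DetA = TP/(TP+FP+FN)`; `A(c) = TPA/(TPA+FPA+FNA)` per
   detected true positive and `AssA` their mean (computed per track pair
   and weighted by TPA, which is algebraically identical);
   `DivA = TPD/(TPD+FPD+FND)`; `AssDivA = sqrt(AssA·DivA)`;
   `Cell-HOTA_α = sqrt(DetA·AssDivA)`; `HOTA_α = sqrt(DetA·AssA)`.
   Integrated scores are arithmetic means over the grid.

## Parameters that matter

- `alpha_grid` (default `seq(0.05, 0.95, by = 0.05)`, 19 values): the
  localisation-stringency sweep. The integrated scores are means over
  exactly this grid; a single `--alpha 0.5` run is supported in the CLI as
  the conventional mid-stringency snapshot.
- `flex` (default `TRUE`): the one-frame division tolerance. The window is
  exactly one frame and not configurable; wider windows are a known
  extension, not implemented here.
- `link_gaps` (default `FALSE`): CTC track tables may contain single-child
  parent links (gap closing). By default the child is treated as a new
  identity — it earns no association credit across the gap — because the
  association score is defined per cell and the division machinery assumes
  binary splits. With `link_gaps = TRUE` the child is merged into the
  parent's identity before scoring.
- The matching bias constants (`1e-6` on IOU, `1e-12` on the label
  tie-break) only order matchings that the alignment score leaves tied;
  they are far below any score difference pixel-count IOUs can produce on
  realistic images.

## Definitional edge cases

- **Strict inequality.** A pair with IOU exactly equal to α is *not* a
  match; an IOU of exactly 1 passes every threshold in the grid. Golden
  fixtures deliberately avoid IOUs sitting exactly on grid points, except
  the erosion fixture built to flip at 0.6.
- **FPA/FNA.** A false positive association is a frame where the tracker
  track is matched to a *different* ground-truth track (symmetrically for
  FNA). Frames where the counterpart is present but unmatched count against
  detection, not association. This keeps the three sub-metrics orthogonal —
  each synthetic perturbation moves exactly one family of counts — and it
  is what makes the flexible-division rewiring exactly score-preserving.
- **Division-free data.** DivA is undefined (reported `NA`) when neither
  sequence contains a division; `AssDivA` then falls back to `AssA`, so
  Cell-HOTA equals HOTA exactly. Thresholds where DivA is undefined are
  excluded from the integrated DivA mean only.
- **Empty universes.** `DetA` with no detections on either side is 1 (the
  sequences agree) with a warning; `AssA` with no true positives is 0 with
  a warning.
- **Flex rescue fall-back.** If a one-frame-shifted division passes the
  structural checks but its merged-object IOU does not beat α, the whole
  rescue is reverted for that α: the division counts as FPD+FND and no
  tallies are touched. Likewise the rescue is declined if a cell at the
  shifted frame is matched to an unrelated cell.
- **Which daughter match is removed.** For an early division the
  ground-truth cell is matched to at most one tracker daughter
  (one-to-one matching), and that is the match removed; a property test
  confirms the scores are invariant to relabelling the daughters.
- **Lexicographic matching.** An exhaustive search over *all* per-frame
  matchings can score above any per-frame-maximal matcher, because
  discarding a poorly associated true positive can raise
  sqrt(DetA·AssA). The matching is therefore defined lexicographically —
  true positives first — which is the established HOTA behaviour, and the
  brute-force reference in the tests enumerates maximum-cardinality
  matchings only.

## The synthetic generator

`generate_scenario()` builds movies the metric can be verified on, in two
layouts: a mother-machine channel (cells stacked along one axis, divisions
split along the channel) and an open 2-D grid (rectangles or ellipses,
divisions split along the long axis). Three deliberate simplifications keep
every expected score hand-computable:

- **Static masks.** Cells neither move nor grow; IOUs under perturbations
  are exact pixel-count ratios (a cell eroded from 240 to 144 pixels has
  IOU 144/240 = 0.6 at every frame, flipping from TP to FP+FN exactly at
  α = 0.6).
- **Exact partition at division.** Daughters partition the parent's pixel
  set, so the merged-object IOU of a one-frame-shifted division is exactly
  1 and the flexible-division invariance can be asserted as equality.
  Sibling daughters therefore touch; all other cells keep background
  separation so erosion/merge perturbations are unambiguous.
- **One perturbation, one error family.** Each `perturb()` kind (erode,
  dilate, translate, drop, spurious, identity switch/swap, division shift,
  merge) targets a single count family, asserted by tests.

Consequently, passing on these fixtures demonstrates the *metric's*
correctness — counts, formulas, matching, flex adjustments — not robustness
to real-microscopy phenomena (motion, growth, shape change, touching
cells, segmentation noise), which the metric consumes through the masks it
is given.

A note on the identity fixtures: a midpoint *hand-off* of both tracks to
fresh labels yields A(c) = 2/(2+0+2) = 0.5 for every true positive
(AssA = 50); a midpoint *exchange* between two continuing tracks is the
harsher error A(c) = 2/(2+2+2) = 1/3, because each track also spends two
frames matched to the wrong partner. Both are available as perturbations
(`id_switch`, `id_swap`); the catalog's `id_swap` scenario uses the
hand-off, whose 50.00 is the textbook ID-switch value.

## Problem sizes

The shipped tests run on movies of 1–3 cells and 3–6 frames with 12–576-px
cells: large enough to express every behaviour (crossing assignments,
successive divisions, boundary shifts), small enough that the brute-force
matching reference — exhaustive enumeration over 200 seeded random
scenarios, compared to 1e-9 — completes in minutes. The evaluator itself is
vectorised per frame and handles CTC-scale movies; only the brute-force
reference is limited to toy sizes.

## Known limitations

- 2-D masks only; no z-stacks, no bounding-box mode.
- Binary divisions only; a parent with three or more simultaneous children
  is rejected at validation.
- The flexibility window is fixed at one frame.
- Association and division accuracy are weighted equally inside
  `AssDivA`; movies with rare divisions may prefer a down-weighted
  variant, which this version does not expose.
- Whole-lineage trajectory scoring (following a cell through all its
  descendants as one unit) is out of scope.
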