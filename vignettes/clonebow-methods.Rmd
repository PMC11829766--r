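---
title: "Methods: multicolor clonal analysis with cloneBow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicolor clonal analysis with cloneBow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneBow)
```

cloneBow quantifies multicolor (Brainbow/zebrabow-style) clonal experiments:
labelled founder cells recombine to one of several fluorophores, clonally
related cells share a color, and the analysis must turn per-cell channel
measurements, positions and (optionally) tracks into clone-level lineage
statistics. This vignette documents the model, the parameters that matter,
the design decisions taken where the procedure was genuinely open, and what
the synthetic-data generator does and does not emulate.

## Color model

Measured channel means are normalized onto the ternary simplex,
$r = R/(R+G+B)$ and likewise for $g$ and $b$, which removes overall
illumination and expression-level differences; `assignColorIdentity()` then
bins each point into one of 25 regions.

**Why a triangular grid.** The partition must produce exactly 25 identities
on the simplex. The unique subdivision of a triangle into $n^2$ congruent
unit triangles gives $25 = 5^2$ regions when each edge is split into 5 equal
intervals (15 upward, 10 downward triangles); the implementation validates
$n^2 = 25$ and the test suite checks the partition against a brute-force
point-in-triangle oracle. Other 25-cell tilings would be admissible in
principle; the triangular grid is the natural one on a ternary diagram and is
the package's fixed choice.

**Tie-breaks.** Floors are half-open ($[i/5, (i+1)/5)$), the upper simplex
boundary is closed, and grid lattice points are assigned to an upward
triangle incident to them. A point with floor sums $i+j+k = 3$ is in a
downward triangle, otherwise upward. This makes the assignment total,
unique, and invariant to intensity scaling; a numerical guard of $10^{-9}$
absorbs floating-point representation of exact grid values. All-zero
measurements are unclassifiable and raise an error (or `NA` with
`onZero = "na"`).

**Frequency classes.** Identities above 10% of classified cells are
*frequent*, below 2.5% *rare*, otherwise *intermediate* (strict
inequalities; exactly 2.5% or 10% is intermediate). Rare-color clones are
unambiguous enough to trace; frequent-color clones are followed only when
isolated.

**Red/non-red clones.** Functional designs co-express the manipulated
construct with the red fluorophore. A clone is *red* when its mean red
fraction exceeds 5% and *non-red* below 1%; anything in between is excluded.
The red fraction is the per-cell $R/(R+G+B)$ averaged over the clone —
normalization chosen for illumination invariance, with the raw-channel mean
available via `method = "raw"` since the original criterion is stated as a
mean red intensity without an explicit normalization.

## Clone calling

Clones are connected components of the graph joining cells with identical
color identity at centroid distance $\le d_\mathrm{contact}$. The contact
distance is qualitative in the source procedure; the default of **12 µm**
corresponds to about one nuclear diameter in the embryonic zebrafish neural
tube and is exposed in `pipelineConfig()`. Components are numbered by
mediolateral, then dorsoventral centroid position, and shrinking
$d_\mathrm{contact}$ can only refine the partition (tested property).

Traceability filtering keeps clones of 1–3 cells whose members all lie in
the progenitor domain (apical contact, or within the ventricular-zone band).
Frequent-color clones are kept only when no same-colored clone lies within
an isolation radius, defaulting to $2\,d_\mathrm{contact}$ — unstated in the
source procedure, chosen conservatively so that two frequent clones that
could be confused are both dropped.

Cross-timepoint linking matches clones of equal identity within a boundary
by greedy nearest-centroid assignment; a tie between two equidistant
candidates is flagged ambiguous and left unassigned rather than guessed.

## Fates and division modes

A cell is a progenitor (P) when its nucleus is near the ventricle with an
apical contact — an apical contact alone suffices, since radial glia keep
their apical process while the nucleus migrates — and a neuron (N) when it
sits in the mantle zone without apical contact. Ventricular position without
apical contact is contradictory and yields "unassigned"; a missing contact
flag downgrades the call to position only. The VZ/MZ line defaults to a
fractional cutoff (0.4 of a 40 µm dorsoventral extent); an explicit per-
boundary geometry can be supplied by adjusting `vzMax`.

Track-based mode classification follows the daughters: PN when they are not
in contact and separate across the VZ/MZ line; PP (NN) when they remain in
contact at the same dorsoventral level — $|\Delta DV| \le$ `dvTol`, default
$d_\mathrm{contact}/2 = 6$ µm, unquantified in the source procedure — with
both fated P (N). Fate is not ascribed to terminal daughters tracked less
than 3 h after division (`minTrackedAfter`); a daughter that divides again
is a progenitor regardless. Daughters are evaluated at least one frame after
the division because a newborn neuron may still hold its apical endfoot at
the division frame itself.

**Endpoint composition rule.** Without tracks, per-clone mode counts are
inferred from composition: each PP division adds one progenitor, each PN one
neuron, so PP = #P and PN = #N; NN divisions are considered only in clones
with an even number of neurons. Two points were genuinely open:

* *Founders.* The literal rule does not discount the progenitors a clone
  started from; `founders = 0` (the default) keeps it literal, while passing
  the clone's starting cell count subtracts them. The two routes can only
  agree exactly under the founder-subtracting convention — the final
  progenitor count is founders + PP − NN as a matter of bookkeeping — so the
  endpoint/track consistency checks use it.
* *NN attribution.* The default counts one NN per mutually-nearest pair of
  neurons in contact at the same DV level, each counted pair removing two
  neurons from the PN tally; `nnRule = "even_all"` attributes all neurons of
  even-neuron clones to NN for sensitivity analysis. When a clone combines an
  NN division with an odd number of PN-born neurons, the even-neuron gate
  blocks NN attribution and the endpoint estimate is necessarily wrong —
  an intrinsic limit of the composition rule, not of the implementation.
  The consistency check therefore runs on a PP/PN cohort, where the identity
  is exact, with NN pairing unit-tested separately on constructed clones.

**Sister cells.** For two-cell clones at the reference timepoint,
`sisterAnalysis()` reports proliferative concordance (both or neither
divide), synchrony, the absolute inter-division delay, and mode concordance.
Synchrony is defined as a delay of at most one frame interval; with hourly
frames this counts same-frame and adjacent-frame divisions as synchronous,
a deliberately tolerant reading of "dividing at the same time" under
discrete sampling.

**Time-course.** `modeTimecourse()` bins assigned divisions per hour and
regresses each mode's fraction on bin midpoints; a single usable bin is
flagged sparse with an undefined slope, and a constant fraction reports
slope 0 with $R^2 = 0$ by convention.

## Statistics

Two-group comparisons follow a normality gate: Shapiro–Wilk on each group at
$\alpha = 0.05$ (the gating test is a configuration choice; the source
procedure names none), then Welch's unequal-variance two-sided t-test if
both groups pass, otherwise the two-sided Mann–Whitney test. Groups below
$n = 3$ or constant-valued groups fall back to Mann–Whitney with a warning
or note. All tests are two-sided. `welchFromSummary()` provides the
closed-form Welch test from means, s.d. and n, cross-checked in the tests
against `t.test()` on moment-exact samples. Multi-group designs use one-way
ANOVA with Dunnett contrasts against a named reference (via multcomp), with
family-wise adjusted p-values.

## The synthetic-data generator

`simulateDataset()` produces annotated cell tables with complete ground
truth. Defaults are fixed to the study conditions of a hindbrain-boundary
time-lapse and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| imaging window | 32–45 hpf, hourly | tracking window and cadence of the time-lapse design |
| `divisionProbPerFrame` | 0.056 | solves $1-(1-p)^{13} = 0.53$, the observed dividing fraction over 13 h |
| `modeProbs` | PP 0.40, PN 0.58, NN 0.02 | observed division-mode shares |
| sister delay | $\mathcal N(2.8, 1.9^2)$ h, truncated at 0 | observed inter-sister division delay; discretized to the frame grid |
| initial clone size | 1–3 cells, (0.14, 0.77, 0.09) | two-cell clones dominate at the window start (mean ≈ 2) |
| `channelNoiseSD` | 0.02 | a few percent of the normalized channel range, typical of semi-manual ROI means |
| geometry | 40 µm DV extent, VZ fraction 0.4, clones 60 µm apart | one neural-tube wall; clones separated beyond contact range |
| `copyNumberProbs` | 1–3 copies, (0.5, 0.3, 0.2) | the true injected copy-number distribution is unknown; configurable |

Division timing is discretized to the frame interval (an optional
half-frame jitter exists for half-hour division times); pre-window divisions
that create the initial two- or three-cell clones are symmetric
proliferative, emulating a progenitor pool that expanded before neurogenesis
onset, and are excluded when drawn-mode frequencies are checked. When both
daughters of a division are progenitors, the second sister divides at the
first sister's time plus the truncated-normal delay; a delayed division
falling beyond the window does not happen, which couples sister
proliferative behavior the way windowed observation does.

The renderer places progenitors apically with apical contact and neurons in
the mantle zone one frame after their birth; clone members occupy adjacent
5 µm lanes (so sisters are in contact and clones are internally connected at
the window start), distinct clones are separated beyond contact range, NN
sister pairs are the only mutually-nearest contacting neuron pairs at one DV
level, and PN daughters are placed more than one contact distance apart
across the VZ/MZ line. Measured RGB is the founder's true simplex color plus
independent Gaussian noise clipped at zero; unrecombined (far-red default)
founders are emitted flagged, with no simplex color, and are excluded by
color classification.

**What the generator does not emulate:** pixel-level images, photobleaching
or channel crosstalk (noise is constant and independent per channel), cell
migration (positions are static per cell), tissue packing (cells of
different clones never touch), track loss, or temperature-dependent staging.
Passing tests on synthetic data therefore validate the *computations* —
partitioning, graph clustering, counting rules, estimators — not the
upstream imaging and tracking steps, and real data with drift, crowding or
dropout will stress the contact and linking parameters in ways these tests
do not.

One geometric limitation is intrinsic: a two-cell clone consisting of one
progenitor and one neuron cannot simultaneously satisfy "PN daughters not in
contact" and "clone internally connected", so single-timepoint clone calling
is anchored at the window start (where traceable clones lie in the
progenitor domain), and sparse mixed-fate clones at later timepoints may
split under the strict contact rule — as they would in the original
procedure without the imaging context.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 250–800 clones:
large enough that binomial sampling error (the 3-standard-error bands used
throughout) is a few percentage points, small enough to run in seconds on
one CPU. Monte-Carlo checks fix their seeds; the acceptance script derives
every simulation seed from its `--seed` argument. Probability vectors must
sum to 1 within $10^{-9}$; distances and times compare with a $10^{-9}$
guard; division-mode draws, copy-number draws and initial compositions use
index-based sampling so single-valued distributions behave identically to
multi-valued ones.

## Session info

```{r}
sessionInfo()
```
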