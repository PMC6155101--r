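---
title: "The joint-based descriptor: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The joint-based descriptor: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barreljoint)
```

## The model

A β-barrel with n strands is reduced to 2n **joint points**: the Cα
coordinates of the first and last residue of each strand, taken in chain
order (P~2i−1~ = first residue of S~i~, P~2i~ = last). The descriptor is
the series of signed torsion angles over every window of four consecutive
joints, 2n−3 angles in all. Windows starting at an odd joint span
Strand–Loop–Strand and are **β-type**; windows starting at an even joint
span Loop–Strand–Loop and are **γ-type**. The geometric reading:

* β~i~ ≈ 0°: strands S~i~ and S~i+1~ antiparallel; β~i~ ≈ ±180°: parallel.
* γ~i~ ≈ 0°: S~i~ and S~i+2~ on the same side of S~i+1~ (loops
  antiparallel); γ~i~ ≈ ±180°: opposite sides (loops parallel).
* A run of same-sign angles reports twist handedness; (+,+) dyads
  correspond to a right-handed twist.

Because only strand termini enter the construction, loop conformation,
strand register and side chains are invisible to the descriptor; that is
the point — it is a macroscopic summary, complementary to residue-level
φ/ψ analysis, cheap enough to compare hundreds of folds.

### Assumptions

One chain, one model per analysis; strand boundaries come from an
external assignment (SHEET records, STRIDE, a curated table, optionally
clipped to membrane-embedded ranges) and are never re-derived from
coordinates. At least two strands are required (a single β angle); γ
angles exist from n = 3.

## Sign and boundary conventions

The torsion is the standard right-handed convention (see
`?signed_dihedral`). Published projection drawings of "clockwise" angles
do not pin the viewing direction algebraically, so the convention here is
a documented choice, with `flip_sign = TRUE` available to negate an
entire descriptor if comparison against the opposite convention is ever
needed.

The angle domain is (−180, 180]; an exact −180 normalizes to +180.
Together with counting 0 as positive, this makes the sign classification
total — no angle is unclassifiable. Quadrant boundaries are pinned
left-closed: ^+^A = [0, 90), ^+^B = [90, 180], ^−^A = [−90, 0),
^−^B = (−180, −90); interval notation for these sectors is
open/closed-ambiguous in prose, so the package fixes one testable rule.
Histogram bins are left-closed over [−180, 180) with +180 counted in the
top bin; the default 10° width is the finest granularity at which
sub-ranges of the distributions are usually discussed, and any divisor of
360 is accepted.

Degeneracy: a window whose bond vectors contain a zero-length bond or an
exactly collinear triple (cross-product norm < 1e-9 after unit
normalization) has no defined torsion and raises a classed error naming
the angle, rather than returning a silent NaN.

## Reading structures

Residue identity is the pair (number, insertion code) and ordering always
follows file order — deposited numbering need not be monotone. Alternate
locations resolve to the highest-occupancy conformer, ties broken by
altloc identifier ascending (reproducible, and matching common practice).
Residues without a Cα are dropped with a warning at read time; whether a
missing strand *terminus* is an error is decided later, in
`build_annotation()`, where the default is a hard error because joints
define everything downstream. `trim = TRUE` instead shrinks the strand
inward to the nearest resolved residue and logs the adjustment.

Merging: SHEET records routinely split one physical strand at a β-bulge,
so SHEET input defaults to `merge_gap = 1` (fragments sharing a sheet
identifier and separated by at most one residue re-merge); STRIDE and
user tables default to `merge_gap = 0`, which disables merging entirely —
deliberately adjacent strands then keep their zero-residue loop rather
than collapsing, since empty loops are legal (joints still exist at the
termini). Overlapping ranges are always an error, not a merge.

When both a strand assignment and membrane-embedded (TM) ranges are
supplied, the precedence is: user segment table over STRIDE over SHEET
records — most curated wins — and TM ranges are applied afterwards as an
intersection that must hit exactly one strand each.

## The synthetic generator

`generate_barrel()` places strand k of n on a cylinder at azimuth
k·(360/n), with `strand_length` residues rising `rise` Å each (defaults
10 and 3.3 Å, ordinary β-strand dimensions), radius defaulting to
n·4.6/(2π) Å so neighbouring strands sit 4.6 Å apart, and the chain
alternating up/down for antiparallel topologies. Two deliberate
departures from the naive "vertical strands on a cylinder" picture:

* **Twist is strand shear.** The `twist` parameter advances each strand's
  top end azimuthally relative to its bottom end — the idealized
  counterpart of the strand tilt that a barrel's shear number sets. A
  per-strand-step azimuthal offset with vertical strands was tried first
  and rejected: that construction is achiral (reflection through the
  mid-plane maps it onto itself with relabelled directions), so its γ
  angles alternate in sign whatever the offset, and no parameter sign can
  encode handedness. With shear, the default +95° (≈ 38° tilt at the
  8-strand radius, close to observed strand tilts) puts every β and γ
  angle strictly inside (0°, 180°) for all n from 4 to 26; negative twist
  builds the exact mirror image (reflection through the xy-plane), so all
  angles negate elementwise.
* **Axial stagger.** Each strand starts 3 Å higher than its predecessor
  (an open-spiral rim). Without it, the 4-strand barrel at shear = 90°
  has joints vertically aligned with their neighbours and its γ angles
  pinned at exactly 0°/180° — a degenerate boundary where the mirror
  image no longer flips signs. The stagger breaks the alignment for
  every n while leaving the twist = 0 case exact: untwisted antiparallel
  barrels still have every β identically 0.

Optional jitter (uniform, ≤ 0.05 Å, seed-required) perturbs coordinates
for robustness checks; it is off by default so that limiting-case tests
are exact.

`generate_flat_sheet()` provides coplanar limiting cases. For a flat
antiparallel sheet the γ value depends on strand *placement*, not just
direction: strands laid out in chain order (`same_side = FALSE`) put
S~i+2~ on the opposite side of S~i+1~, giving γ = ±180° exactly, while
the default `same_side = TRUE` interleaves strand positions (spatial
order zigzags relative to chain order) so that S~i~ and S~i+2~ share a
side and every β and γ is exactly 0. Parallel sheets have every β exactly
+180° under either placement. Loops are straight-line interpolations in
all generators: loop geometry cannot affect the descriptor, so no realism
is attempted there.

### What the generator does and does not emulate

It reproduces the features the descriptor is sensitive to: strand count,
direction pattern, twist handedness and magnitude, closed and open
(staggered) rims, and flat-sheet limits. It does not model hydrogen-bond
registry, shear-number geometry, loop conformation, irregular strand
lengths or coordinate error beyond bounded jitter. Passing the property
suite therefore certifies the *descriptor machinery* — counting laws,
sign conventions, invariances, pattern bookkeeping — on known geometry;
it says nothing about how real barrels distribute their angles, which
must come from real coordinates through the readers.

## Reference censuses

`tm_structure_census()` and `cyto_structure_census()` carry the
strand-count composition of the published nonredundant transmembrane (29
structures) and cytoplasmic (51 structures) barrel cohorts, with the
angle tallies reported per group. They feed the counting identity
(n−1 β and n−2 γ angles per structure): every cytoplasmic row and the
cohort totals (312 β, 261 γ) check out exactly, as do all transmembrane
rows except the 8-strand group, whose reported 30/24 for 6 structures is
internally inconsistent with any per-structure count (the identity forces
42/36). The row is kept as reported and flagged `consistent = FALSE`; the
package never special-cases it.

## Validation set-up and problem sizes

The test suite builds all fixtures in code: handwritten PDB/STRIDE
snippets for reader edge cases, and synthetic barrels for geometry. The
torsion is checked against an independently written projection-based
oracle (project the outer bonds onto the plane normal to the central
bond, take the signed angle) on 10,000 random quadruples, with worked
planar and perpendicular cases asserted exactly. Property tests — rigid
motion invariance (tolerance 1e-9°), mirror antisymmetry, point-order
reversal, the 2n−3 count law, window-count conservation and
quadrant/histogram exhaustiveness — run across n ∈ {2, 4, 8, 12, 16, 22,
26}; handedness exclusivity across n ∈ {4, 8, 12, 16, 22}. These sizes
cover the strand-count range of known barrels while keeping the default
suite fast.

## Known limitations

* Strand boundaries are trusted as given; a mis-assigned terminus shifts
  one joint and perturbs up to four angles with no internal detection.
* The descriptor ignores strand register and length asymmetry: different
  structures can share a descriptor.
* mmCIF input is not parsed; convert to PDB first.
* Pattern statistics are raw counts; the package deliberately offers no
  significance tests on them.
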