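---
title: "Compiling glycan topologies for AlphaFold 3 and validating the results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling glycan topologies for AlphaFold 3 and validating the results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycobap)
```

## Scope and model

`glycobap` treats a glycan as a rooted tree: monosaccharide residues as
nodes, glycosidic linkages as edges directed donor → acceptor, the
reducing end as the root. This is the single authoritative
representation; the IUPAC-condensed text grammar, the AlphaFold 3 (AF3)
job emitter, the synthetic coordinate builder, and the stereochemistry
validator all consume or produce it. Cyclic glycans and repeating-unit
compression are out of scope: glycosaminoglycan chains are expanded to
explicit residues at whatever degree of polymerization the caller
requests.

Two registry facts drive everything downstream. First, the CCD code of a
residue is a function of (sugar, absolute configuration, ring form,
anomer); anomericity is encoded purely by choosing the right code (`MAN`
vs `BMA`), never by geometry. Second, each sugar class has a fixed
anomeric carbon and leaving atom — C1/O1 for aldoses (and, by analogous
convention, C1/O1 for the open-chain polyol ribitol), C2/O2 for the
ketosidic sialic acids — and only the aldose leaving atom is removed by
AF3 automatically. Ketose donors therefore always trigger generation of
an edited component (O2 and its hydroxyl hydrogen deleted, bonds pruned)
shipped under a deterministic derived code (`SIA` → `SIAX`, with `X2`,
`X3` suffixes on collision) in the `userCCD` field. Hydroxyl
modifications (sulfate, phosphate, acetyl, methyl) follow the same
principle: the sugar oxygen is retained as the bridge and the
modification component loses one terminal oxygen.

## Residue numbering

The numbering rule is breadth-first from the root, children visited in
ascending acceptor position. The rule is a design choice: it is the
unique simple convention that reproduces both published numberings we
could anchor to (terminal galactoses of the biantennary G2 at 8 and 9;
the α1,3-arm mannoses of M9 at 4, 6, 9). Branch order at equal depth is
fully determined, so the `ccdCodes` list and all `bondedAtomPairs`
indices are reproducible byte-for-byte. If a published template is ever
found to use a different branch order, the catalog entry — not the rule —
should carry an override.

## The text grammar

The condensed grammar is `[D-|L-] Sugar [p|f] [<pos><mod>]* [a|b]
[<d>-<a>]`, branches bracketed before their acceptor, root rightmost,
whitespace ignored. Canonical serialization continues the unbracketed
chain through the highest acceptor position (matching the way
biantennary structures are conventionally written) and emits remaining
branches in ascending-position brackets; the root's anomer is omitted
when it is the default β. `parse(write(g))` is the identity on all
supported graphs and is property-tested over random trees. Defaults
follow SNFG conventions: D configuration except Fuc and IdoA (L),
pyranose rings except where the registry says otherwise, β anomer when
unstated.

## Ring puckering

Forward analysis follows the Cremer–Pople construction: center the ring,
define the unique mean plane through the two in-plane Fourier sums,
project displacements *z*ⱼ, and read amplitudes from discrete Fourier
sums; for six-rings Q² = q₂² + q₃², cos θ = q₃/Q. The ring is ordered
oxygen first, then anomeric carbon, then ascending carbons — the
convention that puts the ⁴C₁ chair of D-pyranoses at θ = 0.

The inverse (used by `build_ring`) synthesizes *z*ⱼ from target (Q, θ,
φ) and places atoms on a circle of radius 1.45 Å (close to the mean
C–C/C–O ring bond geometry). Because the synthesized displacement has no
m = 1 Fourier component, the constructed ring's mean plane is exactly the
construction plane and the round trip is exact to machine precision; the
test suite drives it over a 5 × 7 × 12 grid of (Q, θ, φ) and requires
recovery within 1e−6 (φ is undefined at the poles, where only Q and θ are
checked).

Conformer labels are the nearest of the 38 canonical pyranose vertices
(2 chairs, 6 boats, 6 twist-boats, 12 envelopes, 12 half-chairs) by
angular distance on the (θ, φ) sphere, or nearest phase on the 20-member
furanose wheel. The vertex table is not typed in: each canonical label is
defined by its ideal out-of-plane pattern (e.g. ³,ᴼB: C3 and O5 up, the
other four down half as far) and its (θ, φ) vertex is obtained by
projecting that pattern through the forward transform. This keeps labels
and angles mutually consistent by construction and is cross-checked by a
geometric oracle that fits the four-atom reference plane and verifies
which atoms sit above it. Labels with angular margin under 10° to the
second-best vertex are flagged ambiguous — the literature draws no sharp
boundary between, say, a distorted boat and its neighbouring skew, so we
report the nearest vertex and the margin rather than pretending to a
crisper answer. Rings with Q below 0.1 Å are reported `planar`.

## Chirality and valence validation

Each checkable stereocenter (ring carbons bearing a heavy substituent,
plus the anomeric carbon) is judged by the sign of the determinant of
edge vectors to its heavy neighbours taken in canonical name order, with
3-neighbour centers using edges from the center and 4-neighbour centers
(the sialic anomeric carbon) the signed tetrahedron of the neighbours
themselves. The reference sign is computed on the registry's ideal build
of the *expected* residue, so the comparison is total and needs no CIP
priority rules. At anomeric centers the glycosidic oxygen fills the
leaving-hydroxyl slot; when a retained leaving oxygen is also present
(the pathological case the validator exists to catch) the glycosidic
oxygen is preferred, so the valence flag and the anomeric verdict stay
independent. Hydrogens are ignored throughout; side-chain stereocenters
(e.g. the glycerol arm of sialic acid) are not judged.

Bonds are inferred at covalent-radius sum + 0.4 Å over heavy atoms.
Valence flags cover oxygens with more than two heavy neighbours and
carbons bonded to three or more oxygens — the signature of a retained
leaving oxygen. A single retained oxygen at a crowded junction produces
several raw valence states (as at a sialyl junction, where both bridging
oxygens become overbonded); `check_valence` reports them all, while the
aggregated `stereo_report` folds oxygen flags adjacent to a flagged
carbon into the carbon-level finding so one injected defect yields one
finding.

## The synthetic builder, and what it does not emulate

`build_residue` constructs ideal residues: ring at the requested pucker
(default ⁴C₁ at Q = 0.57 Å, a typical pyranose amplitude), substituents
in tetrahedral exocyclic slots chosen axial or equatorial per the
registry pattern, side chains extended with clash-aware candidate
selection, L sugars as mirror builds. Bond lengths are 1.43 Å C–O,
1.45 Å C–N, 1.53 Å C–C. `build_glycan_coords` places each donor by
aligning its anomeric-carbon → leaving-oxygen direction onto the
extension of the acceptor's C–O bond, drops the leaving oxygen, and spins
the donor about the new bond in 15° steps until all inter-residue
contacts clear 1.95 Å (above every bond-inference limit); distances below
1.0 Å after all retries are an error. Glycosidic torsions are therefore
an emergent result of clash avoidance, deterministic but with no claim of
energetic realism.

Corruption rebuilds the model from its recorded topology with exactly
one defect: an epimer flip rigidly rotates the whole substituent subtree
into the opposite slot (then spins it for clearance); an anomer flip
swaps the anomeric slot, which re-orients the donor ring about the
glycosidic bond; a retained leaving oxygen is re-attached in the
direction of maximum clearance from the junction carbon; a ring flatten
sets Q = 0. The acceptance surface verifies that over every registry
sugar × anomer × defect class the validator reports exactly the injected
defect and nothing on clean fixtures.

What passing these tests shows: the detectors are complete and precise
on geometry whose ground truth is known by construction. What they do
not show: performance on real predicted structures, which add thermal
noise, non-ideal bond lengths, alternative chair populations, and
occasionally missing atoms. The sign-based chirality test is robust to
substantial distortion (it only crosses zero when a substituent passes
through the ring plane), but the pucker labels on real models should be
read together with their ambiguity margins.

## Superposition

`kabsch` is the closed-form SVD solution with the determinant correction
that forbids reflections. `align_refine` mirrors refined-alignment
behaviour: after each fit, pairs with residuals above 2.0 standard
deviations are discarded and the rest re-fit, for up to 5 cycles —
defaults chosen to approximate the commonly used structure-alignment
tools, and `cycles = 0` is exactly the plain fit. Because reference
structures and predictions number residues differently, cross-structure
comparison requires an explicit residue map; the shipped benchmark
manifests record our reconstruction of each published comparison
(reference entry, residue selection, heavy-atom filter) and both raw and
refined values are always reported, since published figures rarely state
which was printed. The test suite checks the closed form against an
independent sampled-rotation brute force (global random sweep plus
shrinking local perturbations, evaluated through the trace identity), at
50 random 10-point instances.

## Problem sizes and determinism

The test suite and the acceptance script regenerate all fixtures in
code; nothing binary ships with the package. Default problem sizes — a
420-point pucker grid, the full registry sweep (~150 corrupt-and-detect
cases), 50 superposition instances at 10 points each, and templates up
to the 24-entity Siglec-2 pair — were chosen so the whole suite exercises
every code path at desk scale. All randomness flows through the caller's
seed (`set.seed` in tests, `--seed` in the acceptance script); the
builders themselves are fully deterministic, so emitted JSON and fixture
files are byte-stable across runs.

## Known limitations

- The monosaccharide registry covers the common mammalian sugars plus
  the uronic acids, sialic family, galactofuranose, and ribitol; rare
  sugars (heptoses, Kdo, pseudaminic acids) need registry entries before
  they can be compiled.
- CCD codes for a handful of less common entries follow our curation of
  the public dictionary and are trivially correctable strings if a
  deposition disagrees.
- Lipid building blocks use simplified heavy-atom definitions with
  documented atom names; real CCD files load through the same reader and
  are drop-in compatible, but bonds written against the simplified names
  must be revised if a template is switched to full definitions.
- The GPI and matriglycan-adjacent assemblies encode one plausible
  covalent wiring; where the literature leaves a linkage undetermined
  the template metadata says so rather than silently committing.
- The validator maps model residues to the expected topology by entity
  id and residue index; models whose numbering departs from the
  canonical order must be re-indexed first.
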