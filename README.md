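# glycobap

Glycan topology compiler and stereochemistry validator for AlphaFold 3
covalent-ligand input.

## The problem

Glycans are branched polymers of monosaccharides joined through the
anomeric carbon (C1 of aldoses, C2 of ketoses such as sialic acid) to a
hydroxyl of the next residue. A single sugar ring packs several kinds of
stereochemical information — absolute configuration (D/L), ring form
(pyranose/furanose/open-chain), anomeric configuration (α/β), and the
axial/equatorial pattern that distinguishes epimers such as glucose and
galactose — and generative structure predictors frequently scramble it:
epimers get flipped, α becomes β, rings collapse into high-energy
conformers, and none of this is reflected in the model's confidence
scores.

The reliable way to feed glycans to AlphaFold 3 (AF3) is to specify each
monosaccharide by its Chemical Component Dictionary (CCD) code — which
encodes the anomer exactly (e.g. `MAN` = α-D-mannopyranose, `BMA` =
β-D-mannopyranose) — and to declare every glycosidic bond explicitly with
the `bondedAtomPairs` (BAP) field of the input JSON, pairing the acceptor
hydroxyl oxygen with the donor anomeric carbon. One chemical subtlety
makes this error-prone by hand: AF3 drops the donor's leaving hydroxyl
(O1) automatically for aldoses, but **not** the O2 of sialic acids, which
must be deleted manually from the component definition and supplied as a
`userCCD` block — otherwise the junction carbon ends up bonded to three
oxygens. The same applies to sulfate/phosphate/acetyl/methyl decorations
and to acyl bonds between lipid building blocks.

`glycobap` is for structural glycobiologists who want to

1. **compile** a glycan topology (IUPAC-condensed text or a programmatic
   graph) into a complete, validated AF3 input JSON — CCD codes in
   canonical residue order, every covalent bond emitted, every required
   leaving-atom edit applied automatically;
2. **validate** a predicted structure against the intended topology:
   anomeric configuration and epimeric orientation via signed chirality
   volumes compared against ideal reference builds, valence sanity
   (retained leaving oxygens), glycosidic torsions, and ring puckering via
   Cremer–Pople parameters;
3. **compare** a model with a reference structure by closed-form
   least-squares superposition (Kabsch) with optional iterative outlier
   rejection.

A synthetic coordinate builder generates ideal rings at any prescribed
pucker, full monosaccharides from the registry's substitution patterns,
assembled glycans, and deliberately corrupted variants (epimer flip,
anomer flip, retained leaving oxygen, flattened ring) — so every detector
is exercised against fixtures whose ground truth is known by
construction.

## The methods in brief

**Residue numbering.** Residues are numbered breadth-first from the
reducing end, visiting branches in ascending acceptor position (O2 < O3 <
O4 < O6). This reproduces the conventional published numbering of the
common N-glycans (biantennary G2: terminal galactoses at 8 and 9;
high-mannose M9: the α1,3-arm mannoses at 4, 6, 9), and the `ccdCodes`
list order equals this numbering, so `bondedAtomPairs` indices are
self-consistent.

**Ring puckering.** For an N-ring with centered positions and mean-plane
displacements *z*ⱼ, the Cremer–Pople amplitudes are the discrete Fourier
sums q_m·cos φ_m = √(2/N) Σ z_j·cos(2πm(j−1)/N) (and the sine
counterpart), with Q² = Σ z_j² and, for pyranoses, cos θ = q₃/Q. With
rings ordered (O5, C1, …, C5) the ⁴C₁ chair of D-pyranoses sits at θ = 0,
¹C₄ at θ = 180°, and the boat/twist-boat equator at θ = 90° (e.g. ³,ᴼB at
φ = 0). Conformers are labelled by the nearest of the 38 canonical
pyranose vertices (or the 20-member furanose pseudorotation wheel), each
vertex derived from its ideal displacement pattern rather than a typed-in
table.

**Chirality checks.** Each stereocenter's handedness is the sign of the
determinant of the edge vectors to its heavy-atom neighbours in canonical
name order, compared against the same sign on the registry's ideal build
of the expected residue — total, fast, and exactly testable, with no CIP
priority machinery. The glycosidic oxygen stands in for the leaving
hydroxyl at anomeric centers.

## Worked example

Compile the disialylated biantennary N-glycan G2S2 and inspect the job:

```r
library(glycobap)

g <- parse_iupac_condensed(
  "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6[Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3]Manb1-4GlcNAcb1-4GlcNAc")
g
#> <glycan_graph> 11 residues, 10 linkages
#>    1 GlcNAc-b (pyranose)
#>    2 GlcNAc-b (pyranose)
#>    3 Man-b (pyranose)
#>    ...
#>    8 Gal-b (pyranose)
#>    9 Gal-b (pyranose)
#>   10 Neu5Ac-a (pyranose)
#>   11 Neu5Ac-a (pyranose)

job <- add_glycan(af3_job("g2s2-free"), "NG", g)
job
#> <af3_job> 'g2s2-free': 1 entities, 10 bonded pairs, 1 userCCD block
#>   NG: ligand [NAG,NAG,BMA,MAN,MAN,NAG,NAG,GAL,GAL,SIAX,SIAX]
write_af3_json(job, "g2s2.json")
```

The two sialic acids are donors, so they are emitted under the edited
code `SIAX` whose definition (O2 and its hydroxyl hydrogen removed) rides
along in the `userCCD` field; everything else uses stock CCD codes. The
second bonded pair in the emitted JSON is the chitobiose→mannose junction
`[["NG", 2, "O4"], ["NG", 3, "C1"]]`.

Validate a (synthetically corrupted) model against the same topology:

```r
m   <- build_glycan_coords(g)
bad <- corrupt(m, list(residue = 8, class = "epimer-flip", center = "C4"))
check_stereocenters(bad, g)
#> <stereo_report> entity NG: 11 residues, 1 finding
#>    ...
#>    8 Gal     anomeric=ok epimer![C4] pucker=4C1
#>    ...
```

Residue 8 is the galactose whose C4 hydroxyl was flipped equatorial —
i.e. mis-modeled as glucose — and it is the only finding.

A thin command-line wrapper covers the same workflows
(`exec/glycobap build|validate|compare|templates|synth`), with exit codes
0 (clean), 1 (findings), 2 (usage/parse error).

## Template catalog

`template_catalog()` lists assembled, validated jobs for the common
N-glycans (M9, A1, G2, G2F, G2S2), O-GalNAc cores 1–4 and extensions
(disialyl core 1, keratan-sulfate core 2), the 2-O-phosphorylated
xylose GAG linkers, core M3 with ribitol phosphate, glycosphingolipids
(ganglioside GP1c, Lewis-b lactoside, Globo H with its bacterial lectin),
a dolichol-PP analog carrying chitobiose, a GPI anchor assembled from
CCD building blocks, and a fully N-glycosylated Siglec-2 pair (eleven
G2S2 glycans per chain). Protein sequences in the templates are
deterministic synthetic stand-ins shipped under `inst/extdata/` with
their attachment sites; real UniProt sequences are drop-in replacements.

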