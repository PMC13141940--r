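---
title: "Methods: oligomer assembly, interface and SEC-SAXS analysis in mvatkit"
author: "mvatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oligomer assembly, interface and SEC-SAXS analysis in mvatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The scientific setting

MvaT proteins, the *Pseudomonas* members of the H-NS family of
nucleoid-associated proteins, silence horizontally acquired DNA by
oligomerizing into filaments along it. The N-terminal oligomerization
domain carries two interfaces: a **terminal dimerization site** (TDS,
residues ~1–31) forming head-to-head antiparallel coiled-coil contacts
between monomers whose helix bends near residue 27, and a **central
dimerization site** (CDS, residues ~32–58) forming the second contact.
Alternating use of the two sites yields a filament of dimers. Crystal
structures capture the two sites in different constructs — a TDS-intact
truncation (a bent two-helix monomer; four TDS dimers among eight chains
per asymmetric unit) and an oligomerization-deficient R8A variant (one
elongated helix, CDS dimer) — and a composite model of the native domain
must be spliced from both. In solution, SEC-SAXS reports on the average
conformation of the dimer, which is more extended than the bent crystal
form.

`mvatkit` implements the computations this program needs as a single
tested package. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic test system does
and does not establish.

# Structure handling

Atomic models are flat atom tables (chain, author residue number,
insertion code, residue name, atom name, element, coordinates, occupancy,
B-factor) wrapped in an S4 `StructureModel` with validity checks (finite
coordinates, occupancy in [0,1], unique atom names per residue). Parsing
goes through `bio3d`; the package keeps **polymer protein atoms only**
(waters, other heteroatoms and hydrogens are dropped — the crystal
structures contain no hydrogens, and every cutoff in the package is
heavy-atom based).

Policy decisions, applied identically to PDB and mmCIF input:

* **Altlocs**: keep altloc "A" when present, otherwise the highest
  occupancy, ties resolved to the first record in the file. Deterministic
  and in line with common practice.
* **Numbering**: author (auth_) chain ids and residue numbers verbatim;
  all residue ranges are inclusive. Published residue lists use author
  numbering, so mmCIF label_ identifiers are not used.
* **Insertion codes**: carried through, with a warning when seen (none
  are expected in the structures this package targets).
* **Multi-model files**: first model only.
* Writing emits wwPDB v3.3 ATOM records; >62 chains or residue numbers
  outside [-999, 9999] are refused rather than silently mangled
  (hybrid-36 extensions are deliberately not implemented).

# Rigid-body superposition

`kabschFit()` is the SVD Kabsch algorithm with determinant sign
correction, so the optimum is always a **proper** rotation — fitting a
structure to its mirror image yields det(R) = +1 and a non-zero RMSD
rather than a chemically meaningless reflection. Degeneracy (collinear or
coincident points; fewer than three pairs) is detected from the
covariance singular values (second singular value < 1e-10 x largest) and
reported as a conditioning error. The test suite verifies optimality
against an independently implemented quaternion (Horn) oracle to 1e-9 on
a thousand random instances and against a brute-force rotation grid.

`chainPairRMSD()` pairs Cα atoms between chains by the intersection of
author residue numbers — the literal reading of "common Cα atomic pairs"
— and reports the post-superposition (minimized) RMSD, the convention of
the standard visualization tools.

# Model assembly

`spliceChimera()` builds a composite monomer: the N-donor chain is
superposed onto the C-donor chain via Cα of a `fitRange` shared by both
(default 32–49, the CDS helix), then residues `nRange` (default 2–32) of
the transformed N donor are concatenated with residues `cRange` (default
33–58) of the C donor. The ranges must be disjoint and contiguous.
**Junction geometry is diagnosed, not regularized**: the C(i)–N(i+1)
distance across the splice is reported and flagged outside [1.0, 2.0] Å.
A force-field minimization could close the junction properly but would
drag a molecular-dynamics engine into the package for a cosmetic change
that none of the downstream analyses depend on.

`buildCentralDimer()` performs no fitting at all: because both chimeras
keep their C-donor coordinates fixed, the dimer geometry is inherited
from the C-donor crystal frame. Passing the same chimera twice is an
error (it could only produce a fully clashed object).

`propagateFilament()` grows the oligomer. At each junction the crystal
terminal-dimer template (an anchor chain and its partner) is superposed
onto the current growing-end chain via Cα of `fitRange` (default 2–27,
the TDS helix); the mapped partner position defines the docking frame;
and a copy of the dimer is superposed onto it with its corresponding
chain. The growing end then alternates to the copy's other chain — each
monomer has one TDS — and template pairs cycle through `templatePairs`,
mirroring the use of both terminal dimers of the crystal. Chains are
renamed sequentially (A, B, C, …) with a provenance map. Per junction the
report carries both fit RMSDs and the count of heavy-atom pairs closer
than 2.4 Å between adjacent dimers (a conservative van-der-Waals overlap
criterion). Overlapping atoms are never discarded; clashes are reported
instead, which keeps the operation invertible and auditable. The number
of dimers is an explicit parameter (`nDimers`), since both tetrameric
(2-dimer) and four-dimer (8-chain) oligomer models are of interest.

# Interface characterization

`computeSASA()` is Shrake–Rupley with a **golden-section spiral lattice**
(default 960 points per atom): a deterministic point set, so two runs are
bit-identical and testable, unlike random sphere sampling. Probe radius
defaults to 1.4 Å (water). Van der Waals radii are a Bondi-type element
table shipped in code (`vdwRadii()`): H 1.20, C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80, Se 1.90 Å. Accuracy: an isolated atom reproduces the
analytic sphere to better than 1 %, a fused pair the analytic two-sphere
value to better than 2 %.

`interfaceArea()` is the PISA-style buried area
`(SASA(A) + SASA(B) − SASA(AB))/2`, computed in the one- and two-chain
contexts. When a residue range is given (the TDS analysis uses 2–37),
the per-atom areas are summed over that range only, while the SASA itself
is always evaluated in full context; both the restricted and full-chain
areas are reported because published interface figures are ambiguous
about which convention a range annotation refers to. PISA's solvation
free energy ΔG is not reproduced — its energy model is not public — only
the geometric area.

Salt bridges: basic side-chain nitrogens (Arg NE/NH1/NH2, Lys NZ,
optionally His ND1/NE2) within `cutoff` of acidic side-chain oxygens
(Asp OD1/OD2, Glu OE1/OE2), inter-chain only, one record per residue pair
at the minimum N–O distance. The default cutoff is 4.0 Å, the common
convention; the detection is exactly monotone in the cutoff, so
reproducing a published pair list admits a principled scan over a
plausible window (3.5–4.5 Å). Hydrophobic contacts: side-chain carbons of
Ala, Val, Leu, Ile, Met, Phe, Trp, Pro within 4.5 Å across chains, **plus
the Cα of glycine** — Gly has no side chain, and without the Cα rule a
glycine in a published hydrophobic-core list could never be detected.

# SEC-SAXS analysis

A `FrameSeries` holds an elution series on a shared q grid.
`subtractBackground()` averages the buffer frames (the images collected
before the sample fraction), averages the sample frames (the peak
window), subtracts, and propagates uncertainties in quadrature through
both averages. The operation is linear and exact; the frame windows are
parameters because published descriptions give window sizes, not
absolute indices.

`debyeProfile()` evaluates the Debye double sum with q-independent
per-atom weights: electron counts (default), solvent-corrected excess
electrons (electron count minus 0.334 e/Å³ times an average atomic group
volume), or unit weights for bead bodies. `q = 0` is evaluated by the
sinc limit, so `I(0) = (Σf)²` exactly. For more than ~2x10⁵ atom pairs
the pair distances are histogram-binned at 0.02 Å with weight-averaged
bin distances — deterministic, with phase error below `q·0.02` (well
under 1 % over the small-angle range); the exact pair list is used for
smaller problems and the two paths agree to ~0.1 %.

`guinierFit()` regresses ln I on q² (weighted by `(I/σ)²` when
uncertainties exist) over the largest contiguous low-q window satisfying
`q·Rg ≤ qRgMax`, iterated to self-consistency (tolerance 1e-6, max 50
iterations); `Rg = sqrt(−3·slope)`, `I(0) = exp(intercept)`. The default
bound 1.3 is the conventional validity limit for globular particles.

Two systematic effects are worth recording:

* **Window bias.** For a solid uniform sphere the next term of
  `ln I = −q²Rg²/3 − 0.00286 (qR)⁴ + …` is negative, so a fit out to
  `q·Rg = 1.3` *overestimates* Rg by ~1.8 % (1.0 % at a 1.0 bound,
  0.8 % at 0.9). Consistency tests between the Debye curve and the
  coordinate Rg therefore use a 0.9 window — they probe the q→0 limit,
  not a practical data-analysis window — while the data-analysis default
  stays 1.3.
* **Hydration.** Coordinate-based Rg and Debye curves describe the bare
  atoms; experimental SAXS sees a hydration shell that typically adds a
  few percent to Rg. The package deliberately has no hydration-layer
  model, so theoretical-vs-experimental comparisons carry that known
  systematic gap and `fitTheoretical()` (scale + constant offset, reduced
  χ²) reports the residual structure rather than hiding it.

`normalizedKratky()` returns `(qRg, (qRg)²·I/I(0))`: globular particles
peak at `(√3, 3/e ≈ 1.104)`; extended or flexible chains rise
monotonically to a plateau beyond `qRg ≈ 4` (the package's tests use the
Gaussian-chain Debye function, whose plateau is 2, as the canonical
extended reference).

# Conservation mapping

Alignments load via Biostrings (aligned FASTA or Clustal; conservation
lines ignored). `mapReference()` counts ungapped reference positions from
1 and maps them to alignment columns; correspondence between homologs is
by **alignment column**, not by position number — the convention used in
published alignment figures. Conservation calls are `identical`,
`similar` (same side-chain class), `gap`, or `different`; "similar" has
no canonical definition, so the grouping is a parameter with the
documented default {ILVMA} {FWY} {KRH} {DE} {STNQ} {GP} {C}. Homolog
sequences are user input; the package ships only a tiny fictional
demonstration alignment (`inst/extdata/synthetic_mvat_alignment.fasta`).

# The synthetic study system

The generators produce the features the pipeline needs with known ground
truth, under fixed seeds (R's default Mersenne–Twister, seed recorded):

* `makeHelix()` — ideal α-helical Cα trace (textbook parameters: 1.5 Å
  rise, 100° twist, 2.3 Å Cα radius, all configurable) with pseudo
  backbone N/C/O positions interpolated along the trace, and an optional
  axis bend at a chosen residue, emulating the bent two-helix TDS fold
  versus the elongated variant. The backbone is idealized: C–N junction
  surrogates run ~1.9 Å, side chains are absent (explicit Arg/Glu or Leu
  side-chain atoms for contact tests come from `makeSaltBridgePair()` /
  `makeHydrophobicPair()` at exact geometry).
* `makeAntiparallelDimer()` — chain B is chain A rotated 180° about an
  axis perpendicular to the helix axis and offset, giving controlled
  centroid distance and antiparallel direction vectors.
* `makeBeadSphere()` (uniform rejection sampling) and
  `makeLatticeSphere()` (deterministic cubic lattice) — bodies with
  analytic `Rg = sqrt(3/5)·R` and the analytic sphere form factor. The
  Monte-Carlo body carries ~1/√n sampling noise that becomes dominant
  near the form-factor minimum (the relative error against
  φ(qR=4) ≈ 0.0076 fluctuates by several percent at n = 5000), so
  Debye-vs-analytic validation uses the lattice body and compares the
  coherent pair part (the self-scattering diagonal has no continuum
  counterpart); the Monte-Carlo body is validated on its own ground
  truths (containment, Rg, reproducibility).
* `simulateSECSeries()` — frames `buffer + gaussian(i)·particle + noise`,
  by default 303 frames with the peak at frame 139 and width 4, so that
  frames 1–15 precede the sample fraction and 134–144 span the peak,
  emulating a synchrotron SEC-SAXS acquisition; the amplitude trace is
  retained as ground truth.
* `perturbModel()` — rigid transform plus i.i.d. per-axis Gaussian noise.
  For per-axis σ the expected minimized RMSD against the clean model is
  `σ·sqrt(3)` (each displacement has `E|δ|² = 3σ²`), the value the
  recovery tests assert within ±20 %.

What passing these tests shows — and does not. They establish algorithmic
correctness against closed forms and independent oracles. They do not
exercise real-data pathologies: crystallographic disorder beyond simple
altlocs, missing residues and chain breaks, non-ideal backbone geometry,
inter-particle interference or radiation damage in scattering data, or
hydration effects. The accession-based checks in
`tests/testthat/test-acceptance.R` cover the real-data end once the
deposited files are fetched.

# Problem sizes and runtime

Routine tests run on helices of 10–58 residues, spheres of 150–5000
beads (lattice body: 4169 points at 1 Å spacing), 303-frame SEC series
on ~60-point q grids, and 1000 random superposition instances; the whole
suite completes in well under a minute on one CPU, and
`scripts/acceptance.R` in a few seconds. These sizes were chosen as the
smallest at which the statistical checks have stable expectations (e.g.
n ≥ 100 atoms for the perturbation-RMSD band, n ≈ 4000 lattice points
for sub-percent form-factor agreement).

# Known limitations

* No energy minimization, side-chain repacking or loop rebuilding; splice
  junctions and filament clashes are reported, not repaired.
* No hydration shell in theoretical scattering; no absolute-scale
  calibration; no p(r) inversion, ab initio shapes or molecular-weight
  estimation.
* No symmetry expansion from crystallographic operators; the asymmetric
  unit as deposited is the working object.
* Interface energetics (ΔG, complex significance) are out of scope; only
  geometric quantities are computed.
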