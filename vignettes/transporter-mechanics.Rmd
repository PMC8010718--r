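---
title: "Methods: GNM hinges, gating metrics and trimer geometry in gatemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GNM hinges, gating metrics and trimer geometry in gatemech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatemech)
```

This vignette is the package's account of its methods: the models and their
assumptions, the parameters that matter, what the synthetic-data generators
do and do not emulate, and the numerical and design choices made where the
design was genuinely open.

## The Gaussian network model

The GNM reduces a protein to a network of nodes — one per residue, at the
Cα — connected by identical harmonic springs whenever two nodes lie within
a cutoff distance $r_c$. The network topology is encoded in the Kirchhoff
(connectivity Laplacian) matrix $\Gamma$: $\Gamma_{ij} = -1$ for a contact,
$0$ otherwise, and the node degree on the diagonal. For a connected network
of $N$ nodes the spectrum of $\Gamma$ contains one zero eigenvalue and
$N-1$ normal modes; equilibrium cross-correlations between residue
fluctuations are

$$\langle \Delta R_i \cdot \Delta R_j \rangle
  = \frac{3 k_B T}{\gamma} \left[\Gamma^{-1}\right]_{ij},$$

where $\Gamma^{-1}$ is the Moore–Penrose pseudo-inverse taken over the
nonzero modes and $\gamma$ the uniform spring constant. The model's
assumptions are the usual ones: isotropic Gaussian fluctuations about a
single energy minimum, a uniform spring constant, and dynamics determined
entirely by contact topology. These buy robustness — the slow modes depend
only on the fold, not on a force field — at the cost of atomic detail and
of any information about the direction of motion.

**Global hinges.** The slowest modes of a two-domain fold move the domains
in counterphase; the residues where the slow eigenvectors $u_1, u_2$ change
sign (or nearly vanish) are the fulcrum of that motion. `findHinges` flags
a residue when (a) it sits at a sign crossover between consecutive sequence
neighbours of $u_k$, or (b) $|u_k(i)| < \texttt{zeroBand} \cdot \max_i
|u_k(i)|$. Both rules are reported with per-mode provenance.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `rc` | 7.3 | Å | midpoint of the 7.0–7.5 Å range standard for folded proteins; the contact test is strictly `< rc`, so fixtures with designed distances are unambiguous |
| `zeroTol` | 1e-8 × λmax | – | relative spectral tolerance for calling an eigenvalue zero; the zero-mode count must equal the connected-component count, which is verified |
| `zeroBand` | 0.1 × max\|u\| | – | hinge near-zero band; no canonical value exists, so it is relative to the mode's own amplitude and configurable |
| `scale` | 1 | 3k_BT/γ | reporting in reduced units; supply a physical prefactor to get Å² |

Two design questions were genuinely open. First, whether a hinge must
appear in *both* $u_1$ and $u_2$ or in *either*: both behaviours are
exposed (`combine = "union"` / `"intersection"`); the default is the
union, because the two slowest modes of a multi-domain membrane protein
often partition different interfaces and demanding intersection silently
drops real hinges. Second, eigenvector sign is arbitrary in any
eigensolver; it is fixed by making the first nonzero element positive, so
mode shapes are reproducible across platforms.

## Gating and rotamer metrics

**COM distances.** The gate observable is the distance between
mass-weighted centres of two residue atom sets. The default atom scope is
the heavy sidechain atoms (CB inclusive), because gating interactions of
aromatic pairs are carried by the sidechains; whole-residue heavy-atom
scope is available since published analyses do not always state which was
used. Distances are computed without periodic wrapping — inputs are assumed
whole-molecule — and a guard warns when any distance exceeds 100 Å, the
signature of a wrapping artifact.

**χ1 rotamers.** χ1 is the signed N–CA–CB–Gγ dihedral (IUPAC convention,
degrees in (−180, 180]); the γ atom comes from a built-in per-residue-type
table. Classification into rotamer states uses circular intervals
evaluated modulo 360; the defaults are the two states of the gating
phenylalanine, IF-like 170 ± 15° and OF-like 60 ± 20°. Intervals must be
circularly disjoint, and occupancies over states plus "unassigned" sum
to 1. Because each default interval spans ±1 sd of its own sampling
distribution, roughly 32 % of frames drawn from a state fall outside its
interval; the *ratio* of assigned occupancies is the consistent estimator
of the mixing weight, and that is what the recovery tests assert.

**Pooling.** Multi-run histograms share fixed-width bins (default 0.25 Å;
published gate-distance histograms do not state a bin width) computed over
the pooled range; pooled counts are the bin-wise sum over runs, so pooling
is exactly the histogram of the concatenation and is permutation-invariant.
"Cumulative" histograms in the literature are ambiguous between pooled
counts and a CDF; both are provided (`histogramTable(cumulative = TRUE)`),
with pooled counts the default reading.

**Gate closure.** `gateClosureTime` returns the first time the distance
stays below a threshold for `dwellFrames` consecutive frames (default 5,
suppressing single-frame crossings). No numerical closure criterion is
canonical, so the threshold is a required argument rather than a default.

**RMSD and plateaus.** RMSD uses least-squares rigid-body superposition by
default, so only internal deformation is scored. `plateauCheck` slides a
window (default 20 frames) and reports the earliest window whose
least-squares slope magnitude is below `slopeTol` (default 0.01 Å/ns) —
the standard "has it equilibrated" diagnostic.

## Trimer geometry filtering

Candidate trimers are ranked by docking-cluster size (largest first; ties
broken by cluster id so the order is deterministic) and filtered by three
criteria:

1. **Pseudo-C3 symmetry.** The symmetry axis is the normal of the plane
   through the three monomer centroids, oriented along the membrane
   normal. The score is the mean coordinate RMSD between monomer $i$
   rotated +120° about that axis and monomer $i+1$, with no further
   fitting; zero for exact symmetry. The closed-form axis was chosen over
   nonlinear axis optimisation because it is deterministic and exact for
   near-C3 inputs; it degrades for badly broken symmetry, which is a
   documented limitation (such models fail the score bound anyway).
   The pass bound defaults to 5 Å and is configuration, not physics: no
   canonical value exists for "pseudo-symmetric".
2. **Termini exposure.** Both termini of every monomer must lie on the
   intracellular side beyond the membrane slab. Terminal positions are
   centroids of the first/last 3 residues — single-atom termini are
   noise-sensitive.
3. **Trp anchoring.** Tryptophans anchor membrane proteins at the
   headgroup interfaces; the score is the fraction of Trp sidechain
   centroids within bands (default width 6 Å) centred at ±half-thickness
   along the normal, passing at ≥ 0.5. A trimer with no Trp reports
   not-applicable rather than failing.

The membrane is an implicit slab: normal +z, midplane 0, half-thickness
15 Å, intracellular side −z by default — none of these has a canonical
value, so all are configurable and logged in the run manifest. A criterion
that errors on a model (e.g. collinear centroids) marks the model failed
with the error message as the recorded reason, rather than aborting the
batch.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* of the quantities the
pipeline measures, not the physics that produces them:

- `makeDumbbell` builds two compact random Cα clusters (default 20
  residues each, 6 Å packing radius) joined by a 6-residue near-linear
  linker. Connectivity at the default cutoff is verified by construction,
  and the designed hinge location is returned as ground truth. Defaults
  were chosen once to give a clean two-domain spectrum at a desk-scale
  size (~46 nodes).
- `makeGateTrajectory` draws per-frame gate distances from two normal
  distributions (closed 5.0 ± 0.5 Å, open 9.0 ± 0.5 Å — the separation
  scale of aromatic gate pairs) with a deterministic state switch;
  defaults emulate a 200 ns run (400 × 0.5 ns) closing at 60 ns, the
  reported timescale of extracellular gate closure after substrate
  binding.
- `makeRotamerTrajectory` places a CG atom by explicit rotation about the
  CA–CB axis, sampling χ1 from a wrapped-normal mixture (defaults: the two
  gating-rotamer states above). Wrapped-normal sampling is adequate for
  the narrow states involved (sd ≤ 30°). Bond lengths and angles are
  idealised; only the dihedral carries signal.
- `makeC3Trimer` and `makeMembraneMonomer` build exact C3 trimers from a
  membrane-spanning hairpin monomer, optionally perturbed by per-coordinate
  Gaussian noise applied to all three rotated copies.

They do **not** emulate force-field dynamics, correlated frame-to-frame
motion, membrane/lipid interactions, or sequence realism. Passing tests
therefore demonstrate that the *measurements* are correct and robust —
dihedrals exact to numerical precision, hinge detection reliable on
designed two-domain topologies, occupancy estimation consistent at known
mixing weights — not that any particular biological system behaves this
way. Conclusions about a real transporter still require real structures
and trajectories.

## Numerical choices and problem sizes

- Eigendecomposition uses the symmetric dense solver; spectra are
  reconstructed and residual-checked in tests (relative Frobenius 1e−8).
- The pseudo-inverse is formed spectrally from nonzero modes and
  cross-checked against an independent dense pseudo-inverse on graphs of
  up to 50 nodes, and against an independent elastic-network
  implementation (eigenvalues equal; fluctuations proportional, the
  constant being its physical 3k_BT/γ prefactor at T = 300 K).
- Altloc resolution keeps the highest-occupancy copy (tie: first
  encountered); element masses come from a built-in table and unknown
  elements are an error, never a silent default.
- Test and acceptance problem sizes — ≤ 50-node networks, 100 dumbbells,
  1000 single-frame dihedral fixtures, 2000-frame rotamer trajectories,
  20-seed perturbation sweeps — were chosen as the smallest sizes at which
  the asserted statistical properties are stable; the full suite runs in
  well under a minute.

## Known limitations

- The GNM is isotropic: it gives fluctuation magnitudes and hinge
  locations, not directions (no anisotropic 3N×3N variant is provided).
- Hinge detection on a disconnected network is refused unless forced,
  because eigenvector sign structure across components is meaningless.
- The symmetry-axis construction assumes near-C3 input; for grossly
  asymmetric trimers the score is large but not a meaningful metric.
- PDB parsing targets well-formed ATOM/HETATM/MODEL records; mmCIF and
  binary trajectory formats are out of scope.
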