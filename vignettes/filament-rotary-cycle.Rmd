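---
title: "Methods: targeted MD and dihedral-rotation analysis of filament conformational cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted MD and dihedral-rotation analysis of filament conformational cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

RecA-family recombinases (bacterial RecA, archaeal RadA, eukaryotic Rad51)
assemble on DNA as helical nucleoprotein filaments. The same protein is
observed crystallographically in strikingly different filament forms —
right-handed helices, left-handed helices and closed rings — and the
transitions between them have been proposed to act as a rotary motor
coupled to ATP turnover, with a short linker region (residues I71–K88 in
*Sulfolobus solfataricus* RadA) serving as the mechanical joint. Two
questions follow naturally:

1. Can a biased simulation drive a filament model through the full
   four-state cycle (left-handed → ring-like → intermediate →
   right-handed → left-handed) and back to its starting conformation?
2. Which linker residues actually *rotate* — complete full turns of their
   backbone dihedrals — during the cycle, and which stay fixed and act as
   the axis?

`radmotor` implements the two methods these questions need — targeted
molecular dynamics (TMD) and the cumulative changed dihedral angle (CCDA)
statistic — at desk scale: a coarse-grained elastic-network filament model
that runs in seconds rather than the weeks an all-atom solvated system
would take, with synthetic generators that provide exact ground truth for
every claim the analysis makes.

## The TMD restraint

TMD biases an otherwise ordinary simulation with a harmonic penalty on the
best-fit RMSD to a target structure:

$$U_\mathrm{TMD} = \frac{K}{2N}\,\bigl(\mathrm{RMSD}(t) -
\mathrm{RMSD}_0(t)\bigr)^2$$

where $K$ is the force constant (default 200 kcal mol⁻¹ Å⁻²), $N$ the
number of restrained atoms, $\mathrm{RMSD}(t)$ the best-fit RMSD of the
instantaneous structure to the target over the restrained selection, and
$\mathrm{RMSD}_0(t)$ a prescribed value that decreases over the run,
dragging the system onto the target. Points worth spelling out:

* **Prefactor convention.** The prefactor is $K/(2N)$ — the per-atom
  normalized convention used by the major MD engines' TMD modules — so
  that $K$ keeps units of kcal mol⁻¹ Å⁻² regardless of system size. With
  $K = 200$, $N = 100$ and a 1 Å offset the energy is exactly
  1.0 kcal/mol; the test suite asserts this closed form.
* **Best-fit RMSD.** RMSD is evaluated after optimal rigid superposition
  (closed-form SVD/Kabsch solution with determinant correction, so
  reflections are never returned). The restraint therefore exerts no net
  force or torque on the system.
* **Gradient.** Because the optimal rotation and translation are
  stationary points of the deviation, the gradient of the fitted RMSD with
  respect to mobile atom $i$ reduces to $(x_i - y'_i)/(N\,\mathrm{RMSD})$,
  with $y'$ the target superposed onto the mobile structure. At
  RMSD $= 0$ the gradient is defined as the zero vector — the physically
  sensible convention at the non-differentiable point, where the restraint
  force vanishes anyway once the schedule has reached zero. Forces are
  validated against central finite differences (20 random systems,
  1 × 10⁻⁵ relative tolerance).
* **Selection.** The default restrained selection is Cα only; the engine
  is Cα-resolution, and restraining all backbone beads only dilutes the
  per-atom force (which scales as $K/N^2$ for a collective offset).
* **Schedule.** $\mathrm{RMSD}_0(t)$ decreases linearly from the current
  fitted RMSD to zero — the standard continuously-decreasing prescription —
  reaching zero at a settable fraction of each leg (`settle_frac`,
  default 0.7). The remaining 30 % of the leg anneals the structure in the
  target basin with $\mathrm{RMSD}_0 = 0$; without this tail the system
  always lags the schedule and ends each leg short of its target.

## The coarse-grained engine

The force field under the restraint is an elastic-network model: harmonic
springs between all bead pairs within a 10 Å cutoff, rest lengths taken
from a reference conformation, default spring constant 1 kcal mol⁻¹ Å⁻²
(`build_elastic_network`). Dynamics is Langevin — velocity Verlet with the
BAOAB splitting — at 10 fs steps, friction 1 ps⁻¹, 310 K, uniform 110 Da
beads. Runs are exactly reproducible for a fixed seed.

**Morphing network for the cycle.** A single-basin network anchored at the
starting state cannot accommodate a four-state tour, so `run_cycle`
morphs the rest lengths toward each leg's target. A first design —
linear interpolation of the pair-distance sets — fails in an instructive
way: pair distances are blind to handedness, and on legs that invert the
filament's twist the system condenses into the *mirror image* of the
target, from which the collective restraint force (per-atom stiffness
$K/N^2$) cannot rescue it. The engine therefore interpolates *structures*,
not distances: the target is superposed onto the current conformation and
the rest lengths follow the pair distances of the straight Cartesian path
between the two. Along that path the handedness flip happens near the
achiral midpoint, where the mirror barrier vanishes and the restraint can
steer the branch choice. With this network the four-leg toy cycle closes
to within 0.5 Å of its starting state; `network_mode = "static"` retains
the single-basin behaviour for comparison.

For the cycle driver the spring constant default is 3 kcal mol⁻¹ Å⁻²
(three times the module default): the morphing path removes the penalty a
stiffer network used to impose on chirality-inverting legs, and the extra
stiffness halves the thermal RMSD floor at 310 K, which is what limits how
tightly the cycle can close.

**Energy bookkeeping.** The reported potential is the network energy
zero-referenced to the initial state, so the profile starts at exactly 0
kcal/mol, and each leg is summarized by its start/end potentials and
barrier height (maximum minus leg start). At toy scale the four steering
barriers are of comparable height — the coarse-grained landscape has no
reason to reproduce the strongly asymmetric two-barrier profile of the
all-atom system, and absolute energies here are not comparable to all-atom
values in any way.

## CCDA: counting full dihedral rotations

The backbone dihedrals are phi (C′–N–Cα–C′) and psi (N–Cα–C′–N),
reported in degrees in (−180°, 180°] under the IUPAC sign convention. For
each residue and angle the per-frame series is **unwound**: successive
differences are mapped into (−180°, 180°] and cumulatively summed,
producing a continuous angle from which the net winding number —
the signed count of completed 360° turns — is read off. The CCDA is

$$\mathrm{CCDA} = 360° \times \left|\,\mathrm{round}\!\left(
\frac{u_\mathrm{last} - u_\mathrm{first}}{360°}\right)\right|$$

i.e. the magnitude of the net winding, in degrees. Two deliberate
interpretive choices:

* **Net winding, not accumulated path length.** Summing absolute per-frame
  changes would count thermal jitter and would not be quantized; the net
  winding is an integer number of turns by construction, which is exactly
  the 0/360/720 pattern such tables display. A half-turn excursion that
  comes back reports 0.
* **Exact-zero classification.** A residue is *zero-rotary* when both its
  phi and psi CCDA are exactly zero, and *rotary* otherwise. Because
  winding numbers are integers, no degree tolerance is involved. Under
  this rule every residue with any nonzero entry is rotary — including
  residues that carry a single full turn on only one of the two angles.
  For the reference linker table shipped with the package that yields 13
  rotary and 5 zero-rotary residues out of 18; published discussions of
  the same pattern sometimes highlight only the 11 residues with
  variations on the dominant angle, leaving two single-entry residues
  (73 and 85) unlisted either way. The package states its rule and applies
  it uniformly rather than guessing at an unstated distinction.
* **Undefined termini.** Phi of the first and psi of the last residue do
  not exist; they are reported as explicit `NA`, never zero-filled, and
  `classify_rotary` refuses to classify them unless asked to skip.

Unwinding is valid when true per-frame steps stay below 180°; the
trajectory output stride must honour this, and the programmed generator
refuses infeasible programs.

## Synthetic ground truth

Two generators make every claim testable without any external data:

* `make_filament` places Cα beads on a parametric helix (radius, rise,
  twist; the twist sign sets the handedness) and can attach ideal N and C′
  atoms in the local helix frame. Mirroring the twist produces an exact
  mirror image — same internal distances, superposable only onto the
  reflected copy — which is the property the mirror-trap analysis above
  relies on. `make_state_quartet` builds the four cycle states from one
  base spec and verifies they are pairwise distinct (fitted RMSD > 1 Å).
* `build_backbone` grows an N–Cα–C′ chain from internal coordinates
  (natural-extension-reference-frame construction; bond lengths N–Cα
  1.46 Å, Cα–C′ 1.52 Å, C′–N 1.33 Å, angles 111°/117.2°/121.7°, trans
  omega — conventional idealized peptide geometry), so phi/psi can be set
  exactly. `make_rotation_trajectory` advances programmed dihedrals
  linearly to an integer number of full turns across the frames, with
  Gaussian jitter applied *in dihedral space* — so the ground-truth
  winding of every series is exact regardless of noise (up to ~20° sd),
  and CCDA recovery can be asserted as an identity, not an approximation.

What the generators deliberately do not emulate: real RadA geometry,
protomer–protomer interfaces, nucleotide or DNA binding, side chains,
solvent, or an all-atom force field. Passing tests therefore demonstrate
that the *methods* — superposition, restraint forces, unwinding, winding
recovery, classification — are correct, and that the engine can steer a
filament-like object through a closed four-state tour; they say nothing
about the energetics of the real protein.

## Problem sizes and numerical settings

The standard study conditions used by the tests, the analysis scripts and
the acceptance script: 20-residue filaments (60 backbone beads), four legs
of 6000 steps at 10 fs (240 ps of coarse-grained time in total), frames
recorded every 20 steps, temperature 310 K, $K = 200$ kcal mol⁻¹ Å⁻²,
cutoff 10 Å, cycle spring constant 3 kcal mol⁻¹ Å⁻², `settle_frac` 0.7.
CCDA validation uses 10–20-residue backbones, 144–160-frame trajectories,
windings up to ±3 and noise up to 20°. These sizes were chosen so the full
cycle plus analysis completes in well under a minute while keeping every
qualitative feature of the method visible; they are stated here once and
used everywhere.

Other numerical conventions: coordinates in Å, times in ns (steps in fs),
1-based residue numbering matching PDB convention; PDB output at 3
decimals, so file round trips preserve coordinates to 10⁻³ Å; superposition
rejects collinear point sets (second singular value below 10⁻⁸ of the
first); ties in the global-barrier flag go to the earliest leg; the
sequence-identity scoring (match +1, mismatch 0, linear gap −1, identity =
matches / alignment length) is deliberately transparent rather than tuned —
alignment-dependent identities between non-identical sequences depend on
the aligner's conventions, and only the identical-sequence case (100 %) is
treated as a fixed point.

## Known limitations

* The elastic network is chirality-blind; the Cartesian-morph path
  resolves this for steering, but barrier *heights* along
  chirality-inverting legs are artifacts of the morph path, not estimates
  of physical barriers.
* CCDA, as a net-winding statistic, cannot distinguish a residue that
  rotates once and back (reported 0) from one that never moves; that is a
  property of the statistic, shared with the quantized tables it mirrors.
* The restraint's collective force shrinks as $K/N^2$ with system size at
  fixed offset; for much larger filaments K would need rescaling.
* Langevin dynamics at 310 K leaves a thermal RMSD floor of a few tenths
  of an Å on the toy system; closure much below that would require cooling
  or frame averaging, which the package does not do.
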