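---
title: "The phfold model: pH-dependent coarse-grained peptide folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phfold model: pH-dependent coarse-grained peptide folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fast peptide structure predictors are trained on, and tuned for, structures
solved near neutral pH.  Poly-charged peptides such as (K)15 or (E)15 are a
well-known failure mode: their conformational preference flips with pH as
side chains titrate, which a pH-blind predictor cannot express.  `phfold`
implements a coarse-grained peptide model in which the electrostatic part of
the energy responds explicitly to pH and ionic strength, together with the
machinery needed to turn that energy into predicted conformational
ensembles: a simulated-annealing Monte Carlo sampler over backbone
dihedrals, RMSD clustering with energy-ranked representative selection, and
a rule-based secondary-structure analyzer.

## Representation

Each residue contributes five backbone particles (N, H, CA, C, O) and, for
all amino acids except glycine, one side-chain bead placed at a
residue-specific distance from CA along the pseudo-C-beta direction with
L-chirality.  Conformations are generated from backbone dihedrals
(phi, psi) with fixed internal coordinates (N-CA 1.46 Å, CA-C 1.52 Å,
C-N 1.33 Å, C=O 1.23 Å, N-H 1.00 Å, standard sp² angles, omega fixed at
180°).  Working in dihedral space keeps the sampler's state small and makes
every proposed conformation geometrically valid by construction.  All
distances are in Å and all energies in kcal/mol; the dielectric slope
s = 0.6 below is "per Å", which is why the Å convention is fixed
throughout.

## The energy model

The total energy is a sum of four pH-independent terms and one
pH-dependent term:

E = E_local + E_nonbonded + E_Hbond,pair + E_Hbond,coop + E_DH

**Local term.**  Each phi and psi angle feels a flat-bottomed quadratic
well: zero inside a residue-type-specific interval, and
eps_phi · (angular distance to the nearest bound)² outside, with the
distance taken on the circle (shorter arc).  The default stiffness is
eps_phi = 0.005 kcal/mol/deg², and the default wells
(phi in [-160°, -45°], psi in [-75°, 160°], wider for glycine, narrower
for proline) are broad enough to contain both the helical and the extended
basins — the local term excludes implausible backbone geometry rather than
choosing secondary structure, which is left to the hydrogen-bond terms.
Terminal phi(1) and psi(L) are not measurable from coordinates and carry no
local energy.

**Non-bonded term.**  Particle pairs separated by more than two covalent
bonds interact through a Mie potential (generalized Lennard-Jones),

E(r) = eps · [ m/(n−m) (r0/r)ⁿ − n/(n−m) (r0/r)ᵐ ],

with depth −eps at r0 and zero crossing at gR0 = (m/n)^(1/(n−m)) r0.  The
exponents default to (n, m) = (12, 6) for every pair and can be overridden
per pair type in the parameter file.  Pair parameters come from a
combination rule (r0 = sum of the two particle radii, eps geometric mean)
over per-kind backbone radii and per-residue side-chain bead radii, all
tabulated in one YAML document shipped with the package.  1-2 and 1-3 pairs
are excluded; 1-4 pairs interact at full weight.

**Hydrogen bonds.**  Backbone H...O=C bonds use a 12-10 radial term
mu(r) = depth · (5 (sigma/r)¹² − 6 (sigma/r)¹⁰) with its minimum −depth at
sigma = 1.8 Å, times an angular factor nu(alpha) = cos²(alpha) for
donor-H-acceptor angles above 90° and zero otherwise.  The cos² form keeps
mu·nu ≤ 0 at the radial minimum for any admissible geometry (a plain
cos alpha would flip the sign of favourable bonds) while agreeing with the
boundary behaviour at 90° and 180°.  Pairs of residues closer than four
positions in sequence are not considered.  Helical bonds — acceptor O(i)
with donor H(i+4) — carry the weight eps_alpha_hb (2.5 kcal/mol by
default); all other admissible pairs carry eps_beta_hb (2.0).  A bond is
*recorded* when mu·nu ≤ −0.25·depth; recording feeds the cooperative term
and the secondary-structure analyzer, giving both a crisp, testable
criterion.

A four-body cooperative term rewards pairs of recorded bonds that form
regular patterns: (i→j) with (i+1→j+1) (consecutive helical bonds, weight
eps_alpha_coop = −1.5) and (i→j) with (i+2→j−2) or (i+2→j+2) (antiparallel
or parallel sheet ladders, weight eps_beta_coop = −1.0), each scaled by a
Gaussian factor exp(−(r_ij−sigma)²/2)·exp(−(r_kl−sigma)²/2) with unit
width in Å.

**Electrostatics.**  Charged particles interact through a screened
Debye-Hückel term

E_DH = C_elec · q_i q_j · exp(−r_sh / l_DH) / (eps(r) · r_sh),

with C_elec = 332.06 kcal·Å/(mol·e²), the Debye length
l_DH = 3.04/√I Å at 298 K (capped at 10⁴ Å below I = 10⁻⁷ mol/L, so the
no-salt limit is effectively unscreened at peptide scales), and a sigmoidal
distance-dependent dielectric

eps(r) = Dw − (Dw − Dp)(s²r²/2 + s r + 1) e^(−s r),

which rises from the protein-interior value Dp = 2 at contact to the
bulk-water value Dw = 78 at large separation (slope s = 0.6 per Å).

Because a side-chain bead is much larger than the point charge it carries,
the raw DH curve and the Mie curve of a bead pair are on incompatible
distance scales.  The model reconciles them by a per-pair distance shift:
the crossing distance is where the pair's repulsive Mie branch reaches
+k (k = 4 kcal/mol), and the shift is fitted (bisection to 10⁻⁶ Å) so that
the shifted DH magnitude equals k at that same distance, with the
dielectric always evaluated at the unshifted distance.  The magnitude
|q_i q_j| is used during fitting so attractive pairs receive the same
geometric shift; the sign is restored when the energy is evaluated.  Below
the crossing the DH magnitude is truncated (clamped) at k — the Mie core,
not the electrostatics, should govern close contact.  An alternative
reading of the truncation (zeroing below the crossing) is available as a
config switch (`dh$truncation`), with clamping the default because zeroing
would remove all electrostatic repulsion exactly where like charges
overlap.  Shifts depend only on (pair type, pH, ionic strength) and are
cached per charge state; pairs with |q_i q_j| < 10⁻⁸ e² are left unshifted
and untruncated since their energy is negligible on the kcal/mol scale.

Each DH pair term is weighted by sequence separation: 10 for residues
fewer than 7 apart, 2 otherwise.  The sum runs over charged particle pairs
with particle index j > i + 1 and residue separation of at least 1 (the
particle-index reading of the j > i + 1 rule, combined with a residue
separation floor, excludes intra-residue pairs).  Side-chain beads carrying
|q| ≥ 0.5 interact with each other through the repulsive Mie branch only
(the attractive well is clamped to zero), since the tabulated side-chain
attraction already contains the average electrostatic attraction the DH
term now supplies explicitly.

**Charges.**  Titratable side chains (D, E, H, K, R, pKa 3.9, 4.2, 6.0,
10.5, 12.5) and the free termini (N-terminal ammonium 9.0 on the first
backbone N, C-terminal carboxyl 2.0 on the last backbone C) receive
fractional Henderson-Hasselbalch charges: acids
q = −1/(1 + 10^(pKa−pH)), bases q = +1/(1 + 10^(pH−pKa)).  Fractional
charges make titration curves smooth and testable and reduce to the binary
picture three pH units from the pKa.  Acetyl / N-methyl caps are modelled
as charge suppression only — they do not add particles, because in this
model the caps influence nothing but the electrostic term.  The standard
pKa values are used irrespective of sequence context or conformation;
conformation-dependent pKa shifts are a known limitation of this class of
model and are out of scope here.

## Sampling, model selection, analysis

The prediction protocol generates 200 models by default; each model is an
independent simulated-annealing run of 5,000 Metropolis steps over a
geometric ladder of 8 reduced temperatures from 2.0 down to 0.3, starting
from the fully extended chain.  Moves are 80% single-residue (phi, psi)
Gaussian perturbations (sd = 15°) and 20% pivots (a uniform redraw of one
dihedral; with the chain rebuilt from dihedrals this rotates the whole
downstream segment).  Energies are divided by the reduced temperature
directly; no physical kB mapping is claimed.  Runs are bit-reproducible
for a fixed seed.

Models are clustered by greedy leader clustering on backbone (N, CA, C, O)
RMSD after optimal superposition, visiting models in ascending energy
order with a 2.5 Å cutoff (both configurable; the clustering algorithm
itself is a package choice since only "the five best clusters" is
prescribed by the protocol).  The representatives are the lowest-energy
members of the five lowest-energy clusters; if fewer than five clusters
exist, the remaining slots are filled with the next-lowest-energy models.
The DH-enabled protocol ranks by the total including E_DH; disabling DH
(the pH-blind variant) both removes the term and ranks by the remaining
energy, and is bit-identical to running with all charges zeroed.

Secondary structure is assigned per residue by explicit rules on dihedrals
and recorded H-bonds (helix: dihedrals within 30° of (−57°, −47°) inside a
run of at least 3 consecutive helical bonds; extended: beta-region
dihedrals plus a cross-strand bond; turn: interior of a short chain
reversal bridged by an (i, i+3) or (i, i+4) CA contact under 7 Å without
helix dihedrals; else coil).  All thresholds are constants in one table, so
content comparisons are reproducible without external binaries.  Contents
are pooled over the five representatives.  Coarser than a full
assignment program: "turn" here is a single T class, and strand/bridge
distinctions collapse into E.

## Fixtures and what the tests show

The package ships a sequence registry (the six poly-charged homopolymers
with their experimental capping flags, and the benchmark peptide sequences
keyed by PDB id) plus three built geometries: an ideal helix, an ideal
extended chain, and a 14-mer beta2-like hairpin (two extended strands
around a tight reversal, carrying two cross-strand H-bonds but not a full
ladder).  These are generated by code, not stored.

The test suite verifies the energy terms against independent brute-force
evaluations, the geometry against a third-party torsion implementation,
RMSD against a closed-form quaternion superposition, the DH calibration
against dense grid scans, and the sampler against a closed-form two-state
Boltzmann ratio.  The pH-switch checks run the full protocol at reduced
size (50 models of 5,000 steps; the full protocol's 200 models behave the
same way, and the reduced size keeps a complete run in seconds on one
core): protonated (K)15 at pH 3.6 and deprotonated (E)15 at pH 12 both
give pure coil ensembles, and forcing unit charges never increases helix
content relative to a zero-charge run at matched seeds.

What passing these tests does *not* show: that the sampler reaches the
helical ground state of a neutral chain within the default 5,000-step
annealing.  It does not — nucleating an i,i+4 bond network from an
extended start with single-dihedral moves takes roughly an order of
magnitude more steps (helices begin to appear around 50,000+ steps per
model), whereas the charge-dominated coil ensembles are reached robustly
at the default length.  The energy model itself ranks an ideal helix far
below an extended chain for a neutral peptide (about −54 vs +9 kcal/mol
for (A)15 with the default parameters), so this is a sampling-length
trade-off, not a defect of the potential.  Predictions that hinge on
*forming* rich secondary structure should raise `n_steps`; predictions
about charge-driven unfolding — the pH-switch behaviour this model exists
for — do not need to.

## Numerical choices and degenerate inputs

* Dihedrals live on (−180°, 180]; all interval distances use the shorter
  arc, and the well penalty is continuous (C¹ except exactly at the
  bounds, where the flat bottom meets the parabola).
* The shift fit brackets the root on (rs → 0⁺, +100 Å] and bisects to
  10⁻⁶ Å; the Mie crossing is likewise bisected on (0, gR0).  A pair whose
  unshifted DH already passes through k at the crossing gets shift ≈ 0.
* Zero-step sampler runs return the extended start unchanged; an ensemble
  with fewer clusters than requested representatives pads with
  next-lowest-energy models; glycine contributes no side-chain bead and
  proline's backbone NH is present but never donates an H-bond.
* The C++ kernel (chain building, energy, annealing) and the pure-R
  reference implementations are written independently and agree to
  10⁻⁸ kcal/mol on random conformations; the sampler uses R's RNG, so
  `set.seed()` gives bit-identical ensembles.

## Parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| eps_phi | 0.005 | kcal/mol/deg² | dihedral well stiffness |
| (n, m) | (12, 6) | — | Mie exponents (per-pair overridable) |
| sigma | 1.8 | Å | H-bond radial minimum |
| eps_alpha_hb / eps_beta_hb | 2.5 / 2.0 | kcal/mol | pairwise H-bond weights |
| eps_alpha_coop / eps_beta_coop | −1.5 / −1.0 | kcal/mol | cooperative weights |
| Dw, Dp, s | 78, 2, 0.6 | —, —, /Å | sigmoidal dielectric |
| k | 4 | kcal/mol | DH/Mie crossing energy |
| w_near / w_far (cutoff) | 10 / 2 (7) | — | DH sequence-separation weights |
| pKa (D, E, H, K, R) | 3.9, 4.2, 6.0, 10.5, 12.5 | — | side-chain titration |
| pKa (N-term, C-term) | 9.0, 2.0 | — | terminal titration |
| n_models / n_steps | 200 / 5000 | — | protocol size |
| temperatures | 2.0 → 0.3 (8, geometric) | reduced | annealing ladder |
| rmsd_cutoff | 2.5 | Å | leader clustering |

All of these live in `inst/extdata/forcefield_defaults.yaml` and can be
overridden via `load_forcefield()`.

## Known limitations

* Fixed, context-free pKa values; no conformation-dependent titration.
* The side-chain bead table (distances, radii, well depths) is a generic
  documented default, not a fitted interaction matrix; quantitative
  energies should be read comparatively, not absolutely.
* Default-length annealing undersamples helix formation (see above).
* The secondary-structure rules are deliberately coarse (H/E/T/C).
* No disulfides, cis-proline, D-amino acids, or explicit ions.
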