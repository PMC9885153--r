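# Default force-field parameter tables for the phfold coarse-grained model.
# Distances in Angstrom, energies in kcal/mol, angles in degrees.
# Any entry can be overridden via load_forcefield(path, overrides = ...).

geometry:
  bond_n_ca: 1.46
  bond_ca_c: 1.52
  bond_c_n: 1.33
  bond_c_o: 1.23
  bond_n_h: 1.00
  angle_n_ca_c: 111.0
  angle_ca_c_n: 116.6
  angle_c_n_ca: 121.9
  angle_ca_c_o: 120.5
  angle_n_ca_sc: 110.5
  improper_sc: -122.6     # dihedral(C, N, CA, SC), L-chirality
  omega: 180.0

local:
  eps_phi: 0.005         # kcal/mol/deg^2, same stiffness for phi and psi wells
  default: {phi_low: -160.0, phi_high: -45.0, psi_low: -75.0, psi_high: 160.0}
  G: {phi_low: -179.0, phi_high: 179.0, psi_low: -179.0, psi_high: 179.0}
  P: {phi_low: -90.0, phi_high: -50.0, psi_low: -60.0, psi_high: 160.0}

mie:
  "n": 12
  "m": 6
  backbone:              # per backbone particle kind: vdW radius, well depth
    "N":  {radius: 1.60, eps: 0.20}
    H:  {radius: 1.00, eps: 0.10}
    CA: {radius: 1.80, eps: 0.20}
    C:  {radius: 1.70, eps: 0.20}
    O:  {radius: 1.50, eps: 0.20}
  # optional per-pair overrides; each entry:
  # {type_i: "SC_K", type_j: "SC_E", eps: 0.3, r0: 5.6, n: 12, m: 6}
  pair_overrides: []

hbond:
  sigma: 1.8             # 0.18 nm, position of the radial minimum
  depth: 1.0             # epsilon of the 12-10 radial term
  eps_alpha_hb: 2.5      # weight of helical O(i)...H(i+4) bonds
  eps_beta_hb: 2.0       # weight of all other bonds (separation >= 4)
  eps_alpha_coop: -1.5   # cooperative reward, consecutive helical bonds
  eps_beta_coop: -1.0    # cooperative reward, sheet-ladder patterns
  min_separation: 4
  record_threshold: 0.25 # |mu*nu| >= threshold*depth records an H-bond

dh:
  dw: 78.0               # bulk water dielectric
  dp: 2.0                # protein-interior dielectric
  s: 0.6                 # sigmoidal slope, per Angstrom
  coulomb: 332.06        # kcal*A/(mol*e^2)
  k_cross: 4.0           # Mie/DH calibration energy, kcal/mol
  w_near: 10.0           # weight, residue separation < separation_cutoff
  w_far: 2.0
  separation_cutoff: 7
  truncation: clamp      # clamp | none : behaviour below the crossing distance
  charge_threshold: 0.5  # |q| above which a side chain counts as charged

pka:
  side_chain: {D: 3.9, E: 4.2, H: 6.0, K: 10.5, R: 12.5}
  n_terminus: 9.0
  c_terminus: 2.0

# Per-residue side-chain bead: CA->bead distance, bead vdW radius, well depth.
# Glycine has no bead.  hb_donor false excludes the backbone NH as a donor.
residues:
  A: {sc_distance: 1.5, sc_radius: 2.3, sc_eps: 0.20, hb_donor: true}
  R: {sc_distance: 3.6, sc_radius: 3.2, sc_eps: 0.20, hb_donor: true}
  "N": {sc_distance: 2.0, sc_radius: 2.7, sc_eps: 0.20, hb_donor: true}
  D: {sc_distance: 2.0, sc_radius: 2.6, sc_eps: 0.20, hb_donor: true}
  C: {sc_distance: 1.8, sc_radius: 2.5, sc_eps: 0.25, hb_donor: true}
  Q: {sc_distance: 2.4, sc_radius: 2.9, sc_eps: 0.20, hb_donor: true}
  E: {sc_distance: 2.5, sc_radius: 2.8, sc_eps: 0.20, hb_donor: true}
  G: {sc_distance: 0.0, sc_radius: 0.0, sc_eps: 0.00, hb_donor: true}
  H: {sc_distance: 2.4, sc_radius: 3.0, sc_eps: 0.25, hb_donor: true}
  I: {sc_distance: 1.9, sc_radius: 3.1, sc_eps: 0.35, hb_donor: true}
  L: {sc_distance: 2.1, sc_radius: 3.1, sc_eps: 0.35, hb_donor: true}
  K: {sc_distance: 2.9, sc_radius: 3.0, sc_eps: 0.20, hb_donor: true}
  M: {sc_distance: 2.3, sc_radius: 3.1, sc_eps: 0.30, hb_donor: true}
  F: {sc_distance: 2.6, sc_radius: 3.2, sc_eps: 0.35, hb_donor: true}
  P: {sc_distance: 1.5, sc_radius: 2.7, sc_eps: 0.20, hb_donor: false}
  S: {sc_distance: 1.5, sc_radius: 2.4, sc_eps: 0.20, hb_donor: true}
  T: {sc_distance: 1.6, sc_radius: 2.6, sc_eps: 0.20, hb_donor: true}
  W: {sc_distance: 3.6, sc_radius: 3.4, sc_eps: 0.35, hb_donor: true}
  V: {sc_distance: 1.7, sc_radius: 2.9, sc_eps: 0.30, hb_donor: true}
  "Y": {sc_distance: 2.9, sc_radius: 3.3, sc_eps: 0.30, hb_donor: true}
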