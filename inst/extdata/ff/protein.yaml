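# Protein (united-residue) force-field table.
# Energies kcal/mol, lengths Angstrom, angles degrees, dipoles e*Angstrom,
# masses amu. All weights default to 1 (the published optimized weights are
# not printed in the source literature); the temperature multipliers applied
# to each term are fixed by the energy expression, not by this file.
# Side-chain Gay-Berne well depths follow a hydrophobicity ordering and are
# calibration-pending defaults; sigma values are rounded side-chain
# centroid diameters.
model: protein
T0: 300.0
cap: 1.0e4
weights:
  SCSC: 1.0
  SCp: 1.0
  el: 1.0
  tor: 1.0
  tord: 1.0
  "b": 1.0
  rot: 1.0
  corr3: 1.0
  turn3: 1.0
  turn4: 1.0
  bond: 1.0
bonded:
  k_bond: 50.0          # backbone virtual-bond stretch, kcal/mol/A^2
  k_branch: 10.0        # side-chain virtual-bond stretch
  k_theta: 5.0          # virtual-bond-angle bending, kcal/mol/rad^2
  theta0_deg: 110.0
  torsion:              # U_tor(gamma) = sum_k a_k cos(k gamma) + b_k sin(k gamma)
    default:
      "a": [0.6, 0.3, 0.15, 0.0, 0.0, 0.0]
      "b": [0.0, 0.0, 0.0, 0.0, 0.0, 0.0]
  tord:                 # sum_k A_k cos(k g1)cos(k g2) + B_k sin(k g1)sin(k g2)
    "a": [0.2, 0.05]
    "b": [0.2, 0.05]
  rot:
    k_alpha: 2.0        # kcal/mol/rad^2 about alpha0
    alpha0_deg: 50.0
    beta_cos: [0.3, 0.1]
    beta_sin: [0.0, 0.0]
gay_berne:              # side chain - side chain; pairwise eps0 = sqrt(ei ej),
  chi: 0.3              # sigma0 = (si + sj)/2; glycine is isotropic
  chip: 0.2
  eps:
    "G": 0.30
    "A": 0.38
    "S": 0.30
    "C": 0.45
    "T": 0.33
    "V": 0.51
    "P": 0.35
    "I": 0.60
    "L": 0.57
    "N": 0.28
    "D": 0.25
    "M": 0.52
    "E": 0.25
    "Q": 0.28
    "K": 0.26
    "R": 0.27
    "H": 0.35
    "F": 0.60
    "Y": 0.45
    "W": 0.55
  sigma:
    "G": 3.0
    "A": 3.4
    "S": 3.6
    "C": 3.9
    "T": 4.0
    "V": 4.2
    "P": 4.0
    "I": 4.5
    "L": 4.5
    "N": 4.1
    "D": 4.1
    "M": 4.6
    "E": 4.4
    "Q": 4.4
    "K": 4.6
    "R": 4.8
    "H": 4.4
    "F": 4.7
    "Y": 4.8
    "W": 5.0
excluded:               # side chain - peptide group excluded volume (12-6)
  eps: 0.2
  sigma: 4.0
dipole:
  r_core: 3.0           # softening core of the point-dipole kernel, A
  eps_r: 4.0
  ev_eps: 0.3            # peptide-group excluded-volume core
  ev_sigma: 3.8
  sites:                # united peptide group: ~3.7 D mostly perpendicular
    "p": {mu_par: 0.20, mu_perp: 0.72}
correlation:
  corr3: 0.10           # coupling of nonlocal dipole pairs to torsional states
  turn3: 1.0            # adjacent peptide-group dipole pairs
  turn4: 0.20
masses:
  anchor: 56.0          # Calpha + backbone share of the residue
  branch:
    "G": 1.0
    "A": 15.0
    "S": 31.0
    "C": 47.0
    "T": 45.0
    "V": 43.0
    "P": 41.0
    "I": 57.0
    "L": 57.0
    "N": 58.0
    "D": 59.0
    "M": 75.0
    "E": 73.0
    "Q": 72.0
    "K": 72.0
    "R": 100.0
    "H": 81.0
    "F": 91.0
    "Y": 107.0
    "W": 130.0
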