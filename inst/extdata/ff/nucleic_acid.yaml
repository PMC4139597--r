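# Nucleic-acid (two-site-per-nucleotide) force-field table.
# The base-base Gay-Berne weight is 0.5 and all other weights 2.0, the
# combination that places the duplex melting transition near physiological
# temperature. Base dipoles (e*A; 1 e*A = 4.803 D): purines carry a
# dominant component parallel to the sugar->base rotation axis, pyrimidines
# a dominant perpendicular component - the asymmetry that makes the
# mean-field base-base energy favour perpendicular base axes (Watson-Crick
# like geometry). Backbone equilibria correspond to an ideal right-handed
# duplex trace (radius 7 A, twist 36 deg, rise 3.4 A).
model: nucleic_acid
T0: 300.0
cap: 1.0e4
weights:
  BB_GB: 0.5
  BB_el: 2.0
  PP: 2.0
  PB: 2.0
  bond: 2.0
  "b": 2.0
  tor: 2.0
  rot: 2.0
bonded:
  k_bond: 20.0
  k_branch: 10.0
  k_theta: 3.0
  theta0_deg: 151.9
  torsion:              # single-harmonic Fourier with minimum at -22.7 deg
    default:
      "a": [-1.384, 0.0, 0.0, 0.0, 0.0, 0.0]
      "b": [0.579, 0.0, 0.0, 0.0, 0.0, 0.0]
  rot:
    k_alpha: 1.0
    alpha0_deg: 160.0
    beta_cos: [0.0, 0.0]
    beta_sin: [0.0, 0.0]
gay_berne:
  chi: 0.4
  chip: 0.3
  eps:
    "A": 0.35
    "G": 0.40
    "C": 0.30
    "T": 0.30
    "U": 0.30
  sigma:
    "A": 3.5
    "G": 3.5
    "C": 3.3
    "T": 3.3
    "U": 3.3
excluded:               # phosphate - base excluded volume (12-6)
  eps: 0.3
  sigma: 4.5
debye_huckel:
  charge: -1.0          # phosphate charge, e
  eps_r: 80.0
  ionic_strength: 0.1   # mol/L, sets the screening constant at 300 K
dipole:
  r_core: 2.0           # softening core of the point-dipole kernel, A
  eps_r: 1.5
  sites:
    "A": {mu_par: 0.52, mu_perp: 0.10}
    "G": {mu_par: 1.35, mu_perp: 0.25}
    "C": {mu_par: 0.25, mu_perp: 1.33}
    "T": {mu_par: 0.15, mu_perp: 0.85}
    "U": {mu_par: 0.15, mu_perp: 0.87}
masses:
  anchor: 196.0         # deoxyribose + phosphate lump
  branch:
    "A": 134.0
    "G": 150.0
    "C": 110.0
    "T": 125.0
    "U": 111.0
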