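# Polysaccharide (one-site-per-ring) force-field table for 1,4-linked
# alpha/beta-D-glucose chains. The ring interaction site sits midway between
# consecutive glycosidic oxygens; its dipole rotates about the O...O
# virtual-bond axis. Correlation terms reuse the peptide-chain functional
# forms (dipole-dipole kernel coupled to flanking torsional states).
model: polysaccharide
T0: 300.0
cap: 1.0e4
weights:
  SS_GB: 1.0
  SS_el: 1.0
  corr3: 1.0
  turn3: 1.0
  w4: 0.0               # fourth-order correlation stub, off by default
  bond: 1.0
  "b": 1.0
  tor: 1.0
bonded:
  k_bond: 30.0
  k_theta: 4.0
  theta0_deg: 130.0
  torsion:
    default:
      "a": [0.5, 0.25, 0.0, 0.0, 0.0, 0.0]
      "b": [0.3, 0.0, 0.0, 0.0, 0.0, 0.0]
gay_berne:
  chi: 0.25
  chip: 0.2
  eps:
    "a": 0.50
    "b": 0.50
  sigma:
    "a": 6.0
    "b": 6.0
dipole:
  r_core: 3.0           # softening core of the point-dipole kernel, A
  eps_r: 4.0
  sites:                # glucose ~2.2 D, mixed orientation
    "a": {mu_par: 0.30, mu_perp: 0.45}
    "b": {mu_par: 0.25, mu_perp: 0.45}
correlation:
  corr3: 0.10
  turn3: 1.0
masses:
  anchor: 162.0         # one glucose unit per glycosidic-oxygen anchor
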