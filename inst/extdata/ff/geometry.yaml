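# Chain-geometry constants for the three coarse-grained chain classes.
# Lengths in Angstrom, angles in degrees. The extended-state values define
# the all-trans starting geometry used by place_extended(); the paper-level
# constants are the trans/cis backbone virtual-bond lengths of the protein
# branch. Branch lengths are anchor-to-interaction-site virtual-bond lengths
# (Calpha..SC centroid for amino acids, sugar-center..base centroid for
# nucleotides); values are rounded literature centroid distances.
protein:
  d0_trans: 3.8
  d0_cis: 2.8
  theta0_deg: 124.0
  gamma0_deg: 180.0
  branch:
    alpha0_deg: 50.0
    beta0_deg: 0.0
    lengths:
      "G": 0.0
      "A": 1.53
      "S": 1.90
      "C": 2.07
      "T": 1.94
      "V": 1.97
      "P": 1.87
      "I": 2.30
      "L": 2.60
      "N": 2.50
      "D": 2.47
      "M": 2.97
      "E": 3.10
      "Q": 3.09
      "K": 3.50
      "R": 4.10
      "H": 3.14
      "F": 3.41
      "Y": 3.86
      "W": 3.86
nucleic_acid:
  d0: 5.5
  theta0_deg: 140.0
  gamma0_deg: 180.0
  branch:
    alpha0_deg: 60.0
    beta0_deg: 0.0
    lengths:
      "A": 4.60
      "G": 4.70
      "C": 4.20
      "T": 4.30
      "U": 4.20
polysaccharide:
  d0: 4.50
  theta0_deg: 130.0
  gamma0_deg: 180.0
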