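## Physical constants and unit conventions used throughout the package.
## Coordinates are in Angstrom, energies in kcal/mol, time in fs, masses in amu,
## temperatures in K, charges in elementary charges, dipoles in e*Angstrom.

#' Physical constants used by the coarse-grained engine
#'
#' A named list with the gas constant `R` in kcal/(mol K), the Coulomb
#' constant `coulomb` in kcal A/(mol e^2), and `ekin` converting kcal/mol to
#' amu A^2/fs^2 (so that acceleration in A/fs^2 is `force * ekin / mass`).
#'
#' @format Named list of numeric scalars.
#' @export
cg_constants <- list(
  R       = 1.98720425e-3,  # kcal/(mol K)
  coulomb = 332.0637,       # kcal*A/(mol*e^2)
  ekin    = 4.184e-4,       # 1 kcal/mol in amu*A^2/fs^2
  avogadro_per_L_A3 = 6.02214076e-4  # (mol/L) -> number density in 1/A^3
)

.RGAS <- cg_constants$R
.COUL <- cg_constants$coulomb
.EKIN <- cg_constants$ekin

## default cap for any pair energy, kcal/mol (keeps integrators finite)
.ECAP_DEFAULT <- 1e4
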