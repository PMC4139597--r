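## User-facing total energy, energy breakdown, correlation terms and forces.

#' Total coarse-grained energy with per-term breakdown
#'
#' Evaluates the model's full energy expression: the weighted sum of all
#' pair, local and correlation terms, with the temperature multipliers
#' \eqn{f_n(T)} applied to the terms originating from order-n cumulant
#' factors (protein: f2 on the peptide-dipole and torsional terms, f3 on the
#' double-torsional, third-order correlation and three-segment turn terms,
#' f4 on the four-segment turn term; nucleic acid: f2 on the torsional term
#' only; polysaccharide: f2 on the ring-dipole electrostatic and torsional
#' terms, f3 on the third-order correlation/turn terms). Mean-field dipole
#' kernels are parameterised at the force field's reference temperature; all
#' explicit temperature dependence of those terms is carried by the
#' multipliers.
#'
#' @param topology a `cg_topology`.
#' @param conf a `cg_conformation`.
#' @param ff a `cg_forcefield` for the same model.
#' @param T temperature, K.
#' @return Object of class `cg_energy`: list with `terms` (unweighted
#'   per-term energies, kcal/mol), `weights`, `fmult` (multipliers at `T`),
#'   `total` (kcal/mol) and `T`. The total always equals
#'   `sum(weights * fmult * terms)`.
#' @export
total_energy <- function(topology, conf, ff, T = 300) {
  sys <- cg_system(topology, ff)
  X <- .stack_coords(topology, conf)
  terms <- sys_energy_terms(sys, X)
  f <- ifelse(sys$forder > 1,
              temperature_multiplier(pmax(sys$forder, 2), T, sys$T0), 1)
  structure(list(terms = terms, weights = sys$weights,
                 fmult = structure(as.numeric(f), names = names(terms)),
                 total = sum(sys$weights * f * terms), T = T,
                 model = sys$model),
            class = "cg_energy")
}

#' @export
print.cg_energy <- function(x, ...) {
  cat(sprintf("cg_energy (%s) at T = %g K\n", x$model, x$T))
  tab <- data.frame(term = names(x$terms), U = round(unname(x$terms), 4),
                    w = unname(x$weights), f = round(unname(x$fmult), 4))
  print(tab, row.names = FALSE)
  cat(sprintf("total: %.4f kcal/mol\n", x$total))
  invisible(x)
}

#' Correlation and turn energy terms
#'
#' Returns the third- (and for proteins fourth-) order correlation terms:
#' mean-field dipole-dipole kernels between chain-dipole pairs coupled to
#' the flanking torsional states, and the turn terms over consecutive chain
#' segments. Nucleic-acid chains carry no correlation terms beyond the
#' torsional potential and return an empty map.
#'
#' @inheritParams total_energy
#' @return Named list of energies (kcal/mol); empty for nucleic acids.
#' @export
correlation_energies <- function(topology, conf, ff, T = 300) {
  if (topology$model == "nucleic_acid") return(list())
  sys <- cg_system(topology, ff)
  X <- .stack_coords(topology, conf)
  keep <- c("corr3", "turn3", "turn4")
  out <- list()
  for (cl in sys$classes) {
    if (!cl$term %in% keep) next
    nm <- paste0("U_", cl$term)
    out[[nm]] <- (out[[nm]] %||% 0) +
      sum(.cpp_class_energy(cl$id, X, cl$pts, cl$par))
  }
  out
}

#' Forces on all explicit sites
#'
#' Negative gradient of [total_energy()] with respect to the anchor and
#' branch coordinates. Stiff local terms (bond stretching, angle bending,
#' torsions) use analytic gradients; all remaining terms use vectorised
#' central differences on the defining points of each pair term.
#'
#' @inheritParams total_energy
#' @param parts `"all"`, or the `"fast"` (stiff local) / `"slow"`
#'   (nonbonded, mean-field, rotamer, correlation) share of the force.
#' @return Matrix (n_anchor + n_branch) x 3, kcal/(mol A); branch rows
#'   follow anchor rows.
#' @export
forces <- function(topology, conf, ff, T = 300,
                   parts = c("all", "fast", "slow")) {
  parts <- match.arg(parts)
  sys <- cg_system(topology, ff)
  X <- .stack_coords(topology, conf)
  -sys_gradient(sys, X, T, parts)
}
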