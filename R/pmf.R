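## Restricted free energy (potential of mean force) machinery on gridded toy
## systems: component energies over secondary degrees of freedom, subset
## RFEs, Kubo cluster-cumulant factors by signed inclusion-exclusion, and
## the derivation/fitting of mean-field dipole tables.

#' Define a component energy
#'
#' A component energy is one additive piece of a toy all-atom energy
#' function: it depends on the coarse-grained (primary) variables `X` and on
#' a declared subset of the secondary variables that are integrated out.
#'
#' @param label name of the component.
#' @param fn function `(X, z)` returning energy in kcal/mol; `z` is a named
#'   list of equal-length numeric vectors (one entry per secondary variable
#'   the component declares), and `fn` must be vectorised over them.
#' @param secondary_vars character vector of secondary-variable names.
#' @return Object of class `cg_component`.
#' @export
component_energy <- function(label, fn, secondary_vars = character()) {
  stopifnot(is.function(fn), is.character(secondary_vars))
  structure(list(label = label, fn = fn, secondary_vars = secondary_vars),
            class = "cg_component")
}

#' Define a periodic secondary-variable grid
#'
#' Uniform grids over \eqn{[0, 2\pi)} for each named secondary variable
#' (angles of internal rotation). The trapezoidal rule on these periodic
#' grids is spectrally accurate and reduces to an equal-weight average.
#'
#' @param ... named integers (grid sizes, each >= 8) or numeric vectors of
#'   explicit grid points.
#' @return Object of class `cg_secondary_grid`.
#' @export
secondary_grid <- function(...) {
  args <- list(...)
  if (length(args) == 0 || is.null(names(args)) || any(names(args) == ""))
    stop("secondary variables must be named")
  pts <- lapply(args, function(a) {
    if (length(a) == 1L) {
      if (a < 8) stop("grid sizes must be at least 8")
      2 * pi * (seq_len(a) - 1) / a
    } else as.numeric(a)
  })
  structure(list(points = pts), class = "cg_secondary_grid")
}

## joint mesh of the named variables (named list of equal-length vectors)
.grid_mesh <- function(grid, vars) {
  if (length(vars) == 0L)
    return(structure(list(), n = 1L))
  missing <- setdiff(vars, names(grid$points))
  if (length(missing))
    stop("secondary variable(s) not on the grid: ",
         paste(missing, collapse = ", "))
  mesh <- do.call(expand.grid, c(grid$points[vars],
                                 list(KEEP.OUT.ATTRS = FALSE)))
  if (nrow(mesh) > 5e7) stop("joint secondary grid too large")
  structure(as.list(mesh), n = nrow(mesh))
}

## total energy of a component set on a joint mesh
.mesh_energy <- function(components, mesh, X) {
  n <- attr(mesh, "n")
  E <- numeric(n)
  for (cmp in components) {
    z <- mesh[cmp$secondary_vars]
    E <- E + cmp$fn(X, z)
  }
  E
}

#' Restricted free energy of a component set
#'
#' \deqn{F(X) = -RT \ln\{ (1/V_Y) \int \exp[-E(X; Y)/RT] dV_Y \}}
#' with the secondary variables integrated over the uniform (normalised)
#' measure of the periodic grid. An energy that does not depend on the
#' secondary variables gives back exactly itself.
#'
#' @param components list of [component_energy()] objects (a single
#'   component may be given bare).
#' @param grid a [secondary_grid()].
#' @param X primary-variable value(s) passed through to the components.
#' @param T temperature, K.
#' @return Free energy, kcal/mol.
#' @export
restricted_free_energy <- function(components, grid, X = NULL, T = 300) {
  if (inherits(components, "cg_component")) components <- list(components)
  if (T <= 0) stop("temperature must be positive")
  if (length(grid$points) == 0) stop("empty secondary grid")
  vars <- unique(unlist(lapply(components, `[[`, "secondary_vars")))
  mesh <- .grid_mesh(grid, vars)
  E <- .mesh_energy(components, mesh, X)
  rt <- .RGAS * T
  m <- min(E)
  m - rt * log(mean(exp(-(E - m) / rt)))
}

#' Restricted free energy of a component subset
#'
#' Evaluates the RFE containing only the listed components, integrating over
#' the union of their secondary variables (the subspace volume of that
#' union normalises the integral).
#'
#' @inheritParams restricted_free_energy
#' @param subset integer indices into `components`.
#' @return Free energy, kcal/mol.
#' @export
subset_rfe <- function(components, subset, grid, X = NULL, T = 300) {
  if (inherits(components, "cg_component")) components <- list(components)
  if (length(subset) == 0) stop("subset must be non-empty")
  if (any(subset < 1 | subset > length(components)))
    stop("invalid component index")
  restricted_free_energy(components[subset], grid, X, T)
}

#' Kubo cluster-cumulant factor of a component subset
#'
#' The order-k factor of the cluster-cumulant expansion of the RFE,
#' obtained by signed inclusion-exclusion over all non-empty sub-subsets:
#' \deqn{f^{(k)}_{i_1 \ldots i_k} = \sum_{l=1}^{k} \sum_{S, |S| = l}
#'   (-1)^{k-l} F^{(l)}_S.}
#' Factors vanish identically when the components of the subset share no
#' secondary variables, and the sum of all factors over all subsets
#' reconstructs the full RFE.
#'
#' @inheritParams subset_rfe
#' @return Factor value, kcal/mol.
#' @export
cluster_cumulant <- function(components, subset, grid, X = NULL, T = 300) {
  if (inherits(components, "cg_component")) components <- list(components)
  if (length(subset) == 0) stop("subset must be non-empty")
  k <- length(subset)
  total <- 0
  for (l in seq_len(k)) {
    for (s in .subsets_of(subset, l)) {
      total <- total + (-1)^(k - l) * subset_rfe(components, s, grid, X, T)
    }
  }
  total
}

## all size-l subsets of an index vector (combn() would misread a scalar)
.subsets_of <- function(x, l) {
  if (length(x) == 1L) {
    if (l == 1L) list(x) else list()
  } else {
    utils::combn(x, l, simplify = FALSE)
  }
}

#' All cluster-cumulant factors of a component set
#'
#' Convenience enumeration of every non-empty subset's factor, returned
#' with the subset composition; `sum(values)` telescopes back to the full
#' RFE.
#'
#' @inheritParams restricted_free_energy
#' @return data.frame with columns `subset` (comma-separated indices),
#'   `order`, `value`.
#' @export
factor_table <- function(components, grid, X = NULL, T = 300) {
  if (inherits(components, "cg_component")) components <- list(components)
  n <- length(components)
  out <- list()
  for (k in seq_len(n)) {
    for (s in .subsets_of(seq_len(n), k)) {
      out[[length(out) + 1L]] <- data.frame(
        subset = paste(s, collapse = ","), order = k,
        value = cluster_cumulant(components, s, grid, X, T))
    }
  }
  do.call(rbind, out)
}

## ---------------------------------------------------------------------------
## derivation of mean-field dipole tables

## deterministic quasi-uniform unit vectors (Fibonacci sphere)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Derive and fit a mean-field dipole-dipole potential table
#'
#' Tabulates the Boltzmann-averaged dipole-dipole energy
#' ([mean_field_dipole_energy()]) on a grid of separations times a
#' deterministic quasi-uniform sample of axis orientations, then fits the
#' documented analytic basis by linear least squares:
#' the fixed-dipole kernel \eqn{(u_i\cdot u_j - 3 (u_i\cdot \hat r)(u_j\cdot
#' \hat r))/r^3}, an isotropic \eqn{1/r^6} attraction from the rotating
#' components, and its axial-projection corrections.
#'
#' @param r separations, A (default covers 3-15 A).
#' @param n_orient number of orientation pairs per separation.
#' @param p_i,p_j dipole parameter lists (`mu_par`, `mu_perp`, opt `eps_r`).
#' @param T temperature, K.
#' @param K_grid quadrature size passed to the averaging integral.
#' @return Object of class `cg_dipole_fit`: list with `table` (data.frame),
#'   `coef`, `rmse`, and `predict(ui, uj, r)` closure.
#' @export
derive_dipole_table <- function(r = seq(3, 15, by = 0.5), n_orient = 24,
                                p_i, p_j, T = 300, K_grid = 36) {
  ui <- .fib_sphere(n_orient)
  uj <- .fib_sphere(n_orient + 1)[-1, , drop = FALSE]  # decorrelated set
  rows <- list()
  for (rr in r) {
    for (o in seq_len(n_orient)) {
      u <- mean_field_dipole_energy(c(rr, 0, 0), ui[o, ], uj[o, ],
                                    p_i, p_j, T, K_grid)
      rows[[length(rows) + 1L]] <- c(r = rr, o = o, ui[o, ], uj[o, ], U = u)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("r", "orient", "uix", "uiy", "uiz", "ujx", "ujy", "ujz", "U")
  basis <- .dipole_basis(as.matrix(tab[, 3:5]), as.matrix(tab[, 6:8]), tab$r)
  qrd <- qr(basis)
  if (qrd$rank < ncol(basis)) stop("singular design matrix in dipole fit")
  coef <- qr.coef(qrd, tab$U)
  resid <- tab$U - basis %*% coef
  fit <- list(
    table = tab,
    coef = structure(as.numeric(coef), names = colnames(basis)),
    rmse = sqrt(mean(resid^2)),
    predict = function(ui, uj, r) {
      b <- .dipole_basis(matrix(ui, ncol = 3), matrix(uj, ncol = 3), r)
      as.numeric(b %*% coef)
    })
  class(fit) <- "cg_dipole_fit"
  fit
}

.dipole_basis <- function(ui, uj, r) {
  rh <- cbind(1, 0, 0)[rep(1, length(r)), , drop = FALSE]
  ai <- ui[, 1]; aj <- uj[, 1]          # axis projections on rhat = +x
  cc <- row_dot(ui, uj)
  cbind(kernel = (cc - 3 * ai * aj) / r^3,
        iso6 = 1 / r^6,
        ax6 = (ai^2 + aj^2) / r^6,
        axax6 = (ai^2 * aj^2) / r^6,
        kernel2 = (cc - 3 * ai * aj)^2 / r^6)
}

#' Write a derived dipole table as tab-separated text
#'
#' @param fit a `cg_dipole_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dipole_table <- function(fit, path) {
  utils::write.table(fit$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write fitted dipole-basis coefficients in the force-field file format
#'
#' @param fit a `cg_dipole_fit`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_dipole_coef <- function(fit, path) {
  yaml::write_yaml(list(dipole_fit = list(
    basis = names(fit$coef), coef = as.numeric(fit$coef),
    rmse = fit$rmse)), path)
  invisible(path)
}
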