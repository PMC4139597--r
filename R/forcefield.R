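## Energy terms of the mean-field coarse-grained force fields: temperature
## multipliers, Gay-Berne anisotropic contacts, Boltzmann-averaged (mean
## field) dipole-dipole interactions, Debye-Hueckel screened electrostatics,
## excluded-volume terms and the local (bonded) potentials.

#' Temperature multiplier for cumulant-order-n energy terms
#'
#' Terms of the energy expression that originate from an order-n factor of
#' the cluster-cumulant expansion carry an explicit temperature dependence,
#' encoded by
#' \deqn{f_n(T) = \ln(e + e^{-1}) / \ln\{\exp[(T/T_0)^{n-1}] +
#'   \exp[-(T/T_0)^{n-1}]\}.}
#' The multiplier equals 1 at the reference temperature and decays as
#' \eqn{1/T^{n-1}} at high temperature.
#'
#' @param n cumulant order, integer >= 2.
#' @param T temperature, K.
#' @param T0 reference temperature, K (default 300).
#' @return Dimensionless positive factor (vectorised over `T`).
#' @export
temperature_multiplier <- function(n, T, T0 = 300) {
  if (any(n < 2)) stop("temperature multipliers are defined for order n >= 2")
  if (any(T <= 0) || any(T0 <= 0)) stop("temperatures must be positive")
  x <- (T / T0)^(n - 1)
  ## log(exp(x) + exp(-x)) computed overflow-safely; the numerator uses the
  ## same expression at x = 1 so that f_n(T0) is exactly 1
  lcosh2 <- function(x) abs(x) + log1p(exp(-2 * abs(x)))
  lcosh2(1) / lcosh2(x)
}

#' Load a packaged force-field parameter table
#'
#' @param model chain class.
#' @param path optional path to a YAML parameter file overriding the
#'   packaged table.
#' @return An object of class `cg_forcefield` (named parameter list).
#' @export
load_forcefield <- function(model = .CG_MODELS, path = NULL) {
  model <- match.arg(model)
  if (is.null(path))
    path <- system.file("extdata", "ff", paste0(model, ".yaml"),
                        package = "mfcg")
  ff <- yaml::read_yaml(path)
  if (!identical(ff$model, model))
    stop(sprintf("parameter file is for model '%s', not '%s'",
                 ff$model, model))
  ff$cap <- as.numeric(ff$cap %||% .ECAP_DEFAULT)
  class(ff) <- "cg_forcefield"
  ff
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat(sprintf("cg_forcefield: %s (T0 = %g K)\n", x$model, x$T0))
  w <- unlist(x$weights)
  cat("  weights:", paste(sprintf("%s=%g", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Debye screening constant from ionic strength
#'
#' Standard Debye-Hueckel screening for a 1:1 electrolyte:
#' \eqn{\kappa^2 = 8 \pi \lambda_B n}, with the Bjerrum length
#' \eqn{\lambda_B = C / (\epsilon_r R T)} and number density `n` from the
#' molar ionic strength.
#'
#' @param ionic_strength mol/L.
#' @param eps_r relative dielectric constant.
#' @param T temperature, K.
#' @return kappa in 1/A.
#' @export
kappa_from_ionic_strength <- function(ionic_strength, eps_r = 80, T = 300) {
  lb <- .COUL / (eps_r * .RGAS * T)
  n <- ionic_strength * cg_constants$avogadro_per_L_A3
  sqrt(8 * pi * lb * n)
}

## ---------------------------------------------------------------------------
## Gay-Berne anisotropic pair potential (vectorised core).
## a = rhat.ui, b = rhat.uj, c = ui.uj; shifted 12-6 radial shape with
## orientation-dependent contact distance sigma and well depth eps.
.gb_core <- function(r, a, b, cc, eps0, sig0, chi, chip, cap) {
  hp <- (a + b)^2 / (1 + chi * cc) + (a - b)^2 / (1 - chi * cc)
  sig <- sig0 / sqrt(pmax(1 - 0.5 * chi * hp, 1e-12))
  e1 <- 1 / sqrt(pmax(1 - chi^2 * cc^2, 1e-12))
  hpp <- (a + b)^2 / (1 + chip * cc) + (a - b)^2 / (1 - chip * cc)
  e2 <- pmax(1 - 0.5 * chip * hpp, 0)
  eps <- eps0 * e1 * e2^2
  rr <- r - sig + sig0
  u <- rep(cap, length(r))
  ok <- rr > sig0 * 0.1
  rho6 <- (sig0 / rr[ok])^6
  u[ok] <- 4 * eps[ok] * (rho6^2 - rho6)
  pmin(u, cap)
}

#' Gay-Berne anisotropic pair energy
#'
#' Orientation-dependent Lennard-Jones-like potential for two ellipsoidal
#' sites with unit axes `u_i`, `u_j` separated by `r_vec`. In the spherical
#' limit (`chi = chip = 0`) it reduces exactly to a 12-6 Lennard-Jones
#' potential with well depth `eps0` and zero crossing `sigma0`. Energies are
#' capped at `cap` (default 1e4 kcal/mol) below the hard core.
#'
#' @param r_vec 3-vector from site i to site j, A.
#' @param u_i,u_j unit axis vectors.
#' @param p list with `eps0`, `sigma0`, `chi`, `chip` (and optionally `cap`).
#' @return Energy, kcal/mol.
#' @export
gay_berne_energy <- function(r_vec, u_i, u_j, p) {
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("zero separation")
  if (abs(sum(u_i^2) - 1) > 1e-6 || abs(sum(u_j^2) - 1) > 1e-6)
    stop("axes must be unit vectors")
  rh <- r_vec / r
  .gb_core(r, sum(rh * u_i), sum(rh * u_j), sum(u_i * u_j),
           p$eps0, p$sigma0, p$chi %||% 0, p$chip %||% 0,
           p$cap %||% .ECAP_DEFAULT)
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' \eqn{U = C q_i q_j \exp(-\kappa r) / (\epsilon_r r)} with the Coulomb
#' constant C in kcal A/(mol e^2).
#'
#' @param r separation, A.
#' @param p list with `qq` (charge product, e^2), `kappa` (1/A), `eps_r`.
#' @return Energy, kcal/mol.
#' @export
debye_huckel_energy <- function(r, p) {
  if (any(r <= 0)) stop("zero separation")
  .COUL * p$qq * exp(-(p$kappa %||% 0) * r) / ((p$eps_r %||% 1) * r)
}

#' Lennard-Jones excluded-volume pair energy
#'
#' The 12-6 excluded-volume term used for side chain-peptide and
#' phosphate-base contacts; shares its parameter record with the
#' electrostatic terms of the same site pair.
#'
#' @param r separation, A.
#' @param p list with `eps`, `sigma` (and optionally `cap`).
#' @return Energy, kcal/mol.
#' @export
lj_excluded_energy <- function(r, p) {
  if (any(r <= 0)) stop("zero separation")
  s6 <- (p$sigma / r)^6
  pmin(4 * p$eps * (s6^2 - s6), p$cap %||% .ECAP_DEFAULT)
}

## ---------------------------------------------------------------------------
## Mean-field dipole-dipole interaction.
## Each site carries a dipole with component mu_par along its rotation axis
## and mu_perp rotating freely about it; the mean-field energy is the
## Boltzmann log-average over independent uniform rotations lambda_i,
## lambda_j of the point dipole-dipole energy.

## 3x3 coefficient matrix c[p,q] of E = sum c_pq f_p(li) f_q(lj),
## f = (1, cos, sin), for a single pair. e-list: axis, e1, e2.
.dip_coef <- function(rhat, r, ax_i, ax_j, mu_i, mu_j, eps_r) {
  fi <- perp_frame(ax_i); fj <- perp_frame(ax_j)
  Ei <- rbind(ax_i, fi$e1, fi$e2)
  Ej <- rbind(ax_j, fj$e1, fj$e2)
  mi <- c(mu_i$mu_par, mu_i$mu_perp, mu_i$mu_perp)
  mj <- c(mu_j$mu_par, mu_j$mu_perp, mu_j$mu_perp)
  k <- .COUL / (eps_r * r^3)
  cc <- matrix(0, 3, 3)
  for (p in 1:3) for (q in 1:3) {
    cc[p, q] <- k * mi[p] * mj[q] *
      (sum(Ei[p, ] * Ej[q, ]) - 3 * sum(Ei[p, ] * rhat) * sum(Ej[q, ] * rhat))
  }
  cc
}

#' Mean-field (Boltzmann-averaged) dipole-dipole pair energy
#'
#' The dipole of each site has a fixed component `mu_par` along the site's
#' rotation axis and a component `mu_perp` that rotates freely about it.
#' The mean-field energy is
#' \deqn{U = -RT \ln \langle \exp(-E_{dd}(\lambda_i,\lambda_j)/RT)\rangle,}
#' the average running over independent uniform rotations of the
#' perpendicular components, evaluated by trapezoidal quadrature on a
#' `K_grid` x `K_grid` grid (exact equal-weight rule on the periodic
#' domain). Deterministic for fixed `K_grid`.
#'
#' @param r_vec 3-vector from site i to site j, A.
#' @param axis_i,axis_j unit rotation axes.
#' @param p_i,p_j dipole parameter lists with `mu_par`, `mu_perp` (e*A) and
#'   optionally `eps_r` (taken from `p_i`, default 1).
#' @param T temperature, K.
#' @param K_grid quadrature points per angle (>= 8, default 36).
#' @return Energy, kcal/mol.
#' @export
mean_field_dipole_energy <- function(r_vec, axis_i, axis_j, p_i, p_j,
                                     T = 300, K_grid = 36) {
  if (K_grid < 8) stop("K_grid must be at least 8")
  if (abs(sum(axis_i^2) - 1) > 1e-6 || abs(sum(axis_j^2) - 1) > 1e-6)
    stop("axes must be unit vectors")
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("zero separation")
  cc <- .dip_coef(r_vec / r, r, axis_i, axis_j, p_i, p_j,
                  p_i$eps_r %||% 1)
  lam <- 2 * pi * (seq_len(K_grid) - 1) / K_grid
  Fi <- rbind(1, cos(lam), sin(lam))          # 3 x K
  E <- t(Fi) %*% cc %*% Fi                    # K x K energy surface
  rt <- .RGAS * T
  m <- min(E)
  -rt * (log(mean(exp(-(E - m) / rt))) - m / rt)
}

#' Second-order cumulant closed form of the mean-field dipole energy
#'
#' Fast path used inside the chain energy functions:
#' \eqn{U \approx \langle E \rangle - \mathrm{Var}(E) / (2RT)}, where the
#' average and variance over the free rotations are analytic (the rotating
#' components average to zero; their variance contributes half the squared
#' coupling coefficients). Agrees with the quadrature evaluator at
#' separations beyond contact.
#'
#' @inheritParams mean_field_dipole_energy
#' @return Energy, kcal/mol.
#' @export
mean_field_dipole_cumulant2 <- function(r_vec, axis_i, axis_j, p_i, p_j,
                                        T = 300) {
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("zero separation")
  cc <- .dip_coef(r_vec / r, r, axis_i, axis_j, p_i, p_j,
                  p_i$eps_r %||% 1)
  w <- c(1, 0.5, 0.5)
  mean_e <- cc[1, 1]
  var_e <- sum((cc^2) * outer(w, w)) - cc[1, 1]^2
  mean_e - var_e / (2 * .RGAS * T)
}

## ---------------------------------------------------------------------------
## Local (bonded) energies.

#' Resolve the bonded parameter tables for a topology
#'
#' Expands the per-residue-type bonded parameters of a force field into
#' flat per-bond / per-angle / per-torsion / per-branch vectors aligned with
#' the topology's index tables. Missing residue-type entries raise an error
#' naming the gap.
#'
#' @param topology a `cg_topology`.
#' @param ff a `cg_forcefield` for the same model.
#' @return List of resolved parameter vectors (class `cg_bonded`).
#' @export
bonded_params <- function(topology, ff) {
  stopifnot(inherits(topology, "cg_topology"))
  if (!identical(ff$model, topology$model))
    stop("force field / topology model mismatch")
  geom <- chain_geometry(topology$model)
  b <- ff$bonded
  nb <- nrow(topology$bonds)
  d0 <- rep(if (topology$model == "protein") geom$d0_trans else geom$d0, nb)
  if (topology$model == "protein") d0[topology$bonds$cis] <- geom$d0_cis
  ## per-torsion Fourier coefficients: lookup by flanking residue-type pair
  ## with fall-back to the "default" entry
  nt <- nrow(topology$torsions)
  tor_a <- matrix(0, nt, 6); tor_b <- matrix(0, nt, 6)
  if (nt > 0) {
    ## residue-type-pair lookup ("X:Y" key for the central virtual bond),
    ## falling back to the "default" table
    code_of_anchor <- rep(NA_character_, topology$n_anchor)
    if (topology$model == "polysaccharide") {
      code_of_anchor[topology$mids$a1] <- topology$mids$code
    } else {
      code_of_anchor[seq_len(topology$n_res)] <- topology$sequence
    }
    key <- paste(code_of_anchor[topology$torsions$j],
                 code_of_anchor[topology$torsions$k], sep = ":")
    for (t in seq_len(nt)) {
      ent <- b$torsion[[key[t]]] %||% b$torsion[["default"]]
      if (is.null(ent))
        stop(sprintf("missing torsion parameters for residue-type pair '%s'",
                     key[t]))
      tor_a[t, ] <- unlist(ent$a); tor_b[t, ] <- unlist(ent$b)
    }
  }
  br <- topology$branches
  rot <- NULL
  if (!is.null(b$rot) && nrow(br)) {
    rot <- list(k_alpha = rep(b$rot$k_alpha, nrow(br)),
                alpha0 = rep(deg2rad(b$rot$alpha0_deg), nrow(br)),
                beta_cos = unlist(b$rot$beta_cos),
                beta_sin = unlist(b$rot$beta_sin))
  }
  db0 <- if (nrow(br)) {
    v <- unname(unlist(geom$branch$lengths)[br$code])
    if (anyNA(v))
      stop(sprintf("missing branch length for residue type '%s'",
                   br$code[which(is.na(v))[1]]))
    v
  } else numeric()
  structure(list(
    model = topology$model,
    d0 = d0, k_bond = b$k_bond,
    db0 = db0, k_branch = b$k_branch %||% 0,
    theta0 = rep(deg2rad(b$theta0_deg), nrow(topology$angles)),
    k_theta = b$k_theta,
    tor_a = tor_a, tor_b = tor_b,
    tord_a = unlist(b$tord$a %||% numeric()),
    tord_b = unlist(b$tord$b %||% numeric()),
    rot = rot
  ), class = "cg_bonded")
}

#' Local (bonded) energy terms from internal coordinates
#'
#' Computes the virtual-bond stretching, angle-bending, torsional,
#' double-torsional and side-chain-rotamer energies:
#' \eqn{U_{bond} = \sum k_d (d_i - d_0)^2} (backbone and branch bonds),
#' \eqn{U_b = \sum k_\theta (\theta_i - \theta_0)^2},
#' \eqn{U_{tor} = \sum_i \sum_k a_k \cos(k\gamma_i) + b_k \sin(k\gamma_i)},
#' a product-Fourier double-torsional surface in consecutive
#' \eqn{(\gamma_i, \gamma_{i+1})}, and a harmonic-plus-Fourier rotamer
#' surface in the branch polar angles \eqn{(\alpha, \beta)}.
#'
#' @param ic a `cg_internal`.
#' @param p resolved bonded parameters from [bonded_params()].
#' @return Named list with `U_bond`, `U_b`, `U_tor`, `U_tord`, `U_rot`
#'   (kcal/mol).
#' @export
local_energies <- function(ic, p) {
  stopifnot(inherits(ic, "cg_internal"), inherits(p, "cg_bonded"))
  u_bond <- sum(p$k_bond * (ic$d - p$d0)^2)
  if (length(p$db0)) {
    live <- p$db0 > 0
    u_bond <- u_bond +
      sum(p$k_branch * (ic$d_branch[live] - p$db0[live])^2)
  }
  u_b <- sum(p$k_theta * (ic$theta - p$theta0)^2)
  u_tor <- 0
  if (length(ic$gamma)) {
    k <- seq_len(ncol(p$tor_a))
    cosm <- cos(outer(ic$gamma, k)); sinm <- sin(outer(ic$gamma, k))
    u_tor <- sum(cosm * p$tor_a) + sum(sinm * p$tor_b)
  }
  u_tord <- 0
  if (length(p$tord_a) && length(ic$gamma) >= 2) {
    ## consecutive dihedral pairs (within the flat list; chain-aware pairing
    ## is handled by the chain energy functions)
    g1 <- ic$gamma[-length(ic$gamma)]; g2 <- ic$gamma[-1]
    for (k in seq_along(p$tord_a)) {
      u_tord <- u_tord + sum(p$tord_a[k] * cos(k * g1) * cos(k * g2) +
                             p$tord_b[k] * sin(k * g1) * sin(k * g2))
    }
  }
  u_rot <- 0
  if (!is.null(p$rot) && length(ic$alpha)) {
    live <- p$db0 > 0
    a <- ic$alpha[live]; be <- ic$beta[live]
    u_rot <- sum(p$rot$k_alpha[live] * (a - p$rot$alpha0[live])^2)
    for (k in seq_along(p$rot$beta_cos)) {
      u_rot <- u_rot + sum(p$rot$beta_cos[k] * cos(k * be) +
                           p$rot$beta_sin[k] * sin(k * be))
    }
  }
  list(U_bond = u_bond, U_b = u_b, U_tor = u_tor, U_tord = u_tord,
       U_rot = u_rot)
}
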