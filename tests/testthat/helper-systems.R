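## Shared builders and independent reference implementations used as
## oracles across the test files.

RGAS <- cg_constants$R

## harmonic dimer: two glycines with every energy term switched off except
## the backbone virtual-bond spring
harmonic_dimer <- function(k = 5) {
  top <- build_topology("GG", "protein")
  ff <- load_forcefield("protein")
  for (w in names(ff$weights)) ff$weights[[w]] <- 0
  ff$weights$bond <- 1
  ff$bonded$k_bond <- k
  list(top = top, conf = place_extended(top), ff = ff)
}

## a mildly perturbed extended conformation (clash-free, non-planar)
perturbed_system <- function(model, seed = 1, sd = 0.2) {
  sq <- switch(model,
               protein = "ARNDCEQGHILKMFPSTWYV",
               nucleic_acid = c("ACGTACGT", "ACGTACGT"),
               polysaccharide = "aabbaabb")
  top <- build_topology(sq, model)
  conf <- place_extended(top)
  set.seed(seed)
  conf$anchors <- conf$anchors +
    matrix(rnorm(length(conf$anchors), 0, sd), ncol = 3)
  if (nrow(conf$branches))
    conf$branches <- conf$branches +
      matrix(rnorm(length(conf$branches), 0, sd), ncol = 3)
  list(top = top, conf = conf, ff = load_forcefield(model))
}

## independently coded scalar Gay-Berne (second implementation as oracle)
ref_gay_berne <- function(r_vec, ui, uj, eps0, sigma0, chi, chip) {
  r <- sqrt(sum(r_vec * r_vec))
  rh <- r_vec / r
  a <- sum(rh * ui); b <- sum(rh * uj); cc <- sum(ui * uj)
  hfun <- function(x) {
    (a + b)^2 / (1 + x * cc) + (a - b)^2 / (1 - x * cc)
  }
  sig <- sigma0 * (1 - 0.5 * chi * hfun(chi))^(-0.5)
  eps <- eps0 * (1 - chi^2 * cc^2)^(-0.5) * (1 - 0.5 * chip * hfun(chip))^2
  rho <- (r - sig + sigma0) / sigma0
  4 * eps * (rho^-12 - rho^-6)
}

## fixed point-dipole interaction energy (closed form)
fixed_dipole_energy <- function(r_vec, mu_i, mu_j, eps_r = 1) {
  r <- sqrt(sum(r_vec^2))
  rh <- r_vec / r
  cg_constants$coulomb / (eps_r * r^3) *
    (sum(mu_i * mu_j) - 3 * sum(mu_i * rh) * sum(mu_j * rh))
}

## rotation matrix about a unit axis
rot_mat <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## apply a rigid-body motion to a conformation
rigid_move <- function(conf, R, shift) {
  out <- conf
  out$anchors <- conf$anchors %*% t(R) +
    matrix(shift, nrow(conf$anchors), 3, byrow = TRUE)
  if (nrow(conf$branches))
    out$branches <- conf$branches %*% t(R) +
      matrix(shift, nrow(conf$branches), 3, byrow = TRUE)
  out
}

## independent all-trans chain-builder oracle: places anchors sequentially
## with explicit rotation matrices in the plane
ref_extended_chain <- function(n, d, theta) {
  X <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    X[i, ] <- X[i - 1, ] + d * dir
    ## alternate the in-plane bend to keep an all-trans zig-zag
    ang <- (pi - theta) * (-1)^i
    dir <- as.vector(rot_mat(c(0, 0, 1), ang) %*% dir)
  }
  X
}
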