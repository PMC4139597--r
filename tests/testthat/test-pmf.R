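## toy component sets used throughout
.cmp_cos <- function(A = 1, var = "lam", label = "cos") {
  component_energy(label, function(X, z) -A * cos(z[[var]]), var)
}

test_that("restricted free energy: constant integrand, Bessel closed form, bounds", {
  g <- secondary_grid(lam = 72)
  ## energy independent of the secondary variables -> F = E exactly
  const <- component_energy("const", function(X, z) rep(2.5, length(z[[1]])),
                            "lam")
  expect_equal(restricted_free_energy(const, g, T = 300), 2.5,
               tolerance = 1e-12)
  ## E = -A cos(lam): F = -RT ln I0(A/RT), checked at A = 1, RT = 0.6
  A <- 1; RT <- 0.6
  Tb <- RT / RGAS
  Fq <- restricted_free_energy(.cmp_cos(A), secondary_grid(lam = 360),
                               T = Tb)
  expect_equal(Fq, -RT * log(besselI(A / RT, 0)), tolerance = 1e-8)
  ## log-sum-exp bounds: min E <= F <= <E>
  set.seed(4)
  for (i in 1:5) {
    A <- runif(1, 0.3, 3)
    f <- restricted_free_energy(.cmp_cos(A), g, T = 300)
    expect_gte(f, -A - 1e-12)        # min over the grid
    expect_lte(f, 0 + 1e-12)         # <E> = -A <cos> = 0
  }
  expect_error(restricted_free_energy(.cmp_cos(), secondary_grid(lam = 4)),
               "at least 8")
  expect_error(restricted_free_energy(.cmp_cos(1, "mu"), g), "not on the grid")
})

test_that("subset RFEs: singletons, full set, shared-variable double integral", {
  g <- secondary_grid(l1 = 48, l2 = 48)
  comps <- list(
    component_energy("a", function(X, z) -1.2 * cos(z$l1), "l1"),
    component_energy("b", function(X, z) 0.8 * cos(z$l1) * sin(z$l2),
                     c("l1", "l2")),
    component_energy("c", function(X, z) -0.5 * cos(z$l2), "l2"))
  ## singleton subset equals the RFE of that component alone
  expect_equal(subset_rfe(comps, 1, g, T = 300),
               restricted_free_energy(comps[[1]], g, T = 300),
               tolerance = 1e-12)
  ## full set equals the joint RFE
  expect_equal(subset_rfe(comps, 1:3, g, T = 300),
               restricted_free_energy(comps, g, T = 300),
               tolerance = 1e-12)
  ## two components sharing l1: direct double-integral oracle
  RT <- RGAS * 300
  l1 <- 2 * pi * (0:47) / 48; l2 <- l1
  E <- outer(l1, l2, function(a, b) -1.2 * cos(a) + 0.8 * cos(a) * sin(b))
  Fdirect <- -RT * log(mean(exp(-E / RT)))
  expect_equal(subset_rfe(comps, 1:2, g, T = 300), Fdirect,
               tolerance = 1e-10)
  expect_error(subset_rfe(comps, integer(), g), "non-empty")
  expect_error(subset_rfe(comps, 7, g), "invalid")
})

test_that("cluster cumulants: disjoint factors vanish, expansion telescopes", {
  g <- secondary_grid(l1 = 32, l2 = 32, l3 = 32)
  disj <- list(
    component_energy("a", function(X, z) -cos(z$l1), "l1"),
    component_energy("b", function(X, z) 0.7 * sin(z$l2), "l2"))
  ## no shared secondary variables -> pair factor is zero
  expect_lt(abs(cluster_cumulant(disj, 1:2, g, T = 300)), 1e-10)

  comps <- list(
    component_energy("a", function(X, z) -cos(z$l1), "l1"),
    component_energy("b", function(X, z) 0.6 * cos(z$l1) * cos(z$l2),
                     c("l1", "l2")),
    component_energy("c", function(X, z) 0.4 * sin(z$l2) * sin(z$l3),
                     c("l2", "l3")))
  ## sum of all factors over all subsets reconstructs the full RFE
  ft <- factor_table(comps, g, T = 320)
  expect_equal(sum(ft$value), restricted_free_energy(comps, g, T = 320),
               tolerance = 1e-10)
  ## third-order factor equals an independent inclusion-exclusion oracle
  RT <- RGAS * 320
  lam <- 2 * pi * (0:31) / 32
  rfe_direct <- function(idx) {
    ## brute-force grid sum over the union of variables of the subset
    mesh <- expand.grid(l1 = lam, l2 = lam, l3 = lam)
    E <- 0
    for (k in idx) E <- E + comps[[k]]$fn(NULL, mesh)
    -RT * log(mean(exp(-E / RT)))
  }
  f3 <- 0
  for (l in 1:3) {
    for (s in utils::combn(3, l, simplify = FALSE)) {
      f3 <- f3 + (-1)^(3 - l) * rfe_direct(s)
    }
  }
  expect_equal(cluster_cumulant(comps, 1:3, g, T = 320), f3,
               tolerance = 1e-10)
})

test_that("factor magnitudes decay with order for weak coupling", {
  ## hierarchy of couplings: a-b strongly coupled through l1, the
  ## three-way (irreducible) coupling enters only at strength delta
  g <- secondary_grid(l1 = 32, l2 = 32)
  for (del in c(0.3, 0.15)) {
    comps <- list(
      component_energy("a", function(X, z) -cos(z$l1), "l1"),
      component_energy("b", function(X, z)
        -0.5 * cos(z$l1) + del * cos(z$l1) * cos(z$l2), c("l1", "l2")),
      component_energy("c", function(X, z) del * cos(z$l2), "l2"))
    f1 <- abs(cluster_cumulant(comps, 1, g, T = 503))
    f2 <- abs(cluster_cumulant(comps, 1:2, g, T = 503))
    f3 <- abs(cluster_cumulant(comps, 1:3, g, T = 503))
    expect_gt(f1, f2)
    expect_gt(f2, f3)
  }
})

test_that("high-temperature factor scaling follows 1/T^(m-1)", {
  ## a pair factor (lowest nonzero cumulant of order m = 2) scales as 1/T
  g <- secondary_grid(l1 = 64)
  comps <- list(
    component_energy("a", function(X, z) -0.8 * cos(z$l1), "l1"),
    component_energy("b", function(X, z) 0.6 * cos(z$l1), "l1"))
  Ts <- c(2000, 4000, 8000)
  fv <- vapply(Ts, function(T) cluster_cumulant(comps, 1:2, g, T = T), 0)
  slope <- coef(stats::lm(log(abs(fv)) ~ log(Ts)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
})

test_that("quadrature is converged: doubling the grid changes nothing", {
  comps <- list(
    component_energy("a", function(X, z) -1.1 * cos(z$l1) + 0.4 * sin(z$l2),
                     c("l1", "l2")))
  f72 <- restricted_free_energy(comps, secondary_grid(l1 = 72, l2 = 72),
                                T = 300)
  f144 <- restricted_free_energy(comps, secondary_grid(l1 = 144, l2 = 144),
                                 T = 300)
  expect_lt(abs(f72 - f144), 1e-6)
})

test_that("dipole-table derivation: exact model class, cross-validation, symmetry", {
  ## mu_perp = 0: the fixed-dipole kernel is in the basis -> near-zero RMSE
  pfix <- list(mu_par = 0.9, mu_perp = 0, eps_r = 1)
  fit0 <- derive_dipole_table(r = seq(3, 15, by = 1), n_orient = 16,
                              p_i = pfix, p_j = pfix)
  expect_lt(fit0$rmse, 1e-8)
  ## rotating components: held-out orientations predicted about as well as
  ## the training set
  p <- list(mu_par = 0.8, mu_perp = 0.6, eps_r = 1)
  fit <- derive_dipole_table(r = seq(3, 15, by = 1), n_orient = 20,
                             p_i = p, p_j = p)
  uh <- mfcg:::.fib_sphere(37)
  held <- 0; nh <- 0
  for (r in c(4, 6.5, 9, 12)) {
    for (k in seq(1, 36, by = 4)) {
      ui <- uh[k, ]; uj <- uh[k + 1, ]
      pred <- fit$predict(ui, uj, r)
      truth <- mean_field_dipole_energy(c(r, 0, 0), ui, uj, p, p)
      held <- held + (pred - truth)^2; nh <- nh + 1
    }
  }
  expect_lt(sqrt(held / nh), 2 * fit$rmse + 1e-8)
  ## tabulated energies symmetric under swapping the sites
  expect_equal(
    mean_field_dipole_energy(c(5, 0, 0), c(0, 0, 1), c(0.6, 0.8, 0), p, p),
    mean_field_dipole_energy(c(-5, 0, 0), c(0.6, 0.8, 0), c(0, 0, 1), p, p),
    tolerance = 1e-12)
  ## table/coefficient dumps are plain text
  tf <- tempfile(fileext = ".tsv"); yf <- tempfile(fileext = ".yaml")
  write_dipole_table(fit0, tf)
  write_dipole_coef(fit0, yf)
  expect_true(file.exists(tf) && file.exists(yf))
  tab <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_true(all(c("r", "U") %in% names(tab)))
})
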