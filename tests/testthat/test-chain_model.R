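test_that("topology counting rules hold for all three chain classes", {
  ## worked examples
  tp <- build_topology("AAA", "protein")
  expect_equal(tp$n_anchor, 3)           # 3 CA anchors
  expect_equal(nrow(tp$branches), 3)     # 3 side chains
  expect_equal(nrow(tp$mids), 2)         # 2 peptide sites
  tn <- build_topology("ACGT", "nucleic_acid")
  expect_equal(tn$n_anchor, 4)           # 4 sugar anchors
  expect_equal(nrow(tn$branches), 4)     # 4 bases
  expect_equal(nrow(tn$mids), 3)         # P sites between consecutive S
  ts <- build_topology("aaab", "polysaccharide")
  expect_equal(nrow(ts$mids), 4)         # one ring site per unit
  expect_equal(ts$n_anchor, 5)           # n + 1 glycosidic oxygens

  ## property: counts for random sequences and chain counts
  set.seed(42)
  alph <- list(protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
               nucleic_acid = c("A", "C", "G", "T", "U"),
               polysaccharide = c("a", "b"))
  for (model in names(alph)) {
    for (rep in 1:5) {
      nch <- sample(1:3, 1)
      lens <- sample(2:8, nch, replace = TRUE)
      seqs <- vapply(lens, function(l)
        paste(sample(alph[[model]], l, replace = TRUE), collapse = ""), "")
      tp <- build_topology(seqs, model)
      n <- sum(lens)
      if (model == "polysaccharide") {
        expect_equal(tp$n_anchor, n + nch)
        expect_equal(nrow(tp$branches), 0)
      } else {
        expect_equal(tp$n_anchor, n)
        expect_equal(nrow(tp$branches), n)
      }
      expect_equal(nrow(tp$mids),
                   if (model == "nucleic_acid") n - nch else
                     if (model == "protein") n - nch else n)
      ## anchors form a connected path per chain
      expect_equal(nrow(tp$bonds), tp$n_anchor - nch)
    }
  }
})

test_that("invalid sequences are rejected with position information", {
  expect_error(build_topology("", "protein"), "empty")
  expect_error(build_topology(character(0), "protein"), "empty")
  expect_error(build_topology("ACGX", "nucleic_acid"), "position 4")
  expect_error(build_topology("azb", "polysaccharide"), "'z' at position 2")
})

test_that("extended placement reproduces the equilibrium backbone geometry", {
  tp <- build_topology("AA", "protein")
  conf <- place_extended(tp)
  expect_equal(sqrt(sum((conf$anchors[2, ] - conf$anchors[1, ])^2)), 3.8,
               tolerance = 1e-12)
  ## cis-flagged peptide bond takes the 2.8 A equilibrium
  tpc <- build_topology("AA", "protein", cis = 1L)
  cc <- place_extended(tpc)
  expect_equal(sqrt(sum((cc$anchors[2, ] - cc$anchors[1, ])^2)), 2.8,
               tolerance = 1e-12)
  ## peptide sites are exact midpoints of flanking anchors
  tp5 <- build_topology("ARNDC", "protein")
  c5 <- place_extended(tp5)
  ds <- derived_sites(tp5, c5)
  expect_equal(ds$mid,
               0.5 * (c5$anchors[tp5$mids$a1, ] + c5$anchors[tp5$mids$a2, ]),
               tolerance = 1e-12)

  ## all-trans sugar chain matches an independent in-plane chain builder
  ## (compared through the rigid-motion-invariant distance matrix)
  tsg <- build_topology("aaa", "polysaccharide")
  cs <- place_extended(tsg)
  geom <- chain_geometry("polysaccharide")
  ref <- ref_extended_chain(4, geom$d0, geom$theta0_deg * pi / 180)
  expect_equal(as.matrix(dist(cs$anchors)), as.matrix(dist(ref)),
               tolerance = 1e-9)
})

test_that("internal/cartesian conversions are exact inverses", {
  set.seed(7)
  for (model in c("protein", "nucleic_acid", "polysaccharide")) {
    sq <- switch(model, protein = c("ARNDC", "GGK"),
                 nucleic_acid = "ACGTU", polysaccharide = "abab")
    tp <- build_topology(sq, model)
    nb <- nrow(tp$bonds); na <- nrow(tp$angles); nt <- nrow(tp$torsions)
    nbr <- nrow(tp$branches)
    ic <- new_internal(tp, d = runif(nb, 3, 5.5),
                       theta = runif(na, 1, 2.6),
                       gamma = runif(nt, -3, 3),
                       alpha = runif(nbr, 0.3, 2.8),
                       beta = runif(nbr, -3, 3),
                       d_branch = if (nbr) runif(nbr, 1.5, 4) else numeric())
    conf <- internal_to_cartesian(tp, ic)
    ic2 <- cartesian_to_internal(tp, conf)
    expect_equal(ic2$d, ic$d, tolerance = 1e-9)
    expect_equal(ic2$theta, ic$theta, tolerance = 1e-9)
    expect_equal(ic2$gamma, ic$gamma, tolerance = 1e-9)
    if (nbr) {
      expect_equal(ic2$alpha, ic$alpha, tolerance = 1e-9)
      expect_equal(sin(ic2$beta), sin(ic$beta), tolerance = 1e-9)
      expect_equal(ic2$d_branch, ic$d_branch, tolerance = 1e-9)
    }
    ## round trip in the other direction seats the chain exactly
    conf2 <- internal_to_cartesian(tp, ic2)
    expect_equal(conf2$anchors, conf$anchors, tolerance = 1e-9)
    if (nbr) expect_equal(conf2$branches, conf$branches, tolerance = 1e-9)
  }
})

test_that("all-trans dihedrals give a planar zig-zag", {
  tp <- build_topology("AAAAAA", "protein")
  ic <- new_internal(tp, d = rep(3.8, 5), theta = rep(2, 4),
                     gamma = rep(pi, 3), beta = rep(0, 6))
  conf <- internal_to_cartesian(tp, ic)
  ## all anchors coplanar: z-extent of the canonical frame is zero
  n <- svd(scale(conf$anchors, scale = FALSE))$d
  expect_lt(n[3], 1e-9)
})

test_that("dihedral sign convention: printed toy quadruple is cis (gamma = 0)", {
  tp <- build_topology("AAAA", "protein")
  conf <- structure(list(
    anchors = rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0)),
    branches = matrix(0, 4, 3)), class = "cg_conformation")
  conf$branches <- conf$anchors + 1.5  # arbitrary finite branches
  ic <- cartesian_to_internal(tp, conf)
  expect_equal(ic$gamma, 0, tolerance = 1e-12)
})

test_that("random conformations match a step-by-step vector-algebra oracle", {
  ## independent oracle: rebuild anchor positions bond by bond using
  ## rotation matrices, then compare pairwise distances
  set.seed(13)
  tp <- build_topology("AAAAAA", "protein")
  d <- runif(5, 3.4, 4.2); th <- runif(4, 1.2, 2.4); ga <- runif(3, -3, 3)
  ic <- new_internal(tp, d = d, theta = th, gamma = ga, beta = rep(0, 6))
  conf <- internal_to_cartesian(tp, ic)
  ## oracle: local-frame propagation
  X <- matrix(0, 6, 3)
  X[2, ] <- c(d[1], 0, 0)
  ez <- c(0, 0, 1)
  dir <- c(1, 0, 0)
  X[3, ] <- X[2, ] + d[2] * as.vector(rot_mat(ez, pi - th[1]) %*% dir)
  for (i in 4:6) {
    b1 <- X[i - 2, ] - X[i - 3, ]
    b2 <- X[i - 1, ] - X[i - 2, ]
    b2h <- b2 / sqrt(sum(b2^2))
    ## place i at the trans position, then rotate about b2 by (pi - gamma)
    ## with the right-handed convention
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n1 <- n1 / sqrt(sum(n1^2))
    m <- c(n1[2] * b2h[3] - n1[3] * b2h[2], n1[3] * b2h[1] - n1[1] * b2h[3],
           n1[1] * b2h[2] - n1[2] * b2h[1])
    thi <- th[i - 2]; gai <- ga[i - 3]
    X[i, ] <- X[i - 1, ] + d[i - 1] *
      (-cos(thi) * b2h + sin(thi) * (cos(gai) * m - sin(gai) * n1))
  }
  expect_equal(as.matrix(dist(conf$anchors)), as.matrix(dist(X)),
               tolerance = 1e-9)
  ## and the rebuilt internal coordinates of the oracle chain agree
  co <- structure(list(anchors = X, branches = conf$branches),
                  class = "cg_conformation")
  ico <- cartesian_to_internal(tp, co)
  expect_equal(ico$gamma, ga, tolerance = 1e-9)
})

test_that("internal coordinates and derived sites are rigid-motion invariant", {
  set.seed(5)
  sys <- perturbed_system("nucleic_acid")
  ic <- cartesian_to_internal(sys$top, sys$conf)
  R <- rot_mat(c(1, 2, -1), 0.83)
  moved <- rigid_move(sys$conf, R, c(5, -3, 11))
  ic2 <- cartesian_to_internal(sys$top, moved)
  expect_equal(ic2$d, ic$d, tolerance = 1e-9)
  expect_equal(ic2$theta, ic$theta, tolerance = 1e-9)
  expect_equal(ic2$gamma, ic$gamma, tolerance = 1e-9)
  expect_equal(ic2$alpha, ic$alpha, tolerance = 1e-9)
  ## derived midpoint sites are affine in the anchors: equivariant
  ds <- derived_sites(sys$top, sys$conf)
  ds2 <- derived_sites(sys$top, moved)
  expect_equal(ds2$mid,
               ds$mid %*% t(R) + matrix(c(5, -3, 11), nrow(ds$mid), 3,
                                        byrow = TRUE),
               tolerance = 1e-9)
})

test_that("degenerate geometries raise errors", {
  tp <- build_topology("AAAA", "protein")
  expect_error(new_internal(tp, d = c(3.8, 0, 3.8), theta = rep(2, 2),
                            gamma = 0), "positive")
  expect_error(new_internal(tp, d = rep(3.8, 3), theta = c(2, pi),
                            gamma = 0), "\\(0, pi\\)")
  ic <- new_internal(tp, d = rep(3.8, 3), theta = c(2, 1e-12), gamma = 0)
  expect_error(internal_to_cartesian(tp, ic), "degenerate")
  conf <- place_extended(tp)
  conf$anchors[2, ] <- conf$anchors[1, ]
  expect_error(cartesian_to_internal(tp, conf), "zero-length")
})
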