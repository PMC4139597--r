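## Assembly and evaluation of the full chain energy functions.
##
## A "system" binds a topology to a force field: all per-term parameter
## lookups are resolved once into flat index/parameter tables, and the
## energy/force evaluators then work on a single stacked coordinate matrix
## (anchors first, then branch sites).
##
## Force evaluation is split into a *fast* part (virtual-bond stretching,
## angle bending, torsions - analytic gradients) and a *slow* part (all
## nonbonded/mean-field/correlation/rotamer/double-torsion terms - gradients
## by vectorised central differences on the defining points of each pair
## term, using translation invariance for the last point). The split feeds
## the multiple-time-step integrator.

## ---------------------------------------------------------------------------
## vectorised geometry helpers on point-index matrices

.row_perp <- function(u) {
  ## orthonormal completion of unit rows u -> e1, e2 (right-handed with u)
  n <- nrow(u)
  ref <- matrix(0, n, 3)
  ref[cbind(seq_len(n), max.col(-abs(u), ties.method = "first"))] <- 1
  e1 <- ref - row_dot(ref, u) * u
  e1 <- e1 / row_norm(e1)
  list(e1 = e1, e2 = row_cross(u, e1))
}

## mean-field dipole pair energy, second-order cumulant, vectorised.
## si, sj: site positions; ui, uj: unit axes; mp*, ms*: mu_par, mu_perp.
.dip2_rows <- function(si, sj, ui, uj, mpi, msi, mpj, msj, eps_r, rt0, cap,
                       rcore = 0) {
  rv <- sj - si
  r <- row_norm(rv)
  rh <- rv / r
  reff <- sqrt(r^2 + rcore^2)
  k <- .COUL / (eps_r * reff^3)
  fi <- .row_perp(ui); fj <- .row_perp(uj)
  Ei <- list(ui, fi$e1, fi$e2)
  Ej <- list(uj, fj$e1, fj$e2)
  mi <- list(mpi, msi, msi)
  mj <- list(mpj, msj, msj)
  ai <- lapply(Ei, function(e) row_dot(e, rh))
  aj <- lapply(Ej, function(e) row_dot(e, rh))
  w <- c(1, 0.5, 0.5)
  mean_e <- 0; second <- 0
  for (p in 1:3) for (q in 1:3) {
    cpq <- k * mi[[p]] * mj[[q]] *
      (row_dot(Ei[[p]], Ej[[q]]) - 3 * ai[[p]] * aj[[q]])
    if (p == 1 && q == 1) mean_e <- cpq
    second <- second + w[p] * w[q] * cpq^2
  }
  u <- mean_e - (second - mean_e^2) / (2 * rt0)
  pmax(pmin(u, cap), -cap)
}

## Gay-Berne, vectorised, per-row chi (isotropic rows have chi = 0 and a
## dummy axis)
.gb_rows <- function(si, sj, ui, uj, eps0, sig0, chi, chip, cap) {
  rv <- sj - si
  r <- row_norm(rv)
  rh <- rv / r
  .gb_core(r, row_dot(rh, ui), row_dot(rh, uj), row_dot(ui, uj),
           eps0, sig0, chi, chip, cap)
}

## unit axis of rows b - a, with dummy axis where |b - a| ~ 0 (zero-offset
## branches, which are isotropic by construction)
.axis_rows <- function(a, b) {
  v <- b - a
  n <- row_norm(v)
  bad <- n < 1e-9
  if (any(bad)) { v[bad, ] <- rep(c(1, 0, 0), each = sum(bad)); n[bad] <- 1 }
  v / n
}

## ---------------------------------------------------------------------------
## slow-term class evaluators: efun(pts, par) -> per-row energies, where pts
## is a list of m x 3 matrices (one per defining point)

.r_ef_gb_branch <- function(pts, par) {
  .gb_rows(pts[[2]], pts[[4]],
           .axis_rows(pts[[1]], pts[[2]]), .axis_rows(pts[[3]], pts[[4]]),
           par$eps0, par$sig0, par$chi, par$chip, par$cap)
}

.r_ef_gb_mid <- function(pts, par) {
  .gb_rows(0.5 * (pts[[1]] + pts[[2]]), 0.5 * (pts[[3]] + pts[[4]]),
           .axis_rows(pts[[1]], pts[[2]]), .axis_rows(pts[[3]], pts[[4]]),
           par$eps0, par$sig0, par$chi, par$chip, par$cap)
}

.r_ef_dip_mid <- function(pts, par) {
  si <- 0.5 * (pts[[1]] + pts[[2]]); sj <- 0.5 * (pts[[3]] + pts[[4]])
  u <- .dip2_rows(si, sj,
                  .axis_rows(pts[[1]], pts[[2]]), .axis_rows(pts[[3]], pts[[4]]),
                  par$mpi, par$msi, par$mpj, par$msj, par$eps_r, par$rt0,
                  par$cap, par$rcore %||% 0)
  .dip_ev(u, si, sj, par)
}

.r_ef_dip_branch <- function(pts, par) {
  u <- .dip2_rows(pts[[2]], pts[[4]],
                  .axis_rows(pts[[1]], pts[[2]]), .axis_rows(pts[[3]], pts[[4]]),
                  par$mpi, par$msi, par$mpj, par$msj, par$eps_r, par$rt0,
                  par$cap, par$rcore %||% 0)
  .dip_ev(u, pts[[2]], pts[[4]], par)
}

## repulsive excluded-volume core of the polar sites (plain dipole classes)
.dip_ev <- function(u, si, sj, par) {
  ev <- par$ev_eps %||% 0
  if (ev <= 0) return(u)
  pmin(u + 4 * ev * (par$ev_sigma / row_norm(sj - si))^12, par$cap)
}

.r_ef_dh <- function(pts, par) {
  r <- row_norm(0.5 * (pts[[3]] + pts[[4]]) - 0.5 * (pts[[1]] + pts[[2]]))
  pmin(par$pref * exp(-par$kappa * r) / r, par$cap)
}

## excluded volume between a point site (pts[[1]]) and a midpoint site
.r_ef_lj_pm <- function(pts, par) {
  r <- row_norm(0.5 * (pts[[2]] + pts[[3]]) - pts[[1]])
  s6 <- (par$sigma / r)^6
  pmin(4 * par$eps * (s6^2 - s6), par$cap)
}

.r_ef_tord <- function(pts, par) {
  g1 <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  g2 <- dihedral_angle(pts[[2]], pts[[3]], pts[[4]], pts[[5]])
  u <- 0
  for (k in seq_along(par$a)) {
    u <- u + par$a[k] * cos(k * g1) * cos(k * g2) +
      par$b[k] * sin(k * g1) * sin(k * g2)
  }
  u
}

.r_ef_rot <- function(pts, par) {
  ## pts: frame anchors f1, f2, f3, branch origin anchor, branch site
  m <- nrow(pts[[1]])
  e1 <- e2 <- e3 <- matrix(0, m, 3)
  full <- !par$two
  if (any(full)) {
    u <- row_unit(pts[[2]][full, , drop = FALSE] - pts[[1]][full, , drop = FALSE])
    v <- row_unit(pts[[3]][full, , drop = FALSE] - pts[[2]][full, , drop = FALSE])
    dd <- u - v; ss <- u + v
    e1[full, ] <- dd / row_norm(dd)
    e2[full, ] <- ss / row_norm(ss)
    e3[full, ] <- row_cross(e1[full, , drop = FALSE], e2[full, , drop = FALSE])
  }
  for (b in which(par$two)) {
    u <- pts[[2]][b, ] - pts[[1]][b, ]
    u <- u / sqrt(sum(u^2))
    pf <- perp_frame(u)
    e1[b, ] <- pf$e1; e2[b, ] <- u
    e3[b, ] <- c(e1[b, 2] * u[3] - e1[b, 3] * u[2],
                 e1[b, 3] * u[1] - e1[b, 1] * u[3],
                 e1[b, 1] * u[2] - e1[b, 2] * u[1])
  }
  w <- pts[[5]] - pts[[4]]
  wn <- row_norm(w)
  wu <- w / wn
  al <- acos(clamp1(row_dot(wu, e1)))
  be <- atan2(row_dot(wu, e3), row_dot(wu, e2))
  u <- par$k_alpha * (al - par$alpha0)^2
  for (k in seq_along(par$beta_cos)) {
    u <- u + par$beta_cos[k] * cos(k * be) + par$beta_sin[k] * sin(k * be)
  }
  u
}

## third-order correlation: dipole kernel between the central bonds of two
## torsion quadruples, coupled to both torsional states
.r_ef_corr3 <- function(pts, par) {
  d <- .dip2_rows(0.5 * (pts[[2]] + pts[[3]]), 0.5 * (pts[[6]] + pts[[7]]),
                  .axis_rows(pts[[2]], pts[[3]]), .axis_rows(pts[[6]], pts[[7]]),
                  par$mpi, par$msi, par$mpj, par$msj, par$eps_r, par$rt0,
                  par$cap, par$rcore %||% 0)
  g1 <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  g2 <- dihedral_angle(pts[[5]], pts[[6]], pts[[7]], pts[[8]])
  par$c * d * cos(g1) * cos(g2)
}

## third-order turn term: dipole kernel of the two bonds flanking one anchor
.r_ef_turn3 <- function(pts, par) {
  par$c * .dip2_rows(0.5 * (pts[[1]] + pts[[2]]), 0.5 * (pts[[2]] + pts[[3]]),
                     .axis_rows(pts[[1]], pts[[2]]),
                     .axis_rows(pts[[2]], pts[[3]]),
                     par$mpi, par$msi, par$mpj, par$msj, par$eps_r, par$rt0,
                     par$cap, par$rcore %||% 0)
}

## fourth-order turn term: dipole kernel of bonds (i, i+2) of a torsion
## quadruple, coupled to the spanned dihedral
.r_ef_turn4 <- function(pts, par) {
  d <- .dip2_rows(0.5 * (pts[[1]] + pts[[2]]), 0.5 * (pts[[3]] + pts[[4]]),
                  .axis_rows(pts[[1]], pts[[2]]), .axis_rows(pts[[3]], pts[[4]]),
                  par$mpi, par$msi, par$mpj, par$msj, par$eps_r, par$rt0,
                  par$cap, par$rcore %||% 0)
  g <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  par$c * d * cos(g)
}

## ---------------------------------------------------------------------------
## compiled-kernel class ids (see src/engine.cpp); the .r_ef_* functions
## above are the reference implementations, cross-checked in the test suite

.CLASS_ID <- c(gb_branch = 1L, gb_mid = 2L, dip_branch = 3L, dip_mid = 4L,
               dh = 5L, lj_pm = 6L, tord = 7L, rot = 8L, corr3 = 9L,
               turn3 = 10L, turn4 = 11L)

## R reference evaluator for each class kind (used by tests)
.r_ef_of <- function(kind) {
  switch(kind,
         gb_branch = .r_ef_gb_branch, gb_mid = .r_ef_gb_mid,
         dip_branch = .r_ef_dip_branch, dip_mid = .r_ef_dip_mid,
         dh = .r_ef_dh, lj_pm = .r_ef_lj_pm, tord = .r_ef_tord,
         rot = .r_ef_rot, corr3 = .r_ef_corr3, turn3 = .r_ef_turn3,
         turn4 = .r_ef_turn4)
}

## ---------------------------------------------------------------------------
## pair-list construction helpers

.all_pairs <- function(n) {
  if (n < 2) return(cbind(i = integer(), j = integer()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, 1], j = idx[, 2])
}

## pairs of rows of a per-chain-indexed table with a minimum same-chain
## separation (cross-chain pairs always included)
.sep_pairs <- function(chain, local, min_sep) {
  pr <- .all_pairs(length(chain))
  if (!nrow(pr)) return(pr)
  keep <- chain[pr[, 1]] != chain[pr[, 2]] |
    abs(local[pr[, 2]] - local[pr[, 1]]) >= min_sep
  pr[keep, , drop = FALSE]
}

## local (within-chain) index of every bond / angle / torsion row
.local_index <- function(chain_col) {
  unlist(lapply(split(seq_along(chain_col), chain_col),
                seq_along), use.names = FALSE)[order(order(chain_col))]
}

## ---------------------------------------------------------------------------
## system assembly

cg_system <- function(topology, ff) {
  stopifnot(inherits(topology, "cg_topology"))
  if (!inherits(ff, "cg_forcefield")) stop("need a cg_forcefield")
  if (!identical(ff$model, topology$model))
    stop("force field / topology model mismatch")
  model <- topology$model
  na <- topology$n_anchor
  br <- topology$branches
  nb <- nrow(br)
  bp <- bonded_params(topology, ff)
  cap <- ff$cap
  rt0 <- .RGAS * ff$T0

  ## --- fast (stiff local) tables -----------------------------------------
  bonds <- data.frame(i = topology$bonds$i, j = topology$bonds$j,
                      d0 = bp$d0, k = bp$k_bond)
  if (nb && any(!br$riding)) {
    live <- !br$riding
    bonds <- rbind(bonds, data.frame(i = br$anchor[live],
                                     j = na + which(live),
                                     d0 = bp$db0[live],
                                     k = rep(bp$k_branch, sum(live))))
  }
  angles <- if (nrow(topology$angles)) {
    cbind(as.matrix(topology$angles), theta0 = bp$theta0,
          kth = rep_len(bp$k_theta, nrow(topology$angles)))
  } else {
    matrix(numeric(0), 0, 5,
           dimnames = list(NULL, c("i", "j", "k", "theta0", "kth")))
  }
  torsions <- list(idx = as.matrix(topology$torsions),
                   a = bp$tor_a, b = bp$tor_b)

  ## --- slow classes -------------------------------------------------------
  bnd <- topology$bonds
  bnd_local <- .local_index(bnd$chain)
  classes <- list()
  add_class <- function(term, kind, pts_idx, par) {
    if (nrow(pts_idx) == 0) return()
    par$cap <- cap
    storage.mode(pts_idx) <- "integer"
    classes[[length(classes) + 1L]] <<-
      list(term = term, kind = kind, id = .CLASS_ID[[kind]],
           pts = pts_idx, par = par)
  }
  dip_par <- function(codes_i, codes_j, ev = FALSE) {
    s <- ff$dipole$sites
    out <- list(mpi = vapply(codes_i, function(cd) s[[cd]]$mu_par, 0),
                msi = vapply(codes_i, function(cd) s[[cd]]$mu_perp, 0),
                mpj = vapply(codes_j, function(cd) s[[cd]]$mu_par, 0),
                msj = vapply(codes_j, function(cd) s[[cd]]$mu_perp, 0),
                eps_r = ff$dipole$eps_r %||% 1, rt0 = rt0,
                rcore = ff$dipole$r_core %||% 3.0)
    if (ev) {
      out$ev_eps <- ff$dipole$ev_eps %||% 0
      out$ev_sigma <- ff$dipole$ev_sigma %||% 0
    }
    out
  }
  gb_par <- function(codes_i, codes_j, iso = NULL) {
    ei <- unlist(ff$gay_berne$eps)[codes_i]
    ej <- unlist(ff$gay_berne$eps)[codes_j]
    si <- unlist(ff$gay_berne$sigma)[codes_i]
    sj <- unlist(ff$gay_berne$sigma)[codes_j]
    chi <- rep(ff$gay_berne$chi %||% 0, length(ei))
    chip <- rep(ff$gay_berne$chip %||% 0, length(ei))
    if (!is.null(iso)) { chi[iso] <- 0; chip[iso] <- 0 }
    list(eps0 = unname(sqrt(ei * ej)), sig0 = unname((si + sj) / 2),
         chi = chi, chip = chip)
  }

  if (model == "protein") {
    ## side chain - side chain (Gay-Berne, branch sites)
    pr <- .all_pairs(nb)
    iso <- br$riding[pr[, 1]] | br$riding[pr[, 2]]
    add_class("SCSC", "gb_branch",
              cbind(br$anchor[pr[, 1]], na + pr[, 1],
                    br$anchor[pr[, 2]], na + pr[, 2]),
              gb_par(br$code[pr[, 1]], br$code[pr[, 2]], iso))
    ## side chain - peptide group excluded volume
    sc <- rep(seq_len(nb), each = nrow(bnd))
    pb <- rep(seq_len(nrow(bnd)), nb)
    keep <- bnd$i[pb] != br$anchor[sc] & bnd$j[pb] != br$anchor[sc]
    add_class("SCp", "lj_pm",
              cbind(na + sc[keep], bnd$i[pb[keep]], bnd$j[pb[keep]]),
              list(eps = ff$excluded$eps, sigma = ff$excluded$sigma))
    ## peptide - peptide mean-field dipole term (skips adjacent bonds)
    pp <- .sep_pairs(bnd$chain, bnd_local, 2L)
    add_class("el", "dip_mid",
              cbind(bnd$i[pp[, 1]], bnd$j[pp[, 1]],
                    bnd$i[pp[, 2]], bnd$j[pp[, 2]]),
              dip_par(rep("p", nrow(pp)), rep("p", nrow(pp)), ev = TRUE))
    ## correlation / turn terms
    tor <- topology$torsions
    tor_chain <- topology$anchors$chain[tor$j]
    tor_local <- .local_index(tor_chain)
    tc <- .sep_pairs(tor_chain, tor_local, 2L)  # torsion pairs
    if (nrow(tc)) {
      add_class("corr3", "corr3",
                cbind(tor$i[tc[, 1]], tor$j[tc[, 1]], tor$k[tc[, 1]], tor$l[tc[, 1]],
                      tor$i[tc[, 2]], tor$j[tc[, 2]], tor$k[tc[, 2]], tor$l[tc[, 2]]),
                c(dip_par(rep("p", nrow(tc)), rep("p", nrow(tc))),
                  list(c = ff$correlation$corr3)))
    }
    ang <- topology$angles
    add_class("turn3", "turn3", as.matrix(ang),
              c(dip_par(rep("p", nrow(ang)), rep("p", nrow(ang))),
                list(c = ff$correlation$turn3)))
    add_class("turn4", "turn4", as.matrix(tor),
              c(dip_par(rep("p", nrow(tor)), rep("p", nrow(tor))),
                list(c = ff$correlation$turn4)))
  } else if (model == "nucleic_acid") {
    ## base - base Gay-Berne and mean-field electrostatic terms
    pr <- .all_pairs(nb)
    pts_bb <- cbind(br$anchor[pr[, 1]], na + pr[, 1],
                    br$anchor[pr[, 2]], na + pr[, 2])
    add_class("BB_GB", "gb_branch", pts_bb,
              gb_par(br$code[pr[, 1]], br$code[pr[, 2]]))
    add_class("BB_el", "dip_branch", pts_bb,
              dip_par(br$code[pr[, 1]], br$code[pr[, 2]], ev = TRUE))
    ## phosphate - phosphate Debye-Hueckel (midpoint sites)
    dh <- ff$debye_huckel
    kap <- kappa_from_ionic_strength(dh$ionic_strength %||% 0.1,
                                     dh$eps_r %||% 80, ff$T0)
    pp <- .sep_pairs(bnd$chain, bnd_local, 1L)
    add_class("PP", "dh",
              cbind(bnd$i[pp[, 1]], bnd$j[pp[, 1]],
                    bnd$i[pp[, 2]], bnd$j[pp[, 2]]),
              list(pref = .COUL * dh$charge^2 / (dh$eps_r %||% 80),
                   kappa = kap))
    ## phosphate - base excluded volume (skip the two flanking nucleotides)
    bs <- rep(seq_len(nb), each = nrow(bnd))
    pb <- rep(seq_len(nrow(bnd)), nb)
    keep <- bnd$i[pb] != br$anchor[bs] & bnd$j[pb] != br$anchor[bs]
    add_class("PB", "lj_pm",
              cbind(na + bs[keep], bnd$i[pb[keep]], bnd$j[pb[keep]]),
              list(eps = ff$excluded$eps, sigma = ff$excluded$sigma))
  } else {  # polysaccharide
    codes <- topology$mids$code
    pp <- .sep_pairs(bnd$chain, bnd_local, 2L)
    pts_ss <- cbind(bnd$i[pp[, 1]], bnd$j[pp[, 1]],
                    bnd$i[pp[, 2]], bnd$j[pp[, 2]])
    add_class("SS_GB", "gb_mid", pts_ss,
              gb_par(codes[pp[, 1]], codes[pp[, 2]]))
    add_class("SS_el", "dip_mid", pts_ss,
              dip_par(codes[pp[, 1]], codes[pp[, 2]], ev = TRUE))
    tor <- topology$torsions
    tor_chain <- topology$anchors$chain[tor$j]
    tor_local <- .local_index(tor_chain)
    tc <- .sep_pairs(tor_chain, tor_local, 2L)
    if (nrow(tor) >= 1 && nrow(tc)) {
      ctr <- match(tor$j, bnd$i)  # central bond row of each quadruple
      add_class("corr3", "corr3",
                cbind(tor$i[tc[, 1]], tor$j[tc[, 1]], tor$k[tc[, 1]], tor$l[tc[, 1]],
                      tor$i[tc[, 2]], tor$j[tc[, 2]], tor$k[tc[, 2]], tor$l[tc[, 2]]),
                c(dip_par(codes[ctr[tc[, 1]]], codes[ctr[tc[, 2]]]),
                  list(c = ff$correlation$corr3)))
    }
    ang <- topology$angles
    b1 <- match(ang$i, bnd$i); b2 <- match(ang$j, bnd$i)
    add_class("turn3", "turn3", as.matrix(ang),
              c(dip_par(codes[b1], codes[b2]),
                list(c = ff$correlation$turn3)))
  }

  ## rotamer class (protein SC and nucleic B local states)
  if (nb && !is.null(bp$rot)) {
    live <- which(!br$riding)
    if (length(live)) {
      fr <- topology$branch_frames[live, , drop = FALSE]
      two <- is.na(fr$f3)
      lone <- is.na(fr$f2)
      use <- !lone
      if (any(use)) {
        f3 <- ifelse(is.na(fr$f3[use]), fr$f2[use], fr$f3[use])
        add_class("rot", "rot",
                  cbind(fr$f1[use], fr$f2[use], f3,
                        br$anchor[live[use]], na + live[use]),
                  list(two = two[use],
                       k_alpha = bp$rot$k_alpha[live[use]],
                       alpha0 = bp$rot$alpha0[live[use]],
                       beta_cos = bp$rot$beta_cos,
                       beta_sin = bp$rot$beta_sin))
      }
    }
  }
  ## double-torsion class (protein): consecutive torsion quadruples
  if (model == "protein" && length(bp$tord_a)) {
    tor <- topology$torsions
    tor_local <- .local_index(rep(seq_len(topology$n_chain),
                                  pmax(topology$per_chain_anchor - 3L, 0L)))
    first <- which(tor_local[-1] == tor_local[-nrow(tor)] + 1L)
    if (length(first)) {
      add_class("tord", "tord",
                cbind(tor$i[first], tor$j[first], tor$k[first], tor$l[first],
                      tor$l[first + 1L]),
                list(a = bp$tord_a, b = bp$tord_b))
    }
  }

  ## term bookkeeping: weights and temperature-multiplier orders
  wmap <- switch(model,
    protein = c(SCSC = "SCSC", SCp = "SCp", el = "el", tor = "tor",
                tord = "tord", b = "b", rot = "rot", corr3 = "corr3",
                turn3 = "turn3", turn4 = "turn4", bond = "bond"),
    nucleic_acid = c(BB_GB = "BB_GB", BB_el = "BB_el", PP = "PP", PB = "PB",
                     bond = "bond", b = "b", tor = "tor", rot = "rot"),
    polysaccharide = c(SS_GB = "SS_GB", SS_el = "SS_el", corr3 = "corr3",
                       turn3 = "turn3", corr4 = "w4", bond = "bond",
                       b = "b", tor = "tor"))
  forder <- switch(model,
    protein = c(SCSC = 1, SCp = 1, el = 2, tor = 2, tord = 3, b = 1, rot = 1,
                corr3 = 3, turn3 = 3, turn4 = 4, bond = 1),
    nucleic_acid = c(BB_GB = 1, BB_el = 1, PP = 1, PB = 1, bond = 1, b = 1,
                     tor = 2, rot = 1),
    polysaccharide = c(SS_GB = 1, SS_el = 2, corr3 = 3, turn3 = 3, corr4 = 1,
                       bond = 1, b = 1, tor = 2))
  weights <- vapply(names(wmap), function(t) ff$weights[[wmap[[t]]]] %||% 0,
                    0)

  ## masses (amu) per stacked site; zero-offset branches ride their anchor
  m_anchor <- rep(ff$masses$anchor %||% 100, na)
  m_branch <- if (nb) {
    vapply(br$code, function(cd) ff$masses$branch[[cd]] %||% 20, 0)
  } else numeric()
  structure(list(
    model = model, topology = topology, ff = ff,
    na = na, nb = nb, nsite = na + nb,
    bonds = bonds, angles = angles, torsions = torsions,
    classes = classes, weights = weights, forder = forder, T0 = ff$T0,
    cap = cap, masses = unname(c(m_anchor, m_branch)),
    riding = if (nb) br$riding else logical(),
    branch_anchor = if (nb) br$anchor else integer()
  ), class = "cg_system")
}

## ---------------------------------------------------------------------------
## energy evaluation on the stacked coordinate matrix

.fast_energy <- function(sys, X) {
  b <- sys$bonds
  d <- row_norm(X[b$j, , drop = FALSE] - X[b$i, , drop = FALSE])
  u_bond <- sum(b$k * (d - b$d0)^2)
  u_b <- 0
  if (nrow(sys$angles)) {
    a <- sys$angles
    th <- bend_angle(X[a[, 1], , drop = FALSE], X[a[, 2], , drop = FALSE],
                     X[a[, 3], , drop = FALSE])
    u_b <- sum(a[, "kth"] * (th - a[, "theta0"])^2)
  }
  u_tor <- 0
  if (nrow(sys$torsions$idx)) {
    tx <- sys$torsions$idx
    g <- dihedral_angle(X[tx[, 1], , drop = FALSE], X[tx[, 2], , drop = FALSE],
                        X[tx[, 3], , drop = FALSE], X[tx[, 4], , drop = FALSE])
    kk <- seq_len(ncol(sys$torsions$a))
    u_tor <- sum(cos(outer(g, kk)) * sys$torsions$a) +
      sum(sin(outer(g, kk)) * sys$torsions$b)
  }
  c(bond = u_bond, b = u_b, tor = u_tor)
}

.slow_energy <- function(sys, X) {
  out <- numeric(0)
  for (cl in sys$classes) {
    e <- sum(.cpp_class_energy(cl$id, X, cl$pts, cl$par))
    prev <- if (cl$term %in% names(out)) out[[cl$term]] else 0
    out[cl$term] <- prev + e
  }
  out
}

sys_energy_terms <- function(sys, X) {
  terms <- structure(numeric(length(sys$weights)), names = names(sys$weights))
  fe <- .fast_energy(sys, X)
  terms[names(fe)] <- fe
  se <- .slow_energy(sys, X)
  terms[names(se)] <- terms[names(se)] + se
  terms
}

sys_total <- function(sys, terms, T) {
  f <- ifelse(sys$forder > 1,
              temperature_multiplier(pmax(sys$forder, 2), T, sys$T0), 1)
  sum(sys$weights * f * terms)
}

## ---------------------------------------------------------------------------
## forces

## analytic gradients of the fast terms (compiled); returns dU/dX
.fast_grad <- function(sys, X) {
  b <- sys$bonds
  a <- sys$angles
  tx <- sys$torsions$idx
  .cpp_fast_grad(X, b$i, b$j, b$d0, b$k,
                 if (nrow(a)) a[, 1] else integer(),
                 if (nrow(a)) a[, 2] else integer(),
                 if (nrow(a)) a[, 3] else integer(),
                 if (nrow(a)) a[, "theta0"] else numeric(),
                 if (nrow(a)) a[, "kth"] else numeric(),
                 if (nrow(tx)) tx[, 1] else integer(),
                 if (nrow(tx)) tx[, 2] else integer(),
                 if (nrow(tx)) tx[, 3] else integer(),
                 if (nrow(tx)) tx[, 4] else integer(),
                 sys$torsions$a, sys$torsions$b)
}

## pure-R reference implementation of the same gradient
.fast_grad_r <- function(sys, X) {
  G <- matrix(0, nrow(X), 3)
  b <- sys$bonds
  rv <- X[b$j, , drop = FALSE] - X[b$i, , drop = FALSE]
  d <- row_norm(rv)
  if (any(d < 1e-9)) stop("coincident bonded sites")
  coef <- 2 * b$k * (d - b$d0) / d
  gb <- coef * rv
  for (c_i in 1:3) {
    G[, c_i] <- G[, c_i] + .scatter(nrow(X), b$j, gb[, c_i]) -
      .scatter(nrow(X), b$i, gb[, c_i])
  }
  ## angles
  if (nrow(sys$angles)) {
    a <- sys$angles
    p1 <- X[a[, 1], , drop = FALSE]; p2 <- X[a[, 2], , drop = FALSE]
    p3 <- X[a[, 3], , drop = FALSE]
    u <- p1 - p2; v <- p3 - p2
    nu <- row_norm(u); nv <- row_norm(v)
    uh <- u / nu; vh <- v / nv
    ct <- clamp1(row_dot(uh, vh))
    th <- acos(ct)
    st <- sqrt(pmax(1 - ct^2, 1e-12))
    dEdth <- 2 * a[, "kth"] * (th - a[, "theta0"])
    g1 <- dEdth / (nu * st) * (ct * uh - vh)
    g3 <- dEdth / (nv * st) * (ct * vh - uh)
    for (c_i in 1:3) {
      G[, c_i] <- G[, c_i] + .scatter(nrow(X), a[, 1], g1[, c_i]) +
        .scatter(nrow(X), a[, 3], g3[, c_i]) -
        .scatter(nrow(X), a[, 2], g1[, c_i] + g3[, c_i])
    }
  }
  ## torsions
  if (nrow(sys$torsions$idx)) {
    tx <- sys$torsions$idx
    p1 <- X[tx[, 1], , drop = FALSE]; p2 <- X[tx[, 2], , drop = FALSE]
    p3 <- X[tx[, 3], , drop = FALSE]; p4 <- X[tx[, 4], , drop = FALSE]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
    n1s <- row_dot(n1, n1); n2s <- row_dot(n2, n2)
    if (any(n1s < 1e-16) || any(n2s < 1e-16)) {
      bad <- which(n1s < 1e-16 | n2s < 1e-16)[1]
      stop(sprintf("degenerate torsion geometry at anchors %d-%d-%d-%d",
                   tx[bad, 1], tx[bad, 2], tx[bad, 3], tx[bad, 4]))
    }
    nb2 <- row_norm(b2)
    g <- dihedral_angle(p1, p2, p3, p4)
    kk <- seq_len(ncol(sys$torsions$a))
    cosg <- cos(outer(g, kk)); sing <- sin(outer(g, kk))
    kmat <- matrix(kk, nrow(tx), length(kk), byrow = TRUE)
    dEdg <- rowSums(-sys$torsions$a * kmat * sing +
                    sys$torsions$b * kmat * cosg)
    dgd1 <- (nb2 / n1s) * n1
    dgd4 <- -(nb2 / n2s) * n2
    f1 <- row_dot(b1, b2) / (nb2^2)
    f2 <- row_dot(b3, b2) / (nb2^2)
    dgd2 <- -(1 + f1) * dgd1 + f2 * dgd4
    dgd3 <- f1 * dgd1 - (1 + f2) * dgd4
    for (c_i in 1:3) {
      G[, c_i] <- G[, c_i] +
        .scatter(nrow(X), tx[, 1], dEdg * dgd1[, c_i]) +
        .scatter(nrow(X), tx[, 2], dEdg * dgd2[, c_i]) +
        .scatter(nrow(X), tx[, 3], dEdg * dgd3[, c_i]) +
        .scatter(nrow(X), tx[, 4], dEdg * dgd4[, c_i])
    }
  }
  G
}

.scatter <- function(n, idx, val) {
  out <- numeric(n)
  s <- rowsum(val, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s
  out
}

## central-difference gradient of one slow class (compiled driver)
.class_grad <- function(cl, X, weight, h = 1e-6) {
  G <- matrix(0, nrow(X), 3)
  .cpp_class_grad(cl$id, X, cl$pts, cl$par, weight, h, G)
  G
}

## pure-R reference version of the same driver (uses the .r_ef_* evaluators)
.class_grad_r <- function(cl, X, weight, h = 1e-6) {
  cl$efun <- .r_ef_of(cl$kind)
  k <- ncol(cl$pts)
  pts <- lapply(seq_len(k), function(c_i) X[cl$pts[, c_i], , drop = FALSE])
  m <- nrow(cl$pts)
  G <- matrix(0, nrow(X), 3)
  glast <- matrix(0, m, 3)
  for (p in seq_len(k - 1L)) {
    gp <- matrix(0, m, 3)
    for (c_i in 1:3) {
      pp <- pts
      pp[[p]][, c_i] <- pp[[p]][, c_i] + h
      ep <- cl$efun(pp, cl$par)
      pp[[p]][, c_i] <- pp[[p]][, c_i] - 2 * h
      em <- cl$efun(pp, cl$par)
      gp[, c_i] <- (ep - em) / (2 * h)
    }
    glast <- glast - gp
    for (c_i in 1:3)
      G[, c_i] <- G[, c_i] + .scatter(nrow(X), cl$pts[, p], weight * gp[, c_i])
  }
  for (c_i in 1:3)
    G[, c_i] <- G[, c_i] + .scatter(nrow(X), cl$pts[, k], weight * glast[, c_i])
  G
}

sys_gradient <- function(sys, X, T, parts = c("all", "fast", "slow")) {
  parts <- match.arg(parts)
  f <- ifelse(sys$forder > 1,
              temperature_multiplier(pmax(sys$forder, 2), T, sys$T0), 1)
  wf <- sys$weights * f
  G <- matrix(0, nrow(X), 3)
  if (parts %in% c("all", "fast")) {
    ## fast terms share one analytic pass; scale bond/b/tor jointly only if
    ## their weighted multipliers coincide, otherwise compute separately
    Gf <- .fast_grad_weighted(sys, X, wf)
    G <- G + Gf
  }
  if (parts %in% c("all", "slow")) {
    for (cl in sys$classes) {
      if (wf[[cl$term]] == 0) next
      G <- G + .class_grad(cl, X, wf[[cl$term]])
    }
  }
  G
}

## fast gradient with per-term weights folded into the spring constants and
## Fourier coefficients
.fast_grad_weighted <- function(sys, X, wf) {
  sys2 <- sys
  sys2$bonds$k <- sys$bonds$k * wf[["bond"]]
  if (nrow(sys$angles)) sys2$angles[, "kth"] <- sys$angles[, "kth"] * wf[["b"]]
  sys2$torsions$a <- sys$torsions$a * wf[["tor"]]
  sys2$torsions$b <- sys$torsions$b * wf[["tor"]]
  .fast_grad(sys2, X)
}
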