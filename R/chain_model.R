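## Chain topologies and virtual-bond geometry for the three coarse-grained
## chain classes:
##   protein        - Calpha anchor trace, united peptide groups (p) at the
##                    bond midpoints, united side chains (SC) attached to the
##                    anchors;
##   nucleic_acid   - sugar-center (S) anchor trace, phosphate sites (P) at
##                    bond midpoints, base sites (B) attached to the anchors;
##   polysaccharide - glycosidic-oxygen (O) anchor trace with one sugar-ring
##                    site per unit lying between consecutive O anchors.

.CG_MODELS <- c("protein", "nucleic_acid", "polysaccharide")

.CG_ALPHABET <- list(
  protein        = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
  nucleic_acid   = c("A", "C", "G", "T", "U"),
  polysaccharide = c("a", "b")
)

.geometry_cache <- new.env(parent = emptyenv())

#' Chain-geometry constants table
#'
#' Reads the packaged geometry table (equilibrium virtual-bond lengths,
#' extended-state bond angles and dihedrals, branch virtual-bond lengths).
#' The protein backbone equilibrium lengths are 3.8 A (trans) and 2.8 A (cis).
#'
#' @param model one of `"protein"`, `"nucleic_acid"`, `"polysaccharide"`.
#' @return Named list of geometry constants for the model.
#' @export
chain_geometry <- function(model = .CG_MODELS) {
  model <- match.arg(model)
  if (is.null(.geometry_cache$tab)) {
    path <- system.file("extdata", "ff", "geometry.yaml", package = "mfcg")
    .geometry_cache$tab <- yaml::read_yaml(path)
  }
  .geometry_cache$tab[[model]]
}

#' Build a coarse-grained chain topology
#'
#' Constructs the anchor trace, interaction sites and virtual-bond index
#' tables for one or more chains. Proteins get one side-chain site per
#' residue (glycine as a zero-offset site) and one peptide site per backbone
#' bond; nucleic acids one base site per nucleotide and one phosphate site
#' midway between consecutive sugar anchors; polysaccharides one ring site
#' per unit between consecutive glycosidic-oxygen anchors.
#'
#' @param sequence character vector, one string of one-letter residue codes
#'   per chain (protein: amino acids; nucleic acid: A/C/G/T/U; sugar:
#'   "a" = alpha-D-glucose, "b" = beta-D-glucose, 1-4 linkage implied).
#' @param model chain class, one of `"protein"`, `"nucleic_acid"`,
#'   `"polysaccharide"`.
#' @param cis integer indices of protein backbone bonds (within the whole
#'   topology, in bond order) taking the cis equilibrium length 2.8 A.
#' @return An object of class `cg_topology`.
#' @export
build_topology <- function(sequence, model = .CG_MODELS, cis = integer()) {
  model <- match.arg(model)
  if (length(sequence) == 0L) stop("empty sequence")
  seqs <- lapply(sequence, function(s) strsplit(s, "")[[1]])
  if (any(lengths(seqs) == 0L)) stop("empty sequence")
  codes <- unlist(seqs)
  bad <- which(!(codes %in% .CG_ALPHABET[[model]]))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d for model '%s'",
                 codes[bad[1]], bad[1], model))
  }
  chain <- rep(seq_along(seqs), lengths(seqs))
  n_res <- length(codes)
  geom <- chain_geometry(model)

  ## anchors: one per residue, plus one extra terminal O per sugar chain
  if (model == "polysaccharide") {
    per_chain <- lengths(seqs) + 1L
  } else {
    per_chain <- lengths(seqs)
  }
  anchors <- data.frame(
    chain = rep(seq_along(seqs), per_chain),
    local = unlist(lapply(per_chain, seq_len))
  )
  n_anchor <- nrow(anchors)
  a_off <- c(0L, cumsum(per_chain))[seq_along(seqs)]  # anchor offset per chain

  ## residue -> anchor of attachment (protein/nucleic); sugar rings are
  ## midpoint sites between anchors res and res+1 of their chain
  res_local <- unlist(lapply(lengths(seqs), seq_len))
  res_anchor <- a_off[chain] + res_local

  ## branch sites (SC for protein, B for nucleic acid)
  if (model %in% c("protein", "nucleic_acid")) {
    d_b <- unname(unlist(geom$branch$lengths)[codes])
    branches <- data.frame(
      res = seq_len(n_res), code = codes, chain = chain,
      anchor = res_anchor, d_b = d_b, riding = d_b == 0
    )
  } else {
    branches <- data.frame(res = integer(), code = character(),
                           chain = integer(), anchor = integer(),
                           d_b = numeric(), riding = logical())
  }

  ## backbone virtual bonds per chain
  bi <- bj <- integer(0); bchain <- integer(0)
  for (c_i in seq_along(seqs)) {
    idx <- a_off[c_i] + seq_len(per_chain[c_i])
    if (per_chain[c_i] >= 2L) {
      bi <- c(bi, idx[-length(idx)]); bj <- c(bj, idx[-1])
      bchain <- c(bchain, rep(c_i, per_chain[c_i] - 1L))
    }
  }
  bonds <- data.frame(i = bi, j = bj, chain = bchain,
                      cis = seq_along(bi) %in% cis)
  if (model != "protein" && length(cis))
    stop("cis bonds are defined only for the protein backbone")

  ## midpoint sites: p (protein), P (nucleic), ring (sugar)
  mid_kind <- switch(model, protein = "p", nucleic_acid = "P",
                     polysaccharide = "ring")
  mids <- data.frame(kind = rep(mid_kind, nrow(bonds)),
                     a1 = bonds$i, a2 = bonds$j, chain = bonds$chain)
  if (model == "polysaccharide") mids$code <- codes

  ## bend-angle triples and dihedral quadruples per chain
  ai <- aj <- ak <- integer(0)
  ti <- tj <- tk <- tl <- integer(0)
  for (c_i in seq_along(seqs)) {
    idx <- a_off[c_i] + seq_len(per_chain[c_i])
    n <- length(idx)
    if (n >= 3L) { ai <- c(ai, idx[1:(n - 2)]); aj <- c(aj, idx[2:(n - 1)]); ak <- c(ak, idx[3:n]) }
    if (n >= 4L) { ti <- c(ti, idx[1:(n - 3)]); tj <- c(tj, idx[2:(n - 2)])
                   tk <- c(tk, idx[3:(n - 1)]); tl <- c(tl, idx[4:n]) }
  }

  ## frame anchors for each branch (used to place SC/B sites from alpha,beta)
  fr <- .branch_frame_index(anchors, per_chain, a_off, branches)

  structure(list(
    model = model, sequence = codes, chain = chain, n_res = n_res,
    n_chain = length(seqs), per_chain_anchor = per_chain,
    anchor_offset = a_off, anchors = anchors, n_anchor = n_anchor,
    branches = branches, bonds = bonds, mids = mids,
    angles = data.frame(i = ai, j = aj, k = ak),
    torsions = data.frame(i = ti, j = tj, k = tk, l = tl),
    branch_frames = fr,
    chain_breaks = if (length(seqs) > 1L)
      unname(cumsum(lengths(seqs))[-length(seqs)] + 1L) else integer()
  ), class = "cg_topology")
}

## frame anchor indices (f1,f2,f3) per branch; f3 = NA marks the two-anchor
## fallback frame built from the single bond direction, f2 = NA a lone anchor
.branch_frame_index <- function(anchors, per_chain, a_off, branches) {
  if (!nrow(branches))
    return(data.frame(f1 = integer(), f2 = integer(), f3 = integer()))
  f1 <- f2 <- f3 <- integer(nrow(branches))
  for (b in seq_len(nrow(branches))) {
    c_i <- branches$chain[b]; n <- per_chain[c_i]; off <- a_off[c_i]
    l <- branches$anchor[b] - off
    if (n >= 3L) {
      ctr <- min(max(l, 2L), n - 1L)
      f1[b] <- off + ctr - 1L; f2[b] <- off + ctr; f3[b] <- off + ctr + 1L
    } else if (n == 2L) {
      f1[b] <- off + 1L; f2[b] <- off + 2L; f3[b] <- NA_integer_
    } else {
      f1[b] <- off + 1L; f2[b] <- NA_integer_; f3[b] <- NA_integer_
    }
  }
  data.frame(f1 = f1, f2 = f2, f3 = f3)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %s, %d residue(s), %d chain(s)\n",
              x$model, x$n_res, x$n_chain))
  cat(sprintf("  anchors: %d  branch sites: %d  midpoint sites (%s): %d\n",
              x$n_anchor, nrow(x$branches),
              if (nrow(x$mids)) x$mids$kind[1] else "-", nrow(x$mids)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## branch frames (vectorised): local orthonormal triads used to place and
## read off the polar angles alpha (from the outward bisector e1) and beta
## (about the chain tangent plane) of branch sites.
## Interior anchor i: u = unit(r_i - r_(i-1)), v = unit(r_(i+1) - r_i),
## e1 = unit(u - v), e2 = unit(u + v), e3 = e1 x e2.
.branch_triads <- function(topology, A) {
  fr <- topology$branch_frames
  nb <- nrow(fr)
  e1 <- e2 <- e3 <- matrix(0, nb, 3)
  full <- !is.na(fr$f3)
  if (any(full)) {
    p1 <- A[fr$f1[full], , drop = FALSE]
    p2 <- A[fr$f2[full], , drop = FALSE]
    p3 <- A[fr$f3[full], , drop = FALSE]
    u <- row_unit(p2 - p1); v <- row_unit(p3 - p2)
    d <- u - v; s <- u + v
    dn <- row_norm(d)
    if (any(dn < 1e-9))
      stop("degenerate branch frame: collinear anchors at anchor index ",
           fr$f2[full][which(dn < 1e-9)[1]])
    e1[full, ] <- d / dn
    e2[full, ] <- s / row_norm(s)
    e3[full, ] <- row_cross(e1[full, , drop = FALSE], e2[full, , drop = FALSE])
  }
  two <- is.na(fr$f3) & !is.na(fr$f2)
  for (b in which(two)) {
    u <- A[fr$f2[b], ] - A[fr$f1[b], ]
    u <- u / sqrt(sum(u^2))
    pf <- perp_frame(u)
    e1[b, ] <- pf$e1; e2[b, ] <- u
    e3[b, ] <- c(e1[b, 2] * u[3] - e1[b, 3] * u[2],
                 e1[b, 3] * u[1] - e1[b, 1] * u[3],
                 e1[b, 1] * u[2] - e1[b, 2] * u[1])
  }
  lone <- is.na(fr$f2)
  if (any(lone)) {
    e1[lone, 1] <- 1; e2[lone, 2] <- 1; e3[lone, 3] <- 1
  }
  list(e1 = e1, e2 = e2, e3 = e3)
}

## place branch sites given anchor coordinates and (alpha, beta, d_b)
.place_branches <- function(topology, A, alpha, beta, d_b) {
  br <- topology$branches
  if (!nrow(br)) return(matrix(numeric(0), 0, 3))
  tri <- .branch_triads(topology, A)
  o <- A[br$anchor, , drop = FALSE]
  o + d_b * (cos(alpha) * tri$e1 +
             sin(alpha) * (cos(beta) * tri$e2 + sin(beta) * tri$e3))
}

#' Build an extended (all-trans) starting conformation
#'
#' Places the chain at the model's documented extended-state geometry: all
#' backbone dihedrals trans, equilibrium virtual-bond lengths (3.8 A for the
#' trans protein backbone, 2.8 A for bonds flagged cis) and the extended
#' virtual-bond angle. Branch sites are placed at their default polar angles.
#' Successive chains are offset along z to avoid overlap.
#'
#' @param topology a `cg_topology`.
#' @return A `cg_conformation` (list with `anchors` and `branches` matrices).
#' @export
place_extended <- function(topology) {
  stopifnot(inherits(topology, "cg_topology"))
  geom <- chain_geometry(topology$model)
  d0 <- if (topology$model == "protein") geom$d0_trans else geom$d0
  nb <- nrow(topology$bonds)
  d <- rep(d0, nb)
  if (topology$model == "protein") d[topology$bonds$cis] <- geom$d0_cis
  br <- topology$branches
  ic <- new_internal(
    topology,
    d = d,
    theta = rep(deg2rad(geom$theta0_deg), nrow(topology$angles)),
    gamma = rep(deg2rad(geom$gamma0_deg), nrow(topology$torsions)),
    alpha = rep(deg2rad(geom$branch$alpha0_deg %||% 90), nrow(br)),
    beta  = rep(deg2rad(geom$branch$beta0_deg %||% 0), nrow(br)),
    d_branch = br$d_b
  )
  internal_to_cartesian(topology, ic)
}

#' Construct an internal-coordinate object
#'
#' @param topology a `cg_topology` the coordinates refer to.
#' @param d virtual-bond lengths (A), one per backbone bond.
#' @param theta virtual-bond angles (rad), one per anchor triple.
#' @param gamma virtual-bond dihedrals (rad), one per anchor quadruple.
#' @param alpha,beta branch polar angles (rad), one per branch site.
#' @param d_branch branch virtual-bond lengths (A), one per branch site.
#' @param frames optional list (one per chain) of seed anchor coordinates
#'   (up to 3 x 3 matrix) that pin the chain's rigid-body placement.
#' @return An object of class `cg_internal`.
#' @export
new_internal <- function(topology, d, theta, gamma, alpha = numeric(),
                         beta = numeric(), d_branch = numeric(),
                         frames = NULL) {
  stopifnot(length(d) == nrow(topology$bonds),
            length(theta) == nrow(topology$angles),
            length(gamma) == nrow(topology$torsions))
  if (any(d <= 0)) stop("virtual-bond lengths must be positive")
  if (length(theta) && any(theta <= 0 | theta >= pi))
    stop("virtual-bond angles must lie in (0, pi)")
  nb <- nrow(topology$branches)
  if (length(alpha) == 0L) alpha <- rep(pi / 2, nb)
  if (length(beta) == 0L) beta <- rep(0, nb)
  if (length(d_branch) == 0L) d_branch <- topology$branches$d_b
  stopifnot(length(alpha) == nb, length(beta) == nb, length(d_branch) == nb)
  structure(list(d = d, theta = theta, gamma = wrap_pi(gamma), alpha = alpha,
                 beta = beta, d_branch = d_branch, frames = frames),
            class = "cg_internal")
}

#' Convert internal (virtual-bond) coordinates to Cartesian
#'
#' Standard sequential chain building: the first anchor at the origin, the
#' second along +x, the third in the xy-plane, unless the internal-coordinate
#' object carries stored seed frames (as produced by
#' [cartesian_to_internal()]), which pin each chain's absolute placement.
#' Branch sites are placed from their polar angles in the local triad of the
#' two flanking virtual bonds.
#'
#' @param topology a `cg_topology`.
#' @param ic a `cg_internal` consistent with `topology`.
#' @return A `cg_conformation`.
#' @export
internal_to_cartesian <- function(topology, ic) {
  stopifnot(inherits(topology, "cg_topology"), inherits(ic, "cg_internal"))
  if (any(ic$theta <= 1e-9 | ic$theta >= pi - 1e-9))
    stop("degenerate frame: virtual-bond angle at 0 or pi")
  A <- matrix(NA_real_, topology$n_anchor, 3)
  nbnd <- c(0L, cumsum(pmax(topology$per_chain_anchor - 1L, 0L)))
  nang <- c(0L, cumsum(pmax(topology$per_chain_anchor - 2L, 0L)))
  ntor <- c(0L, cumsum(pmax(topology$per_chain_anchor - 3L, 0L)))
  for (c_i in seq_len(topology$n_chain)) {
    n <- topology$per_chain_anchor[c_i]
    off <- topology$anchor_offset[c_i]
    d <- ic$d[(nbnd[c_i] + 1L):nbnd[c_i + 1L]][seq_len(max(n - 1L, 0L))]
    th <- if (n >= 3L) ic$theta[(nang[c_i] + 1L):nang[c_i + 1L]] else numeric()
    ga <- if (n >= 4L) ic$gamma[(ntor[c_i] + 1L):ntor[c_i + 1L]] else numeric()
    X <- matrix(0, n, 3)
    seed <- ic$frames[[c_i]]
    if (!is.null(seed)) {
      k <- nrow(seed)
      X[seq_len(k), ] <- seed
    } else {
      ## canonical seed, chains stacked 30 A apart along z
      z0 <- (c_i - 1L) * 30
      X[1, ] <- c(0, 0, z0)
      if (n >= 2L) X[2, ] <- c(d[1], 0, z0)
      if (n >= 3L) X[3, ] <- X[2, ] + d[2] * c(-cos(th[1]), sin(th[1]), 0)
      k <- min(n, 3L)
    }
    if (n >= 4L) {
      for (i in (k + 1L):n) {
        if (i <= 3L) next
        b1 <- X[i - 2L, ] - X[i - 3L, ]
        bc <- X[i - 1L, ] - X[i - 2L, ]
        bc <- bc / sqrt(sum(bc^2))
        nrm <- c(b1[2] * bc[3] - b1[3] * bc[2],
                 b1[3] * bc[1] - b1[1] * bc[3],
                 b1[1] * bc[2] - b1[2] * bc[1])
        nrm <- nrm / sqrt(sum(nrm^2))
        m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
               nrm[3] * bc[1] - nrm[1] * bc[3],
               nrm[1] * bc[2] - nrm[2] * bc[1])
        thi <- th[i - 2L]; gai <- ga[i - 3L]
        X[i, ] <- X[i - 1L, ] + d[i - 1L] *
          (-cos(thi) * bc + sin(thi) * (cos(gai) * m - sin(gai) * nrm))
      }
    }
    A[off + seq_len(n), ] <- X
  }
  B <- .place_branches(topology, A, ic$alpha, ic$beta, ic$d_branch)
  structure(list(anchors = A, branches = B), class = "cg_conformation")
}

#' Convert a Cartesian conformation to internal coordinates
#'
#' Recovers virtual-bond lengths, angles, dihedrals (IUPAC right-handed sign
#' convention: cis = 0, trans = pi) and the branch polar angles. The first
#' (up to) three anchor positions of each chain are stored as seed frames so
#' the inverse transform reproduces the input exactly, including the relative
#' placement of multiple chains.
#'
#' @param topology a `cg_topology`.
#' @param conf a `cg_conformation`.
#' @return A `cg_internal`.
#' @export
cartesian_to_internal <- function(topology, conf) {
  stopifnot(inherits(topology, "cg_topology"))
  A <- as_mat3(conf$anchors)
  if (nrow(A) != topology$n_anchor) stop("anchor count mismatch")
  bv <- A[topology$bonds$j, , drop = FALSE] - A[topology$bonds$i, , drop = FALSE]
  d <- row_norm(bv)
  if (any(d < 1e-9)) stop("zero-length virtual bond between coincident anchors")
  theta <- if (nrow(topology$angles)) {
    bend_angle(A[topology$angles$i, , drop = FALSE],
               A[topology$angles$j, , drop = FALSE],
               A[topology$angles$k, , drop = FALSE])
  } else numeric()
  gamma <- if (nrow(topology$torsions)) {
    dihedral_angle(A[topology$torsions$i, , drop = FALSE],
                   A[topology$torsions$j, , drop = FALSE],
                   A[topology$torsions$k, , drop = FALSE],
                   A[topology$torsions$l, , drop = FALSE])
  } else numeric()
  br <- topology$branches
  if (nrow(br)) {
    B <- as_mat3(conf$branches)
    tri <- .branch_triads(topology, A)
    w <- B - A[br$anchor, , drop = FALSE]
    db <- row_norm(w)
    alpha <- beta <- numeric(nrow(br))
    ok <- db > 1e-9
    if (any(ok)) {
      wu <- w[ok, , drop = FALSE] / db[ok]
      alpha[ok] <- acos(clamp1(row_dot(wu, tri$e1[ok, , drop = FALSE])))
      beta[ok] <- atan2(row_dot(wu, tri$e3[ok, , drop = FALSE]),
                        row_dot(wu, tri$e2[ok, , drop = FALSE]))
    }
  } else {
    alpha <- beta <- db <- numeric()
  }
  frames <- lapply(seq_len(topology$n_chain), function(c_i) {
    off <- topology$anchor_offset[c_i]
    n <- topology$per_chain_anchor[c_i]
    A[off + seq_len(min(n, 3L)), , drop = FALSE]
  })
  new_internal(topology, d = d, theta = theta, gamma = gamma, alpha = alpha,
               beta = beta, d_branch = db, frames = frames)
}

#' Midpoint interaction sites and dipole axes
#'
#' Computes the positions of the derived midpoint sites (peptide p, phosphate
#' P, or sugar-ring sites, depending on the model) as exact midpoints of
#' their flanking anchors, together with the unit rotation axes of the
#' site dipoles (the virtual-bond direction for midpoint sites, the
#' anchor-to-branch direction for base sites).
#'
#' @param topology a `cg_topology`.
#' @param conf a `cg_conformation`.
#' @return List with `mid` (positions), `mid_axis`, and for branched models
#'   `branch_axis` (unit axes; zero rows for zero-offset branches).
#' @export
derived_sites <- function(topology, conf) {
  A <- as_mat3(conf$anchors)
  m <- topology$mids
  mid <- 0.5 * (A[m$a1, , drop = FALSE] + A[m$a2, , drop = FALSE])
  ax <- A[m$a2, , drop = FALSE] - A[m$a1, , drop = FALSE]
  mid_axis <- ax / row_norm(ax)
  out <- list(mid = mid, mid_axis = mid_axis)
  br <- topology$branches
  if (nrow(br)) {
    B <- as_mat3(conf$branches)
    w <- B - A[br$anchor, , drop = FALSE]
    n <- row_norm(w)
    bax <- matrix(0, nrow(br), 3)
    ok <- n > 1e-9
    bax[ok, ] <- w[ok, , drop = FALSE] / n[ok]
    out$branch_axis <- bax
  }
  out
}

## total number of explicit sites (anchors + branches); coordinate stacking
## order used by the energy/force engine and the integrator
.stack_coords <- function(topology, conf) {
  rbind(as_mat3(conf$anchors),
        if (nrow(topology$branches)) as_mat3(conf$branches))
}

.unstack_coords <- function(topology, X) {
  na <- topology$n_anchor
  structure(list(anchors = X[seq_len(na), , drop = FALSE],
                 branches = X[-seq_len(na), , drop = FALSE]),
            class = "cg_conformation")
}
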