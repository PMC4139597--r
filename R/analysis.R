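## Multi-temperature reweighting (binless WHAM), thermodynamic melting
## curves, Kabsch superposition/RMSD and single-linkage conformational
## clustering with ensemble-averaged representatives.

#' Assemble a WHAM input from per-temperature energy samples
#'
#' @param energies list of numeric vectors (total potential energies,
#'   kcal/mol), one per temperature.
#' @param temperatures temperatures, K (same length as `energies`).
#' @param indicator optional list of per-sample 0/1 folded indicators,
#'   aligned with `energies`.
#' @return Object of class `cg_wham_input`.
#' @export
wham_input <- function(energies, temperatures, indicator = NULL) {
  stopifnot(length(energies) == length(temperatures))
  if (any(lengths(energies) < 2))
    stop("need at least 2 samples per temperature")
  structure(list(energies = energies, temperatures = temperatures,
                 indicator = indicator),
            class = "cg_wham_input")
}

#' Solve the WHAM equations (binless form)
#'
#' Self-consistent iteration of the sample-based (binless) WHAM equations:
#' \deqn{e^{-f_k} = \sum_n \frac{e^{-\beta_k U_n}}{\sum_m N_m e^{f_m -
#'   \beta_m U_n}}}
#' until the largest change in any dimensionless free energy falls below
#' `tol`. Free energies are reported relative to the first temperature.
#'
#' @param input a [wham_input()] (or list of energies plus `temperatures`).
#' @param tol convergence threshold on `max |df|`.
#' @param max_iter iteration limit; exceeding it raises an error carrying
#'   the residual.
#' @return Object of class `cg_wham`: list with `f` (dimensionless free
#'   energies), `temperatures`, `U` (pooled samples), `origin` (sample
#'   temperature index), `iterations`.
#' @export
wham_solve <- function(input, tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(input, "cg_wham_input"))
  Tk <- input$temperatures
  beta <- 1 / (.RGAS * Tk)
  N <- lengths(input$energies)
  U <- unlist(input$energies)
  origin <- rep(seq_along(Tk), N)
  K <- length(Tk)
  ## overlap diagnostic between neighbouring temperatures
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      lo <- range(input$energies[[k]]); hi <- range(input$energies[[k + 1]])
      n_ov <- sum(input$energies[[k]] >= hi[1] & input$energies[[k]] <= hi[2]) +
        sum(input$energies[[k + 1]] >= lo[1] & input$energies[[k + 1]] <= lo[2])
      if (n_ov < 5)
        warning(sprintf(
          "little energy overlap between T = %g and T = %g (n = %d)",
          Tk[k], Tk[k + 1], n_ov))
    }
  }
  f <- numeric(K)
  bu <- outer(beta, U)              # K x n
  logN <- log(N)
  for (it in seq_len(max_iter)) {
    ## log denominator per sample: logsumexp_m (logN_m + f_m - beta_m U_n)
    A <- logN + f - bu              # K x n
    amax <- apply(A, 2, max)
    logden <- amax + log(colSums(exp(sweep(A, 2, amax))))
    B <- -bu - rep(logden, each = K)   # K x n
    bmax <- apply(B, 1, max)
    fnew <- -(bmax + log(rowSums(exp(B - bmax))))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) {
      return(structure(list(f = f, temperatures = Tk, U = U,
                            origin = origin, N = N,
                            indicator = if (!is.null(input$indicator))
                              unlist(input$indicator) else NULL,
                            iterations = it),
                       class = "cg_wham"))
    }
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

## log reweighting weights of all pooled samples at temperature T
.wham_logw <- function(w, T) {
  beta <- 1 / (.RGAS * T)
  A <- log(w$N) + w$f - outer(1 / (.RGAS * w$temperatures), w$U)  # K x n
  amax <- apply(A, 2, max)
  logden <- amax + log(colSums(exp(sweep(A, 2, amax))))
  lw <- -beta * w$U - logden
  lw - max(lw)
}

#' Reweighted average of a per-sample observable at temperature T
#'
#' @param w a solved `cg_wham` object.
#' @param x per-sample values aligned with the pooled samples `w$U`.
#' @param T temperature, K.
#' @return The ensemble average of `x` at `T`.
#' @export
wham_average <- function(w, x, T) {
  lw <- .wham_logw(w, T)
  ww <- exp(lw); ww <- ww / sum(ww)
  sum(ww * x)
}

#' Thermodynamic curves and melting parameters from WHAM
#'
#' Computes the reweighted mean energy U(T), the heat capacity from energy
#' fluctuations \eqn{C_v = (\langle U^2\rangle - \langle U\rangle^2)/RT^2},
#' the melting temperature as the Cv-peak position (quadratic interpolation
#' through the three highest grid points), and - when a folded/duplex
#' indicator is available - a two-state van't Hoff analysis of the folded
#' fraction: \eqn{\ln K} vs \eqn{1/T} slope gives \eqn{\Delta H}, the
#' midpoint gives the van't Hoff melting temperature, and
#' \eqn{\Delta S = \Delta H / T_m}.
#'
#' @param w a solved `cg_wham`.
#' @param T_grid temperatures at which to evaluate the curves.
#' @return Object of class `cg_thermo`: data.frame `curves` (T, U, Cv, and
#'   `x_fold` if available) plus `Tm`, `dH`, `dS` (NA when undefined).
#' @export
thermo_curves <- function(w, T_grid) {
  stopifnot(inherits(w, "cg_wham"))
  n <- length(T_grid)
  Um <- Cv <- xf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lw <- .wham_logw(w, T_grid[i])
    ww <- exp(lw); ww <- ww / sum(ww)
    u1 <- sum(ww * w$U); u2 <- sum(ww * w$U^2)
    Um[i] <- u1
    Cv[i] <- max(u2 - u1^2, 0) / (.RGAS * T_grid[i]^2)
    if (!is.null(w$indicator)) xf[i] <- sum(ww * w$indicator)
  }
  ## Tm from the Cv peak, quadratic interpolation over the 3 highest points
  Tm <- NA_real_
  pk <- which.max(Cv)
  if (pk > 1 && pk < n && stats::sd(Cv) > 1e-12) {
    ii <- (pk - 1):(pk + 1)
    co <- stats::lm.fit(cbind(1, T_grid[ii], T_grid[ii]^2), Cv[ii])$coefficients
    if (is.finite(co[3]) && co[3] < 0) Tm <- -co[2] / (2 * co[3])
  } else if (stats::sd(Cv) <= 1e-12) {
    Tm <- NA_real_                      # flat Cv: no transition
  }
  dH <- dS <- Tm_vh <- NA_real_
  if (!is.null(w$indicator)) {
    ok <- xf > 0.05 & xf < 0.95
    if (sum(ok) >= 3) {
      ## melting (unfolding) equilibrium constant: positive dH on melting
      lnK <- log((1 - xf[ok]) / xf[ok])
      fitc <- stats::lm.fit(cbind(1, 1 / T_grid[ok]), lnK)$coefficients
      dH <- -.RGAS * fitc[2]            # kcal/mol
      ## midpoint x = 0.5
      cross <- which(diff(sign(xf - 0.5)) != 0)
      if (length(cross)) {
        i1 <- cross[1]
        Tm_vh <- T_grid[i1] + (0.5 - xf[i1]) *
          (T_grid[i1 + 1] - T_grid[i1]) / (xf[i1 + 1] - xf[i1])
        dS <- dH / Tm_vh
      }
    }
  }
  structure(list(curves = data.frame(T = T_grid, U = Um, Cv = Cv,
                                     x_fold = xf),
                 Tm = unname(Tm), Tm_vh = unname(Tm_vh),
                 dH = unname(dH), dS = unname(dS)),
            class = "cg_thermo")
}

#' Native inter-strand base contacts of a duplex
#'
#' Identifies the base-base site pairs across different chains whose
#' separation in a reference (native) conformation lies within `factor`
#' times the pair's minimum-energy contact distance (taken from the
#' Gay-Berne table as \eqn{2^{1/6}\sigma_0}). The returned table is the
#' duplex/folded indicator used in melting analyses.
#'
#' @param topology a nucleic-acid `cg_topology`.
#' @param ff the nucleic-acid `cg_forcefield`.
#' @param ref_conf reference (native) conformation.
#' @param factor contact cutoff multiplier (default 1.5).
#' @return data.frame with branch indices `i`, `j` and cutoff `rcut` (A).
#' @export
native_base_contacts <- function(topology, ff, ref_conf, factor = 1.5) {
  if (topology$model != "nucleic_acid") stop("need a nucleic-acid topology")
  br <- topology$branches
  B <- as_mat3(ref_conf$branches)
  sig <- unlist(ff$gay_berne$sigma)
  out <- list()
  for (i in seq_len(nrow(br) - 1)) {
    for (j in (i + 1):nrow(br)) {
      if (br$chain[i] == br$chain[j]) next
      rcut <- factor * 2^(1 / 6) *
        (sig[[br$code[i]]] + sig[[br$code[j]]]) / 2
      if (sqrt(sum((B[i, ] - B[j, ])^2)) < rcut) {
        out[[length(out) + 1L]] <- data.frame(i = i, j = j, rcut = rcut)
      }
    }
  }
  if (!length(out)) stop("no native inter-strand contacts found")
  do.call(rbind, out)
}

#' Fraction of native contacts present in a conformation
#'
#' @param contacts table from [native_base_contacts()].
#' @param conf a `cg_conformation`.
#' @return Fraction in [0, 1].
#' @export
contact_fraction <- function(contacts, conf) {
  B <- as_mat3(conf$branches)
  d <- sqrt(rowSums((B[contacts$i, , drop = FALSE] -
                     B[contacts$j, , drop = FALSE])^2))
  mean(d < contacts$rcut)
}

## ---------------------------------------------------------------------------
## superposition and clustering

## optimal proper-rotation superposition of B onto A (Kabsch)
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, shift_a = ca, shift_b = cb,
       fit = sweep(B0 %*% R, 2, ca, "+"))
}

#' Minimum RMSD under rigid superposition (Kabsch)
#'
#' Optimal translation plus proper rotation (no reflections) of `coords_b`
#' onto `coords_a`, returning the minimised root-mean-square deviation.
#'
#' @param coords_a,coords_b matched n x 3 coordinate matrices (n >= 3).
#' @return RMSD, A.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  A <- as_mat3(coords_a); B <- as_mat3(coords_b)
  if (nrow(A) != nrow(B)) stop("coordinate sets must have equal size")
  if (nrow(A) < 3) stop("need at least 3 points")
  fit <- .kabsch(A, B)$fit
  sqrt(mean(rowSums((A - fit)^2)))
}

#' Superpose a conformation onto a reference
#'
#' @param coords_a reference n x 3 matrix.
#' @param coords_b mobile n x 3 matrix.
#' @return The transformed copy of `coords_b`.
#' @export
kabsch_fit <- function(coords_a, coords_b) {
  .kabsch(as_mat3(coords_a), as_mat3(coords_b))$fit
}

#' Single-linkage conformational clustering with ensemble-averaged
#' representative
#'
#' Clusters frames on pairwise anchor-trace RMSD (Kabsch-minimised) by
#' single linkage at the given cutoff. The representative structure is the
#' coordinate average of the most populated cluster after superposing all
#' of its members onto the cluster's first frame.
#'
#' @param frames a `cg_trajectory`, or a list of n x 3 coordinate matrices.
#' @param cutoff RMSD cutoff, A.
#' @return Object of class `cg_clusters`: `labels`, `populations` (sums to
#'   1), `representative` (averaged coordinates of the top cluster),
#'   `rep_population`.
#' @export
cluster_conformations <- function(frames, cutoff) {
  if (inherits(frames, "cg_trajectory"))
    frames <- lapply(frames$frames, `[[`, "anchors")
  n <- length(frames)
  if (n < 1) stop("need at least one frame")
  if (n == 1) {
    return(structure(list(labels = 1L, populations = 1,
                          representative = frames[[1]],
                          rep_population = 1), class = "cg_clusters"))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kabsch_rmsd(frames[[i]], frames[[j]])
    }
  }
  if (is.finite(cutoff)) {
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    labels <- unname(stats::cutree(hc, h = cutoff))
  } else {
    labels <- rep(1L, n)
  }
  pops <- as.numeric(table(labels)) / n
  top <- as.integer(names(which.max(table(labels))))
  members <- which(labels == top)
  ref <- frames[[members[1]]]
  acc <- matrix(0, nrow(ref), 3)
  for (m in members) acc <- acc + kabsch_fit(ref, frames[[m]])
  structure(list(labels = labels, populations = pops,
                 representative = acc / length(members),
                 rep_population = length(members) / n),
            class = "cg_clusters")
}
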