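## Langevin dynamics in Cartesian site coordinates with lumped site masses,
## and a RESPA-style adaptive multiple-time-step (A-MTS) scheme: stiff local
## forces (bond, angle, torsion) advance on the inner step, all remaining
## (nonbonded / mean-field / correlation / rotamer) forces are applied as
## outer-step impulses; the inner step is halved adaptively whenever the
## fast-force magnitude exceeds a threshold.

#' Molecular-dynamics configuration
#'
#' @param dt outer time step, fs.
#' @param ratio inner steps per outer step (>= 1).
#' @param gamma friction coefficient, 1/fs (0 turns the integrator into
#'   plain velocity-Verlet/RESPA).
#' @param T target temperature, K.
#' @param steps number of outer steps.
#' @param stride snapshot interval in outer steps.
#' @param seed RNG seed for the thermostat noise and velocity draw.
#' @param fmax fast-force threshold (kcal/(mol A)) that triggers halving of
#'   the inner step.
#' @param max_halvings abort limit for repeated halving.
#' @return Object of class `cg_md_config`.
#' @export
md_config <- function(dt = 5, ratio = 10, gamma = 0.1, T = 300,
                      steps = 1000, stride = 100, seed = 1,
                      fmax = 100, max_halvings = 8) {
  stopifnot(dt > 0, ratio >= 1, gamma >= 0, T > 0, steps >= 1)
  structure(list(dt = dt, ratio = as.integer(ratio), gamma = gamma, T = T,
                 steps = as.integer(steps), stride = as.integer(stride),
                 seed = as.integer(seed), fmax = fmax,
                 max_halvings = as.integer(max_halvings)),
            class = "cg_md_config")
}

#' One Langevin (BAOAB) integration step
#'
#' Splitting-scheme integrator: half kick, half drift, Ornstein-Uhlenbeck
#' velocity update, half drift, half kick. With `gamma = 0` the
#' Ornstein-Uhlenbeck map is the identity and the step reduces exactly to
#' velocity-Verlet. Uses R's global RNG stream for the noise.
#'
#' @param state list with `X` (n x 3 positions, A), `V` (n x 3 velocities,
#'   A/fs), `m` (masses, amu), `t` (time, fs).
#' @param force_fn function `X -> n x 3` force matrix, kcal/(mol A).
#' @param cfg a [md_config()]; `cfg$dt` is the step used.
#' @return Updated state (with `force` caching the end-of-step force).
#' @export
langevin_step <- function(state, force_fn, cfg) {
  dt <- cfg$dt
  m <- state$m
  f <- state$force %||% force_fn(state$X)
  if (any(!is.finite(f))) stop("NaN force encountered in langevin_step")
  a <- f * (.EKIN / m)
  v <- state$V + 0.5 * dt * a
  x <- state$X + 0.5 * dt * v
  if (cfg$gamma > 0) {
    c1 <- exp(-cfg$gamma * dt)
    c2 <- sqrt((1 - c1^2) * .RGAS * cfg$T * .EKIN / m)
    v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3)
  }
  x <- x + 0.5 * dt * v
  f <- force_fn(x)
  if (any(!is.finite(f))) stop("NaN force encountered in langevin_step")
  v <- v + 0.5 * dt * f * (.EKIN / m)
  list(X = x, V = v, m = m, t = state$t + dt, force = f)
}

#' Kinetic energy of a dynamic state, kcal/mol
#'
#' @param state integrator state with `V` and `m`.
#' @return Kinetic energy in kcal/mol.
#' @export
kinetic_energy <- function(state) {
  0.5 * sum(state$m * rowSums(state$V^2)) / .EKIN
}

## dynamic-dof bookkeeping: riding (zero-offset) branches are slaved to
## their anchors and carry no independent coordinates
.dyn_map <- function(sys) {
  na <- sys$na
  riding <- which(sys$riding)
  live <- c(seq_len(na), na + which(!sys$riding))
  list(live = live, riding = riding,
       riding_anchor = sys$branch_anchor[riding],
       masses = {
         m <- sys$masses
         if (length(riding))
           m[sys$branch_anchor[riding]] <-
             m[sys$branch_anchor[riding]] + m[na + riding]
         m[live]
       })
}

.expand_X <- function(sys, map, Xd) {
  X <- matrix(0, sys$nsite, 3)
  X[map$live, ] <- Xd
  if (length(map$riding))
    X[sys$na + map$riding, ] <- X[map$riding_anchor, , drop = FALSE]
  X
}

.fold_G <- function(sys, map, G) {
  if (length(map$riding)) {
    ridx <- sys$na + map$riding
    G[map$riding_anchor, ] <- G[map$riding_anchor, , drop = FALSE] +
      G[ridx, , drop = FALSE]
  }
  G[map$live, , drop = FALSE]
}

#' Langevin dynamics with adaptive multiple-time-step integration
#'
#' RESPA-style splitting: the slow (nonbonded, mean-field, correlation,
#' rotamer, double-torsion) forces are applied as impulses at the outer
#' step `cfg$dt`; the stiff local forces advance with BAOAB inner steps of
#' `cfg$dt / cfg$ratio`. At every outer step the inner step is halved (and
#' the inner count doubled) until the maximum fast-force component falls
#' below `cfg$fmax` times the accumulated halving factor; exceeding
#' `cfg$max_halvings` aborts. With `ratio = 1`, no adaptation and
#' `gamma = 0`, the scheme is plain velocity-Verlet with full forces.
#'
#' @param topology a `cg_topology`.
#' @param conf starting `cg_conformation` (optional `velocities`).
#' @param ff a `cg_forcefield`.
#' @param cfg a [md_config()].
#' @return Object of class `cg_trajectory`: list with `times`, `frames`
#'   (conformations at snapshots), `energy` (data.frame: time, per-term,
#'   total, kinetic, instantaneous temperature), `n_adapt` (outer steps
#'   that triggered halving), `state` (final integrator state), `cfg`.
#' @export
amts_run <- function(topology, conf, ff, cfg) {
  sys <- cg_system(topology, ff)
  map <- .dyn_map(sys)
  set.seed(cfg$seed)
  X <- .stack_coords(topology, conf)
  Xd <- X[map$live, , drop = FALSE]
  m <- map$masses
  nd <- length(m)
  V <- conf$velocities
  if (is.null(V)) {
    V <- matrix(stats::rnorm(nd * 3), nd, 3) *
      sqrt(.RGAS * cfg$T * .EKIN / m)
  } else {
    V <- V[map$live, , drop = FALSE]
  }
  Tsim <- cfg$T

  slow_force <- function(Xd) {
    Xf <- .expand_X(sys, map, Xd)
    -.fold_G(sys, map, sys_gradient(sys, Xf, Tsim, "slow"))
  }
  fast_force <- function(Xd) {
    Xf <- .expand_X(sys, map, Xd)
    -.fold_G(sys, map, sys_gradient(sys, Xf, Tsim, "fast"))
  }

  n_snap <- length(seq(0L, cfg$steps, by = cfg$stride))
  times <- numeric(0); frames <- list(); erows <- list()
  n_adapt <- 0L
  record <- function(t, Xd, V) {
    Xf <- .expand_X(sys, map, Xd)
    terms <- sys_energy_terms(sys, Xf)
    tot <- sys_total(sys, terms, Tsim)
    ke <- 0.5 * sum(m * rowSums(V^2)) / .EKIN
    tkin <- 2 * ke / (3 * nd * .RGAS)
    times <<- c(times, t)
    frames[[length(frames) + 1L]] <<- .unstack_coords(sys$topology, Xf)
    erows[[length(erows) + 1L]] <<-
      c(time = t, terms, total = tot, kinetic = ke, T_kin = tkin)
  }

  fs <- slow_force(Xd)
  record(0, Xd, V)
  t <- 0
  for (step in seq_len(cfg$steps)) {
    ## outer half-kick with slow forces
    V <- V + 0.5 * cfg$dt * fs * (.EKIN / m)
    ## adaptive inner stepping
    ffst <- fast_force(Xd)
    fmaxv <- max(abs(ffst))
    n_half <- 0L
    while (fmaxv > cfg$fmax * 2^n_half) {
      n_half <- n_half + 1L
      if (n_half > cfg$max_halvings)
        stop(sprintf(
          "A-MTS halving floor reached at t = %.1f fs (|F|max = %.1f)",
          t, fmaxv))
    }
    if (n_half > 0L) n_adapt <- n_adapt + 1L
    n_inner <- cfg$ratio * 2L^n_half
    icfg <- cfg; icfg$dt <- cfg$dt / n_inner
    st <- list(X = Xd, V = V, m = m, t = t, force = ffst)
    for (k in seq_len(n_inner)) st <- langevin_step(st, fast_force, icfg)
    Xd <- st$X; V <- st$V; t <- st$t
    ## outer half-kick
    fs <- slow_force(Xd)
    if (any(!is.finite(fs)))
      stop(sprintf("NaN slow force at t = %.1f fs", t))
    V <- V + 0.5 * cfg$dt * fs * (.EKIN / m)
    if (step %% cfg$stride == 0L) record(t, Xd, V)
  }
  Xf <- .expand_X(sys, map, Xd)
  final <- .unstack_coords(sys$topology, Xf)
  Vfull <- matrix(0, sys$nsite, 3); Vfull[map$live, ] <- V
  final$velocities <- Vfull
  structure(list(times = times, frames = frames,
                 energy = as.data.frame(do.call(rbind, erows)),
                 n_adapt = n_adapt,
                 state = list(X = Xd, V = V, m = m, t = t),
                 final = final, cfg = cfg, model = sys$model),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "cg_trajectory: %d snapshots over %.0f fs (%s), %d adaptive outer steps\n",
    length(x$times), max(x$times), x$model, x$n_adapt))
  invisible(x)
}
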