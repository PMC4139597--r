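## Temperature replica exchange (REMD) and its multiplexed variant (MREMD)
## over Langevin trajectories. Exchanges swap temperatures (slot
## assignments) between replicas, not coordinates; velocities are rescaled
## by sqrt(T_new/T_old) on acceptance. All attempts are logged so the full
## replica walk can be reconstructed.

#' Define a replica ladder
#'
#' @param temperatures strictly increasing temperatures, K.
#' @param mux replicas per temperature (multiplexing factor, >= 1).
#' @param exchange_interval outer MD steps between exchange attempts.
#' @param seed RNG seed governing the whole run (per-segment MD seeds are
#'   derived from it).
#' @return Object of class `cg_replica_ladder`.
#' @export
replica_ladder <- function(temperatures, mux = 1, exchange_interval = 1000,
                           seed = 1) {
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (mux < 1) stop("multiplexing factor must be >= 1")
  structure(list(temperatures = temperatures, mux = as.integer(mux),
                 exchange_interval = as.integer(exchange_interval),
                 seed = as.integer(seed)),
            class = "cg_replica_ladder")
}

#' Metropolis replica-exchange acceptance
#'
#' Accepts a temperature swap with probability
#' \eqn{\min(1, e^{\Delta})}, \eqn{\Delta = (1/RT_i - 1/RT_j)(U_i - U_j)}.
#' Draws one uniform variate from R's global RNG stream (none when the
#' swap is unconditionally accepted).
#'
#' @param U_i,U_j potential energies of the two replicas, kcal/mol.
#' @param T_i,T_j their temperatures, K.
#' @return List with `accepted` (logical), `delta`, `prob`.
#' @export
attempt_exchange <- function(U_i, U_j, T_i, T_j) {
  delta <- (1 / (.RGAS * T_i) - 1 / (.RGAS * T_j)) * (U_i - U_j)
  prob <- min(1, exp(delta))
  accepted <- if (delta >= 0) TRUE else stats::runif(1) < prob
  list(accepted = accepted, delta = delta, prob = prob)
}

## deterministic per-segment seed derivation (kept below 2^31)
.derive_seed <- function(seed, cycle, replica) {
  as.integer((as.double(seed) * 7919 + cycle * 104729 + replica * 1299709) %%
               2147483647)
}

#' Multiplexed temperature replica-exchange molecular dynamics
#'
#' Runs `length(temperatures) * mux` Langevin replicas with the A-MTS
#' integrator, attempting Metropolis temperature swaps every
#' `exchange_interval` outer steps: neighbouring temperature pairs alternate
#' even/odd across cycles, and with `mux > 1` same-temperature layer swaps
#' (always accepted) mix the multiplexed layers. Exchanges swap slot
#' temperatures between replicas; the log reconstructs the full replica
#' walk. Per-temperature potential-energy samples are collected for WHAM.
#'
#' @param topology a `cg_topology`.
#' @param conf starting conformation (all replicas start here).
#' @param ff a `cg_forcefield`.
#' @param ladder a [replica_ladder()].
#' @param cfg a [md_config()]; `cfg$steps` is ignored (segment length comes
#'   from the ladder), `cfg$T` is overridden per replica.
#' @param cycles number of exchange cycles.
#' @return Object of class `cg_mremd`: list with `energies` (per-temperature
#'   list of potential-energy samples), `temperatures`, `records`
#'   (data.frame of all attempts), `walk` (cycles x replicas slot matrix),
#'   `final` (per-replica final conformations), `acceptance` (per neighbour
#'   pair).
#' @export
mremd_run <- function(topology, conf, ff, ladder, cfg, cycles = 10) {
  nT <- length(ladder$temperatures)
  nR <- nT * ladder$mux
  ## slot r: temperature index slot_T[r], layer slot_L[r]
  slot_T <- rep(seq_len(nT), each = ladder$mux)
  slot_L <- rep(seq_len(ladder$mux), nT)
  assign_slot <- seq_len(nR)       # replica -> slot
  confs <- replicate(nR, conf, simplify = FALSE)
  U <- rep(NA_real_, nR)
  energies <- vector("list", nT)
  walk <- matrix(NA_integer_, cycles, nR)
  records <- list()
  diverged <- logical(nR)
  set.seed(ladder$seed)

  seg_cfg <- cfg
  seg_cfg$steps <- ladder$exchange_interval
  seg_cfg$stride <- ladder$exchange_interval

  for (cyc in seq_len(cycles)) {
    for (r in seq_len(nR)) {
      if (diverged[r]) next
      s <- assign_slot[r]
      rcfg <- seg_cfg
      rcfg$T <- ladder$temperatures[slot_T[s]]
      rcfg$seed <- .derive_seed(ladder$seed, cyc, r)
      tr <- tryCatch(amts_run(topology, confs[[r]], ff, rcfg),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        diverged[r] <- TRUE
        warning(sprintf("replica %d flagged divergent at cycle %d: %s",
                        r, cyc, conditionMessage(tr)))
        next
      }
      confs[[r]] <- tr$final
      U[r] <- tr$energy$total[nrow(tr$energy)]
    }
    ## restore the ladder RNG stream after the MD segments reseeded it
    set.seed(.derive_seed(ladder$seed, cyc, 0L) + 1L)
    ## collect energy samples per temperature slot
    for (r in seq_len(nR)) {
      if (diverged[r]) next
      ti <- slot_T[assign_slot[r]]
      energies[[ti]] <- c(energies[[ti]], U[r])
    }
    walk[cyc, ] <- assign_slot
    ## same-temperature layer swaps (multiplexing), always accepted
    if (ladder$mux > 1) {
      for (ti in seq_len(nT)) {
        lfirst <- if (cyc %% 2L) 1L else 2L
        lay <- if (lfirst > ladder$mux - 1L) integer(0)
               else seq(lfirst, ladder$mux - 1L, by = 2L)
        for (l in lay) {
          s1 <- which(slot_T == ti & slot_L == l)
          s2 <- which(slot_T == ti & slot_L == l + 1L)
          r1 <- which(assign_slot == s1); r2 <- which(assign_slot == s2)
          if (diverged[r1] || diverged[r2]) next
          assign_slot[c(r1, r2)] <- c(s2, s1)
          records[[length(records) + 1L]] <- data.frame(
            cycle = cyc, kind = "layer", T_lo = ladder$temperatures[ti],
            T_hi = ladder$temperatures[ti], replica_i = r1, replica_j = r2,
            delta = 0, accepted = TRUE)
        }
      }
    }
    ## neighbour-temperature swaps, even/odd alternation
    first <- if (cyc %% 2L) 1L else 2L
    pairs <- if (first > nT - 1L) integer(0) else seq(first, nT - 1L, by = 2L)
    for (ti in pairs) {
      for (l in seq_len(ladder$mux)) {
        s1 <- which(slot_T == ti & slot_L == l)
        s2 <- which(slot_T == ti + 1L & slot_L == l)
        r1 <- which(assign_slot == s1); r2 <- which(assign_slot == s2)
        if (diverged[r1] || diverged[r2]) next
        ex <- attempt_exchange(U[r1], U[r2], ladder$temperatures[ti],
                               ladder$temperatures[ti + 1L])
        if (ex$accepted) {
          assign_slot[c(r1, r2)] <- c(s2, s1)
          sc <- sqrt(ladder$temperatures[ti + 1L] / ladder$temperatures[ti])
          confs[[r1]]$velocities <- confs[[r1]]$velocities * sc
          confs[[r2]]$velocities <- confs[[r2]]$velocities / sc
        }
        records[[length(records) + 1L]] <- data.frame(
          cycle = cyc, kind = "temperature",
          T_lo = ladder$temperatures[ti],
          T_hi = ladder$temperatures[ti + 1L],
          replica_i = r1, replica_j = r2,
          delta = ex$delta, accepted = ex$accepted)
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(cycle = integer(), kind = character(), T_lo = numeric(),
               T_hi = numeric(), replica_i = integer(),
               replica_j = integer(), delta = numeric(),
               accepted = logical())
  tr_rec <- records[records$kind == "temperature", , drop = FALSE]
  acc <- if (nrow(tr_rec)) {
    stats::aggregate(accepted ~ T_lo + T_hi, tr_rec, mean)
  } else data.frame(T_lo = numeric(), T_hi = numeric(), accepted = numeric())
  structure(list(energies = energies,
                 temperatures = ladder$temperatures,
                 records = records, walk = walk, final = confs,
                 acceptance = acc, diverged = diverged, ladder = ladder),
            class = "cg_mremd")
}

#' @export
print.cg_mremd <- function(x, ...) {
  cat(sprintf("cg_mremd: %d temperatures x %d layers, %d cycles\n",
              length(x$temperatures), x$ladder$mux, nrow(x$walk)))
  if (nrow(x$acceptance))
    print(x$acceptance, row.names = FALSE)
  invisible(x)
}
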