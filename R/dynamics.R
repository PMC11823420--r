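# NVE/NVT integration, instrumented trajectories, checkpointing, and
# temperature replica exchange on unscaled restraint energies.

# base friction (fs^-1): friction_scale = 0.05 then gives a velocity
# autocorrelation time 1/(0.05 * 0.01) = 2 ps, the declared stand-in for
# water friction on the bead scale
.gamma_base <- 0.01

#' Thermostat specification
#'
#' @param kind `"none"` (NVE), `"langevin"` (BAOAB splitting; satisfies the
#'   fluctuation-dissipation relation at `T_bath`) or `"berendsen"`
#'   (velocity rescaling with coupling time `tau_berendsen`).
#' @param T_bath bath temperature, K.
#' @param friction_scale dimensionless multiplier on the base friction
#'   0.01 fs^-1 (the values 0.02 and 0.05 emulate scaled-down water friction).
#' @param tau_berendsen Berendsen coupling time, fs.
#' @return object of class `thermostat_spec`.
#' @export
thermostat_spec <- function(kind = c("none", "langevin", "berendsen"),
                            T_bath = 300, friction_scale = 0.05,
                            tau_berendsen = 489) {
  kind <- match.arg(kind)
  stopifnot(T_bath > 0, friction_scale >= 0, tau_berendsen > 0)
  structure(list(kind = kind, T_bath = T_bath,
                 friction_scale = friction_scale,
                 tau_berendsen = tau_berendsen),
            class = "thermostat_spec")
}

#' MD run configuration
#'
#' @param n_steps number of MD steps.
#' @param dt time step, fs (4.89 production, 0.489 diagnostic).
#' @param save_interval save a conformation every this many steps (0 = none).
#' @param energy_interval record energies/temperature every this many steps.
#' @param restraint_mode `"none"`, `"instantaneous"` or `"time_averaged"`.
#' @param thermostat a [thermostat_spec()].
#' @param T_init temperature (K) for Maxwell-Boltzmann initial velocities.
#' @param seed integer seed for velocities and the Langevin stream.
#' @param tau,n_ave,N_tau time-averaging parameters (fs, steps, steps); see
#'   [memory_window_state()].
#' @param energy_scaling_diagnostic scale the reported restraint energy along
#'   with the forces (total-energy conservation check in NVE runs).
#' @param ndof_mode `"3n"` (default; Langevin dynamics does not conserve
#'   momentum) or `"3n-3"` for NVE diagnostics with COM motion removed.
#' @return object of class `md_config`.
#' @export
md_config <- function(n_steps, dt = 4.89, save_interval = 1000,
                      energy_interval = 100,
                      restraint_mode = c("none", "instantaneous",
                                         "time_averaged"),
                      thermostat = thermostat_spec("none"),
                      T_init = 300, seed = 1,
                      tau = 489000, n_ave = 1000, N_tau = NULL,
                      energy_scaling_diagnostic = FALSE,
                      ndof_mode = c("3n", "3n-3")) {
  restraint_mode <- match.arg(restraint_mode)
  ndof_mode <- match.arg(ndof_mode)
  stopifnot(dt > 0, n_steps >= 1, inherits(thermostat, "thermostat_spec"))
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 save_interval = as.integer(save_interval),
                 energy_interval = as.integer(energy_interval),
                 restraint_mode = restraint_mode, thermostat = thermostat,
                 T_init = T_init, seed = as.integer(seed),
                 tau = tau, n_ave = as.integer(n_ave), N_tau = N_tau,
                 energy_scaling_diagnostic = energy_scaling_diagnostic,
                 ndof_mode = ndof_mode),
            class = "md_config")
}

#' Kinetic temperature
#'
#' `T = 2 E_kin / (k_B N_dof)` with `N_dof = 3 n` by default (no
#' centre-of-mass correction; Langevin dynamics does not conserve momentum).
#'
#' @param velocities n x 3 matrix, A/fs.
#' @param masses per-bead masses, amu.
#' @param n_dof degrees of freedom (default `3 n`; use `3 n - 3` for NVE
#'   diagnostics with COM motion removed).
#' @return temperature in K.
#' @export
kinetic_temperature <- function(velocities, masses, n_dof = NULL) {
  velocities <- as.matrix(velocities)
  n <- nrow(velocities)
  stopifnot(n >= 1, length(masses) == n)
  if (is.null(n_dof)) n_dof <- 3 * n
  ekin <- 0.5 * sum(masses * rowSums(velocities^2)) / .kcal
  2 * ekin / (.kB * n_dof)
}

#' One velocity-Verlet step
#'
#' @param coords,velocities n x 3 matrices (A, A/fs).
#' @param forces current forces at `coords` (kcal/mol/A).
#' @param dt time step, fs.
#' @param masses per-bead masses, amu.
#' @param force_fun function of coordinates returning a list with `forces`
#'   (and optionally `energy`).
#' @return list with updated `coords`, `velocities`, `forces`, `energy`.
#' @export
velocity_verlet_step <- function(coords, velocities, forces, dt, masses,
                                 force_fun) {
  if (!all(is.finite(forces))) {
    bad <- which(!is.finite(rowSums(forces)))[1]
    stop("non-finite force on bead ", bad)
  }
  am <- .kcal / masses * 0.5 * dt
  velocities <- velocities + forces * am
  coords <- coords + dt * velocities
  nf <- force_fun(coords)
  if (!all(is.finite(nf$forces))) {
    bad <- which(!is.finite(rowSums(nf$forces)))[1]
    stop("non-finite force on bead ", bad)
  }
  velocities <- velocities + nf$forces * am
  list(coords = coords, velocities = velocities, forces = nf$forces,
       energy = nf$energy)
}

#' One Langevin (BAOAB) step
#'
#' Half kick, half drift, Ornstein-Uhlenbeck velocity update at `T_bath`
#' (friction `friction_scale * 0.01 fs^-1`), half drift, half kick.  With
#' zero friction this reduces exactly to [velocity_verlet_step()].
#'
#' @inheritParams velocity_verlet_step
#' @param thermostat a [thermostat_spec()] of kind `"langevin"` (or any spec;
#'   only `T_bath` and `friction_scale` are used).
#' @return list as for [velocity_verlet_step()].
#' @export
langevin_step <- function(coords, velocities, forces, dt, masses, force_fun,
                          thermostat) {
  gam <- thermostat$friction_scale * .gamma_base
  if (gam == 0)
    return(velocity_verlet_step(coords, velocities, forces, dt, masses,
                                force_fun))
  am <- .kcal / masses * 0.5 * dt
  velocities <- velocities + forces * am
  coords <- coords + 0.5 * dt * velocities
  c1 <- exp(-gam * dt)
  c2 <- sqrt(.kB * thermostat$T_bath * .kcal * (1 - c1^2) / masses)
  n <- nrow(coords)
  # column-major draw order matches the C++ core (per bead, then x, y, z)
  xi <- matrix(rnorm(3 * n), n, 3, byrow = TRUE)
  velocities <- c1 * velocities + c2 * xi
  coords <- coords + 0.5 * dt * velocities
  nf <- force_fun(coords)
  velocities <- velocities + nf$forces * am
  list(coords = coords, velocities = velocities, forces = nf$forces,
       energy = nf$energy)
}

#' Berendsen velocity rescaling
#'
#' `lambda = sqrt(1 + (dt / tau_B) (T_bath / T_kin - 1))`.
#'
#' @param velocities n x 3 matrix.
#' @param T_kin current kinetic temperature, K (> 0).
#' @param spec a [thermostat_spec()] supplying `T_bath` and `tau_berendsen`.
#' @param dt time step, fs.
#' @return rescaled velocities.
#' @export
berendsen_rescale <- function(velocities, T_kin, spec, dt) {
  stopifnot(T_kin > 0)
  lam <- sqrt(1 + (dt / spec$tau_berendsen) * (spec$T_bath / T_kin - 1))
  velocities * lam
}

.mode_code <- c(none = 0L, instantaneous = 1L, time_averaged = 2L)
.thermo_code <- c(none = 0L, langevin = 1L, berendsen = 2L)

.empty_rf <- function() .rset_flat(restraint_set())

#' Run an MD trajectory
#'
#' Dispatches on `cfg$restraint_mode`: toy forces only; plus instantaneous
#' restraint forces; or time-averaged restraints (per-step accumulation,
#' block commits every `n_ave` steps, forces scaled by the ramp `f_i`).
#' Instrumentation (potential, unscaled restraint, kinetic and total energy,
#' kinetic temperature, `f_i`) is recorded every `energy_interval` steps and
#' conformations every `save_interval` steps.  Runs abort with the step index
#' if a coordinate exceeds 1e4 A or an energy turns non-finite.
#'
#' @param conf0 starting conformation (n x 3).
#' @param ff a [toy_forcefield()].
#' @param set a [restraint_set()] or `NULL`.
#' @param cfg an [md_config()].
#' @param mass per-bead mass (scalar or vector), amu.
#' @param velocities optional starting velocities; default Maxwell-Boltzmann
#'   at `cfg$T_init` drawn after `set.seed(cfg$seed)`.
#' @param resume a checkpoint list from [read_checkpoint()]; continues the
#'   run bit-exactly (coordinates, velocities, averaging state, RNG stream).
#' @return object of class `trajectory_record`.
#' @export
run_trajectory <- function(conf0, ff, set = NULL, cfg, mass = 110,
                           velocities = NULL, resume = NULL) {
  stopifnot(inherits(cfg, "md_config"))
  conf0 <- .as_conformation(conf0)
  n <- nrow(conf0)
  masses <- rep_len(mass, n)
  mode <- .mode_code[[cfg$restraint_mode]]
  if (mode > 0 && (is.null(set) || length(set) == 0) && mode == 1) {
    # instantaneous mode with an empty set equals unrestrained dynamics
    set <- set %||% restraint_set()
  }
  if (mode > 0 && is.null(set))
    stop("restraint_mode '", cfg$restraint_mode, "' needs a restraint set")
  rf <- if (mode > 0) .rset_flat(set, n) else .empty_rf()

  tstate <- NULL
  if (!is.null(resume)) {
    conf0 <- resume$coords
    velocities <- resume$velocities
    tstate <- resume$tavg_state
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  } else {
    set.seed(cfg$seed)
    if (is.null(velocities)) velocities <- maxwell_velocities(masses, cfg$T_init)
  }
  if (mode == 2 && is.null(tstate))
    tstate <- memory_window_state(set, dt = cfg$dt, tau = cfg$tau,
                                  n_ave = cfg$n_ave, N_tau = cfg$N_tau)

  th <- cfg$thermostat
  ccfg <- list(dt = cfg$dt, n_steps = cfg$n_steps,
               save_every = cfg$save_interval,
               energy_every = cfg$energy_interval,
               mode = mode, thermo = .thermo_code[[th$kind]],
               T_bath = th$T_bath, gamma = th$friction_scale * .gamma_base,
               tau_b = th$tau_berendsen,
               scale_energy = isTRUE(cfg$energy_scaling_diagnostic),
               masses = masses, blowup = 1e4,
               ndof = if (cfg$ndof_mode == "3n") 3L * n else 3L * n - 3L)
  out <- cpp_run_md(conf0, velocities, unclass(ff), rf, ccfg,
                    if (is.null(tstate)) list() else unclass(tstate))

  en <- as.data.frame(out$energies)
  names(en) <- c("E_pot", "E_restraint", "E_kin", "E_total", "T_kin", "f_i",
                 "time_ps")
  en$step <- out$energy_steps
  en <- en[, c("step", "time_ps", "E_pot", "E_restraint", "E_kin", "E_total",
               "T_kin", "f_i")]
  confs <- list()
  if (out$n_saved > 0) {
    arr <- array(out$traj, dim = c(n, 3, out$n_saved))
    confs <- lapply(seq_len(out$n_saved), function(k) arr[, , k])
  }
  tav <- if (mode == 2) {
    stt <- out$tavg_state
    class(stt) <- "memory_window_state"
    stt
  } else NULL
  structure(list(
    conformations = confs, saved_steps = out$traj_steps[seq_len(out$n_saved)],
    energies = en,
    final = list(coords = out$coords, velocities = out$velocities,
                 tavg_state = tav,
                 rng_state = get(".Random.seed", envir = globalenv())),
    config = cfg, seed = cfg$seed, masses = masses),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("trajectory_record:", x$config$n_steps, "steps,",
      length(x$conformations), "saved conformations, restraint mode",
      x$config$restraint_mode, "\n")
  invisible(x)
}

#' Write / read a trajectory checkpoint
#'
#' The checkpoint holds coordinates, velocities, the averaging state and the
#' RNG stream, so a resumed run is bit-identical to an uninterrupted one.
#'
#' @param rec a [run_trajectory()] record.
#' @param path checkpoint file (RDS).
#' @return `path` / the checkpoint list.
#' @export
write_checkpoint <- function(rec, path) {
  stopifnot(inherits(rec, "trajectory_record"))
  saveRDS(rec$final, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Metropolis temperature-exchange attempt
#'
#' Acceptance `p = min(1, exp((beta_a - beta_b) (E_a - E_b)))` on the
#' extended potential energy (toy energy plus UNSCALED restraint penalty).
#' On acceptance the bath temperatures swap; coordinates stay.
#'
#' @param replica_a,replica_b lists with `temperature` (K) and `energy`
#'   (extended potential, kcal/mol).
#' @param u uniform random number (drawn if missing).
#' @return list with `accepted`, `p`, and the updated replicas.
#' @export
attempt_exchange <- function(replica_a, replica_b, u = NULL) {
  beta_a <- 1 / (.kB * replica_a$temperature)
  beta_b <- 1 / (.kB * replica_b$temperature)
  p <- min(1, exp((beta_a - beta_b) * (replica_a$energy - replica_b$energy)))
  if (is.null(u)) u <- runif(1)
  accepted <- u < p || p >= 1
  if (accepted) {
    tmp <- replica_a$temperature
    replica_a$temperature <- replica_b$temperature
    replica_b$temperature <- tmp
  }
  list(accepted = accepted, p = p, replica_a = replica_a,
       replica_b = replica_b)
}

#' Temperature replica-exchange MD
#'
#' Runs one replica per temperature; every `exchange_interval` steps,
#' neighbouring pairs (alternating even/odd pairings) attempt a Metropolis
#' temperature swap on the extended potential energy with UNSCALED
#' time-averaged restraint components.  Each replica owns an independent
#' seeded RNG stream; exchanges swap bath temperatures, not coordinates.
#'
#' @param conf0s list of starting conformations (recycled over replicas).
#' @param ff a [toy_forcefield()].
#' @param set shared [restraint_set()].  All replicas evaluate the same set
#'   by construction, so mismatched restraint sets between exchange partners
#'   cannot arise at this interface.
#' @param cfg an [md_config()]; its thermostat supplies kind/friction, its
#'   `n_steps` is ignored in favour of `exchange_interval * n_exchanges`.
#' @param temperatures replica temperature list, K.
#' @param exchange_interval steps between exchange attempts.
#' @param n_exchanges number of segments.
#' @param mass per-bead mass, amu.
#' @return list with per-replica records (`replicas`), the exchange log
#'   data frame and the temperature trace.
#' @export
run_remd <- function(conf0s, ff, set, cfg, temperatures, exchange_interval,
                     n_exchanges, mass = 110) {
  n_rep <- length(temperatures)
  if (is.matrix(conf0s)) conf0s <- list(conf0s)
  conf0s <- rep_len(conf0s, n_rep)
  set.seed(cfg$seed)
  seeds <- sample.int(2^31 - 2, n_rep + 1)
  n <- nrow(conf0s[[1]])
  masses <- rep_len(mass, n)
  mode <- .mode_code[[cfg$restraint_mode]]

  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    reps[[r]] <- list(
      coords = .as_conformation(conf0s[[r]]),
      velocities = maxwell_velocities(masses, temperatures[r]),
      temperature = temperatures[r],
      tavg_state = if (mode == 2)
        memory_window_state(set, dt = cfg$dt, tau = cfg$tau,
                            n_ave = cfg$n_ave, N_tau = cfg$N_tau) else NULL,
      rng_state = get(".Random.seed", envir = globalenv()),
      trace = list())
  }
  set.seed(seeds[n_rep + 1])
  ex_rng <- get(".Random.seed", envir = globalenv())

  log <- data.frame(attempt = integer(0), replica_i = integer(0),
                    replica_j = integer(0), delta_E = numeric(0),
                    p = numeric(0), accepted = logical(0))
  temp_trace <- matrix(NA_real_, n_exchanges + 1, n_rep)
  temp_trace[1, ] <- vapply(reps, `[[`, numeric(1), "temperature")

  seg_cfg <- cfg
  seg_cfg$n_steps <- as.integer(exchange_interval)
  attempt <- 0
  for (leg in seq_len(n_exchanges)) {
    for (r in seq_len(n_rep)) {
      rep_r <- reps[[r]]
      th <- cfg$thermostat
      th$T_bath <- rep_r$temperature
      seg_cfg$thermostat <- th
      chk <- list(coords = rep_r$coords, velocities = rep_r$velocities,
                  tavg_state = rep_r$tavg_state, rng_state = rep_r$rng_state)
      rec <- run_trajectory(conf0 = rep_r$coords, ff = ff, set = set,
                            cfg = seg_cfg, mass = mass, resume = chk)
      reps[[r]]$coords <- rec$final$coords
      reps[[r]]$velocities <- rec$final$velocities
      reps[[r]]$tavg_state <- rec$final$tavg_state
      reps[[r]]$rng_state <- rec$final$rng_state
      ne <- nrow(rec$energies)
      reps[[r]]$energy <- if (ne > 0)
        rec$energies$E_pot[ne] + rec$energies$E_restraint[ne]
      else stop("set energy_interval to divide exchange_interval")
      reps[[r]]$trace[[leg]] <- rec$final$coords
    }
    # alternate neighbour pairings: (1,2),(3,4),... then (2,3),(4,5),...
    assign(".Random.seed", ex_rng, envir = globalenv())
    first <- if (n_rep == 2 || leg %% 2 == 1) 1 else 2
    pairs <- if (first > n_rep - 1) integer(0) else seq(first, n_rep - 1, by = 2)
    for (i in pairs) {
      attempt <- attempt + 1
      ex <- attempt_exchange(reps[[i]], reps[[i + 1]])
      reps[[i]]$temperature <- ex$replica_a$temperature
      reps[[i + 1]]$temperature <- ex$replica_b$temperature
      log[nrow(log) + 1, ] <- list(attempt, i, i + 1L,
                                   reps[[i]]$energy - reps[[i + 1]]$energy,
                                   ex$p, ex$accepted)
    }
    ex_rng <- get(".Random.seed", envir = globalenv())
    temp_trace[leg + 1, ] <- vapply(reps, `[[`, numeric(1), "temperature")
  }
  list(replicas = reps, exchange_log = log, temperature_trace = temp_trace,
       temperatures = temperatures)
}
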