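# Integrators, thermostats, trajectory driver and replica exchange.

free_forces <- function(x) list(energy = 0, forces = matrix(0, nrow(x), 3))

test_that("velocity Verlet gives uniform motion without forces and the
           analytic period for a harmonic dimer", {
  X <- rbind(c(0, 0, 0), c(5, 0, 0))
  V <- rbind(c(0.01, 0, 0), c(0, 0.02, 0))
  out <- velocity_verlet_step(X, V, matrix(0, 2, 3), 2, c(110, 110), free_forces)
  expect_equal(out$coords, X + 2 * V)
  expect_equal(out$velocities, V)
  expect_error(velocity_verlet_step(X, V, matrix(c(NaN, rep(0, 5)), 2, 3), 2,
                                    c(110, 110), free_forces),
               "non-finite force on bead 1")

  # dimer stretched along x: period 2 pi sqrt(mu / k_bond)
  ffb <- toy_forcefield(eps_ev = 0)
  mu <- 110 / 2
  period <- 2 * pi / sqrt(ffb$k_bond * tardyn:::.kcal / mu)
  dt <- period / 1000
  X <- rbind(c(0, 0, 0), c(ffb$b0 + 0.2, 0, 0))
  V <- matrix(0, 2, 3)
  force_fun <- function(x) toy_energy_forces(x, ffb)
  Fc <- force_fun(X)
  sep <- numeric(2500)
  for (s in 1:2500) {
    out <- velocity_verlet_step(X, V, Fc$forces, dt, c(110, 110), force_fun)
    X <- out$coords; V <- out$velocities; Fc <- out
    sep[s] <- X[2, 1] - X[1, 1]
  }
  crossings <- which(diff(sign(sep - ffb$b0)) > 0)
  measured <- mean(diff(crossings)) * dt
  expect_equal(measured, period, tolerance = 1e-3)
})

test_that("NVE total energy shows no secular drift over 1e5 steps", {
  ffb <- toy_forcefield(eps_ev = 0)
  conf <- rbind(c(0, 0, 0), c(ffb$b0 + 0.4, 0, 0))
  cfg <- md_config(n_steps = 100000, dt = 0.1, save_interval = 0,
                   energy_interval = 10, restraint_mode = "none", seed = 1,
                   T_init = 1)
  rec <- run_trajectory(conf, ffb, NULL, cfg)
  E <- rec$energies$E_total
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-6)
})

test_that("the Langevin step reduces to velocity Verlet at zero friction and
           is seeded-reproducible", {
  conf <- generate_random_chain(8, seed = 2)
  set.seed(10)
  V <- maxwell_velocities(rep(110, 8), 300)
  force_fun <- function(x) toy_energy_forces(x, ff_default)
  Fc <- force_fun(conf)
  th0 <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0)
  a <- langevin_step(conf, V, Fc$forces, 4.89, rep(110, 8), force_fun, th0)
  b <- velocity_verlet_step(conf, V, Fc$forces, 4.89, rep(110, 8), force_fun)
  expect_identical(a$coords, b$coords)
  expect_identical(a$velocities, b$velocities)

  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  set.seed(4)
  c1 <- langevin_step(conf, V, Fc$forces, 4.89, rep(110, 8), force_fun, th)
  set.seed(4)
  c2 <- langevin_step(conf, V, Fc$forces, 4.89, rep(110, 8), force_fun, th)
  expect_identical(c1$coords, c2$coords)
})

test_that("a free Langevin bead equilibrates at the bath temperature", {
  # single free bead, gamma = 0.05 * 0.01 fs^-1, long run
  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  X <- matrix(0, 1, 3); V <- matrix(0, 1, 3)
  force_fun <- function(x) list(energy = 0, forces = matrix(0, 1, 3))
  set.seed(21)
  n <- 40000
  Ts <- numeric(n)
  Fc <- matrix(0, 1, 3)
  for (s in 1:n) {
    out <- langevin_step(X, V, Fc, 4.89, 110, force_fun, th)
    X <- out$coords; V <- out$velocities
    Ts[s] <- kinetic_temperature(V, 110)
  }
  sel <- Ts[seq(5000, n, by = 50)]   # roughly decorrelated samples
  se <- sd(sel) / sqrt(length(sel))
  expect_lt(abs(mean(sel) - 300), 3 * se + 5)
})

test_that("Berendsen rescaling follows its closed form and drives the
           temperature to the bath", {
  spec <- thermostat_spec("berendsen", T_bath = 300, tau_berendsen = 489)
  V <- matrix(1:6 / 100, 2, 3)
  expect_identical(berendsen_rescale(V, 300, spec, 4.89), V)
  set.seed(3)
  for (k in 1:20) {
    Tk <- runif(1, 50, 900); dt <- runif(1, 0.1, 10)
    lam <- sqrt(1 + (dt / spec$tau_berendsen) * (300 / Tk - 1))
    expect_equal(berendsen_rescale(V, Tk, spec, dt) / V,
                 matrix(lam, 2, 3), tolerance = 1e-12)
  }
  # free-particle gas: repeated rescaling approaches T_bath monotonically
  set.seed(9)
  V <- maxwell_velocities(rep(110, 50), 600)
  Tk <- kinetic_temperature(V, rep(110, 50))
  for (s in 1:800) {
    V <- berendsen_rescale(V, Tk, spec, 4.89)
    Tnew <- kinetic_temperature(V, rep(110, 50))
    expect_lte(Tnew, Tk + 1e-9)
    Tk <- Tnew
  }
  expect_lt(abs(Tk - 300), 1)
})

test_that("kinetic temperature implements 2 E_kin / (kB N_dof)", {
  expect_equal(kinetic_temperature(matrix(0, 4, 3), rep(110, 4)), 0)
  # single bead with speed set for E_kin = (3/2) kB 250
  m <- 110
  v2 <- 3 * tardyn:::.kB * 250 * tardyn:::.kcal / m
  V <- matrix(c(sqrt(v2), 0, 0), 1, 3)
  expect_equal(kinetic_temperature(V, m), 250, tolerance = 1e-12)
  # Maxwell-Boltzmann sample at 300 K, 1e4 beads
  set.seed(11)
  V <- maxwell_velocities(rep(110, 1e4), 300)
  Tk <- kinetic_temperature(V, rep(110, 1e4))
  se <- 300 * sqrt(2 / (3 * 1e4))
  expect_lt(abs(Tk - 300), 3 * se)
})

test_that("run_trajectory dispatches restraint modes consistently", {
  conf <- generate_random_chain(10, seed = 6)
  cfg <- md_config(n_steps = 500, dt = 4.89, save_interval = 100,
                   energy_interval = 100, restraint_mode = "none", seed = 3)
  a <- run_trajectory(conf, ff_default, NULL, cfg)
  cfg$restraint_mode <- "instantaneous"
  b <- run_trajectory(conf, ff_default, restraint_set(), cfg)
  expect_identical(a$final$coords, b$final$coords)
  expect_identical(a$final$velocities, b$final$velocities)
  expect_equal(length(a$conformations), 5)
  expect_equal(nrow(a$energies), 5)
  expect_error(run_trajectory(conf, ff_default, NULL,
                              md_config(n_steps = 10,
                                        restraint_mode = "time_averaged")),
               "needs a restraint set")
})

test_that("canonical runs hold the bath temperature within 1 percent", {
  conf <- generate_random_chain(25, seed = 3)
  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  cfg <- md_config(n_steps = 200000, dt = 4.89, save_interval = 0,
                   energy_interval = 100, restraint_mode = "none",
                   thermostat = th, seed = 4, T_init = 300)
  rec <- run_trajectory(conf, ff_default, NULL, cfg)
  en <- rec$energies
  expect_lt(abs(mean(en$T_kin[en$step > 100000]) - 300), 3)
})

test_that("temperature conservation improves with larger tau and n_ave in
           time-averaged canonical runs", {
  conf <- generate_random_chain(25, seed = 1)
  set <- synthesize_restraints(conf, cutoff = 8, pad = 0.5, A = 5)
  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  devs <- vapply(list(c(4890, 1), c(489000, 1000)), function(g) {
    cfg <- md_config(n_steps = 60000, dt = 4.89, save_interval = 0,
                     energy_interval = 200, restraint_mode = "time_averaged",
                     tau = g[1], n_ave = g[2], thermostat = th, seed = 7,
                     T_init = 300)
    rec <- run_trajectory(conf, ff_default, set, cfg)
    en <- rec$energies
    abs(mean(en$T_kin[en$step > 30000]) - 300)
  }, numeric(1))
  expect_gt(devs[1], devs[2])   # short-memory run is the hotter one
})

test_that("Metropolis temperature exchange accepts downhill and matches the
           analytic rate", {
  a <- list(temperature = 300, energy = -50)
  b <- list(temperature = 330, energy = -50)
  ex <- attempt_exchange(a, b)
  expect_true(ex$accepted)
  expect_equal(ex$p, 1)
  expect_equal(ex$replica_a$temperature, 330)
  # hot replica lower in energy: downhill swap, p = 1
  ex2 <- attempt_exchange(list(temperature = 300, energy = -10),
                          list(temperature = 330, energy = -60))
  expect_equal(ex2$p, 1)
  # empirical acceptance over analytic-sampled harmonic energies
  kB <- tardyn:::.kB
  Ta <- 290; Tb <- 330; shape <- 10   # 20 harmonic dofs -> Gamma(10, kB T)
  set.seed(15)
  Ea <- rgamma(10000, shape, scale = kB * Ta)
  Eb <- rgamma(10000, shape, scale = kB * Tb)
  acc <- vapply(1:10000, function(i)
    attempt_exchange(list(temperature = Ta, energy = Ea[i]),
                     list(temperature = Tb, energy = Eb[i]))$accepted,
    logical(1))
  Ea2 <- rgamma(2e5, shape, scale = kB * Ta)   # independent analytic estimate
  Eb2 <- rgamma(2e5, shape, scale = kB * Tb)
  p_exp <- mean(pmin(1, exp((1 / (kB * Ta) - 1 / (kB * Tb)) * (Ea2 - Eb2))))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(mean(acc) - p_exp), 3 * se + 0.01)
})

test_that("replica exchange swaps temperatures with consistent bookkeeping", {
  conf <- generate_random_chain(10, seed = 5)
  set <- synthesize_restraints(conf, cutoff = 8, pad = 0.5)
  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  cfg <- md_config(n_steps = 1, dt = 4.89, energy_interval = 100,
                   restraint_mode = "instantaneous", thermostat = th, seed = 3)
  # identical temperatures: every attempt accepted
  res <- run_remd(conf, ff_default, set, cfg, temperatures = c(300, 300),
                  exchange_interval = 300, n_exchanges = 5)
  expect_equal(mean(res$exchange_log$accepted), 1)
  expect_equal(nrow(res$exchange_log), 5)
  # three temperatures: alternating neighbour pairings, temperatures permute
  res3 <- run_remd(conf, ff_default, set, cfg, temperatures = c(280, 300, 330),
                   exchange_interval = 300, n_exchanges = 6)
  expect_equal(nrow(res3$exchange_log), 6)  # 1 pair on odd legs, 1 on even
  for (leg in seq_len(nrow(res3$temperature_trace)))
    expect_setequal(res3$temperature_trace[leg, ], c(280, 300, 330))
})

test_that("exploding trajectories abort with the step index", {
  conf <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  cfg <- md_config(n_steps = 1000, dt = 4.89, save_interval = 0,
                   energy_interval = 100, restraint_mode = "none", seed = 1)
  v <- matrix(c(120, rep(0, 5)), 2, 3)  # absurd velocity: 120 A/fs
  expect_error(run_trajectory(conf, ff_default, NULL, cfg, velocities = v),
               "blew up at step")
})
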