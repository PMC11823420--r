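# Exponential-memory time averaging: accumulation, block commits, effective
# averages, force scaling, and the time-averaged force chain rule.

simple_set <- restraint_set(
  distance = list(distance_restraint(1, 3, 3, 5)),
  angle = list(angle_restraint(2, 80, 120)),
  dihedral = list(dihedral_restraint(2, -40, 40)))

test_that("block accumulation is a commutative running sum of y^-m", {
  st <- memory_window_state(simple_set, dt = 1, tau = 100, n_ave = 8)
  for (i in 1:8)
    st <- accumulate_step(st, list(dist = 4, theta = 100, gamma = 20))
  expect_equal(st$acc_d / st$acc_steps, 4^-3)
  expect_equal(st$acc_theta / st$acc_n_theta, 100)
  expect_error(accumulate_step(st, list(dist = 4, theta = 100, gamma = 20)),
               "commit_block")
  # order within a block does not matter beyond round-off; running sum
  # matches an independently stored list
  set.seed(6)
  ys <- runif(8, 3, 6)
  s1 <- memory_window_state(restraint_set(
    distance = list(distance_restraint(1, 3, 3, 5))), dt = 1, tau = 100, n_ave = 8)
  s2 <- s1
  for (y in ys) s1 <- accumulate_step(s1, list(dist = y))
  for (y in rev(ys)) s2 <- accumulate_step(s2, list(dist = y))
  expect_equal(s1$acc_d, s2$acc_d, tolerance = 1e-12)
  expect_equal(s1$acc_d, sum(ys^-3), tolerance = 1e-12)
  fresh <- memory_window_state(restraint_set(
    distance = list(distance_restraint(1, 3, 3, 5))), dt = 1, tau = 100,
    n_ave = 8)
  expect_error(accumulate_step(fresh, list(dist = -1)), "positive")
})

test_that("committing appends decaying block averages and evicts beyond tau", {
  st <- memory_window_state(simple_set, dt = 1, tau = 50, n_ave = 10)
  expect_error(commit_block(st), "cannot commit")
  st <- drive_state(st, dist = rep(4, 200), theta = rep(100, 200),
                    gamma = rep(20, 200))
  expect_equal(ncol(st$hist_d), st$K_max)   # eviction at K_max = 5 blocks
  expect_equal(st$I, 20)
  expect_equal(st$i, 200)
  # constant signal committed over >= tau of history: fixed point
  ea <- effective_average(st, list(dist = 4, theta = 100, gamma = 20))
  expect_equal(ea$dist, 4, tolerance = 1e-6)
  expect_equal(ea$theta, 100, tolerance = 1e-6)
  expect_equal(ea$gamma, 20, tolerance = 1e-6)
})

test_that("the filled window weight matches tau (1 - e^-1) block units", {
  st <- memory_window_state(simple_set, dt = 1, tau = 100, n_ave = 1)
  st <- drive_state(st, dist = rep(4, 150), theta = rep(100, 150),
                    gamma = rep(20, 150))
  W <- sum(exp(-seq_len(ncol(st$hist_d)) * st$n_ave * st$dt / st$tau))
  target <- st$tau * (1 - exp(-1)) / (st$n_ave * st$dt)
  expect_equal(W, target, tolerance = 0.02)   # trapezoid-level error
})

test_that("effective averages reduce to the momentary value, mix committed
           blocks and wrap dihedrals circularly", {
  st0 <- memory_window_state(simple_set, dt = 1, tau = 100, n_ave = 10)
  ea0 <- effective_average(st0, list(dist = 4.7, theta = 93, gamma = -12))
  expect_identical(ea0$dist, 4.7)
  expect_identical(ea0$theta, 93)
  expect_identical(ea0$gamma, -12)
  expect_error(effective_average(st0, NULL), "empty state")

  # m = -1: two committed blocks with means 10 and 20 average to 15 up to
  # the weight-decay correction computed by the direct oracle
  sa <- restraint_set(angle = list(angle_restraint(2, 80, 120)))
  st <- memory_window_state(sa, dt = 1, tau = 1e6, n_ave = 5)
  hist <- c(rep(10, 5), rep(20, 5))
  st <- drive_state(st, theta = hist)
  ea <- effective_average(st, list(theta = 20))
  oracle <- oracle_direct_average(c(hist, 20), tau = 1e6, dt = 1, m = -1,
                                  n_ave = 5)
  expect_equal(ea$theta, oracle, tolerance = 1e-9)
  # committed history alone: equal-weight blocks at 10 and 20 average to 15
  # (up to the tau-decay of the older block, negligible at tau = 1e6)
  expect_equal(effective_average(st, NULL)$theta, 15, tolerance = 1e-4)

  # dihedral history alternating +/-179 averages to 180, not 0
  sg <- restraint_set(dihedral = list(dihedral_restraint(2, -40, 40)))
  stg <- memory_window_state(sg, dt = 1, tau = 100, n_ave = 1)
  stg <- drive_state(stg, gamma = rep(c(179, -179), 60))
  g <- effective_average(stg, list(gamma = 179))$gamma
  expect_lt(min(abs(g - 180), abs(g + 180)), 1)
})

test_that("degenerate-angle steps are skipped with renormalized weights", {
  sa <- restraint_set(angle = list(angle_restraint(2, 80, 120)))
  st <- memory_window_state(sa, dt = 1, tau = 100, n_ave = 4)
  for (v in c(100, NA, NA, 140)) st <- accumulate_step(st, list(theta = v))
  st <- commit_block(st)
  expect_equal(st$hist_theta[1, 1], 120)      # mean over the 2 valid steps
  expect_equal(st$hist_frac_theta[1, 1], 0.5)
  expect_equal(effective_average(st, NULL)$theta, 120)
})

test_that("the force-scaling ramp runs linearly from 1 to the closed-form
           maximum", {
  # tau = 4.89 ps, dt = 0.489 fs, n_ave = 1: f_max = (1 - e^-1) 1e4
  st <- memory_window_state(simple_set, dt = 0.489, tau = 4890, n_ave = 1)
  expect_equal(scaling_factor(st, 0), 1)
  expect_equal(scaling_factor(st, st$N_tau), (1 - exp(-1)) * 1e4,
               tolerance = 0.1 / 6321)
  expect_equal(scaling_factor(st, st$N_tau * 50), st$f_max)
  f <- vapply(0:12000, function(i) scaling_factor(st, i), numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 1 & f <= st$f_max))
  # with n_ave dt >= tau (1 - e^-1) the factor clamps to 1
  stc <- memory_window_state(simple_set, dt = 1, tau = 10, n_ave = 10)
  expect_equal(stc$f_max, 1)
})

test_that("the direct-quadrature oracle agrees with the incremental state
           machine on random signals", {
  # constant history and the uniform-weight (tau -> infinity) limit
  expect_equal(oracle_direct_average(rep(3, 50), 100, 1, 3), 3)
  set.seed(8)
  y <- runif(200, 10, 30)
  expect_equal(oracle_direct_average(y, 1e9, 1, -1),
               mean(c(y, y[200])), tolerance = 1e-3)
  # cross-validation of the two code paths (see also the acceptance suite)
  for (n_ave in c(1, 7)) {
    sig <- smooth_signal(400, 5, seed = n_ave)
    st <- memory_window_state(restraint_set(
      distance = list(distance_restraint(1, 3, 3, 5))), dt = 1, tau = 120,
      n_ave = n_ave)
    st <- drive_state(st, dist = sig)
    ea <- effective_average(st, list(dist = sig[400]))$dist
    expect_equal(ea, oracle_direct_average(sig, 120, 1, 3, n_ave),
                 tolerance = 1e-9)
  }
})

test_that("time-averaged forces scale to the instantaneous force at frozen
           geometry and are exact gradients within a block", {
  conf <- generate_random_chain(15, seed = 11)
  set <- synthesize_restraints(conf, cutoff = 10, pad = 0.5)
  set$angle <- list(angle_restraint(5, 80, 100), angle_restraint(8, 80, 100))
  set$dihedral <- list(dihedral_restraint(6, -30, 30))
  conf2 <- conf + matrix(rnorm(45, 0, 0.35), 15, 3)   # push into the walls
  dt <- 4.89
  st <- memory_window_state(set, dt = dt, tau = 1e4 * dt, n_ave = 10)
  mv <- measure(conf2, set)
  for (i in seq_len(2 * st$N_tau)) {
    st <- accumulate_step(st, mv)
    if (st$acc_steps == st$n_ave) st <- commit_block(st)
  }
  tf <- timeavg_forces(st, conf2, set)
  inst <- tardyn:::cpp_inst_restraint(conf2, tardyn:::.rset_flat(set))
  expect_lt(max(abs(tf$forces - inst$forces)) / max(abs(inst$forces)), 0.02)

  # empty set: zero forces, zero energy
  st0 <- memory_window_state(restraint_set(), dt = dt, tau = 100)
  tf0 <- timeavg_forces(st0, conf, restraint_set())
  expect_equal(tf0$energy, 0)
  expect_equal(max(abs(tf0$forces)), 0)

  # within a block the scaled energy is the exact potential of the scaled
  # force: central differences at frozen state
  tfs <- timeavg_forces(st, conf2, set, scale_energy = TRUE)
  h <- 1e-5
  set.seed(12)
  for (k in sample(45, 8)) {
    i <- (k - 1) %/% 3 + 1; q <- (k - 1) %% 3 + 1
    cp <- conf2; cp[i, q] <- cp[i, q] + h
    cm <- conf2; cm[i, q] <- cm[i, q] - h
    fd <- -(timeavg_forces(st, cp, set, TRUE)$energy_scaled -
              timeavg_forces(st, cm, set, TRUE)$energy_scaled) / (2 * h)
    expect_equal(fd, tfs$forces[i, q],
                 tolerance = 1e-5 * max(1, abs(tfs$forces[i, q])))
  }
  # repeated evaluation at the same coordinates is bitwise identical
  expect_identical(timeavg_forces(st, conf2, set)$energy, tf$energy)
  expect_identical(timeavg_forces(st, conf2, set)$forces, tf$forces)
})

test_that("the r^-3 time average never exceeds the plain mean of the same
           history", {
  set.seed(17)
  for (k in 1:20) {
    sig <- runif(300, 2, 12)
    ybar <- oracle_direct_average(sig, 150, 1, 3)
    w <- exp(-(0:149) / 150)       # same truncated window, plain mean
    plain <- sum(w * rev(sig)[1:150]) / sum(w)
    expect_lte(ybar, plain + 1e-9)
  }
})

test_that("the C++ trajectory loop reproduces the R-level state machine", {
  conf <- generate_random_chain(12, seed = 31)
  set <- synthesize_restraints(conf, cutoff = 9, pad = 0.4)
  set$angle <- list(angle_restraint(5, 80, 100))
  set$dihedral <- list(dihedral_restraint(4, -30, 30))
  cfg <- md_config(n_steps = 150, dt = 0.489, save_interval = 0,
                   energy_interval = 0, restraint_mode = "time_averaged",
                   tau = 0.489 * 40, n_ave = 10, seed = 5, T_init = 300)
  rec <- run_trajectory(conf, ff_default, set, cfg)

  masses <- rep(110, 12)
  set.seed(5)
  vel <- maxwell_velocities(masses, 300)
  X <- conf
  rf <- tardyn:::.rset_flat(set)
  st <- memory_window_state(set, dt = cfg$dt, tau = cfg$tau, n_ave = cfg$n_ave)
  st <- accumulate_step(st, measure(X, set))
  force_fun <- function(x) {
    tf <- toy_energy_forces(x, ff_default)
    tv <- tardyn:::cpp_tavg_forces(x, rf, unclass(st), FALSE)
    list(energy = tf$energy + tv$energy, forces = tf$forces + tv$forces)
  }
  Fc <- force_fun(X)
  for (s in 1:150) {
    out <- velocity_verlet_step(X, vel, Fc$forces, cfg$dt, masses, force_fun)
    X <- out$coords; vel <- out$velocities; Fc <- out
    st <- accumulate_step(st, measure(X, set))
    if (st$acc_steps == st$n_ave) { st <- commit_block(st); Fc <- force_fun(X) }
  }
  expect_equal(max(abs(X - rec$final$coords)), 0)
  expect_equal(st$i, rec$final$tavg_state$i)
  expect_equal(st$hist_d, rec$final$tavg_state$hist_d, tolerance = 1e-14)
})

test_that("checkpointed runs resume bit-exactly", {
  conf <- generate_random_chain(10, seed = 5)
  set <- synthesize_restraints(conf, cutoff = 8, pad = 0.5)
  th <- thermostat_spec("langevin", T_bath = 300, friction_scale = 0.05)
  cfg <- md_config(n_steps = 2000, dt = 4.89, save_interval = 0,
                   energy_interval = 500, restraint_mode = "time_averaged",
                   tau = 4890, n_ave = 100, thermostat = th, seed = 9)
  full <- run_trajectory(conf, ff_default, set, cfg)
  cfg$n_steps <- 1000L
  part <- run_trajectory(conf, ff_default, set, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(part, path)
  chk <- read_checkpoint(path)
  resumed <- run_trajectory(conf, ff_default, set, cfg, resume = chk)
  expect_identical(resumed$final$coords, full$final$coords)
  expect_identical(resumed$final$velocities, full$final$velocities)
  expect_equal(resumed$final$tavg_state$hist_d, full$final$tavg_state$hist_d)
  # write -> read -> write is idempotent
  path2 <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(part, path2)
  expect_identical(readRDS(path), readRDS(path2))
})
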