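# Exponential-memory time averaging of restrained quantities.
#
# The restrained quantity y_j is averaged over a trailing memory window of
# length tau with exponential weighting.  The memory integral is committed in
# blocks of n_ave steps: each committed block stores the simple average of
# y^-m over the block (sines/cosines for dihedrals) and carries weight
# exp(-k * n_ave * dt / tau) when it lies k blocks back; blocks older than
# tau are evicted.  Between commits the momentary value stands in for the
# current block (weight 1), so the extended energy depends only on the
# current coordinates and frozen history inside a block.  With the window
# filled, the normalization weight approaches tau (1 - e^-1) / (n_ave dt)
# block units, and the momentary-term weight fraction approaches
# n_ave dt / [tau (1 - e^-1)] -- the attenuation that the force-scaling ramp
# f_i (1 -> (1 - e^-1) tau / (n_ave dt) over N_tau steps) cancels.

#' Memory-window state for time-averaged restraints
#'
#' @param set a [restraint_set()].
#' @param dt MD time step, fs.
#' @param tau memory-window length, fs (default 489 ps).
#' @param n_ave steps per committed block.
#' @param N_tau force-scaling ramp length in steps; default `floor(tau/dt)`.
#' @return object of class `memory_window_state`.
#' @export
memory_window_state <- function(set, dt, tau = 489000, n_ave = 1000,
                                N_tau = NULL) {
  stopifnot(inherits(set, "restraint_set"), dt > 0, tau > 0, n_ave >= 1)
  n_ave <- as.integer(n_ave)
  if (is.null(N_tau)) N_tau <- floor(tau / dt)
  K_max <- max(1L, as.integer(floor(tau / (n_ave * dt))))
  f_max <- max(1, (1 - exp(-1)) * tau / (n_ave * dt))
  nd <- length(set$distance); nt <- length(set$angle); ng <- length(set$dihedral)
  structure(list(
    tau = tau, dt = dt, n_ave = n_ave, N_tau = as.integer(N_tau),
    K_max = K_max, f_max = f_max, i = 0, I = 0,
    nd = nd, nt = nt, ng = ng,
    hist_d = matrix(0, nd, 0), hist_theta = matrix(0, nt, 0),
    hist_sin = matrix(0, ng, 0), hist_cos = matrix(0, ng, 0),
    hist_frac_theta = matrix(0, nt, 0), hist_frac_gamma = matrix(0, ng, 0),
    acc_d = numeric(nd), acc_theta = numeric(nt),
    acc_sin = numeric(ng), acc_cos = numeric(ng),
    acc_n_theta = integer(nt), acc_n_gamma = integer(ng),
    acc_steps = 0L), class = "memory_window_state")
}

#' Accumulate one step of instantaneous values into the current block
#'
#' Adds `y^-m` (sines and cosines for dihedrals) of the momentary values to
#' the running block accumulator.  `NA` angle values (flagged degenerate
#' geometry) skip accumulation; their block weight is renormalized over the
#' valid steps.  The committed history is untouched.
#'
#' @param state a [memory_window_state()].
#' @param values list with `dist`, `theta`, `gamma` as from [measure()].
#' @return the updated state.
#' @export
accumulate_step <- function(state, values) {
  stopifnot(inherits(state, "memory_window_state"))
  if (state$acc_steps >= state$n_ave)
    stop("current block already holds n_ave steps; commit_block() first")
  d <- values$dist %||% numeric(0)
  th <- values$theta %||% numeric(0)
  g <- values$gamma %||% numeric(0)
  if (length(d) != state$nd || length(th) != state$nt || length(g) != state$ng)
    stop("value vectors do not match the restraint counts")
  if (any(!is.na(d) & d <= 0) || anyNA(d))
    stop("restrained distances must be positive and present")
  state$acc_d <- state$acc_d + d^(-3)
  ok <- !is.na(th)
  state$acc_theta[ok] <- state$acc_theta[ok] + th[ok]
  state$acc_n_theta[ok] <- state$acc_n_theta[ok] + 1L
  ok <- !is.na(g)
  grad <- g[ok] * pi / 180
  state$acc_sin[ok] <- state$acc_sin[ok] + sin(grad)
  state$acc_cos[ok] <- state$acc_cos[ok] + cos(grad)
  state$acc_n_gamma[ok] <- state$acc_n_gamma[ok] + 1L
  state$acc_steps <- state$acc_steps + 1L
  state$i <- state$i + 1
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Commit the current block to the memory window
#'
#' Appends the block's simple average (over its valid steps) to the committed
#' history; all block weights decay by `exp(-n_ave dt / tau)` implicitly
#' through their position, and blocks older than tau are evicted.  The block
#' accumulator is reset and the block counter advanced.
#'
#' @param state a [memory_window_state()] whose block is full.
#' @return the updated state.
#' @export
commit_block <- function(state) {
  stopifnot(inherits(state, "memory_window_state"))
  if (state$acc_steps != state$n_ave)
    stop("cannot commit: block holds ", state$acc_steps, " of ",
         state$n_ave, " steps")
  nav <- state$n_ave
  bd <- state$acc_d / nav
  bt <- ifelse(state$acc_n_theta > 0, state$acc_theta / pmax(state$acc_n_theta, 1), 0)
  ft <- state$acc_n_theta / nav
  bs <- ifelse(state$acc_n_gamma > 0, state$acc_sin / pmax(state$acc_n_gamma, 1), 0)
  bc <- ifelse(state$acc_n_gamma > 0, state$acc_cos / pmax(state$acc_n_gamma, 1), 0)
  fg <- state$acc_n_gamma / nav
  keep <- seq_len(min(ncol(state$hist_d), state$K_max - 1L))
  state$hist_d <- cbind(bd, state$hist_d[, keep, drop = FALSE], deparse.level = 0)
  state$hist_theta <- cbind(bt, state$hist_theta[, keep, drop = FALSE], deparse.level = 0)
  state$hist_sin <- cbind(bs, state$hist_sin[, keep, drop = FALSE], deparse.level = 0)
  state$hist_cos <- cbind(bc, state$hist_cos[, keep, drop = FALSE], deparse.level = 0)
  state$hist_frac_theta <- cbind(ft, state$hist_frac_theta[, keep, drop = FALSE],
                                 deparse.level = 0)
  state$hist_frac_gamma <- cbind(fg, state$hist_frac_gamma[, keep, drop = FALSE],
                                 deparse.level = 0)
  state$acc_d <- numeric(state$nd)
  state$acc_theta <- numeric(state$nt)
  state$acc_sin <- numeric(state$ng)
  state$acc_cos <- numeric(state$ng)
  state$acc_n_theta <- integer(state$nt)
  state$acc_n_gamma <- integer(state$ng)
  state$acc_steps <- 0L
  state$I <- state$I + 1
  state
}

# committed-window weights and sums; returns per-kind numerator/denominator
.window_sums <- function(state) {
  nb <- ncol(state$hist_d)
  a <- state$n_ave * state$dt / state$tau
  w <- if (nb > 0) exp(-a * seq_len(nb)) else numeric(0)
  list(
    Nd = if (state$nd) as.numeric(state$hist_d %*% w) else numeric(0),
    Wd = sum(w),
    Nt = if (state$nt) as.numeric((state$hist_theta * state$hist_frac_theta) %*% w) else numeric(0),
    Wt = if (state$nt) as.numeric(state$hist_frac_theta %*% w) else numeric(0),
    Ns = if (state$ng) as.numeric((state$hist_sin * state$hist_frac_gamma) %*% w) else numeric(0),
    Nc = if (state$ng) as.numeric((state$hist_cos * state$hist_frac_gamma) %*% w) else numeric(0),
    Wg = if (state$ng) as.numeric(state$hist_frac_gamma %*% w) else numeric(0))
}

#' Effective time-averaged values
#'
#' Weighted mean of the committed `y^-m` history plus the momentary term,
#' back-transformed: `ybar = S^(-1/m)` for distances (m = 3), the direct
#' weighted mean for angles (m = -1) and `atan2` of the averaged sine and
#' cosine for dihedrals.  Before any history exists, `ybar = y_now`.
#'
#' @param state a [memory_window_state()].
#' @param values momentary values as from [measure()]; may be `NULL` once
#'   history exists (the momentary term is then omitted).
#' @return list with `dist`, `theta`, `gamma`.
#' @export
effective_average <- function(state, values = NULL) {
  stopifnot(inherits(state, "memory_window_state"))
  s <- .window_sums(state)
  nb <- ncol(state$hist_d)
  if (is.null(values) && nb == 0)
    stop("empty state and no momentary values")
  d <- values$dist %||% rep(NA_real_, state$nd)
  th <- values$theta %||% rep(NA_real_, state$nt)
  g <- values$gamma %||% rep(NA_real_, state$ng)

  w0d <- as.numeric(!is.na(d))
  if (any(w0d == 0) && nb == 0) stop("missing distance with empty history")
  if (nb == 0) {
    dist <- d                      # no committed history: momentary value
  } else {
    Sd <- (s$Nd + ifelse(w0d > 0, d^(-3), 0)) / (s$Wd + w0d)
    dist <- Sd^(-1 / 3)
  }

  w0t <- as.numeric(!is.na(th))
  Wt <- s$Wt + w0t
  theta <- ifelse(Wt > 0, (s$Nt + ifelse(w0t > 0, th, 0)) / pmax(Wt, 1e-300),
                  NA_real_)

  w0g <- as.numeric(!is.na(g))
  grad <- ifelse(w0g > 0, g * pi / 180, 0)
  Wg <- s$Wg + w0g
  Sbar <- (s$Ns + w0g * sin(grad)) / pmax(Wg, 1e-300)
  Cbar <- (s$Nc + w0g * cos(grad)) / pmax(Wg, 1e-300)
  gamma <- ifelse(Wg > 0, .wrap180(atan2(Sbar, Cbar) * 180 / pi), NA_real_)

  list(dist = dist, theta = theta, gamma = gamma)
}

#' Restraint-force scaling factor
#'
#' Ramps linearly from 1 at step 0 to
#' `f_max = max(1, (1 - e^-1) tau / (n_ave dt))` at step `N_tau` and stays
#' there; monotone non-decreasing.
#'
#' @param state a [memory_window_state()].
#' @param i step index (default: the state's own step counter).
#' @return the scaling factor `f_i`.
#' @export
scaling_factor <- function(state, i = state$i) {
  stopifnot(inherits(state, "memory_window_state"), i >= 0)
  if (state$N_tau <= 0 || i >= state$N_tau) return(state$f_max)
  1 + (state$f_max - 1) * (i / state$N_tau)
}

#' Time-averaged restraint forces and (unscaled) energy
#'
#' Chain rule through the effective average: `dV/dybar` at the time-averaged
#' value, times the momentary-term weight `d(ybar)/d(y)`, times the geometric
#' gradient of the restrained quantity.  The force is multiplied by the
#' scaling factor `f_i`; the returned energy is the unscaled `V(ybar)` used
#' for replica exchange and reporting.  With `scale_energy = TRUE` the scaled
#' energy `f_i V(ybar)` is also returned (the total-energy conservation
#' diagnostic).
#'
#' @param state a [memory_window_state()].
#' @param conf n x 3 coordinate matrix.
#' @param set the [restraint_set()] the state was built for.
#' @param scale_energy also return the force-consistent scaled energy.
#' @return list with `forces` (n x 3, scaled), `energy` (unscaled, kcal/mol),
#'   `f` and optionally `energy_scaled`.
#' @export
timeavg_forces <- function(state, conf, set, scale_energy = FALSE) {
  stopifnot(inherits(state, "memory_window_state"),
            inherits(set, "restraint_set"))
  if (length(set$distance) != state$nd || length(set$angle) != state$nt ||
      length(set$dihedral) != state$ng)
    stop("restraint set does not match the state's restraint counts")
  conf <- .as_conformation(conf)
  rf <- .rset_flat(set, nrow(conf))
  out <- cpp_tavg_forces(conf, rf, unclass(state), scale_energy)
  res <- list(forces = out$forces, energy = out$energy, f = out$f)
  if (scale_energy) res$energy_scaled <- out$energy_scaled
  res
}

#' Direct-quadrature oracle for the memory-window average
#'
#' Brute-force evaluation of the truncated-exponential weighted average over
#' a complete stored per-step history: the history is cut into consecutive
#' blocks of `n_ave` steps (simple block averages of `y^-m`), block k back
#' carries weight `exp(-k n_ave dt / tau)`, blocks older than tau are
#' dropped, and the final history entry supplies the momentary term with
#' weight 1.  With `n_ave = 1` this is the direct per-step quadrature of the
#' memory integral.  Kept deliberately non-recursive as a cross-check of the
#' incremental state machine.
#'
#' @param history numeric vector of per-step values, oldest first; the last
#'   entry is the momentary value.
#' @param tau,dt memory-window length and step, fs.
#' @param m averaging exponent (3 for distances, -1 for angles).
#' @param n_ave steps per block.
#' @return the effective average `ybar`.
#' @export
oracle_direct_average <- function(history, tau, dt, m, n_ave = 1) {
  stopifnot(length(history) >= 1, tau > 0, dt > 0, n_ave >= 1)
  n <- length(history)
  y_now <- history[n]
  z <- history^(-m)
  nb <- n %/% n_ave
  K_max <- max(1L, as.integer(floor(tau / (n_ave * dt))))
  a <- n_ave * dt / tau
  num <- z[n]                      # momentary term, weight 1
  den <- 1
  K_use <- min(nb, K_max)
  for (k in seq_len(K_use)) {
    blk <- ((nb - k) * n_ave + 1):((nb - k + 1) * n_ave)
    num <- num + exp(-a * k) * mean(z[blk])
    den <- den + exp(-a * k)
  }
  (num / den)^(-1 / m)
}
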