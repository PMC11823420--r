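# Shared fixtures: all built in code, fixed seeds.

ff_default <- toy_forcefield()

# planar zigzag with right angles in the xy plane
zigzag_chain <- function(n, b = 3.8) {
  X <- matrix(0, n, 3)
  for (i in 2:n) {
    dir <- if (i %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
    X[i, ] <- X[i - 1, ] + b * dir
  }
  X
}

# independent signed-dihedral oracle: interplanar angle via normalized plane
# normals, sign from the triple product (distinct route from atan2 formula)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

random_rigid_motion <- function(X, seed) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix, forced to det +1
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% Q, 2, rnorm(3, sd = 10), `+`)
}

# smooth, MD-like random signal (positive, slowly varying)
smooth_signal <- function(n, base, seed, sd_step = 0.02) {
  set.seed(seed)
  base + cumsum(rnorm(n, 0, sd_step))
}

mixed_restraint_set <- function() {
  restraint_set(
    distance = list(distance_restraint(1, 4, 4, 6),
                    distance_restraint(2, 6, 5, 7, A = 2)),
    angle = list(angle_restraint(3, 90, 120)),
    dihedral = list(dihedral_restraint(3, -40, 40)))
}

# drive the R-level state machine over a per-step value list
drive_state <- function(state, dist = NULL, theta = NULL, gamma = NULL) {
  n <- max(length(dist), length(theta), length(gamma))
  for (i in seq_len(n)) {
    state <- accumulate_step(state, list(
      dist = if (!is.null(dist)) dist[i],
      theta = if (!is.null(theta)) theta[i],
      gamma = if (!is.null(gamma)) gamma[i]))
    if (state$acc_steps == state$n_ave) state <- commit_block(state)
  }
  state
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
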