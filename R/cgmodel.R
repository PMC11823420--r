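# Coarse-grained C-alpha bead chain: topology, internal coordinates, the
# declared toy force field, and the random-chain build-up generator.

#' Chain topology of a C-alpha bead model
#'
#' @param n_beads number of residues (beads); at least 2, and at least 4 for
#'   any run using virtual-bond-angle or dihedral restraints.
#' @param labels optional per-bead residue identifiers (default `ALA`).
#' @param b0 equilibrium virtual-bond length in Angstrom.
#' @param mass per-bead mass in amu (scalar or length `n_beads`).
#' @return an object of class `chain_topology`.
#' @export
chain_topology <- function(n_beads, labels = NULL, b0 = 3.8, mass = 110) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 2) stop("chain must have at least 2 beads")
  if (b0 <= 0) stop("b0 must be positive")
  mass <- rep_len(mass, n_beads)
  if (any(mass <= 0)) stop("masses must be positive")
  if (is.null(labels)) labels <- rep("ALA", n_beads)
  if (length(labels) != n_beads) stop("labels must have one entry per bead")
  structure(list(n_beads = n_beads, labels = labels, b0 = b0, mass = mass),
            class = "chain_topology")
}

#' Toy bead force field
#'
#' A minimal stand-in potential for a coarse-grained protein force field:
#' harmonic virtual bonds, harmonic virtual-bond angles, a cosine series on
#' the virtual-bond dihedrals and a purely repulsive (WCA) excluded-volume
#' term that vanishes with zero slope at its cutoff `2^(1/6) * sigma_ev`.
#'
#' Default constants are chosen so that the stiffest virtual-bond normal mode
#' (period about 360 fs at the default masses) is resolved roughly 70-fold by
#' the production time step of 4.89 fs.
#'
#' @param k_bond bond force constant, kcal/mol/A^2.
#' @param theta0,k_theta harmonic virtual-bond-angle minimum (deg) and force
#'   constant (kcal/mol/deg^2).
#' @param dihedral_coef coefficients `c_k` of `sum_k c_k (1 + cos(k gamma))`,
#'   kcal/mol.
#' @param eps_ev,sigma_ev WCA excluded-volume parameters (kcal/mol, A).
#' @param b0 equilibrium virtual-bond length, A.
#' @param clash_cutoff nonbonded distance (A) treated as an overlap by the
#'   chain generator (roughly where the WCA energy reaches a few kT at 300 K).
#' @return an object of class `toy_forcefield`.
#' @export
toy_forcefield <- function(k_bond = 20, theta0 = 105, k_theta = 0.005,
                           dihedral_coef = c(0.2, 0, 0.3),
                           eps_ev = 0.5, sigma_ev = 4.0, b0 = 3.8,
                           clash_cutoff = 3.7) {
  stopifnot(is.finite(k_bond), is.finite(theta0), is.finite(k_theta),
            all(is.finite(dihedral_coef)), eps_ev >= 0, sigma_ev > 0, b0 > 0)
  structure(list(k_bond = k_bond, theta0 = theta0, k_theta = k_theta,
                 dihedral_coef = as.numeric(dihedral_coef),
                 eps_ev = eps_ev, sigma_ev = sigma_ev, b0 = b0,
                 clash_cutoff = clash_cutoff),
            class = "toy_forcefield")
}

.as_conformation <- function(conf) {
  conf <- as.matrix(conf)
  if (ncol(conf) != 3) stop("a conformation is an n x 3 coordinate matrix")
  if (!all(is.finite(conf))) stop("coordinates must be finite")
  storage.mode(conf) <- "double"
  conf
}

#' Internal coordinates of a C-alpha trace
#'
#' Virtual-bond angles `theta_i` (vertex at bead i, i = 2..n-1) and signed
#' virtual-bond dihedrals `gamma_i` (axis through beads i and i+1,
#' i = 2..n-2), both in degrees, `gamma` wrapped to (-180, 180].  Collinear
#' triples make the dihedral geometrically undefined; such dihedrals are
#' flagged (`gamma_ok = FALSE`, value `NA`) rather than assigned arbitrarily.
#'
#' @param conf n x 3 coordinate matrix (Angstrom), n >= 4.
#' @return list with `theta`, `gamma`, `theta_ok`, `gamma_ok`.
#' @export
internal_coords <- function(conf) {
  conf <- .as_conformation(conf)
  n <- nrow(conf)
  if (n < 4) stop("chain too short: internal coordinates need at least 4 beads")
  theta <- rep(NA_real_, n - 2)
  theta_ok <- rep(TRUE, n - 2)
  for (i in 2:(n - 1)) {
    u <- conf[i - 1, ] - conf[i, ]
    v <- conf[i + 1, ] - conf[i, ]
    ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ct <- max(-1, min(1, ct))
    theta[i - 1] <- acos(ct) * 180 / pi
  }
  gamma <- rep(NA_real_, n - 3)
  gamma_ok <- rep(FALSE, n - 3)
  for (i in 2:(n - 2)) {
    b1 <- conf[i, ] - conf[i - 1, ]
    b2 <- conf[i + 1, ] - conf[i, ]
    b3 <- conf[i + 2, ] - conf[i + 1, ]
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) next  # collinear: undefined
    y <- sum(.cross3(n1, n2) * b2) / nb2
    x <- sum(n1 * n2)
    gamma[i - 1] <- .wrap180(atan2(y, x) * 180 / pi)
    gamma_ok[i - 1] <- TRUE
  }
  list(theta = theta, gamma = gamma, theta_ok = theta_ok, gamma_ok = gamma_ok)
}

#' Toy-force-field energy and forces
#'
#' @param conf n x 3 coordinate matrix (Angstrom).
#' @param ff a [toy_forcefield()].
#' @return list with `energy` (kcal/mol), `forces` (n x 3, kcal/mol/A; the
#'   exact negative gradient) and the per-term `terms` breakdown.
#' @export
toy_energy_forces <- function(conf, ff = toy_forcefield()) {
  conf <- .as_conformation(conf)
  cpp_toy_energy_forces(conf, unclass(ff))
}

# place a new bead from the last three, given bond length, angle at C (deg)
# and dihedral A-B-C-new (deg)
.place_bead <- function(A, B, C, b, theta, gamma) {
  th <- theta * pi / 180
  ga <- gamma * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  nrm <- .cross3(B - A, bc)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate frame while placing bead")
  nrm <- nrm / nn
  m <- .cross3(nrm, bc)
  d <- b * c(-cos(th), sin(th) * cos(ga), sin(th) * sin(ga))
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

#' Random-chain build-up generator
#'
#' Builds a self-avoiding C-alpha chain residue by residue from the
#' N-terminus: each new dihedral `gamma` is drawn uniformly on
#' (-180, 180] degrees and each new virtual-bond angle `theta` from the
#' Boltzmann weight of the force field's harmonic angle term at the build
#' temperature; overlaps with all previously placed beads are rejected, with
#' up to 100 retrials per residue before backtracking one residue.
#'
#' @param n number of beads (>= 2).
#' @param seed integer seed; the same seed gives bitwise-identical output.
#' @param ff a [toy_forcefield()] (supplies `b0`, the angle term and the
#'   clash cutoff).
#' @param build_temp build temperature in K for the theta Boltzmann weight.
#' @param max_retries total retrial budget across the whole build.
#' @return n x 3 coordinate matrix.
#' @export
generate_random_chain <- function(n, seed, ff = toy_forcefield(),
                                  build_temp = 300, max_retries = 1e5) {
  n <- as.integer(n)
  if (n < 2) stop("chain must have at least 2 beads")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sd_theta <- sqrt(.kB * build_temp / (2 * ff$k_theta))
  draw_theta <- function() {
    repeat {
      th <- rnorm(1, ff$theta0, sd_theta)
      if (th > 1e-6 && th < 180 - 1e-6) return(th)
    }
  }
  X <- matrix(NA_real_, n, 3)
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(ff$b0, 0, 0)
  i <- 3
  tries <- integer(n)
  total <- 0
  while (i <= n) {
    ok <- FALSE
    while (tries[i] < 100) {
      tries[i] <- tries[i] + 1
      total <- total + 1
      if (total > max_retries)
        stop("random-chain generation failed: retrial budget exhausted")
      th <- draw_theta()
      if (i == 3) {
        cand <- X[2, ] + ff$b0 * c(-cos(th * pi / 180), sin(th * pi / 180), 0)
      } else {
        ga <- runif(1, -180, 180)
        cand <- .place_bead(X[i - 3, ], X[i - 2, ], X[i - 1, ], ff$b0, th, ga)
      }
      clash <- FALSE
      if (i > 3) {
        dd <- sqrt(rowSums((X[seq_len(i - 2), , drop = FALSE] -
                              matrix(cand, i - 2, 3, byrow = TRUE))^2))
        clash <- any(dd < ff$clash_cutoff)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (ok) {
      X[i, ] <- cand
      i <- i + 1
    } else {
      # 100 retrials failed: restart from one residue backward
      tries[i] <- 0
      if (i <= 4)
        stop("random-chain generation failed at the chain start")
      X[i - 1, ] <- NA_real_
      i <- i - 1
      tries[i] <- 0
    }
  }
  X
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses per-bead masses in amu.
#' @param temperature target temperature in K.
#' @return n x 3 velocity matrix in A/fs, drawn from the current RNG stream.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sds <- sqrt(.kB * temperature * .kcal / masses)
  matrix(rnorm(3 * n, 0, rep(sds, 3)), n, 3)
}
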