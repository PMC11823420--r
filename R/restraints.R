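# Restraint data model, flat-bottom penalty potentials with exact gradients,
# restraint-table I/O, and synthetic-restraint generation.

#' Distance restraint between two (groups of) beads
#'
#' The penalty has a flat bottom of depth `A` between the bounds, Gaussian
#' walls of width `sigma` on both sides, and a linear tail of slope `kappa`
#' above the upper bound that keeps a small restoring gradient at large
#' distances without forcing the fulfilment of contradictory restraints.
#' Groups with more than one member are treated as equivalent sites whose
#' cross-pair distances are r^-6-combined with equal weights.
#'
#' @param i,j residue indices (1-based) of the two groups; vectors allowed.
#' @param d_l,d_u lower/upper distance bounds, Angstrom (0 <= d_l <= d_u).
#' @param A well depth, kcal/mol.
#' @param sigma wall width, Angstrom.
#' @param kappa large-distance slope, kcal/mol/A.
#' @return object of class `distance_restraint`.
#' @export
distance_restraint <- function(i, j, d_l, d_u, A = 5, sigma = 1, kappa = 0.01) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) < 1 || length(j) < 1) stop("restraint groups must be non-empty")
  if (any(i %in% j)) stop("restraint groups must be disjoint")
  if (!(d_l >= 0 && d_l <= d_u)) stop("need 0 <= d_l <= d_u")
  if (sigma <= 0 || A < 0 || kappa < 0) stop("invalid well parameters")
  structure(list(group_i = i, group_j = j, d_l = d_l, d_u = d_u,
                 A = A, sigma = sigma, kappa = kappa),
            class = "distance_restraint")
}

#' Virtual-bond-angle restraint
#'
#' Flat-bottom well of depth `A_theta` on `[theta_l, theta_u]` with Gaussian
#' walls; no linear tail (the angle domain is bounded).
#'
#' @param vertex residue index of the restrained angle's vertex.
#' @param theta_l,theta_u bounds in degrees, 0 < theta_l <= theta_u < 180.
#' @param A_theta well depth, kcal/mol.
#' @param sigma_theta wall width, degrees.
#' @export
angle_restraint <- function(vertex, theta_l, theta_u, A_theta = 1,
                            sigma_theta = 10) {
  vertex <- as.integer(vertex)
  if (!(theta_l > 0 && theta_l <= theta_u && theta_u < 180))
    stop("need 0 < theta_l <= theta_u < 180")
  if (A_theta < 0 || sigma_theta <= 0) stop("invalid well parameters")
  structure(list(vertex = vertex, theta_l = theta_l, theta_u = theta_u,
                 A_theta = A_theta, sigma_theta = sigma_theta),
            class = "angle_restraint")
}

#' Virtual-bond-dihedral restraint
#'
#' Periodic flat-bottom well: the allowed interval runs counterclockwise from
#' `gamma_l` to `gamma_u` (it may span the +/-180 cut), with Gaussian walls on
#' the wrapped angular distance to the nearer boundary, so that
#' `V(gamma) = V(gamma + 360)`.
#'
#' @param bond residue index i of the gamma axis (beads i-1, i, i+1, i+2).
#' @param gamma_l,gamma_u bounds in degrees, wrapped to (-180, 180].
#' @param A_gamma well depth, kcal/mol.
#' @param sigma_gamma wall width, degrees.
#' @export
dihedral_restraint <- function(bond, gamma_l, gamma_u, A_gamma = 5,
                               sigma_gamma = 10) {
  bond <- as.integer(bond)
  if (A_gamma < 0 || sigma_gamma <= 0) stop("invalid well parameters")
  structure(list(bond = bond, gamma_l = .wrap180(gamma_l),
                 gamma_u = .wrap180(gamma_u), A_gamma = A_gamma,
                 sigma_gamma = sigma_gamma),
            class = "dihedral_restraint")
}

#' Restraint set
#'
#' Container for distance, angle and dihedral restraints.  The averaging
#' exponent used by the memory window is fixed per kind: m = 3 for distances
#' (the window averages d^-3, the NOE-consistent power mean over time) and
#' m = -1 for angles (direct averaging; dihedrals through their sines and
#' cosines).
#'
#' @param distance,angle,dihedral lists of the respective restraint objects.
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(distance = list(), angle = list(), dihedral = list()) {
  chk <- function(lst, cls) {
    if (inherits(lst, cls)) lst <- list(lst)
    if (!all(vapply(lst, inherits, logical(1), cls)))
      stop("expected a list of ", cls, " objects")
    lst
  }
  structure(list(distance = chk(distance, "distance_restraint"),
                 angle = chk(angle, "angle_restraint"),
                 dihedral = chk(dihedral, "dihedral_restraint"),
                 m = c(distance = 3, angle = -1)),
            class = "restraint_set")
}

#' @export
length.restraint_set <- function(x)
  length(x$distance) + length(x$angle) + length(x$dihedral)

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set:", length(x$distance), "distance,",
      length(x$angle), "theta,", length(x$dihedral), "gamma restraints\n")
  invisible(x)
}

# flatten a restraint_set for the C++ core (0-based bead indices)
.rset_flat <- function(set, n_beads = NULL) {
  d <- set$distance; a <- set$angle; g <- set$dihedral
  gi <- unlist(lapply(d, `[[`, "group_i"), use.names = FALSE)
  gj <- unlist(lapply(d, `[[`, "group_j"), use.names = FALSE)
  gil <- vapply(d, function(r) length(r$group_i), integer(1))
  gjl <- vapply(d, function(r) length(r$group_j), integer(1))
  num <- function(lst, f) as.numeric(vapply(lst, `[[`, numeric(1), f))
  rf <- list(
    gi = as.integer(if (length(gi)) gi - 1L else integer(0)),
    gip = as.integer(cumsum(c(0L, gil))),
    gj = as.integer(if (length(gj)) gj - 1L else integer(0)),
    gjp = as.integer(cumsum(c(0L, gjl))),
    dl = num(d, "d_l"), du = num(d, "d_u"), A = num(d, "A"),
    sig = num(d, "sigma"), kap = num(d, "kappa"),
    tv = as.integer(vapply(a, `[[`, integer(1), "vertex") - 1L),
    tl = num(a, "theta_l"), tu = num(a, "theta_u"),
    At = num(a, "A_theta"), sigt = num(a, "sigma_theta"),
    gb = as.integer(vapply(g, `[[`, integer(1), "bond") - 1L),
    gl = num(g, "gamma_l"), gu = num(g, "gamma_u"),
    Ag = num(g, "A_gamma"), sigg = num(g, "sigma_gamma"))
  if (!is.null(n_beads)) {
    idx_ok <- all(c(rf$gi, rf$gj) >= 0L) && all(c(rf$gi, rf$gj) < n_beads) &&
      all(rf$tv >= 1L) && all(rf$tv < n_beads - 1L) &&
      all(rf$gb >= 1L) && all(rf$gb < n_beads - 2L)
    if (!idx_ok) stop("restraint indices outside the chain")
  }
  rf
}

#' Distance-restraint penalty and its gradient
#'
#' @param d distance(s), Angstrom (> 0).
#' @param r a [distance_restraint()].
#' @return list with `V` (kcal/mol) and `dV_dd` (kcal/mol/A).
#' @export
eval_distance_penalty <- function(d, r) {
  stopifnot(inherits(r, "distance_restraint"), all(d > 0))
  out <- cpp_pen_dist(as.numeric(d), r$d_l, r$d_u, r$A, r$sigma, r$kappa)
  list(V = out$V, dV_dd = out$dV)
}

#' Virtual-bond-angle penalty and its gradient
#'
#' @param theta angle(s) in degrees, 0 < theta < 180.
#' @param r an [angle_restraint()].
#' @return list with `V` (kcal/mol) and `dV_dtheta` (kcal/mol/deg).
#' @export
eval_theta_penalty <- function(theta, r) {
  stopifnot(inherits(r, "angle_restraint"), all(theta > 0 & theta < 180))
  out <- cpp_pen_theta(as.numeric(theta), r$theta_l, r$theta_u,
                       r$A_theta, r$sigma_theta)
  list(V = out$V, dV_dtheta = out$dV)
}

#' Virtual-bond-dihedral penalty and its gradient
#'
#' Periodic in 360 degrees.
#'
#' @param gamma dihedral(s) in degrees.
#' @param r a [dihedral_restraint()].
#' @return list with `V` (kcal/mol) and `dV_dgamma` (kcal/mol/deg).
#' @export
eval_gamma_penalty <- function(gamma, r) {
  stopifnot(inherits(r, "dihedral_restraint"))
  out <- cpp_pen_gamma(.wrap180(as.numeric(gamma)), r$gamma_l, r$gamma_u,
                       r$A_gamma, r$sigma_gamma)
  list(V = out$V, dV_dgamma = out$dV)
}

#' Total restraint energy from per-restraint values
#'
#' Sums the penalty terms over a restraint set, given current (or
#' time-averaged) values of the restrained quantities.  `NA` values (flagged
#' degenerate angles) are skipped.
#'
#' @param values list with components `dist`, `theta`, `gamma` (each may be
#'   omitted if the set has no restraints of that kind).
#' @param set a [restraint_set()].
#' @return list with `V_total` and per-restraint vectors `V_dist`, `V_theta`,
#'   `V_gamma`.
#' @export
restraint_energy <- function(values, set) {
  stopifnot(inherits(set, "restraint_set"))
  get_vals <- function(name, m) {
    v <- values[[name]]
    if (is.null(v)) v <- numeric(0)
    if (length(v) != m) stop("need one ", name, " value per restraint")
    v
  }
  vd <- get_vals("dist", length(set$distance))
  vt <- get_vals("theta", length(set$angle))
  vg <- get_vals("gamma", length(set$dihedral))
  Vd <- vapply(seq_along(vd), function(k) {
    if (is.na(vd[k])) return(0)
    eval_distance_penalty(vd[k], set$distance[[k]])$V
  }, numeric(1))
  Vt <- vapply(seq_along(vt), function(k) {
    if (is.na(vt[k])) return(0)
    eval_theta_penalty(vt[k], set$angle[[k]])$V
  }, numeric(1))
  Vg <- vapply(seq_along(vg), function(k) {
    if (is.na(vg[k])) return(0)
    eval_gamma_penalty(vg[k], set$dihedral[[k]])$V
  }, numeric(1))
  list(V_total = sum(Vd) + sum(Vt) + sum(Vg),
       V_dist = Vd, V_theta = Vt, V_gamma = Vg)
}

#' Instantaneous restrained quantities of a conformation
#'
#' Distances (r^-6-combined within equivalent-site groups), virtual-bond
#' angles and dihedrals (degrees).  Degenerate angles are returned as `NA`.
#'
#' @param conf n x 3 coordinate matrix.
#' @param set a [restraint_set()].
#' @return list with `dist`, `theta`, `gamma`.
#' @export
measure <- function(conf, set) {
  conf <- .as_conformation(conf)
  rf <- .rset_flat(set, nrow(conf))
  mv <- cpp_measure(conf, rf)
  mv$theta[!mv$theta_ok] <- NA_real_
  mv$gamma[!mv$gamma_ok] <- NA_real_
  list(dist = mv$dist, theta = mv$theta, gamma = mv$gamma)
}

#' Synthesize distance restraints from reference conformations
#'
#' For every bead pair with sequence separation of at least `min_sep` whose
#' weighted r^-6-average distance over the references is within `cutoff`, a
#' distance restraint with bounds `d_bar -/+ pad` (lower bound floored at 0)
#' is emitted, ordered by (i, j).
#'
#' @param refs a single conformation or list of reference conformations.
#' @param weights per-reference weights, summing to 1 (default uniform).
#' @param cutoff include pairs whose averaged distance is <= `cutoff` (A).
#' @param pad half-width of the restraint interval (A).
#' @param A,sigma,kappa well parameters passed to [distance_restraint()].
#' @param min_sep minimum sequence separation (>= 2 excludes bonded pairs).
#' @return a [restraint_set()] of distance restraints.
#' @export
synthesize_restraints <- function(refs, weights = NULL, cutoff = 8, pad = 0.5,
                                  A = 5, sigma = 1, kappa = 0.01, min_sep = 2) {
  if (is.matrix(refs)) refs <- list(refs)
  refs <- lapply(refs, .as_conformation)
  L <- length(refs)
  if (L < 1) stop("need at least one reference conformation")
  if (is.null(weights)) weights <- rep(1 / L, L)
  if (length(weights) != L || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized to 1 (one per reference)")
  n <- nrow(refs[[1]])
  res <- list()
  for (i in seq_len(n - min_sep)) {
    for (j in seq(i + min_sep, n)) {
      dl <- vapply(refs, function(X) sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1))
      dbar <- sum(weights * dl^(-6))^(-1 / 6)
      if (dbar <= cutoff)
        res[[length(res) + 1]] <- distance_restraint(
          i, j, max(0, dbar - pad), dbar + pad, A = A, sigma = sigma,
          kappa = kappa)
    }
  }
  restraint_set(distance = res)
}

# ---------------------------------------------------------------------------
# restraint-table I/O: UTF-8 TSV, one record per line, '#' comments

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a restraint set as a tab-separated restraint table
#'
#' Records: `DIST i_group j_group d_l d_u A sigma kappa` (groups as
#' comma-joined residue indices), `THETA vertex theta_l theta_u A sigma`,
#' `GAMMA bond gamma_l gamma_u A sigma`.  The write -> read round trip is
#' lossless.
#'
#' @param set a [restraint_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(set, path) {
  stopifnot(inherits(set, "restraint_set"))
  lines <- c("# tardyn restraint table")
  for (r in set$distance)
    lines <- c(lines, paste("DIST", paste(r$group_i, collapse = ","),
                            paste(r$group_j, collapse = ","),
                            .fmt_num(r$d_l), .fmt_num(r$d_u), .fmt_num(r$A),
                            .fmt_num(r$sigma), .fmt_num(r$kappa), sep = "\t"))
  for (r in set$angle)
    lines <- c(lines, paste("THETA", r$vertex, .fmt_num(r$theta_l),
                            .fmt_num(r$theta_u), .fmt_num(r$A_theta),
                            .fmt_num(r$sigma_theta), sep = "\t"))
  for (r in set$dihedral)
    lines <- c(lines, paste("GAMMA", r$bond, .fmt_num(r$gamma_l),
                            .fmt_num(r$gamma_u), .fmt_num(r$A_gamma),
                            .fmt_num(r$sigma_gamma), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a restraint table
#'
#' Parses the tab-separated format written by [write_restraints()].
#' Intra-residue distance restraints (overlapping groups) are rejected, as
#' are unknown record types.
#'
#' @param path restraint-table file.
#' @return a [restraint_set()].
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("no such restraint table: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  dist <- list(); ang <- list(); dih <- list()
  parse_group <- function(tok) as.integer(strsplit(tok, ",", fixed = TRUE)[[1]])
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    kind <- f[1]
    if (kind == "DIST") {
      if (length(f) < 5) stop("malformed DIST record: ", ln)
      gi <- parse_group(f[2]); gj <- parse_group(f[3])
      if (any(gi %in% gj))
        stop("intra-residue distance restraint rejected: ", ln)
      opt <- as.numeric(f[-(1:5)])
      dist[[length(dist) + 1]] <- distance_restraint(
        gi, gj, as.numeric(f[4]), as.numeric(f[5]),
        A = if (length(opt) >= 1) opt[1] else 5,
        sigma = if (length(opt) >= 2) opt[2] else 1,
        kappa = if (length(opt) >= 3) opt[3] else 0.01)
    } else if (kind == "THETA") {
      if (length(f) < 4) stop("malformed THETA record: ", ln)
      opt <- as.numeric(f[-(1:4)])
      ang[[length(ang) + 1]] <- angle_restraint(
        as.integer(f[2]), as.numeric(f[3]), as.numeric(f[4]),
        A_theta = if (length(opt) >= 1) opt[1] else 1,
        sigma_theta = if (length(opt) >= 2) opt[2] else 10)
    } else if (kind == "GAMMA") {
      if (length(f) < 4) stop("malformed GAMMA record: ", ln)
      opt <- as.numeric(f[-(1:4)])
      dih[[length(dih) + 1]] <- dihedral_restraint(
        as.integer(f[2]), as.numeric(f[3]), as.numeric(f[4]),
        A_gamma = if (length(opt) >= 1) opt[1] else 5,
        sigma_gamma = if (length(opt) >= 2) opt[2] else 10)
    } else {
      stop("unknown restraint record type: ", kind)
    }
  }
  restraint_set(distance = dist, angle = ang, dihedral = dih)
}
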