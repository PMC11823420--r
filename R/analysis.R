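# Ensemble post-processing: r^-6 ensemble averaging, upper-bound violation
# statistics, Kabsch superposition / RMSD, GDT_TS, Ward clustering and
# RMSD distribution histograms.

#' r^-6 ensemble-averaged distances
#'
#' `d_bar = (sum_l w_l d_l^-6)^(-1/6)` per restraint, the NOE-intensity
#' consistent ensemble mean.
#'
#' @param distances `n_conf x n_restraint` matrix (or vector for one
#'   restraint) of per-conformation distances, Angstrom (> 0).
#' @param weights per-conformation weights, normalized to 1 (default
#'   uniform).
#' @return vector of averaged distances.
#' @export
r6_ensemble_average <- function(distances, weights = NULL) {
  if (is.vector(distances)) distances <- matrix(distances, ncol = 1)
  nc <- nrow(distances)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (length(weights) != nc || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (any(distances <= 0)) stop("distances must be positive")
  as.numeric((t(weights) %*% distances^(-6))^(-1 / 6))
}

#' Upper-bound violation report
#'
#' `rho_u_plus = sqrt(mean(max(d_bar - d_u, 0)^2))` over the distance
#' restraints, the count of violated upper bounds, and the count of excesses
#' of at least `threshold` (2 A by default).
#'
#' @param d_bar ensemble-averaged distances, Angstrom.
#' @param upper upper bounds `d_u`, Angstrom.
#' @param threshold large-violation cutoff, Angstrom.
#' @return object of class `violation_report` with `excess`, `rho_u_plus`,
#'   `n_violated`, `n_violated_2A`, `n_restraints`.
#' @export
violation_report <- function(d_bar, upper, threshold = 2) {
  if (length(d_bar) == 0) stop("violation report needs at least one restraint")
  if (length(d_bar) != length(upper)) stop("d_bar and upper differ in length")
  excess <- pmax(d_bar - upper, 0)
  structure(list(d_bar = d_bar, upper = upper, excess = excess,
                 rho_u_plus = sqrt(mean(excess^2)),
                 n_violated = sum(excess > 0),
                 n_violated_2A = sum(excess >= threshold),
                 threshold = threshold,
                 n_restraints = length(d_bar)),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf(
    "violation_report: rho_u+ = %.3f A, %d of %d violated (%d >= %g A)\n",
    x$rho_u_plus, x$n_violated, x$n_restraints, x$n_violated_2A, x$threshold))
  invisible(x)
}

# optimal proper rotation of centred A onto centred B (Kabsch, via SVD)
.kabsch_rotation <- function(A0, B0) {
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose one conformation onto another (Kabsch)
#'
#' Least-squares rigid superposition with proper rotations only.
#'
#' @param A,B n x 3 coordinate matrices, n >= 3.
#' @return `A` rotated and translated onto `B`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- .as_conformation(A); B <- .as_conformation(B)
  if (nrow(A) != nrow(B)) stop("conformations differ in bead count")
  if (nrow(A) < 3) stop("superposition needs at least 3 beads")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  R <- .kabsch_rotation(A0, B0)
  sweep(A0 %*% R, 2, cb, `+`)
}

#' C-alpha RMSD at optimal superposition
#'
#' @param A,B n x 3 coordinate matrices, n >= 3.
#' @return minimal RMSD over rigid motions, Angstrom.
#' @export
kabsch_rmsd <- function(A, B) {
  As <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((As - B)^2)))
}

#' GDT_TS score of superposed structures
#'
#' Mean over the 1, 2, 4 and 8 A cutoffs of the percentage of beads of `A`
#' within the cutoff of the matching bead of `B`.  Inputs are assumed already
#' superposed; a single whole-chain Kabsch superposition (a lower-bound
#' variant of the multi-superposition GDT search) is available via
#' `superpose = TRUE`.
#'
#' @param A,B n x 3 coordinate matrices.
#' @param superpose apply [kabsch_superpose()] first.
#' @return score in `[0, 100]`.
#' @export
gdt_ts <- function(A, B, superpose = FALSE) {
  A <- .as_conformation(A); B <- .as_conformation(B)
  if (nrow(A) != nrow(B)) stop("conformations differ in bead count")
  if (superpose) A <- kabsch_superpose(A, B)
  dev <- sqrt(rowSums((A - B)^2))
  mean(vapply(c(1, 2, 4, 8), function(ct) 100 * mean(dev <= ct), numeric(1)))
}

# per-conformation violation score for representative selection: rho_u+ of
# the conformation's own distances against the set's upper bounds
.single_conf_rho <- function(conf, set) {
  if (length(set$distance) == 0) return(0)
  d <- measure(conf, set)$dist
  upper <- vapply(set$distance, `[[`, numeric(1), "d_u")
  sqrt(mean(pmax(d - upper, 0)^2))
}

#' Ward clustering of a conformational ensemble
#'
#' Agglomerative Ward (minimum-variance, Lance-Williams) clustering on the
#' pairwise Kabsch-RMSD matrix into `k` families.  Families are ranked by
#' cumulative weight; each family's representative is its member with the
#' lowest restraint violation (per-conformation rho_u+ against the restraint
#' set), ties broken by lowest index.
#'
#' @param confs list of conformations.
#' @param weights per-conformation weights, normalized to 1 (default
#'   uniform).
#' @param k number of families (>= 1).
#' @param set optional [restraint_set()] for representative selection;
#'   without it the representative minimizes the RMSD to its family mates.
#' @return object of class `cluster_result` with `assignment`,
#'   `family_weight`, `family_rank`, `representative`.
#' @export
cluster_ensemble <- function(confs, weights = NULL, k, set = NULL) {
  if (is.matrix(confs)) confs <- list(confs)
  nc <- length(confs)
  if (k < 1) stop("k must be at least 1")
  if (k > nc) stop("more families than conformations")
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  M <- matrix(0, nc, nc)
  if (nc > 1)
    for (i in 1:(nc - 1)) for (j in (i + 1):nc)
      M[i, j] <- M[j, i] <- kabsch_rmsd(confs[[i]], confs[[j]])
  assignment <- if (nc == 1) 1L else
    cutree(hclust(as.dist(M), method = "ward.D2"), k = k)
  fam_w <- vapply(seq_len(k), function(f) sum(weights[assignment == f]),
                  numeric(1))
  rank_order <- order(-fam_w, seq_len(k))
  representative <- integer(k)
  for (f in seq_len(k)) {
    members <- which(assignment == f)
    score <- if (!is.null(set))
      vapply(members, function(m) .single_conf_rho(confs[[m]], set), numeric(1))
    else
      vapply(members, function(m) sum(M[m, members]), numeric(1))
    representative[f] <- members[which.min(score)]
  }
  structure(list(assignment = assignment, family_weight = fam_w,
                 family_rank = rank_order, representative = representative,
                 rmsd_matrix = M, k = k),
            class = "cluster_result")
}

#' RMSD distribution histogram(s) against one or two references
#'
#' Per-conformation Kabsch RMSD against each reference, histogrammed with
#' the ensemble weights; the probability mass sums to 1.  With two
#' references a 2-D histogram is returned whose marginals equal the two 1-D
#' histograms.
#'
#' @param confs list of conformations (or a [run_trajectory()] record, whose
#'   saved conformations are used).
#' @param refs a single reference conformation or a list of one or two.
#' @param weights per-conformation weights (default uniform).
#' @param bin_width histogram bin width, Angstrom.
#' @return list with `rmsd` (matrix `n_conf x n_ref`), `breaks`, and `mass`
#'   (vector or matrix summing to 1).
#' @export
rmsd_distributions <- function(confs, refs, weights = NULL, bin_width = 0.5) {
  if (inherits(confs, "trajectory_record")) confs <- confs$conformations
  if (is.matrix(confs)) confs <- list(confs)
  if (length(confs) == 0) stop("empty ensemble")
  if (is.matrix(refs)) refs <- list(refs)
  nr <- length(refs)
  if (nr < 1 || nr > 2) stop("need one or two references")
  nc <- length(confs)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  rmsd <- vapply(refs, function(rf)
    vapply(confs, kabsch_rmsd, numeric(1), B = rf), numeric(nc))
  rmsd <- matrix(rmsd, nrow = nc)
  top <- max(rmsd) + bin_width
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  bin_of <- function(x) pmin(findInterval(x, breaks, left.open = TRUE) + 0,
                             length(breaks) - 1)
  b1 <- pmax(bin_of(rmsd[, 1]), 1)
  if (nr == 1) {
    mass <- numeric(length(breaks) - 1)
    for (i in seq_len(nc)) mass[b1[i]] <- mass[b1[i]] + weights[i]
  } else {
    b2 <- pmax(bin_of(rmsd[, 2]), 1)
    mass <- matrix(0, length(breaks) - 1, length(breaks) - 1)
    for (i in seq_len(nc)) mass[b1[i], b2[i]] <- mass[b1[i], b2[i]] + weights[i]
  }
  list(rmsd = rmsd, breaks = breaks, mass = mass, bin_width = bin_width)
}

#' Serialize a violation report as CSV
#'
#' Per-restraint rows (id, averaged distance, bound, excess) followed by a
#' commented summary line with rho_u+ and the violation counts.
#'
#' @param report a [violation_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_violation_csv <- function(report, path) {
  stopifnot(inherits(report, "violation_report"))
  df <- data.frame(restraint = seq_along(report$d_bar), d_bar = report$d_bar,
                   upper = report$upper, excess = report$excess)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rho_u_plus,%.6f,n_violated,%d,n_violated_2A,%d",
                     report$rho_u_plus, report$n_violated,
                     report$n_violated_2A), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
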