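# Multi-model C-alpha trace PDB input/output.  Reading goes through bio3d;
# ensemble writing uses the fixed-column ATOM format directly because bio3d
# has no MODEL/ENDMDL ensemble writer.

#' Write a C-alpha trace ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformation; atom name `CA`, occupancy 1.00,
#' B-factor 0.00, standard fixed columns, coordinates in Angstrom.
#'
#' @param confs a single n x 3 matrix or a list of them (equal sizes).
#' @param path output file.
#' @param labels per-bead residue names (default `ALA`).
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(confs, path, labels = NULL) {
  if (is.matrix(confs)) confs <- list(confs)
  n <- nrow(confs[[1]])
  if (is.null(labels)) labels <- rep("ALA", n)
  labels <- rep_len(labels, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    X <- .as_conformation(confs[[m]])
    if (nrow(X) != n) stop("all models must have the same number of beads")
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), labels, seq_len(n), X[, 1], X[, 2], X[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a C-alpha trace ensemble from a (multi-model) PDB file
#'
#' @param path PDB file; only `CA` atoms are used.
#' @return list of n x 3 coordinate matrices, one per model.
#' @export
read_ca_pdb <- function(path) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  lapply(seq_len(nrow(xyz)), function(m)
    matrix(xyz[m, ], ncol = 3, byrow = TRUE))
}
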