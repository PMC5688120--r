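## Toy structure fixtures and PDB I/O for the featurization stage.

#' Generate a toy structure pair for featurization tests
#'
#' Builds a small helical pseudo-protein (atoms N, CA, C, O, CB on every
#' residue, CD on every second residue and a CZ/NZ pair on every third, so
#' the salt-bridge atom-name patterns are exercised), plus:
#' a rigidly rotated + translated copy (RMSD after superposition must be 0),
#' and a variant with the middle residue displaced by `displacement`
#' Angstrom along +x (no refit: RMSD over a selection containing k of its
#' atoms among N is `displacement * sqrt(k/N)`).
#'
#' @param n_residues number of residues (>= 3).
#' @param displacement rigid displacement of the middle residue, Angstrom.
#' @param seed RNG seed (controls the jitter and the rigid transform).
#' @return list with `reference`, `transformed`, `displaced` (single-frame
#'   [coord_traj()]s), `topology`, `rotation`, `translation`,
#'   `displaced_resno`.
#' @export
make_toy_structure_pair <- function(n_residues, displacement = 1, seed = 1L) {
  stopifnot(n_residues >= 3L)
  set.seed(seed)
  atoms <- character(0); resno <- integer(0)
  for (r in seq_len(n_residues)) {
    nm <- c("N", "CA", "C", "O", "CB")
    if (r %% 2L == 0L) nm <- c(nm, "CD")
    if (r %% 3L == 0L) nm <- c(nm, "CZ", "NZ")
    atoms <- c(atoms, nm)
    resno <- c(resno, rep(r, length(nm)))
  }
  top <- topology(atoms, resno,
                  resname = ifelse(resno %% 3L == 0L, "ARG", "ALA"),
                  element = substr(atoms, 1L, 1L))
  ## idealized alpha-helix CA trace, side atoms offset with small jitter
  n_atoms <- nrow(top)
  xyz <- matrix(0, n_atoms, 3L)
  offsets <- list(N = c(-0.5, 1.2, -0.4), CA = c(0, 0, 0),
                  C = c(0.6, -1.1, 0.5), O = c(1.5, -1.4, 0.3),
                  CB = c(-1.2, -0.6, 1.0), CD = c(-2.2, -0.9, 2.0),
                  CZ = c(-3.4, -1.1, 3.0), NZ = c(-4.0, -1.8, 3.6))
  for (i in seq_len(n_atoms)) {
    r <- top$resno[i]
    theta <- r * 100 * pi / 180
    ca <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * r)
    xyz[i, ] <- ca + offsets[[top$atom[i]]] + rnorm(3L, sd = 0.05)
  }
  Rm <- random_rotation()
  tr <- rnorm(3L, sd = 10)
  moved <- xyz %*% t(Rm) + matrix(tr, n_atoms, 3L, byrow = TRUE)
  mid <- top$resno == ((n_residues + 1L) %/% 2L)
  displaced <- xyz
  displaced[mid, 1L] <- displaced[mid, 1L] + displacement
  list(reference = coord_traj(xyz, top),
       transformed = coord_traj(moved, top),
       displaced = coord_traj(displaced, top),
       topology = top, rotation = Rm, translation = tr,
       displaced_resno = (n_residues + 1L) %/% 2L)
}

## Uniform random rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Read a single-structure PDB file into a coordinate trajectory
#'
#' Thin wrapper over `bio3d::read.pdb()` that builds the package's
#' topology/coordinate containers.
#'
#' @param file path to a PDB file.
#' @param dt frame interval to attach, ns.
#' @return a [coord_traj()].
#' @export
read_pdb_coords <- function(file, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  top <- topology(at$elety, at$resno, resname = at$resid,
                  element = ifelse(is.na(at$elesy) | at$elesy == "",
                                   substr(gsub("^[0-9]+", "", at$elety), 1, 1),
                                   at$elesy))
  coord_traj(cbind(at$x, at$y, at$z), top, dt = dt)
}

#' Write the first frame of a coordinate trajectory to PDB
#'
#' @param traj a [coord_traj()].
#' @param file output path.
#' @export
write_pdb_coords <- function(traj, file) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("writing PDB files requires the bio3d package")
  top <- traj$topology
  xyz <- traj$coords[1L, , , drop = TRUE]
  bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)),
                   resno = top$resno, resid = top$resname,
                   elety = top$atom, elesy = top$element)
  invisible(file)
}
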