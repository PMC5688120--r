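## Light-weight containers shared by all stages.

#' Feature trajectory
#'
#' Time-ordered matrix of real-valued features with a fixed frame interval.
#' This is the universal currency between the featurization, tICA and
#' discretization stages.
#'
#' @param values numeric matrix, frames in rows, features in columns.
#' @param dt frame interval in nanoseconds.
#' @param names optional character vector of feature names.
#' @return an object of class `feature_traj`.
#' @export
feature_traj <- function(values, dt, names = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(dt) == 1L, dt > 0)
  if (!all(is.finite(values))) stop("feature trajectory contains non-finite values")
  if (!is.null(names)) {
    if (length(names) != ncol(values))
      stop("feature name count (", length(names), ") != column count (",
           ncol(values), ")")
    colnames(values) <- names
  }
  structure(list(values = values, dt = dt), class = "feature_traj")
}

#' @export
print.feature_traj <- function(x, ...) {
  cat("<feature_traj> ", nrow(x$values), " frames x ", ncol(x$values),
      " features, dt = ", x$dt, " ns\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_traj <- function(x) dim(x$values)

## Coerce a list of feature_traj (or bare matrices) to a list of matrices,
## checking that dimensions and dt agree.  Returns list with attr "dt".
as_feature_list <- function(trajs) {
  if (inherits(trajs, "feature_traj")) trajs <- list(trajs)
  if (!is.list(trajs) || length(trajs) == 0L) stop("empty trajectory list")
  dt <- NA_real_
  out <- lapply(trajs, function(tr) {
    if (inherits(tr, "feature_traj")) {
      if (is.na(dt)) dt <<- tr$dt
      else if (!isTRUE(all.equal(dt, tr$dt))) stop("trajectories disagree on dt")
      tr$values
    } else as.matrix(tr)
  })
  d <- unique(vapply(out, ncol, 1L))
  if (length(d) != 1L) stop("trajectories disagree on feature dimension")
  attr(out, "dt") <- dt
  out
}

#' Coordinate trajectory
#'
#' @param coords numeric array `frames x atoms x 3`, positions in Angstrom.
#'   A single `atoms x 3` matrix is promoted to one frame.
#' @param topology a topology `data.frame`, see [topology()].
#' @param dt frame interval in ns.
#' @return an object of class `coord_traj`.
#' @export
coord_traj <- function(coords, topology, dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L, dt > 0)
  if (dim(coords)[2] != nrow(topology))
    stop("atom count mismatch: ", dim(coords)[2], " coordinates vs ",
         nrow(topology), " topology rows")
  structure(list(coords = coords, topology = topology, dt = dt),
            class = "coord_traj")
}

#' @export
print.coord_traj <- function(x, ...) {
  cat("<coord_traj> ", dim(x$coords)[1], " frames x ", dim(x$coords)[2],
      " atoms, dt = ", x$dt, " ns\n", sep = "")
  invisible(x)
}

#' Build a topology table
#'
#' One row per atom: atom name, element, residue name, author residue number
#' and a heavy-atom flag (element != H).  (residue number, atom name) pairs
#' must be unique so atoms are addressable by the order-parameter specs.
#'
#' @param atom character atom names (e.g. "CA", "CD", "NZ").
#' @param resno integer author residue numbers.
#' @param resname character residue names; recycled.
#' @param element element symbols; inferred from the first letter of the atom
#'   name when missing.
#' @return a `data.frame` with class `c("topology", "data.frame")`.
#' @export
topology <- function(atom, resno, resname = "ALA", element = NULL) {
  atom <- as.character(atom)
  resno <- as.integer(resno)
  if (is.null(element)) element <- substr(gsub("^[0-9]+", "", atom), 1L, 1L)
  df <- data.frame(atom = atom, element = element,
                   resname = rep_len(resname, length(atom)),
                   resno = resno,
                   heavy = toupper(element) != "H",
                   stringsAsFactors = FALSE)
  key <- paste(df$resno, df$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue number, atom name) pair: ",
         key[duplicated(key)][1L])
  class(df) <- c("topology", "data.frame")
  df
}

## Resolve a single atom index; error names residue and atom.
atom_index <- function(top, resno, atom) {
  i <- which(top$resno == resno & top$atom == atom)
  if (length(i) != 1L)
    stop("cannot resolve atom '", atom, "' of residue ", resno, " in topology")
  i
}
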