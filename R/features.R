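## Featurization: torsions, contact distances, RMSD order parameters.
## Coordinates are in Angstrom, times in ns, torsions in radians.

## Torsion angle for vectorized point sets (n x 3 matrices), range (-pi, pi].
## atan2 formulation; the anti-periplanar (trans) arrangement maps to +pi.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- row_cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)  # IUPAC sign (agrees with standard torsion tools)
  ang <- atan2(y, x)
  ifelse(ang <= -pi + 1e-15, pi, ang)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Backbone torsion features
#'
#' Computes phi (`C(i-1), N(i), CA(i), C(i)`) and psi (`N(i), CA(i), C(i),
#' N(i+1)`) torsions, or torsions over explicit atom-index quadruples, and
#' emits each angle as a (sin, cos) pair so the features are continuous
#' across the periodic boundary.
#'
#' @param traj a [coord_traj()].
#' @param which `"backbone"` for phi/psi, or a list of integer length-4 atom
#'   index vectors (named for feature naming).
#' @return a [feature_traj()] with columns `<angle>_sin`, `<angle>_cos`.
#' @export
compute_dihedrals <- function(traj, which = "backbone") {
  top <- traj$topology
  if (identical(which, "backbone")) {
    quads <- list()
    resnos <- sort(unique(top$resno))
    idx <- function(r, a) {
      i <- which(top$resno == r & top$atom == a)
      if (length(i) != 1L)
        stop("missing backbone atom '", a, "' in residue ", r)
      i
    }
    for (k in seq_along(resnos)) {
      r <- resnos[k]
      if (k > 1L)
        quads[[paste0("phi_", r)]] <-
          c(idx(resnos[k - 1L], "C"), idx(r, "N"), idx(r, "CA"), idx(r, "C"))
      if (k < length(resnos))
        quads[[paste0("psi_", r)]] <-
          c(idx(r, "N"), idx(r, "CA"), idx(r, "C"), idx(resnos[k + 1L], "N"))
    }
  } else {
    quads <- which
    if (is.null(names(quads)))
      names(quads) <- sprintf("torsion_%d", seq_along(quads))
  }
  n_frames <- dim(traj$coords)[1L]
  out <- matrix(NA_real_, n_frames, 2L * length(quads))
  nms <- character(2L * length(quads))
  atom_track <- function(i) matrix(traj$coords[, i, ], ncol = 3L)
  for (q in seq_along(quads)) {
    ii <- quads[[q]]
    ang <- torsion_angle(atom_track(ii[1L]), atom_track(ii[2L]),
                         atom_track(ii[3L]), atom_track(ii[4L]))
    out[, 2L * q - 1L] <- sin(ang)
    out[, 2L * q] <- cos(ang)
    nms[2L * q - 1L] <- paste0(names(quads)[q], "_sin")
    nms[2L * q] <- paste0(names(quads)[q], "_cos")
  }
  feature_traj(out, dt = traj$dt, names = nms)
}

## single-frame slice helper: frame t as an atoms x 3 matrix
frame_xyz <- function(traj, t = 1L) {
  matrix(traj$coords[t, , ], ncol = 3L)
}

#' Minimum heavy-atom distances between residue pairs
#'
#' Per frame, the minimum over all heavy-atom pairs of the Euclidean
#' distance between two residues, in Angstrom ("closest heavy atom
#' distance" features).
#'
#' @param traj a [coord_traj()].
#' @param residue_pairs list of length-2 residue-number vectors.
#' @return a [feature_traj()] with one column per pair.
#' @export
compute_min_heavy_distances <- function(traj, residue_pairs) {
  top <- traj$topology
  sel <- lapply(residue_pairs, function(pr) {
    a <- which(top$resno == pr[1L] & top$heavy)
    b <- which(top$resno == pr[2L] & top$heavy)
    if (!length(a)) stop("residue ", pr[1L], " has no heavy atoms")
    if (!length(b)) stop("residue ", pr[2L], " has no heavy atoms")
    list(a = a, b = b)
  })
  n_frames <- dim(traj$coords)[1L]
  out <- matrix(NA_real_, n_frames, length(sel))
  for (t in seq_len(n_frames)) {
    P <- frame_xyz(traj, t)
    for (k in seq_along(sel)) {
      A <- P[sel[[k]]$a, , drop = FALSE]
      B <- P[sel[[k]]$b, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      out[t, k] <- sqrt(max(0, min(d2)))
    }
  }
  feature_traj(out, dt = traj$dt,
               names = vapply(residue_pairs, function(pr)
                 paste0("mindist_", pr[1L], "_", pr[2L]), ""))
}

## Kabsch optimal superposition: returns the rotation R and translation
## minimizing || (X R^T + t) - Y ||^2 over the given rows.
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}

#' Per-frame RMSD to a reference after optimal superposition
#'
#' Computes the root mean squared deviation over a selection of atoms,
#' optionally after optimal rigid-body superposition (Kabsch) fitted on
#' `fit_selection` (defaults to the measured selection, i.e. the RMSD
#' motif is also the fit set).
#'
#' @param traj a [coord_traj()].
#' @param reference reference coordinates: a [coord_traj()] (first frame
#'   used) or an `atoms x 3` matrix over the full topology.
#' @param selection integer atom indices to measure over.
#' @param fit logical; superpose before measuring (default TRUE).
#' @param fit_selection atom indices to fit on; default `selection`.
#' @return numeric vector of per-frame RMSD in Angstrom.
#' @export
superpose_rmsd <- function(traj, reference, selection, fit = TRUE,
                           fit_selection = selection) {
  if (inherits(reference, "coord_traj")) reference <- frame_xyz(reference)
  reference <- as.matrix(reference)
  if (!length(selection)) stop("empty atom selection")
  if (max(selection, fit_selection) > nrow(reference))
    stop("selection exceeds reference atom count")
  refsel <- reference[selection, , drop = FALSE]
  n_frames <- dim(traj$coords)[1L]
  out <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    P <- frame_xyz(traj, t)
    if (fit) {
      k <- kabsch(P[fit_selection, , drop = FALSE],
                  reference[fit_selection, , drop = FALSE])
      Ps <- P[selection, , drop = FALSE] %*% t(k$R) +
        matrix(k$t, length(selection), 3L, byrow = TRUE)
    } else {
      Ps <- P[selection, , drop = FALSE]
    }
    out[t] <- sqrt(mean(rowSums((Ps - refsel)^2)))
  }
  out
}

#' Per-frame distance between two named atoms
#'
#' @param traj a [coord_traj()].
#' @param pair list of two `(resno, atom)` pairs, e.g.
#'   `list(c(439, "CD"), c(468, "CZ"))`.
#' @return numeric vector of per-frame distances in Angstrom.
#' @export
atom_pair_distance <- function(traj, pair) {
  i <- atom_index(traj$topology, as.integer(pair[[1L]][1L]), pair[[1L]][2L])
  j <- atom_index(traj$topology, as.integer(pair[[2L]][1L]), pair[[2L]][2L])
  xi <- matrix(traj$coords[, i, ], ncol = 3L)
  xj <- matrix(traj$coords[, j, ], ncol = 3L)
  sqrt(rowSums((xi - xj)^2))
}

#' Order-parameter specification
#'
#' Resolves the structural-switch selections against a topology: A-loop
#' (heavy atoms of residues 539-559), DFG motif (539-541), P-loop (410-415),
#' R-spine (residues 540, 449, 519, 460) and the two C-helix salt bridges
#' (Glu439 CD - Arg468 CZ; Glu445 CD - Lys430 NZ), all RMSDs relative to a
#' supplied reference structure (a double-helical inactive state in the BTK
#' convention).  Residue numbering is author numbering.
#'
#' @param top a [topology()].
#' @param reference reference coordinates (matrix or [coord_traj()]).
#' @param aloop,dfg,ploop,rspine residue-number vectors.
#' @param sb1,sb2 salt-bridge atom pairs as for [atom_pair_distance()].
#' @param fit `"selection"` (fit on the measured motif, default) or
#'   `"all"` (fit on all heavy atoms).
#' @return object of class `op_spec`.
#' @export
order_parameter_spec <- function(top, reference,
                                 aloop = 539:559, dfg = 539:541,
                                 ploop = 410:415,
                                 rspine = c(540, 449, 519, 460),
                                 sb1 = list(c(439, "CD"), c(468, "CZ")),
                                 sb2 = list(c(445, "CD"), c(430, "NZ")),
                                 fit = c("selection", "all")) {
  fit <- match.arg(fit)
  heavy_of <- function(resnos) {
    i <- which(top$resno %in% resnos & top$heavy)
    if (!length(i)) stop("no heavy atoms found for residues ",
                         paste(resnos, collapse = ","))
    i
  }
  for (pr in list(sb1, sb2))
    for (p in pr) atom_index(top, as.integer(p[1L]), p[2L])
  if (inherits(reference, "coord_traj")) reference <- frame_xyz(reference)
  structure(list(reference = as.matrix(reference),
                 sel = list(aloop = heavy_of(aloop), dfg = heavy_of(dfg),
                            ploop = heavy_of(ploop),
                            rspine = heavy_of(rspine)),
                 sb1 = sb1, sb2 = sb2, fit = fit,
                 all_heavy = which(top$heavy)),
            class = "op_spec")
}

#' Structural order-parameter panel
#'
#' The molecular-switch observables tracked along a trajectory: A-loop,
#' P-loop, R-spine and DFG RMSDs to the reference state plus the two C-helix
#' salt-bridge distances.  Column names and order are stable:
#' `aloop_rmsd`, `r468_e439_dist`, `k430_e445_dist`, `ploop_rmsd`,
#' `rspine_rmsd`, `dfg_rmsd`.
#'
#' @param traj a [coord_traj()].
#' @param spec an [order_parameter_spec()].
#' @return a [feature_traj()] with the six named columns.
#' @export
order_parameter_panel <- function(traj, spec) {
  stopifnot(inherits(spec, "op_spec"))
  fitsel <- function(sel) if (spec$fit == "all") spec$all_heavy else sel
  vals <- cbind(
    aloop_rmsd = superpose_rmsd(traj, spec$reference, spec$sel$aloop,
                                fit_selection = fitsel(spec$sel$aloop)),
    r468_e439_dist = atom_pair_distance(traj, spec$sb1),
    k430_e445_dist = atom_pair_distance(traj, spec$sb2),
    ploop_rmsd = superpose_rmsd(traj, spec$reference, spec$sel$ploop,
                                fit_selection = fitsel(spec$sel$ploop)),
    rspine_rmsd = superpose_rmsd(traj, spec$reference, spec$sel$rspine,
                                 fit_selection = fitsel(spec$sel$rspine)),
    dfg_rmsd = superpose_rmsd(traj, spec$reference, spec$sel$dfg,
                              fit_selection = fitsel(spec$sel$dfg)))
  feature_traj(vals, dt = traj$dt)
}

#' Trailing moving average
#'
#' Mean over the trailing `window` frames; the first `window - 1` entries
#' average over the available prefix only.
#'
#' @param series numeric vector.
#' @param window window length in frames (>= 1, <= length of series).
#' @return smoothed numeric vector of the same length.
#' @export
moving_average <- function(series, window) {
  n <- length(series)
  stopifnot(window >= 1L)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  cs <- cumsum(series)
  out <- numeric(n)
  head_n <- seq_len(min(window, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > window)
    out[(window + 1L):n] <- (cs[(window + 1L):n] - cs[1L:(n - window)]) / window
  out
}

#' Pooled z-score normalization of feature trajectories
#'
#' Per-feature centering and scaling with mean and standard deviation pooled
#' over all trajectories.  Zero-variance features are scaled by 1 and
#' flagged, never divided by zero.
#'
#' @param trajs list of [feature_traj()] (or matrices).
#' @return list with `trajs` (normalized, same classes), `center`, `scale`,
#'   `constant` (logical flags).
#' @export
normalize_features <- function(trajs) {
  xs <- as_feature_list(trajs)
  dt <- attr(xs, "dt")
  all_x <- do.call(rbind, xs)
  ctr <- colMeans(all_x)
  sc <- apply(all_x, 2L, sd)
  constant <- !is.finite(sc) | sc < 1e-300
  sc[constant] <- 1
  out <- lapply(xs, function(x) {
    z <- sweep(sweep(x, 2L, ctr), 2L, sc, "/")
    if (is.na(dt)) z else feature_traj(z, dt = dt, names = colnames(x))
  })
  list(trajs = out, center = ctr, scale = sc, constant = constant)
}
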