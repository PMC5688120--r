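# Independent oracles, deliberately implemented by different algorithms than
# the package code they check.

# Dihedral via explicit plane normals and a signed acos (vs the package's
# atan2 formulation).
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (sum(cross3(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -pi + 1e-15) ang <- pi
  ang
}

# Optimal superposition by Horn's quaternion method (vs the package's
# SVD/Kabsch), returning the minimal RMSD fitting X onto Y.
oracle_superpose_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
}

# Strongly connected components by Kosaraju's two-pass DFS (vs igraph).
# Recursive; fine for the small graphs used in tests.
oracle_scc <- function(adj) {
  n <- nrow(adj)
  visited <- logical(n); order_ <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    for (u in which(adj[v, ])) if (!visited[u]) dfs1(u)
    order_ <<- c(order_, v)
  }
  for (v in seq_len(n)) if (!visited[v]) dfs1(v)
  comp <- integer(n); cur <- 0L
  dfs2 <- function(v) {
    comp[v] <<- cur
    for (u in which(adj[, v])) if (comp[u] == 0L) dfs2(u)
  }
  for (v in rev(order_)) if (comp[v] == 0L) {
    cur <- cur + 1L
    dfs2(v)
  }
  comp
}

# Transition counts by explicit pair enumeration.
oracle_counts <- function(dtrajs, lag, n) {
  C <- matrix(0, n, n)
  for (s in dtrajs) {
    if (length(s) <= lag) next
    for (t in seq_len(length(s) - lag))
      C[s[t], s[t + lag]] <- C[s[t], s[t + lag]] + 1
  }
  C
}

# Minimum pairwise distance by exhaustive double loop.
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}
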