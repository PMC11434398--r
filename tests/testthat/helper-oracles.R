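# Independent oracles used across the suite. Each re-derives its quantity by
# the most direct route available (explicit double loops, exhaustive scans,
# closed forms, multi-start search) and never calls the implementation path
# it checks.

# gyration tensor by explicit double-indexed assembly
oracle_gyration_eigenvalues <- function(coords, w = NULL) {
  n <- nrow(coords)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  centre <- c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w))
  S <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- coords[i, ] - centre
    for (a in 1:3) for (b in 1:3) S[a, b] <- S[a, b] + w[i] * d[a] * d[b]
  }
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

# per-water minimum distance to the solute by an explicit all-pairs scan
oracle_shell_counts <- function(solute_xyz, water_xyz, r1, r2) {
  first <- 0L; second <- 0L
  for (w in seq_len(nrow(water_xyz))) {
    dmin <- Inf
    for (s in seq_len(nrow(solute_xyz)))
      dmin <- min(dmin, sqrt(sum((water_xyz[w, ] - solute_xyz[s, ])^2)))
    if (dmin <= r1) first <- first + 1L
    else if (dmin <= r2) second <- second + 1L
  }
  c(first, second)
}

# exhaustive donor-H-acceptor triple loop over one frame
oracle_hbond_count <- function(xyz, dh_pairs, acceptors, d_max, angle_min) {
  count <- 0L
  for (p in seq_len(nrow(dh_pairs))) {
    d_i <- dh_pairs[p, 1]; h_i <- dh_pairs[p, 2]
    for (a in acceptors) {
      if (a == d_i) next
      if (sqrt(sum((xyz[d_i, ] - xyz[a, ])^2)) > d_max) next
      v1 <- xyz[d_i, ] - xyz[h_i, ]
      v2 <- xyz[a, ] - xyz[h_i, ]
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
        180 / pi
      if (ang >= angle_min) count <- count + 1L
    }
  }
  count
}

rotation_from_vec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimum RMSD over SO(3) by multi-start axis-angle search with local
# refinement; independent of the SVD route
oracle_min_rmsd <- function(A, B, n_starts = 40L) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  f <- function(v) sqrt(mean(rowSums((B %*% rotation_from_vec(v) - A)^2)))
  best <- Inf
  starts <- rbind(matrix(0, 1, 3),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi), ncol = 3))
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(starts[s, ], f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    best <- min(best, r$value)
  }
  best
}

# area of the union of two equal-or-unequal circles at centre distance d
oracle_two_circle_union <- function(r1, r2, d) {
  if (d >= r1 + r2) return(pi * r1^2 + pi * r2^2)
  if (d <= abs(r1 - r2)) return(pi * max(r1, r2)^2)
  lens <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  pi * r1^2 + pi * r2^2 - lens
}

# same-partition check up to cluster relabelling (co-membership equality)
same_partition <- function(a, b) {
  all(outer(a, a, `==`) == outer(b, b, `==`))
}
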