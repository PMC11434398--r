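# Shape descriptors. The gyration tensor S = sum_i w_i (r_i - rbar)(r_i -
# rbar)^T / sum_i w_i has eigenvalues l1 <= l2 <= l3 (A^2) from which
# Rg^2 = l1+l2+l3, asphericity b = l3 - (l1+l2)/2, acylindricity c = l2 - l1
# and relative shape anisotropy kappa^2 = (b^2 + 3c^2/4)/Rg^4 in [0, 1].

#' Gyration-tensor shape descriptors
#'
#' @param coords numeric n x 3 coordinate matrix, Angstrom.
#' @param masses per-atom masses; required when `mass_weighted`.
#' @param mass_weighted weight atoms by mass (default) or uniformly.
#' @return A list with `eigenvalues` (ascending, A^2), `rg` (A),
#'   `asphericity` (A^2), `acylindricity` (A^2) and `kappa2` (dimensionless;
#'   `NA` with a warning when all atoms coincide).
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' gyration_descriptors(cube, mass_weighted = FALSE)$kappa2  # 0
#' @export
gyration_descriptors <- function(coords, masses = NULL, mass_weighted = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 atoms")
  w <- if (mass_weighted) {
    if (is.null(masses)) stop("masses required when mass_weighted = TRUE")
    masses
  } else rep(1, nrow(coords))
  w <- w / sum(w)
  centre <- colSums(coords * w)
  d <- sweep(coords, 2, centre)
  S <- crossprod(d * w, d)          # sum_i w_i d_i d_i^T
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  rg2 <- sum(ev)
  b <- ev[3] - (ev[1] + ev[2]) / 2
  cc <- ev[2] - ev[1]
  kappa2 <- if (rg2 == 0) {
    warning("all atoms coincident: kappa2 undefined")
    NA_real_
  } else (b^2 + 0.75 * cc^2) / rg2^2
  list(eigenvalues = ev, rg = sqrt(rg2), asphericity = b, acylindricity = cc,
       kappa2 = kappa2)
}

#' Principal axes and moments of inertia
#'
#' Eigendecomposition of the inertia tensor
#' I = sum_i m_i (|d_i|^2 Id - d_i d_i^T), d_i = r_i - centre of mass.
#' Degenerate moments are allowed; ties follow the deterministic symmetric
#' eigen-solver ordering.
#'
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param masses per-atom masses, amu.
#' @return A list with `axes` (3 x 3 matrix, orthonormal axis vectors in
#'   columns) and `moments` (ascending, amu A^2).
#' @export
principal_inertia_axes <- function(coords, masses) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 atoms")
  centre <- colSums(coords * masses) / sum(masses)
  d <- sweep(coords, 2, centre)
  r2 <- rowSums(d^2)
  I <- diag(sum(masses * r2), 3) - crossprod(d * masses, d)
  e <- eigen(I, symmetric = TRUE)   # descending
  ord <- order(e$values)
  list(axes = e$vectors[, ord, drop = FALSE], moments = e$values[ord])
}

# union-of-disks area by grid occupancy on cell centres; the grid origin is
# snapped to multiples of res so a sub-disk's cells are a subset of the union's
.disk_union_area <- function(p, radii, res) {
  xr <- range(p[, 1]) + c(-1, 1) * max(radii)
  yr <- range(p[, 2]) + c(-1, 1) * max(radii)
  x0 <- floor(xr[1] / res) * res
  y0 <- floor(yr[1] / res) * res
  nx <- ceiling((xr[2] - x0) / res) + 1L
  ny <- ceiling((yr[2] - y0) / res) + 1L
  occ <- matrix(FALSE, nx, ny)
  cx <- x0 + (seq_len(nx) - 0.5) * res
  cy <- y0 + (seq_len(ny) - 0.5) * res
  for (a in seq_len(nrow(p))) {
    r <- radii[a]
    ix <- which(abs(cx - p[a, 1]) <= r)
    iy <- which(abs(cy - p[a, 2]) <= r)
    if (!length(ix) || !length(iy)) next
    dx2 <- (cx[ix] - p[a, 1])^2
    dy2 <- (cy[iy] - p[a, 2])^2
    occ[ix, iy] <- occ[ix, iy] | (outer(dx2, dy2, `+`) <= r^2)
  }
  sum(occ) * res^2
}

#' Minimal projection area from van der Waals silhouettes
#'
#' Projects the molecule's atoms, as disks of their van der Waals radii, onto
#' the three planes perpendicular to the principal axes of inertia, and
#' measures the area of each disk union by 2-D grid occupancy. The minimal
#' projection area (MPA) is the smallest of the three.
#'
#' @param structure a [mol_structure()] (vdW radii must be tabulated), or a
#'   list with elements `xyz`, `vdw`, `mass`.
#' @param grid_resolution grid spacing in Angstrom (default 0.05).
#' @return A list with `areas` (3 values, A^2, in ascending-moment axis
#'   order), `mpa` (their minimum) and `grid_resolution`.
#' @export
minimal_projection_area <- function(structure, grid_resolution = 0.05) {
  if (grid_resolution <= 0) stop("grid_resolution must be positive")
  xyz <- as.matrix(structure$xyz)
  vdw <- structure$vdw
  if (is.null(vdw) || anyNA(vdw)) stop("vdW radii unavailable")
  if (nrow(xyz) == 1L) {
    ax <- diag(3)
  } else {
    ax <- principal_inertia_axes(xyz, structure$mass)$axes
  }
  areas <- vapply(1:3, function(k) {
    basis <- ax[, -k, drop = FALSE]
    .disk_union_area(xyz %*% basis, vdw, grid_resolution)
  }, 0.0)
  list(areas = areas, mpa = min(areas), grid_resolution = grid_resolution)
}

# optimal proper rotation R with P %*% R ~ Q for centred P, Q (Kabsch)
.kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Kabsch-superposed RMSD between two conformations
#'
#' With `fit = TRUE` the optimal translation and proper rotation (determinant
#' correction applied) minimising the RMSD are removed first. Mass-unweighted.
#' Fewer than 3 atoms cannot fix a rotation: the fit falls back to
#' translation-only with a warning.
#'
#' @param coordsA,coordsB numeric n x 3 matrices with corresponding atom order.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coordsA, coordsB, fit = TRUE) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in atom count")
  if (fit) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    if (nrow(A) >= 3L) {
      B <- B %*% .kabsch_rotation(B, A)
    } else {
      warning("fewer than 3 atoms: translation-only fit")
    }
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-frame shape descriptors along a trajectory
#'
#' Computes the gyration-tensor descriptors and (optionally) the minimal
#' projection area on the solute selection of every frame, and summarises
#' each descriptor by its mean and standard deviation over frames.
#'
#' @param traj a [trajectory()].
#' @param solute_only restrict to solute+metal atoms (default TRUE).
#' @param mass_weighted gyration-tensor weighting, see
#'   [gyration_descriptors()].
#' @param mpa also compute the per-frame MPA (default TRUE).
#' @param grid_resolution MPA grid spacing, Angstrom.
#' @return A list with `per_frame` (data frame: frame, rg, asphericity,
#'   acylindricity, kappa2 and, when requested, mpa) and `summary` (data
#'   frame of means and SDs per descriptor).
#' @export
trajectory_morphology <- function(traj, solute_only = TRUE,
                                  mass_weighted = TRUE, mpa = TRUE,
                                  grid_resolution = 0.05) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- if (solute_only) solute_indices(traj) else seq_len(n_atoms(traj))
  if (length(sel) == 0L) stop("empty solute selection")
  topo <- traj$topology
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$frames[[f]][sel, , drop = FALSE]
    g <- gyration_descriptors(xyz, topo$mass[sel], mass_weighted)
    row <- data.frame(frame = f, rg = g$rg, asphericity = g$asphericity,
                      acylindricity = g$acylindricity, kappa2 = g$kappa2)
    if (mpa) {
      pr <- minimal_projection_area(
        list(xyz = xyz, vdw = topo$vdw[sel], mass = topo$mass[sel]),
        grid_resolution)
      row$mpa <- pr$mpa
    }
    row
  })
  per_frame <- do.call(rbind, rows)
  metrics <- setdiff(names(per_frame), "frame")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_frame[[m]]), 0.0),
    sd = vapply(metrics, function(m) stats::sd(per_frame[[m]]), 0.0),
    row.names = NULL
  )
  list(per_frame = per_frame, summary = summary)
}
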