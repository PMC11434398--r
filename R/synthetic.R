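# Synthetic-data generators. Every generator is a pure function of its
# arguments plus a seed (bit-reproducible) and emits ground truth alongside
# the data, so the descriptor extractors can be tested against known answers
# without any electronic-structure or MD engine.

# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# largest-remainder apportionment: integer counts summing to n, proportional
# to weights, exact whenever n * weights are integers
.stratified_counts <- function(weights, n) {
  if (length(weights) == 0L) stop("empty weights")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  raw <- weights * n
  base <- floor(raw + 1e-9)
  left <- n - sum(base)
  if (left > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a solute structure of controlled shape
#'
#' Shapes have documented exact symmetries: `cube` places 8 atoms at the cube
#' corners (equal gyration eigenvalues), `rod` is collinear (kappa2 = 1),
#' `ring` is a planar regular polygon, `sphere_shell` a deterministic
#' Fibonacci sphere, `random_cloud` a seeded uniform cloud.
#'
#' @param shape one of `"cube"`, `"rod"`, `"ring"`, `"sphere_shell"`,
#'   `"random_cloud"`.
#' @param n_atoms atom count (`cube` requires 8; `rod`/`ring` at least 2/3).
#' @param size characteristic size in Angstrom (cube half-edge, rod
#'   half-length, ring/sphere/cloud radius).
#' @param element element symbol for all atoms (default `"C"`).
#' @param metal optional metal element; when given, one extra atom of this
#'   element with role `"metal"` is placed at the centroid.
#' @param jitter_sigma per-coordinate Gaussian displacement, Angstrom
#'   (default 0: exact symmetry).
#' @param seed RNG seed (used by jitter and `random_cloud`).
#' @return A [mol_structure()].
#' @export
make_structure <- function(shape = c("cube", "rod", "ring", "sphere_shell",
                                     "random_cloud"),
                           n_atoms = 8L, size = 2.0, element = "C",
                           metal = NULL, jitter_sigma = 0, seed = 1L) {
  shape <- match.arg(shape)
  minimum <- c(cube = 8L, rod = 2L, ring = 3L, sphere_shell = 4L,
               random_cloud = 2L)[[shape]]
  if (n_atoms < minimum)
    stop(sprintf("shape '%s' needs at least %d atoms", shape, minimum))
  if (shape == "cube" && n_atoms != 8L) stop("shape 'cube' uses exactly 8 atoms")
  xyz <- with_seed(seed, {
    base <- switch(shape,
      cube = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * size,
      rod = cbind(seq(-size, size, length.out = n_atoms), 0, 0),
      ring = {
        t <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
        cbind(size * cos(t), size * sin(t), 0)
      },
      sphere_shell = {
        i <- seq_len(n_atoms)
        phi <- acos(1 - 2 * (i - 0.5) / n_atoms)
        th <- pi * (1 + sqrt(5)) * i
        size * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
      },
      random_cloud = matrix(stats::runif(3 * n_atoms, -size, size),
                            ncol = 3)
    )
    if (jitter_sigma > 0)
      base <- base + matrix(stats::rnorm(length(base), 0, jitter_sigma),
                            ncol = 3)
    base
  })
  colnames(xyz) <- NULL
  elements <- rep(element, nrow(xyz))
  roles <- rep("solute", nrow(xyz))
  if (!is.null(metal)) {
    xyz <- rbind(colMeans(xyz), xyz)
    elements <- c(metal, elements)
    roles <- c("metal", roles)
  }
  mol_structure(elements, xyz, role = roles)
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a trajectory as a stratified conformer mixture with jitter
#'
#' Frames draw their base geometry from `conformers` with exact
#' (largest-remainder) stratified counts proportional to `weights`, add
#' isotropic per-atom Gaussian jitter of width `jitter_sigma`, and optionally
#' a random rigid rotation+translation per frame. The frame order is a seeded
#' permutation; the ground-truth conformer of each frame is returned in
#' `attr(, "conformer_labels")`.
#'
#' @param conformers list of n x 3 coordinate matrices sharing one topology,
#'   or a single matrix.
#' @param topology a [mol_structure()] describing the atoms.
#' @param weights conformer mixture fractions, summing to 1.
#' @param n_frames number of frames.
#' @param jitter_sigma per-coordinate Gaussian width, Angstrom.
#' @param rigid_motions add a random rigid rotation and translation per frame.
#' @param seed RNG seed.
#' @return A [trajectory()] with attribute `conformer_labels`.
#' @export
make_trajectory <- function(conformers, topology, weights = 1,
                            n_frames = 100L, jitter_sigma = 0.1,
                            rigid_motions = FALSE, seed = 1L) {
  if (is.matrix(conformers)) conformers <- list(conformers)
  if (length(weights) != length(conformers))
    stop("one weight per conformer required")
  counts <- .stratified_counts(weights, n_frames)
  labels0 <- rep(seq_along(conformers), counts)
  traj <- with_seed(seed, {
    perm <- sample.int(n_frames)
    labels <- labels0[perm]
    frames <- lapply(labels, function(l) {
      xyz <- conformers[[l]]
      if (jitter_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma),
                            ncol = 3)
      if (rigid_motions) {
        xyz <- xyz %*% .random_rotation()
        xyz <- sweep(xyz, 2, stats::runif(3, -5, 5), `+`)
      }
      xyz
    })
    out <- trajectory(topology, frames)
    attr(out, "conformer_labels") <- labels
    out
  })
  traj
}

#' Generate a solvated frame with prescribed shell occupancies
#'
#' Places exactly the requested number of water oxygens so that each one's
#' minimum distance to any solute atom falls uniformly inside the requested
#' band, subject to a water-water minimum distance; two hydrogens are
#' attached at 0.96 Angstrom with a rigid 104.5-degree internal angle. The
#' water model is rigid 3-site geometry only - sufficient for distance and
#' H-bond tests, with no physical water model claimed.
#'
#' @param solute a [mol_structure()].
#' @param shell_counts integer vector, waters requested per band.
#' @param shell_bounds matrix with one `(lo, hi)` row per band, Angstrom.
#' @param min_water_dist minimum O-O distance between placed waters.
#' @param seed RNG seed.
#' @param max_tries placement retries per water before giving up.
#' @return A [trajectory()] with a single solvated frame.
#' @export
make_solvated_frame <- function(solute, shell_counts = c(12L, 20L),
                                shell_bounds = rbind(c(2.6, 3.3), c(3.6, 4.9)),
                                min_water_dist = 2.4, seed = 1L,
                                max_tries = 2000L) {
  stopifnot(inherits(solute, "mol_structure"))
  shell_bounds <- matrix(shell_bounds, ncol = 2)
  if (length(shell_counts) != nrow(shell_bounds))
    stop("one (lo, hi) bound pair per shell required")
  if (any(shell_bounds[, 1] >= shell_bounds[, 2]) ||
      any(diff(as.vector(t(shell_bounds))) < 0))
    stop("shell bounds must be ordered")
  S <- solute$xyz
  placed <- with_seed(seed, {
    oxy <- matrix(numeric(0), ncol = 3)
    for (band in seq_along(shell_counts)) {
      lo <- shell_bounds[band, 1]; hi <- shell_bounds[band, 2]
      for (w in seq_len(shell_counts[band])) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          anchor <- S[sample.int(nrow(S), 1L), ]
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pos <- anchor + dir * stats::runif(1, lo, hi)
          dmin <- min(sqrt(rowSums(sweep(S, 2, pos)^2)))
          if (dmin < lo || dmin > hi) next
          if (nrow(oxy) > 0 &&
              min(sqrt(rowSums(sweep(oxy, 2, pos)^2))) < min_water_dist) next
          oxy <- rbind(oxy, pos)
          ok <- TRUE
          break
        }
        if (!ok) stop(sprintf(
          "infeasible packing: could not place water %d of band %d", w, band))
      }
    }
    oxy
  })
  hxyz <- with_seed(seed + 1L, {
    out <- matrix(numeric(0), ncol = 3)
    for (i in seq_len(nrow(placed))) {
      R <- .random_rotation()
      half <- 104.5 / 2 * pi / 180
      local <- rbind(c(sin(half), cos(half), 0),
                     c(-sin(half), cos(half), 0)) * 0.96
      out <- rbind(out, sweep(local %*% R, 2, placed[i, ], `+`))
    }
    out
  })
  nw <- nrow(placed)
  elements <- c(solute$element, rep(c("O", "H", "H"), nw))
  roles <- c(solute$role,
             rep(c("water_oxygen", "water_hydrogen", "water_hydrogen"), nw))
  xyz <- rbind(S, do.call(rbind, lapply(seq_len(max(nw, 0L)), function(i)
    rbind(placed[i, ], hxyz[2 * i - 1, ], hxyz[2 * i, ]))))
  if (nw == 0L) xyz <- S
  topo <- mol_structure(elements, xyz, role = roles, bonds = solute$bonds)
  trajectory(topo, list(xyz))
}

#' Generate an orbital-energy ladder with a prescribed frontier gap
#'
#' Evenly spaced occupied orbitals topping out at `homo` and virtuals
#' starting at `lumo`, so `frontier_gap()` of the result equals
#' `lumo - homo` exactly. Open-shell ladders place the SOMO at `homo` in the
#' alpha channel, with the beta occupied manifold offset downwards.
#'
#' @param homo highest occupied energy, eV.
#' @param lumo lowest unoccupied energy, eV; must exceed `homo`... the
#'   generator refuses inverted ladders (test inverted gaps by shifting a
#'   built spectrum instead).
#' @param n_occ,n_virt counts of occupied and virtual orbitals (>= 1).
#' @param open_shell build an unrestricted alpha/beta spectrum.
#' @param spacing ladder spacing, eV.
#' @return An [orbital_spectrum()].
#' @export
make_orbital_ladder <- function(homo = -6.0, lumo = -1.5, n_occ = 5L,
                                n_virt = 5L, open_shell = FALSE,
                                spacing = 1.0) {
  if (n_occ < 1L || n_virt < 1L) stop("need at least one occupied and one virtual")
  if (homo >= lumo) stop("homo must lie below lumo")
  occ_ladder <- homo - spacing * rev(seq_len(n_occ) - 1L)
  virt_ladder <- lumo + spacing * (seq_len(n_virt) - 1L)
  if (!open_shell) {
    return(orbital_spectrum(list(restricted = data.frame(
      energy = c(occ_ladder, virt_ladder),
      occupation = c(rep(2, n_occ), rep(0, n_virt))))))
  }
  beta_occ <- if (n_occ > 1L) occ_ladder[-n_occ] - 0.4 * spacing else numeric(0)
  orbital_spectrum(list(
    alpha = data.frame(energy = c(occ_ladder, virt_ladder),
                       occupation = c(rep(1, n_occ), rep(0, n_virt))),
    beta = data.frame(energy = c(beta_occ, virt_ladder + 0.3 * spacing),
                      occupation = c(rep(1, length(beta_occ)), rep(0, n_virt)))
  ))
}

# gradient of the A-B-C angle w.r.t. the 3 atom positions (rows A, B, C)
.angle_gradient <- function(A, B, C) {
  v1 <- A - B; R1 <- sqrt(sum(v1^2)); u1 <- v1 / R1
  v2 <- C - B; R2 <- sqrt(sum(v2^2)); u2 <- v2 / R2
  ct <- sum(u1 * u2)
  st <- sqrt(max(1 - ct^2, 1e-12))
  gA <- (ct * u1 - u2) / (R1 * st)
  gC <- (ct * u2 - u1) / (R2 * st)
  rbind(gA, -gA - gC, gC)
}

#' Assemble an analytic harmonic Hessian with known force constants
#'
#' Exact second derivatives, at equilibrium, of
#' E = sum 1/2 k (d - d0)^2 + sum 1/2 k_theta (theta - theta0)^2
#' with the current geometry taken as the equilibrium (so only
#' first-derivative outer products survive). The result is exactly symmetric
#' and translationally invariant (atom-block row sums vanish).
#'
#' @param geometry n x 3 coordinate matrix, Angstrom.
#' @param bonds data frame with columns `i`, `j`, `k` (kcal mol^-1 A^-2).
#' @param angles data frame with columns `i`, `j`, `k` (atom indices, `j`
#'   central) and `k_theta` (kcal mol^-1 rad^-2).
#' @return A [cartesian_hessian()] in kcal mol^-1 A^-2.
#' @examples
#' geom <- rbind(c(0, 0, 0), c(1.5, 0, 0))
#' h <- make_harmonic_hessian(geom, bonds = data.frame(i = 1, j = 2, k = 500))
#' @export
make_harmonic_hessian <- function(geometry, bonds = NULL, angles = NULL) {
  geometry <- as.matrix(geometry)
  n <- nrow(geometry)
  H <- matrix(0, 3 * n, 3 * n)
  add_outer <- function(idx, grads, k) {
    g <- numeric(3 * n)
    for (a in seq_along(idx)) g[(3 * idx[a] - 2):(3 * idx[a])] <- grads[a, ]
    H <<- H + k * tcrossprod(g)
  }
  if (!is.null(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (max(i, j) > n) stop("bond term references a missing atom")
      v <- geometry[i, ] - geometry[j, ]
      u <- v / sqrt(sum(v^2))
      add_outer(c(i, j), rbind(u, -u), bonds$k[r])
    }
  }
  if (!is.null(angles)) {
    for (r in seq_len(nrow(angles))) {
      idx <- c(angles$i[r], angles$j[r], angles$k[r])
      if (max(idx) > n) stop("angle term references a missing atom")
      g <- .angle_gradient(geometry[idx[1], ], geometry[idx[2], ],
                           geometry[idx[3], ])
      add_outer(idx, g, angles$k_theta[r])
    }
  }
  cartesian_hessian((H + t(H)) / 2, geometry)
}

#' Write a complete synthetic compound directory
#'
#' Emits, in the formats the readers consume, everything [run_compound()]
#' looks for: `optimized.xyz`, `mm_optimized.xyz` (a perturbed copy standing
#' in for the force-field-minimised geometry), `orbital_energies.txt`,
#' `scf_energies.txt`, `trajectory.pdb.gz` and `hessian.txt`, plus a
#' `ground_truth.json` sidecar holding every generating parameter so tests
#' never re-derive them.
#'
#' @param dir output directory (created).
#' @param metal metal element symbol.
#' @param gap frontier gap to encode in the orbital ladder, eV.
#' @param open_shell open-shell orbital ladder?
#' @param fundamental_gap delta-SCF fundamental gap to encode, eV.
#' @param n_frames trajectory frames.
#' @param jitter_sigma trajectory jitter, Angstrom.
#' @param n_waters waters per frame placed in the first/second shells.
#' @param mm_shift uniform bond-length perturbation of the MM copy, Angstrom.
#' @param seed RNG seed.
#' @return The ground-truth list, invisibly.
#' @export
write_synthetic_compound <- function(dir, metal = "Ga", gap = 6.5,
                                     open_shell = FALSE, fundamental_gap = 8.0,
                                     n_frames = 25L, jitter_sigma = 0.05,
                                     n_waters = c(6L, 8L), mm_shift = 0.1,
                                     seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  solute <- make_structure("ring", n_atoms = 8L, size = 2.2, element = "N",
                           metal = metal, seed = seed)
  write_xyz(solute, file.path(dir, "optimized.xyz"),
            comment = "synthetic optimized geometry")
  mm <- solute
  mm$xyz <- with_seed(seed + 1L, {
    sh <- sweep(mm$xyz[-1, , drop = FALSE], 2, mm$xyz[1, ])
    d <- sqrt(rowSums(sh^2))
    rbind(mm$xyz[1, ], mm$xyz[1, ] + sh * (d + mm_shift) / d)
  })
  write_xyz(mm, file.path(dir, "mm_optimized.xyz"),
            comment = "synthetic MM-minimised geometry")
  homo <- -5.0 - gap / 10
  spec <- make_orbital_ladder(homo = homo, lumo = homo + gap, n_occ = 6L,
                              n_virt = 6L, open_shell = open_shell)
  write_orbital_energies(spec, file.path(dir, "orbital_energies.txt"))
  E_N <- -2721.14
  IEv <- fundamental_gap / 2 + 6
  EAv <- IEv - fundamental_gap
  writeLines(c("# delta-SCF total energies, eV",
               sprintf("E_N %.6f", E_N),
               sprintf("E_Nminus1 %.6f", E_N + IEv),
               sprintf("E_Nplus1 %.6f", E_N - EAv)),
             file.path(dir, "scf_energies.txt"))
  solv <- make_solvated_frame(solute, shell_counts = n_waters, seed = seed + 2L)
  traj <- make_trajectory(solv$frames[[1]], solv$topology,
                          n_frames = n_frames, jitter_sigma = jitter_sigma,
                          seed = seed + 3L)
  write_pdb_trajectory(traj, file.path(dir, "trajectory.pdb.gz"))
  geom <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(0, 2.0, 0))
  hess <- make_harmonic_hessian(
    geom,
    bonds = data.frame(i = c(1, 1), j = c(2, 3), k = c(500, 500)),
    angles = data.frame(i = 2, j = 1, k = 3, k_theta = 100))
  write_hessian(hess, file.path(dir, "hessian.txt"),
                elements = c(metal, "O", "O"))
  truth <- list(metal = metal, gap = gap, open_shell = open_shell,
                fundamental_gap = fundamental_gap, IEv = IEv, EAv = EAv,
                n_frames = n_frames, jitter_sigma = jitter_sigma,
                n_waters = n_waters, mm_shift = mm_shift,
                k_bond = 500, k_angle = 100, seed = seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
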