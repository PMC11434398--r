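# Solvation-shell counts, geometric hydrogen-bond statistics and per-atom
# RMSF. A water belongs to the first shell of a frame when its oxygen's
# minimum distance to any solute atom is <= r1, to the second when it lies in
# (r1, r2]. An H-bond exists in a frame when the donor-acceptor heavy-atom
# distance is <= d_max and the donor-H-acceptor angle is >= angle_min.

.cross_min_dist <- function(A, B) {
  # for each row of B, its minimum distance to any row of A
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 2, min), 0))
}

#' Water counts in the first and second solvation shells
#'
#' @param traj a [trajectory()] whose topology tags water oxygens.
#' @param r1 first-shell cutoff, Angstrom (default 3.4).
#' @param r2 second-shell cutoff, Angstrom (default 5.0); must exceed `r1`.
#' @param metal_only measure distances to the metal atom only instead of to
#'   any solute atom (default FALSE).
#' @return A list with `first_shell` and `second_shell` (means over frames),
#'   `per_frame` (data frame of integer counts) and `cutoffs`.
#' @export
water_shell_counts <- function(traj, r1 = 3.4, r2 = 5.0, metal_only = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (r1 >= r2) stop("r1 must be smaller than r2")
  sol <- if (metal_only) which(traj$topology$role == "metal") else
    solute_indices(traj)
  if (length(sol) == 0L) stop("empty solute selection")
  wat <- which(traj$topology$role == "water_oxygen")
  per_frame <- t(vapply(traj$frames, function(xyz) {
    if (length(wat) == 0L) return(c(0L, 0L))
    dmin <- .cross_min_dist(xyz[sol, , drop = FALSE], xyz[wat, , drop = FALSE])
    c(sum(dmin <= r1), sum(dmin > r1 & dmin <= r2))
  }, integer(2)))
  per_frame <- data.frame(frame = seq_len(n_frames(traj)),
                          first = per_frame[, 1], second = per_frame[, 2])
  list(first_shell = mean(per_frame$first),
       second_shell = mean(per_frame$second),
       per_frame = per_frame, cutoffs = c(r1 = r1, r2 = r2))
}

# donor-H pairs: heavy N/O/F atoms with a bonded hydrogen; water O-H pairs are
# inferred from roles when the bond list does not cover them
.donor_h_pairs <- function(traj) {
  topo <- traj$topology
  heavy <- c("N", "O", "F")
  pairs <- NULL
  if (nrow(topo$bonds) > 0L) {
    b <- rbind(topo$bonds, topo$bonds[, 2:1, drop = FALSE])
    keep <- topo$element[b[, 1]] %in% heavy & topo$element[b[, 2]] == "H"
    pairs <- b[keep, , drop = FALSE]
  }
  wo <- which(topo$role == "water_oxygen")
  covered <- if (is.null(pairs)) integer(0) else pairs[, 1]
  for (o in setdiff(wo, covered)) {
    xyz <- traj$frames[[1]]
    wh <- which(topo$role == "water_hydrogen")
    if (!length(wh)) next
    d <- sqrt(rowSums((xyz[wh, , drop = FALSE] -
                         matrix(xyz[o, ], length(wh), 3, byrow = TRUE))^2))
    pairs <- rbind(pairs, cbind(o, wh[d < 1.25]))
  }
  pairs
}

#' Geometric hydrogen-bond statistics along a trajectory
#'
#' Donors are N/O/F atoms carrying a bonded hydrogen (water O-H pairs are
#' inferred from atom roles when absent from the bond list); acceptors are all
#' N/O/F atoms. Each donor-H...acceptor triple's occupancy is the fraction of
#' frames in which it satisfies both geometric criteria. Triples are labelled
#' `intra` (donor and acceptor both solute), `solute_water` (one solute, one
#' water) or `water_water`.
#'
#' @param traj a [trajectory()].
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.0).
#' @param angle_min minimum donor-H-acceptor angle, degrees (default 135).
#' @return A list with `pairs` (data frame: donor, hydrogen, acceptor, type,
#'   occupancy), and `per_frame` (data frame of solute-water and intra counts
#'   per frame). Empty when the topology has no donors or acceptors (with a
#'   warning).
#' @export
hbond_statistics <- function(traj, d_max = 3.0, angle_min = 135) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  dh <- .donor_h_pairs(traj)
  acceptors <- which(topo$element %in% c("N", "O", "F"))
  if (is.null(dh) || nrow(dh) == 0L || length(acceptors) == 0L) {
    warning("no donors or no acceptors in topology")
    return(list(pairs = data.frame(), per_frame = data.frame()))
  }
  nf <- n_frames(traj)
  is_water <- topo$role %in% c("water_oxygen", "water_hydrogen")
  hits <- list()
  per_frame <- matrix(0L, nf, 2, dimnames = list(NULL, c("solute_water", "intra")))
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    for (p in seq_len(nrow(dh))) {
      d_i <- dh[p, 1]; h_i <- dh[p, 2]
      acc <- acceptors[acceptors != d_i]
      da <- sqrt(rowSums((xyz[acc, , drop = FALSE] -
                            matrix(xyz[d_i, ], length(acc), 3, byrow = TRUE))^2))
      close <- acc[da <= d_max]
      if (!length(close)) next
      v1 <- matrix(xyz[d_i, ], length(close), 3, byrow = TRUE) -
        matrix(xyz[h_i, ], length(close), 3, byrow = TRUE)
      v2 <- xyz[close, , drop = FALSE] -
        matrix(xyz[h_i, ], length(close), 3, byrow = TRUE)
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      bonded <- close[ang >= angle_min]
      for (a in bonded) {
        key <- paste(d_i, h_i, a)
        hits[[key]] <- c(hits[[key]], f)
        type <- if (!is_water[d_i] && !is_water[a]) "intra"
        else if (is_water[d_i] && is_water[a]) "water_water"
        else "solute_water"
        if (type %in% colnames(per_frame))
          per_frame[f, type] <- per_frame[f, type] + 1L
      }
    }
  }
  if (length(hits) == 0L) {
    pairs <- data.frame(donor = integer(0), hydrogen = integer(0),
                        acceptor = integer(0), type = character(0),
                        occupancy = numeric(0))
  } else {
    ids <- do.call(rbind, lapply(strsplit(names(hits), " "), as.integer))
    type <- apply(ids, 1, function(r) {
      if (!is_water[r[1]] && !is_water[r[3]]) "intra"
      else if (is_water[r[1]] && is_water[r[3]]) "water_water"
      else "solute_water"
    })
    pairs <- data.frame(donor = ids[, 1], hydrogen = ids[, 2],
                        acceptor = ids[, 3], type = type,
                        occupancy = vapply(hits, length, 0L) / nf)
    rownames(pairs) <- NULL
    pairs <- pairs[order(-pairs$occupancy, pairs$donor, pairs$acceptor), ]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       per_frame = data.frame(frame = seq_len(nf), per_frame))
}

#' Per-atom root mean square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2), after superposing every
#' frame onto the average structure (Kabsch fit on the solute selection) when
#' `align` is TRUE. The average structure is refined by a second alignment
#' pass.
#'
#' @param traj a [trajectory()] with at least 2 frames (a single frame yields
#'   zeros with a warning).
#' @param align remove global rotation/translation first (default TRUE).
#' @return Numeric vector of per-atom RMSF values, Angstrom.
#' @export
rmsf <- function(traj, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) {
    warning("single-frame trajectory: RMSF is zero")
    return(numeric(n_atoms(traj)))
  }
  frames <- traj$frames
  sel <- solute_indices(traj)
  if (length(sel) == 0L) sel <- seq_len(n_atoms(traj))
  if (align) {
    ref <- frames[[1]][sel, , drop = FALSE]
    for (pass in 1:2) {
      refc <- colMeans(ref)
      frames <- lapply(frames, function(xyz) {
        P <- xyz[sel, , drop = FALSE]
        pc <- colMeans(P)
        R <- if (length(sel) >= 3L)
          .kabsch_rotation(sweep(P, 2, pc), sweep(ref, 2, refc)) else diag(3)
        sweep(sweep(xyz, 2, pc) %*% R, 2, refc, `+`)
      })
      ref <- Reduce(`+`, lapply(frames, function(x) x[sel, , drop = FALSE])) / nf
    }
  }
  mean_xyz <- Reduce(`+`, frames) / nf
  msd <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mean_xyz)^2))) / nf
  sqrt(msd)
}
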