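# Conformational clustering: hierarchical agglomerative merging on a pairwise
# fitted-RMSD matrix, cluster populations and medoid representatives.

#' Pairwise Kabsch RMSD matrix over trajectory frames
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices to fit and measure on (default: solute).
#' @param stride keep every `stride`-th frame (default 1). The matrix is the
#'   dominant memory cost; pick a stride so at most ~2000 frames enter it.
#' @return A list with `matrix` (symmetric, zero-diagonal, Angstrom) and
#'   `frames` (the original frame indices used).
#' @export
rmsd_matrix <- function(traj, selection = NULL, stride = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(selection)) selection <- solute_indices(traj)
  if (length(selection) == 0L) stop("empty selection")
  keep <- seq(1L, n_frames(traj), by = stride)
  if (length(keep) < 2L) stop("need at least 2 frames")
  coords <- lapply(traj$frames[keep], function(x) {
    x <- x[selection, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  n <- length(coords)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
    }
  }
  list(matrix = M, frames = keep)
}

#' Hierarchical agglomerative clustering of frames
#'
#' Bottom-up merging under the chosen linkage until `n_clusters` remain (fewer
#' when the input has fewer frames). Clusters are relabelled by population,
#' descending; each cluster's representative is its medoid, the member frame
#' minimising the summed intra-cluster RMSD, ties broken by lowest frame
#' index.
#'
#' @param matrix square symmetric non-negative distance matrix (e.g. from
#'   [rmsd_matrix()]), or the list that function returns.
#' @param n_clusters requested number of clusters (default 10, mirroring the
#'   ten most populated conformational clusters convention).
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`.
#' @return A list with `labels` (per-frame cluster id, 1 = most populated),
#'   `populations` (fractions, descending, summing to 1), `representatives`
#'   (medoid frame index per cluster) and `n_clusters`.
#' @export
agglomerate <- function(matrix, n_clusters = 10L,
                        linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.list(matrix) && !is.matrix(matrix)) matrix <- matrix$matrix
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  n <- nrow(matrix)
  if (is.null(n) || n != ncol(matrix)) stop("need a square matrix")
  if (max(abs(matrix - t(matrix))) > 1e-9 * max(1, max(abs(matrix))))
    stop("matrix is not symmetric")
  if (any(matrix < 0)) stop("matrix has negative entries")
  # duplicate frames (zero RMSD) must not be split to honour the requested
  # count: cap at the number of distinct frames (zero-distance components)
  tol <- 1e-8 * max(1, max(matrix))
  n_distinct <- if (n == 1L) 1L else
    max(stats::cutree(stats::hclust(stats::as.dist(matrix), method = "single"),
                      h = tol))
  k <- min(n_clusters, n_distinct)
  labels <- if (n == 1L || k == 1L) rep(1L, n) else
    stats::cutree(stats::hclust(stats::as.dist(matrix), method = linkage), k = k)
  # relabel by population descending; ties by lowest member frame index
  sizes <- tabulate(labels)
  first <- vapply(seq_along(sizes), function(cl) min(which(labels == cl)), 0L)
  ord <- order(-sizes, first)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(sizes)
  labels <- relab[labels]
  k_eff <- max(labels)
  populations <- tabulate(labels, k_eff) / n
  representatives <- vapply(seq_len(k_eff), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1L) return(members)
    tot <- rowSums(matrix[members, members, drop = FALSE])
    members[which.min(tot)]   # which.min takes the first (lowest index) tie
  }, 0L)
  list(labels = labels, populations = populations,
       representatives = representatives, n_clusters = k_eff)
}

#' Cluster a trajectory and write representative conformers
#'
#' Convenience wrapper: builds the RMSD matrix (with striding), clusters it,
#' and optionally writes the representative frames as a multi-model PDB plus
#' a populations text table.
#'
#' @param traj a [trajectory()].
#' @param n_clusters,linkage,selection,stride passed through.
#' @param pdb_path,dat_path optional output paths for the representatives PDB
#'   and the populations table.
#' @return The [agglomerate()] result, with `frames` (original frame indices
#'   of the matrix rows) and `representative_frames` (original frame indices
#'   of the medoids) added.
#' @export
cluster_trajectory <- function(traj, n_clusters = 10L, linkage = "average",
                               selection = NULL, stride = 1L,
                               pdb_path = NULL, dat_path = NULL) {
  rm <- rmsd_matrix(traj, selection = selection, stride = stride)
  res <- agglomerate(rm$matrix, n_clusters = n_clusters, linkage = linkage)
  res$frames <- rm$frames
  res$representative_frames <- rm$frames[res$representatives]
  if (!is.null(pdb_path)) {
    reps <- trajectory(traj$topology, traj$frames[res$representative_frames])
    write_pdb_trajectory(reps, pdb_path)
  }
  if (!is.null(dat_path)) {
    writeLines(c(
      "# cluster population representative_frame",
      sprintf("%d %.6f %d", seq_along(res$populations), res$populations,
              res$representative_frames)
    ), dat_path)
  }
  res
}
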