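# Per-compound descriptor pipeline. A compound directory holds whatever
# subset of {optimized.xyz, mm_optimized.xyz, orbital_energies.txt,
# scf_energies.txt, trajectory.pdb(.gz), hessian.txt} exists; every
# descriptor whose inputs are present is computed, everything else is a
# flagged-missing column. A dataset root follows CYC|ACYC / family /
# compound.

# chelator families and their cyclic/acyclic classification
CHELATOR_FAMILIES <- data.frame(
  family = c("DOTA", "NOTA", "TETA", "SAR", "CBTETA", "MACROPA",
             "DTPA", "DEDPA", "DFO", "EDTA", "ATSM", "HBED", "NEUNPAA",
             "DPAA"),
  cyclic = c(rep(TRUE, 6), rep(FALSE, 8)),
  stringsAsFactors = FALSE
)

#' Default pipeline configuration
#'
#' All cutoffs of the MD descriptor stages in one place, with the package
#' defaults: solvation shells at 3.4/5.0 Angstrom, H-bonds at 3.0 Angstrom
#' and 135 degrees, MPA grid at 0.05 Angstrom, 10 clusters, no striding.
#'
#' @param r1,r2 solvation-shell cutoffs, Angstrom.
#' @param hbond_dmax,hbond_angle_min H-bond criteria (Angstrom, degrees).
#' @param mpa_grid MPA grid resolution, Angstrom.
#' @param n_clusters cluster count for the conformational analysis.
#' @param stride frame stride for the RMSD matrix.
#' @param gap_threshold stability threshold on the frontier gap, eV.
#' @param mae_cutoff coordination-bond detection cutoff, Angstrom.
#' @param seed seed for any stochastic stage.
#' @return A named list of class `radchel_config`.
#' @export
default_config <- function(r1 = 3.4, r2 = 5.0, hbond_dmax = 3.0,
                           hbond_angle_min = 135, mpa_grid = 0.05,
                           n_clusters = 10L, stride = 1L,
                           gap_threshold = 4.0, mae_cutoff = 3.0,
                           seed = 1L) {
  stopifnot(r1 > 0, r2 > r1, hbond_dmax > 0, mpa_grid > 0, n_clusters >= 1)
  structure(list(r1 = r1, r2 = r2, hbond_dmax = hbond_dmax,
                 hbond_angle_min = hbond_angle_min, mpa_grid = mpa_grid,
                 n_clusters = as.integer(n_clusters),
                 stride = as.integer(stride),
                 gap_threshold = gap_threshold, mae_cutoff = mae_cutoff,
                 seed = as.integer(seed)),
            class = "radchel_config")
}

.find_input <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

.empty_record <- function() {
  data.frame(
    compound_id = NA_character_, class = NA_character_, family = NA_character_,
    cyclic = NA, metal = NA_character_,
    frontier_gap_eV = NA_real_, gap_kind = NA_character_, stable_gt4eV = NA,
    IEv_eV = NA_real_, EAv_eV = NA_real_, fundamental_gap_eV = NA_real_,
    eta_eV = NA_real_, softness_invEV = NA_real_, qm_mm_bond_mae_A = NA_real_,
    rg_A_mean = NA_real_, rg_A_sd = NA_real_,
    asphericity_A2_mean = NA_real_, asphericity_A2_sd = NA_real_,
    acylindricity_A2_mean = NA_real_, acylindricity_A2_sd = NA_real_,
    kappa2_mean = NA_real_, kappa2_sd = NA_real_,
    mpa_A2_mean = NA_real_, mpa_A2_sd = NA_real_,
    waters_shell1 = NA_real_, waters_shell2 = NA_real_,
    hbond_solute_water_mean = NA_real_, hbond_intra_mean = NA_real_,
    rmsf_mean_A = NA_real_, n_conf_clusters = NA_integer_,
    top_cluster_population = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Extract every available descriptor for one compound directory
#'
#' Runs each descriptor stage whose input files exist; missing inputs leave
#' their columns as `NA`, never a failure. Stage activity is reported through
#' messages (suppress with `quiet = TRUE`).
#'
#' @param compound_dir directory holding the compound's files.
#' @param config a [default_config()] list.
#' @param quiet suppress stage log messages.
#' @return A one-row data frame (the compound's descriptor record).
#' @export
run_compound <- function(compound_dir, config = default_config(),
                         quiet = FALSE) {
  if (!dir.exists(compound_dir)) stop("no such directory: ", compound_dir)
  say <- function(...) if (!quiet) message(sprintf(...))
  xyz_p <- .find_input(compound_dir, "optimized.xyz")
  orb_p <- .find_input(compound_dir, "orbital_energies.txt")
  scf_p <- .find_input(compound_dir, "scf_energies.txt")
  trj_p <- .find_input(compound_dir, c("trajectory.pdb.gz", "trajectory.pdb"))
  mm_p <- .find_input(compound_dir, "mm_optimized.xyz")
  if (is.null(xyz_p) && is.null(orb_p) && is.null(trj_p))
    stop("directory has none of the recognised inputs: ", compound_dir)
  rec <- .empty_record()
  rec$compound_id <- basename(compound_dir)

  if (!is.null(orb_p)) {
    say("[%s] frontier gap from %s", rec$compound_id, basename(orb_p))
    fg <- frontier_gap(read_orbital_energies(orb_p, unit = "eV"))
    rec$frontier_gap_eV <- fg$gap
    rec$gap_kind <- fg$kind
    rec$stable_gt4eV <- classify_stability(fg$gap, config$gap_threshold)
  }
  if (!is.null(scf_p)) {
    say("[%s] delta-SCF descriptors from %s", rec$compound_id, basename(scf_p))
    ds <- delta_scf(read_scf_energies(scf_p, unit = "eV"))
    rec$IEv_eV <- ds$IEv
    rec$EAv_eV <- ds$EAv
    rec$fundamental_gap_eV <- ds$fundamental_gap
    rec$eta_eV <- ds$hardness
    rec$softness_invEV <- ds$softness
  }
  if (!is.null(xyz_p)) {
    qm <- read_xyz(xyz_p)
    metal_idx <- which(!(qm$element %in%
                           c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")))
    if (length(metal_idx) >= 1L) {
      rec$metal <- qm$element[metal_idx[1]]
      if (!is.null(mm_p)) {
        say("[%s] QM/MM bond-length MAE (cutoff %.1f A)", rec$compound_id,
            config$mae_cutoff)
        mm <- read_xyz(mm_p)
        mae <- try(bond_length_mae(qm, mm, metal_idx[1],
                                   cutoff = config$mae_cutoff), silent = TRUE)
        if (!inherits(mae, "try-error")) rec$qm_mm_bond_mae_A <- mae$mae
      }
    }
  }
  if (!is.null(trj_p)) {
    say("[%s] trajectory descriptors from %s (r1=%.1f r2=%.1f, hbond %.1f A/%g deg, grid %.2f A)",
        rec$compound_id, basename(trj_p), config$r1, config$r2,
        config$hbond_dmax, config$hbond_angle_min, config$mpa_grid)
    traj <- read_pdb_trajectory(trj_p,
                                metal_elements = if (is.na(rec$metal))
                                  character(0) else rec$metal)
    morph <- trajectory_morphology(traj, grid_resolution = config$mpa_grid)
    sm <- morph$summary
    pick <- function(metric, col) sm[[col]][sm$metric == metric]
    rec$rg_A_mean <- pick("rg", "mean"); rec$rg_A_sd <- pick("rg", "sd")
    rec$asphericity_A2_mean <- pick("asphericity", "mean")
    rec$asphericity_A2_sd <- pick("asphericity", "sd")
    rec$acylindricity_A2_mean <- pick("acylindricity", "mean")
    rec$acylindricity_A2_sd <- pick("acylindricity", "sd")
    rec$kappa2_mean <- pick("kappa2", "mean")
    rec$kappa2_sd <- pick("kappa2", "sd")
    rec$mpa_A2_mean <- pick("mpa", "mean"); rec$mpa_A2_sd <- pick("mpa", "sd")
    shells <- water_shell_counts(traj, r1 = config$r1, r2 = config$r2)
    rec$waters_shell1 <- shells$first_shell
    rec$waters_shell2 <- shells$second_shell
    hb <- suppressWarnings(
      hbond_statistics(traj, d_max = config$hbond_dmax,
                       angle_min = config$hbond_angle_min))
    if (nrow(hb$per_frame) > 0L) {
      rec$hbond_solute_water_mean <- mean(hb$per_frame$solute_water)
      rec$hbond_intra_mean <- mean(hb$per_frame$intra)
    }
    rec$rmsf_mean_A <- mean(rmsf(traj)[solute_indices(traj)])
    if (n_frames(traj) >= 2L) {
      cl <- cluster_trajectory(traj, n_clusters = config$n_clusters,
                               stride = config$stride)
      rec$n_conf_clusters <- cl$n_clusters
      rec$top_cluster_population <- cl$populations[1]
    }
  }
  rec
}

#' Run the descriptor pipeline over a CYC/ACYC dataset tree
#'
#' Walks `root/CYC|ACYC/family/compound`, extracts one record per compound
#' (in sorted, traversal-independent order), writes a merged descriptor CSV
#' when `csv_path` is given, and summarises each family (descriptor means and
#' SDs) plus the percentage of compounds per class with a frontier gap above
#' the stability threshold.
#'
#' @param root dataset root directory.
#' @param config a [default_config()] list.
#' @param csv_path optional output path for the merged CSV.
#' @param quiet suppress stage log messages.
#' @return A list with `records` (data frame), `family_summary` and
#'   `class_summary` (percent of compounds above the gap threshold, per
#'   CYC/ACYC class).
#' @export
run_dataset <- function(root, config = default_config(), csv_path = NULL,
                        quiet = FALSE) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- intersect(c("ACYC", "CYC"), list.dirs(root, recursive = FALSE,
                                                   full.names = FALSE))
  rows <- list()
  for (cls in sort(classes)) {
    fams <- sort(list.dirs(file.path(root, cls), recursive = FALSE,
                           full.names = FALSE))
    for (fam in fams) {
      known <- fam %in% CHELATOR_FAMILIES$family
      if (!known)
        warning("unknown chelator family '", fam, "'; passed through")
      for (cmp in sort(list.dirs(file.path(root, cls, fam),
                                 recursive = FALSE, full.names = FALSE))) {
        rec <- run_compound(file.path(root, cls, fam, cmp), config,
                            quiet = quiet)
        rec$class <- cls
        rec$family <- fam
        rec$cyclic <- if (known)
          CHELATOR_FAMILIES$cyclic[CHELATOR_FAMILIES$family == fam] else
            identical(cls, "CYC")
        rows[[paste(cls, fam, cmp, sep = "/")]] <- rec
      }
    }
  }
  if (length(rows) == 0L) stop("empty dataset tree: ", root)
  records <- do.call(rbind, rows[sort(names(rows))])
  rownames(records) <- NULL
  if (any(duplicated(records$compound_id)))
    records$compound_id <- sort(names(rows))   # qualify with class/family
  if (!is.null(csv_path)) write_descriptor_table(records, csv_path)
  num_cols <- names(records)[vapply(records, is.numeric, TRUE)]
  family_summary <- do.call(rbind, lapply(split(records, records$family),
    function(d) {
      out <- data.frame(family = d$family[1], class = d$class[1],
                        n = nrow(d))
      for (cn in num_cols) {
        out[[paste0(cn, "_mean")]] <- mean(d[[cn]], na.rm = TRUE)
        out[[paste0(cn, "_sd")]] <- stats::sd(d[[cn]], na.rm = TRUE)
      }
      out
    }))
  rownames(family_summary) <- NULL
  class_summary <- do.call(rbind, lapply(split(records, records$class),
    function(d) data.frame(
      class = d$class[1], n = nrow(d),
      pct_gap_above_threshold =
        100 * mean(d$frontier_gap_eV > config$gap_threshold, na.rm = TRUE))))
  rownames(class_summary) <- NULL
  list(records = records, family_summary = family_summary,
       class_summary = class_summary)
}
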