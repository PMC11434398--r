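#' Construct a molecular structure
#'
#' The central container of the package: an ordered set of atoms with
#' coordinates in Angstrom, tabulated masses and van der Waals radii, an
#' optional per-atom role tag and an optional bond list. Every reader returns
#' one and every geometric operation consumes one.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix, n x 3, coordinates in Angstrom.
#' @param role per-atom role, one of `"metal"`, `"solute"`, `"water_oxygen"`,
#'   `"water_hydrogen"`, `"ion"`, `"other"`; recycled if length 1.
#' @param total_charge integer total charge (e).
#' @param spin_multiplicity positive integer spin multiplicity.
#' @param bonds optional integer matrix (m x 2) of 1-based atom index pairs.
#' @param partial_charges optional numeric vector of per-atom partial charges.
#' @return An object of class `mol_structure`.
#' @examples
#' water <- mol_structure(
#'   c("O", "H", "H"),
#'   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
#' )
#' n_atoms(water)
#' @export
mol_structure <- function(element, xyz, role = "solute", total_charge = 0L,
                          spin_multiplicity = 1L, bonds = NULL,
                          partial_charges = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(element)
  if (n < 1L) stop("a structure needs at least one atom")
  if (nrow(xyz) != n || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix matching length(element)")
  roles <- c("metal", "solute", "water_oxygen", "water_hydrogen", "ion", "other")
  role <- rep_len(as.character(role), n)
  if (!all(role %in% roles))
    stop("invalid role(s): ", paste(setdiff(role, roles), collapse = ", "))
  if (spin_multiplicity < 1L) stop("spin_multiplicity must be >= 1")
  props <- element_properties(element)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (nrow(bonds) > 0L) {
      if (any(bonds < 1L | bonds > n)) stop("bond index out of range")
      if (any(bonds[, 1L] == bonds[, 2L])) stop("bond connects an atom to itself")
    }
  } else {
    bonds <- matrix(integer(0), ncol = 2L)
  }
  if (!is.null(partial_charges) && length(partial_charges) != n)
    stop("partial_charges must have one value per atom")
  structure(
    list(
      element = as.character(element),
      xyz = unname(xyz),
      mass = props$mass,
      vdw = props$vdw,
      role = role,
      total_charge = as.integer(total_charge),
      spin_multiplicity = as.integer(spin_multiplicity),
      bonds = bonds,
      partial_charges = partial_charges
    ),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf(
    "<mol_structure> %d atoms (%s), charge %+d, multiplicity %d, %d bonds\n",
    n_atoms(x), paste(unique(x$element), collapse = " "),
    x$total_charge, x$spin_multiplicity, nrow(x$bonds)
  ))
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `mol_structure` or `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  length(x$element)
}

#' Construct a trajectory
#'
#' An ordered list of coordinate frames over a fixed topology. Frames are
#' n_atoms x 3 matrices in Angstrom.
#'
#' @param topology a `mol_structure` describing the atoms.
#' @param frames list of n x 3 coordinate matrices.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "mol_structure"))
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  n <- n_atoms(topology)
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    storage.mode(f) <- "double"
    if (nrow(f) != n || ncol(f) != 3L)
      stop(sprintf("frame %d has wrong dimensions (%d x %d, expected %d x 3)",
                   i, nrow(f), ncol(f), n))
    unname(f)
  })
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms (%d solute, %d water O)\n",
              n_frames(x), n_atoms(x),
              length(solute_indices(x)),
              sum(x$topology$role == "water_oxygen")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Indices of solute atoms (metal + chelator) in a trajectory or structure
#' @param x a `trajectory` or `mol_structure`.
#' @return integer vector of 1-based atom indices with role metal or solute.
#' @export
solute_indices <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  which(x$role %in% c("metal", "solute"))
}

#' Construct an orbital spectrum
#'
#' Per-spin-channel orbital energies (eV) with occupations. Restricted
#' (closed-shell) spectra carry one channel with occupations 0/2; unrestricted
#' (open-shell) spectra carry alpha and beta channels with occupations 0/1.
#'
#' @param channels named list of data frames with columns `energy` (eV) and
#'   `occupation`; names either `"restricted"` or `"alpha"`/`"beta"`.
#' @return An object of class `orbital_spectrum` with an `open_shell` flag.
#' @export
orbital_spectrum <- function(channels) {
  nm <- names(channels)
  open_shell <- !identical(nm, "restricted")
  if (open_shell && !all(nm %in% c("alpha", "beta")))
    stop("channels must be 'restricted' or any of 'alpha'/'beta'")
  channels <- lapply(channels, function(ch) {
    ch <- as.data.frame(ch)
    stopifnot(all(c("energy", "occupation") %in% names(ch)))
    if (is.unsorted(ch$energy)) {
      warning("orbital energies not sorted within a channel; resorting")
      ch <- ch[order(ch$energy), , drop = FALSE]
    }
    rownames(ch) <- NULL
    ch
  })
  occs <- unlist(lapply(channels, `[[`, "occupation"))
  valid <- if (open_shell) c(0, 1) else c(0, 2)
  if (!all(occs %in% valid))
    stop("invalid occupations for ", if (open_shell) "an open-shell" else "a closed-shell",
         " spectrum: ", paste(unique(setdiff(occs, valid)), collapse = ", "))
  if (!any(occs > 0)) stop("spectrum has no occupied orbital")
  if (!any(occs == 0)) stop("spectrum has no virtual orbital")
  structure(list(channels = channels, open_shell = open_shell),
            class = "orbital_spectrum")
}

#' Construct a delta-SCF total-energy set
#'
#' Total energies (eV) of the N, N+1 and N-1 electron systems at a fixed
#' geometry, the inputs of the vertical delta-SCF descriptors.
#'
#' @param E_N,E_Nplus1,E_Nminus1 total energies in eV.
#' @return An object of class `scf_energy_set`.
#' @export
scf_energy_set <- function(E_N, E_Nplus1, E_Nminus1) {
  vals <- c(E_N, E_Nplus1, E_Nminus1)
  if (!all(is.finite(vals))) stop("all total energies must be finite")
  structure(list(E_N = E_N, E_Nplus1 = E_Nplus1, E_Nminus1 = E_Nminus1),
            class = "scf_energy_set")
}

#' Construct a Cartesian Hessian
#'
#' A symmetric 3N x 3N matrix of second derivatives in kcal mol^-1 A^-2
#' together with the geometry (Angstrom) it was evaluated at.
#'
#' @param matrix symmetric numeric 3N x 3N matrix, kcal mol^-1 A^-2.
#' @param coords numeric N x 3 matrix, Angstrom.
#' @return An object of class `cartesian_hessian`.
#' @export
cartesian_hessian <- function(matrix, coords) {
  matrix <- as.matrix(matrix)
  coords <- as.matrix(coords)
  if (nrow(matrix) != ncol(matrix)) stop("Hessian must be square")
  if (nrow(matrix) != 3L * nrow(coords))
    stop("Hessian dimension must equal 3 x n_atoms")
  asym <- max(abs(matrix - t(matrix)))
  scale <- max(abs(matrix), 1e-300)
  if (asym > 1e-6 * scale)
    stop(sprintf("Hessian asymmetry %.3g exceeds 1e-6 of its norm", asym / scale))
  structure(list(matrix = unname(matrix), coords = unname(coords)),
            class = "cartesian_hessian")
}
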