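# Readers/writers for the plain-text formats the pipeline touches. All readers
# are strict: anything that does not parse raises an error naming the line,
# never a silently truncated object. Trailing whitespace and blank lines are
# tolerated everywhere.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")  # reads plain text and gzip transparently
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read an XYZ structure file
#'
#' Standard XYZ layout: atom count, comment line, then one `element x y z`
#' line per atom, coordinates in Angstrom. Masses and van der Waals radii are
#' filled from the embedded element table.
#'
#' @param path path to the file.
#' @param role per-atom role passed to [mol_structure()]; default `"solute"`.
#' @return A [mol_structure()].
#' @export
read_xyz <- function(path, role = "solute") {
  lines <- .read_lines(path)
  lines <- lines[!(seq_along(lines) > 2 & !nzchar(trimws(lines)))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed XYZ header at line 1: expected a positive atom count")
  if (length(lines) < n + 2)
    stop(sprintf("XYZ declares %d atoms but only %d atom lines present",
                 n, max(0L, length(lines) - 2L)))
  elements <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(fields) < 4)
      stop(sprintf("XYZ coordinate parse failure at line %d", i + 2L))
    coords <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(coords))
      stop(sprintf("XYZ coordinate parse failure at line %d", i + 2L))
    elements[i] <- normalize_element(fields[1])
    xyz[i, ] <- coords
  }
  mol_structure(elements, xyz, role = role)
}

#' Write an XYZ structure file
#'
#' @param structure a [mol_structure()].
#' @param path output path.
#' @param comment comment placed on line 2.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  lines <- c(
    as.character(n_atoms(structure)),
    comment,
    sprintf("%-3s %14.8f %14.8f %14.8f", structure$element,
            structure$xyz[, 1], structure$xyz[, 2], structure$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

# Default residue-name sets for role tagging.
WATER_RESIDUE_NAMES <- c("WAT", "HOH", "TIP3", "OPC", "SPC")
ION_RESIDUE_NAMES <- c("K+", "CL-", "NA+", "K", "CL", "NA", "ION")

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per `MODEL` record (a file without `MODEL` records yields a
#' single frame). Atoms whose residue name is in `water_residue_names` are
#' tagged `water_oxygen`/`water_hydrogen` by element; residues in `ion_names`
#' are tagged `ion`; everything else is `solute`, except atoms of
#' `metal_elements`, which are tagged `metal`. Plain and gzip-compressed files
#' are both accepted. `CONECT` records are ignored; coordinates are taken
#' verbatim in Angstrom.
#'
#' @param path path to a PDB file, optionally `.gz`.
#' @param water_residue_names residue names identifying water.
#' @param ion_names residue names identifying monatomic ions.
#' @param metal_elements element symbols tagged as the metal centre.
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path,
                                water_residue_names = WATER_RESIDUE_NAMES,
                                ion_names = ION_RESIDUE_NAMES,
                                metal_elements = character(0)) {
  lines <- .read_lines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  frame_id <- cumsum(model_starts)
  if (!any(model_starts)) frame_id[] <- 1L
  atom_lines <- lines[is_atom]
  atom_frames <- frame_id[is_atom]
  if (length(atom_lines) == 0L) stop("PDB file contains no ATOM/HETATM records")
  if (any(atom_frames == 0L))
    stop("ATOM records found before the first MODEL record")
  frames_idx <- split(seq_along(atom_lines), atom_frames)
  counts <- lengths(frames_idx)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts across MODEL records: ",
         paste(unique(counts), collapse = ", "))

  parse_block <- function(ls) {
    name <- trimws(substr(ls, 13, 16))
    resn <- trimws(substr(ls, 18, 20))
    x <- as.numeric(substr(ls, 31, 38))
    y <- as.numeric(substr(ls, 39, 46))
    z <- as.numeric(substr(ls, 47, 54))
    elem <- trimws(substr(ls, 77, 78))
    elem[!nzchar(elem)] <- name[!nzchar(elem)]
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("PDB coordinate parse failure")
    list(element = normalize_element(elem), resn = resn, xyz = cbind(x, y, z))
  }
  first <- parse_block(atom_lines[frames_idx[[1]]])
  role <- rep("solute", length(first$element))
  is_wat <- first$resn %in% water_residue_names
  role[is_wat & first$element == "O"] <- "water_oxygen"
  role[is_wat & first$element == "H"] <- "water_hydrogen"
  role[!is_wat & first$resn %in% ion_names] <- "ion"
  role[role == "solute" & first$element %in% metal_elements] <- "metal"
  topo <- mol_structure(first$element, first$xyz, role = role)
  frames <- lapply(frames_idx, function(ii) parse_block(atom_lines[ii])$xyz)
  trajectory(topo, unname(frames))
}

#' Write a structure set as a multi-model PDB file
#'
#' Writes one `MODEL`/`ENDMDL` block per frame. Residue names are derived
#' from atom roles (`MOL` for solute/metal, `WAT` for water, `ION` for ions)
#' so the file round-trips through [read_pdb_trajectory()].
#'
#' @param traj a [trajectory()], or a [mol_structure()] for a single model.
#' @param path output path (use a `.gz` suffix for gzip compression).
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  if (inherits(traj, "mol_structure")) traj <- trajectory(traj, list(traj$xyz))
  topo <- traj$topology
  resn <- ifelse(topo$role %in% c("water_oxygen", "water_hydrogen"), "WAT",
                 ifelse(topo$role == "ion", "ION", "MOL"))
  # water molecules get consecutive residue ids (each O starts a new residue)
  resid <- integer(n_atoms(traj))
  cur <- 1L
  for (i in seq_len(n_atoms(traj))) {
    if (i > 1L && (topo$role[i] == "water_oxygen" ||
                   (resn[i] != resn[i - 1L]))) cur <- cur + 1L
    resid[i] <- cur
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n_atoms(traj)) %% 100000L,
      substr(paste0(topo$element, seq_len(n_atoms(traj)) %% 100L), 1, 4),
      resn, resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], topo$element
    ), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a TRIPOS mol2 structure
#'
#' Parses the `@<TRIPOS>ATOM` and `@<TRIPOS>BOND` sections. Partial charges
#' (column 9 of the ATOM section) are stored in `$partial_charges`. A missing
#' BOND section yields empty bonds with a warning.
#'
#' @param path path to the mol2 file.
#' @return A [mol_structure()] with bonds and partial charges populated.
#' @export
read_mol2 <- function(path) {
  lines <- .read_lines(path)
  sect <- which(grepl("^@<TRIPOS>", lines))
  if (length(sect) == 0L || !any(grepl("^@<TRIPOS>ATOM", lines)))
    stop("mol2 file has no @<TRIPOS>ATOM section")
  section_lines <- function(name) {
    start <- which(grepl(paste0("^@<TRIPOS>", name, "\\s*$"), lines))
    if (length(start) == 0L) return(NULL)
    start <- start[1]
    nxt <- sect[sect > start]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    ls <- lines[(start + 1L):end]
    ls[nzchar(trimws(ls))]
  }
  atom_ls <- section_lines("ATOM")
  fields <- strsplit(trimws(atom_ls), "\\s+")
  elements <- vapply(fields, function(f) normalize_element(f[6]), "")
  xyz <- t(vapply(fields, function(f) as.numeric(f[3:5]), numeric(3)))
  charges <- vapply(fields, function(f)
    if (length(f) >= 9) as.numeric(f[9]) else NA_real_, 0.0)
  bond_ls <- section_lines("BOND")
  if (is.null(bond_ls)) {
    warning("mol2 file has no @<TRIPOS>BOND section; bonds left empty")
    bonds <- NULL
  } else {
    bf <- strsplit(trimws(bond_ls), "\\s+")
    bonds <- t(vapply(bf, function(f) as.integer(f[2:3]), integer(2)))
  }
  mol_structure(elements, xyz, bonds = bonds,
                partial_charges = if (all(is.na(charges))) NULL else charges)
}

#' Read a plain-text orbital-energy list
#'
#' The package's own layout (the deposited datasets of this field vary; adapt
#' external files to it or extend this reader): one orbital per line as
#' `occupation energy`, sorted or not. A closed-shell file has no section
#' headers and occupations 0/2. An open-shell file marks its two spin channels
#' with bare `alpha` and `beta` header lines and uses occupations 0/1. Lines
#' starting with `#` are comments.
#'
#' @param path path to the file.
#' @param unit energy unit in the file, `"hartree"` or `"eV"`; energies are
#'   stored in eV (1 Hartree = 27.211386 eV).
#' @return An [orbital_spectrum()].
#' @export
read_orbital_energies <- function(path, unit = c("hartree", "eV")) {
  unit <- match.arg(unit)
  lines <- trimws(.read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  headers <- tolower(lines) %in% c("alpha", "beta")
  channel <- cumsum(headers)
  ch_names <- tolower(lines[headers])
  if (length(ch_names) == 0L) {
    ch_names <- "restricted"
    channel[] <- 1L
  } else if (any(channel == 0L)) {
    stop("orbital lines found before the first channel header")
  }
  channels <- lapply(seq_along(ch_names), function(k) {
    ls <- lines[channel == k & !headers]
    if (length(ls) == 0L) stop("empty spin channel: ", ch_names[k])
    fields <- strsplit(ls, "\\s+")
    occ <- vapply(fields, function(f) as.numeric(f[1]), 0.0)
    en <- vapply(fields, function(f) as.numeric(f[2]), 0.0)
    if (anyNA(occ) || anyNA(en)) stop("orbital line parse failure")
    if (unit == "hartree") en <- en * HARTREE_TO_EV
    data.frame(energy = en, occupation = occ)
  })
  names(channels) <- ch_names
  orbital_spectrum(channels)
}

#' Write a plain-text orbital-energy list
#'
#' Inverse of [read_orbital_energies()], in eV.
#'
#' @param spectrum an [orbital_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orbital_energies <- function(spectrum, path) {
  out <- c("# orbital energies, eV: occupation energy")
  for (nm in names(spectrum$channels)) {
    if (nm != "restricted") out <- c(out, nm)
    ch <- spectrum$channels[[nm]]
    out <- c(out, sprintf("%d %.8f", ch$occupation, ch$energy))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a packed lower-triangular Cartesian Hessian
#'
#' The file holds the 3N(3N+1)/2 lower-triangular elements of the Cartesian
#' Hessian in Hartree/Bohr^2 (the layout of a formatted-checkpoint dump),
#' whitespace-separated in row-major order, with optional `#` comments. An
#' optional leading `geometry` section (`element x y z` per line, Angstrom,
#' terminated by a bare `hessian` line) supplies the coordinates the Hessian
#' was evaluated at. On return the full symmetric matrix is reconstructed and
#' converted to kcal mol^-1 A^-2.
#'
#' @param path path to the file.
#' @param coords optional N x 3 coordinate matrix (Angstrom), used when the
#'   file has no embedded geometry.
#' @return A [cartesian_hessian()].
#' @export
read_hessian <- function(path, coords = NULL) {
  lines <- trimws(.read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  geom <- NULL
  if (length(lines) && tolower(lines[1]) == "geometry") {
    hs <- which(tolower(lines) == "hessian")
    if (length(hs) == 0L) stop("geometry section without a 'hessian' line")
    gl <- lines[2:(hs[1] - 1L)]
    gf <- strsplit(gl, "\\s+")
    geom <- t(vapply(gf, function(f) as.numeric(f[2:4]), numeric(3)))
    lines <- lines[-seq_len(hs[1])]
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(lines, "\\s+"))))
  if (anyNA(vals)) stop("Hessian value parse failure")
  m <- length(vals)
  dim3n <- (sqrt(8 * m + 1) - 1) / 2
  if (abs(dim3n - round(dim3n)) > 1e-9)
    stop(sprintf("%d values is not a triangular number for any matrix size", m))
  dim3n <- as.integer(round(dim3n))
  if (dim3n %% 3L != 0L)
    stop("packed Hessian dimension ", dim3n, " is not a multiple of 3")
  H <- matrix(0, dim3n, dim3n)
  H[upper.tri(H, diag = TRUE)] <- vals   # column-major upper == row-major lower
  H <- H + t(H) - diag(diag(H))
  H <- H * HARTREE_BOHR2_TO_KCAL_A2
  if (is.null(coords)) coords <- geom
  if (is.null(coords)) coords <- matrix(0, dim3n / 3L, 3L)
  cartesian_hessian(H, coords)
}

#' Write a packed lower-triangular Cartesian Hessian
#'
#' Inverse of [read_hessian()]: converts back to Hartree/Bohr^2 and writes the
#' lower triangle row-major, preceded by the geometry.
#'
#' @param hessian a [cartesian_hessian()].
#' @param path output path.
#' @param elements optional element symbols for the geometry section.
#' @return `path`, invisibly.
#' @export
write_hessian <- function(hessian, path, elements = NULL) {
  n <- nrow(hessian$coords)
  if (is.null(elements)) elements <- rep("X", n)
  H <- hessian$matrix / HARTREE_BOHR2_TO_KCAL_A2
  packed <- H[upper.tri(H, diag = TRUE)]
  out <- c(
    "# packed lower-triangular Cartesian Hessian, Hartree/Bohr^2",
    "geometry",
    sprintf("%-3s %16.10f %16.10f %16.10f", elements,
            hessian$coords[, 1], hessian$coords[, 2], hessian$coords[, 3]),
    "hessian",
    vapply(split(packed, ceiling(seq_along(packed) / 5)),
           function(v) paste(sprintf("%.12e", v), collapse = " "), "")
  )
  writeLines(out, path)
  invisible(path)
}

#' Read delta-SCF total energies from a small key-value text file
#'
#' Expected lines: `E_N`, `E_Nplus1`, `E_Nminus1`, each followed by a value.
#'
#' @param path path to the file.
#' @param unit `"hartree"` or `"eV"`.
#' @return An [scf_energy_set()] in eV.
#' @export
read_scf_energies <- function(path, unit = c("hartree", "eV")) {
  unit <- match.arg(unit)
  lines <- trimws(.read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s+")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(f) as.numeric(f[2]), 0.0)
  need <- c("E_N", "E_Nplus1", "E_Nminus1")
  if (!all(need %in% keys)) stop("missing key(s): ",
                                 paste(setdiff(need, keys), collapse = ", "))
  v <- vals[match(need, keys)]
  if (unit == "hartree") v <- v * HARTREE_TO_EV
  scf_energy_set(v[1], v[2], v[3])
}

#' Write a descriptor table as CSV
#'
#' One header row, one row per compound, stable column order, missing values
#' as empty fields.
#'
#' @param records a data frame, or a list of one-row data frames sharing one
#'   schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(records, path) {
  if (!is.data.frame(records)) {
    schemas <- lapply(records, names)
    if (length(unique(vapply(schemas, paste, "", collapse = "|"))) != 1L)
      stop("records do not share one schema")
    records <- do.call(rbind, records)
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a descriptor table written by [write_descriptor_table()]
#' @param path CSV path.
#' @return A data frame; empty fields become `NA`.
#' @export
read_descriptor_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
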