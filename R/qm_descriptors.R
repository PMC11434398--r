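# Electronic stability descriptors. The frontier gap (HOMO-LUMO, or SOMO-LUMO
# for open-shell species) is the cheap orbital-eigenvalue indicator; the
# delta-SCF block gives the quasi-particle-corrected fundamental gap
# Egap = IEv - EAv = E_{N+1} + E_{N-1} - 2 E_N and the conceptual-DFT
# hardness/softness eta = Egap/2, S = 1/(2 eta).

#' Frontier-orbital gap of an orbital spectrum
#'
#' Closed shell: gap = E(LUMO) - E(HOMO). Open shell: the highest occupied
#' level over both spin channels (reported as the SOMO) and, by default, the
#' lowest unoccupied level over both channels. A negative gap is reported
#' as-is and flagged, never clamped.
#'
#' @param spectrum an [orbital_spectrum()].
#' @param lumo_across_channels for open-shell spectra, take the LUMO as the
#'   global minimum unoccupied energy across channels (default) rather than
#'   restricting it to the channel holding the SOMO.
#' @return A list with `gap` (eV), `kind` (`"HOMO_LUMO"` or `"SOMO_LUMO"`),
#'   `homo`, `lumo` (eV) and `negative` (logical flag).
#' @examples
#' sp <- orbital_spectrum(list(restricted = data.frame(
#'   energy = c(-10, -8, -6, -1, 2), occupation = c(2, 2, 2, 0, 0))))
#' frontier_gap(sp)$gap  # 5 eV
#' @export
frontier_gap <- function(spectrum, lumo_across_channels = TRUE) {
  stopifnot(inherits(spectrum, "orbital_spectrum"))
  occ_e <- lapply(spectrum$channels, function(ch) ch$energy[ch$occupation > 0])
  vir_e <- lapply(spectrum$channels, function(ch) ch$energy[ch$occupation == 0])
  homo <- max(unlist(occ_e))
  if (length(unlist(vir_e)) == 0L)
    stop("all orbitals occupied: no LUMO available")
  if (spectrum$open_shell && !lumo_across_channels) {
    homo_ch <- which.max(vapply(occ_e, function(e)
      if (length(e)) max(e) else -Inf, 0.0))
    vir <- vir_e[[homo_ch]]
    if (length(vir) == 0L)
      stop("no virtual orbital in the channel holding the SOMO")
    lumo <- min(vir)
  } else {
    lumo <- min(unlist(vir_e))
  }
  gap <- lumo - homo
  list(gap = gap,
       kind = if (spectrum$open_shell) "SOMO_LUMO" else "HOMO_LUMO",
       homo = homo, lumo = lumo, negative = gap < 0)
}

#' Delta-SCF electronic descriptors
#'
#' From the total energies of the N, N+1 and N-1 electron systems at a fixed
#' geometry: vertical ionization energy IEv = E_{N-1} - E_N, vertical electron
#' affinity EAv = E_N - E_{N+1}, fundamental gap Egap = IEv - EAv, chemical
#' hardness eta = Egap/2 and softness S = 1/(2 eta). A zero gap leaves the
#' softness as a flagged missing value.
#'
#' @param energies an [scf_energy_set()] (eV).
#' @return A list with `IEv`, `EAv`, `fundamental_gap`, `hardness` (all eV)
#'   and `softness` (1/eV, `NA` when the gap is zero).
#' @examples
#' delta_scf(scf_energy_set(E_N = -2721.14, E_Nplus1 = -2723.86,
#'                          E_Nminus1 = -2710.25))
#' @export
delta_scf <- function(energies) {
  stopifnot(inherits(energies, "scf_energy_set"))
  IEv <- energies$E_Nminus1 - energies$E_N
  EAv <- energies$E_N - energies$E_Nplus1
  gap <- IEv - EAv
  eta <- gap / 2
  S <- if (eta == 0) NA_real_ else 1 / (2 * eta)
  list(IEv = IEv, EAv = EAv, fundamental_gap = gap, hardness = eta,
       softness = S)
}

#' Classify electronic stability from an energy gap
#'
#' A complex is flagged stable when its gap lies strictly above the threshold
#' (4 eV by default, the conventional dividing line for these complexes).
#'
#' @param gap energy gap in eV (vectorised).
#' @param threshold threshold in eV.
#' @return Logical: `gap > threshold`.
#' @export
classify_stability <- function(gap, threshold = 4.0) {
  stopifnot(all(is.finite(gap)))
  gap > threshold
}

#' Mean absolute error of metal-donor bond lengths between two structures
#'
#' Identifies coordination bonds as metal--X pairs with X among the donor
#' elements and reference distance at or below `cutoff`, then reports the mean
#' absolute difference of those distances between the two structures (same
#' atom ordering assumed).
#'
#' @param ref reference [mol_structure()] (defines the bond set).
#' @param test comparison [mol_structure()] with identical atom ordering.
#' @param metal_index 1-based index of the metal atom.
#' @param donor_elements elements accepted as donors (default O and N).
#' @param cutoff coordination-bond detection cutoff on the reference, Angstrom.
#' @return A list with `mae` (Angstrom), and `bonds`: a data frame of donor
#'   index, reference and test distances and their signed difference.
#' @export
bond_length_mae <- function(ref, test, metal_index,
                            donor_elements = c("O", "N"), cutoff = 3.0) {
  stopifnot(inherits(ref, "mol_structure"), inherits(test, "mol_structure"))
  if (n_atoms(ref) != n_atoms(test))
    stop("structures have different atom counts")
  if (metal_index < 1 || metal_index > n_atoms(ref))
    stop("metal_index out of range")
  if (!identical(ref$element, test$element))
    stop("structures have different atom orderings")
  m <- ref$xyz[metal_index, ]
  d_ref <- sqrt(rowSums((ref$xyz - matrix(m, n_atoms(ref), 3, byrow = TRUE))^2))
  donors <- which(ref$element %in% donor_elements &
                    seq_len(n_atoms(ref)) != metal_index &
                    d_ref <= cutoff)
  if (length(donors) == 0L)
    stop("no coordination bonds found within ", cutoff, " A")
  m2 <- test$xyz[metal_index, ]
  d_test <- sqrt(rowSums((test$xyz[donors, , drop = FALSE] -
                            matrix(m2, length(donors), 3, byrow = TRUE))^2))
  delta <- d_ref[donors] - d_test
  list(
    mae = mean(abs(delta)),
    bonds = data.frame(donor = donors, element = ref$element[donors],
                       d_ref = d_ref[donors], d_test = d_test, delta = delta)
  )
}
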