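# File formats: XYZ, multi-model PDB (plain/gzip), mol2, orbital lists,
# packed Hessians, descriptor CSV.

water_xyz_text <- c(
  "3",
  "water fixture",
  "O   0.000000   0.000000   0.117300",
  "H   0.000000   0.757200  -0.469200",
  "H   0.000000  -0.757200  -0.469200"
)

test_that("XYZ reader parses, validates the header and fills element data", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(water_xyz_text, p)
  s <- read_xyz(p)
  expect_s3_class(s, "mol_structure")
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$element, c("O", "H", "H"))
  expect_equal(s$mass[1], 15.999)
  expect_gt(s$vdw[1], 0)

  writeLines(c("5", "", water_xyz_text[3:5], ""), p)
  expect_error(read_xyz(p), "5 atoms")
  writeLines(c("x", "comment"), p)
  expect_error(read_xyz(p), "header")
  writeLines(c("1", "c", "Qq 0 0 0"), p)
  expect_error(read_xyz(p), "unknown element")
  writeLines(c("1", "c", "O 0 zero 0"), p)
  expect_error(read_xyz(p), "line 3")
})

test_that("XYZ write/read round-trips coordinates and tolerates blank lines", {
  s <- make_structure("random_cloud", 17, size = 4, seed = 7)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, p)
  # append trailing whitespace/blank lines: parsing must be insensitive
  cat("   \n\n", file = p, append = TRUE)
  s2 <- read_xyz(p)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-6)
  expect_identical(s2$element, s$element)
})

make_pdb_lines <- function(frames, resn = c("MOL", "MOL", "WAT", "WAT"),
                           elem = c("N", "C", "O", "H")) {
  out <- character(0)
  for (f in seq_along(frames)) {
    out <- c(out, sprintf("MODEL     %4d", f))
    xyz <- frames[[f]]
    for (i in seq_len(nrow(xyz))) {
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, paste0(elem[i], i), resn[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3],
        elem[i]))
    }
    out <- c(out, "ENDMDL")
  }
  out
}

test_that("multi-model PDB reader builds one frame per MODEL and tags roles", {
  f1 <- matrix(rnorm(12), 4, 3)
  f2 <- f1 + 0.5
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(f1, f2)), p)
  traj <- read_pdb_trajectory(p)
  expect_equal(n_frames(traj), 2L)
  expect_equal(traj$frames[[2]], f2, tolerance = 1e-3)
  expect_equal(traj$topology$role, c("solute", "solute", "water_oxygen",
                                     "water_hydrogen"))
  expect_equal(length(solute_indices(traj)), 2L)
})

test_that("gzip and plain encodings of one PDB parse identically", {
  frames <- list(matrix(rnorm(12), 4, 3))
  txt <- make_pdb_lines(frames)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb.gz")
  writeLines(txt, p1)
  con <- gzfile(p2, "wt"); writeLines(txt, con); close(con)
  expect_identical(read_pdb_trajectory(p1), read_pdb_trajectory(p2))
})

test_that("PDB reader rejects inconsistent models and empty files", {
  f1 <- matrix(0, 4, 3)
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(make_pdb_lines(list(f1)),
             make_pdb_lines(list(f1[1:3, ]), resn = rep("MOL", 3),
                            elem = c("N", "C", "O")))
  lines[6 + 1] <- sub("MODEL     1", "MODEL     2", lines[6 + 1])
  writeLines(lines, p)
  expect_error(read_pdb_trajectory(p), "inconsistent atom counts")
  writeLines("END", p)
  expect_error(read_pdb_trajectory(p), "no ATOM")
})

test_that("PDB writer round-trips roles and coordinates through the reader", {
  sol <- make_structure("ring", 6, size = 2, element = "N", metal = "Cu")
  fr <- make_solvated_frame(sol, shell_counts = c(3L, 2L), seed = 11)
  p <- withr::local_tempfile(fileext = ".pdb.gz")
  write_pdb_trajectory(fr, p)
  back <- read_pdb_trajectory(p, metal_elements = "Cu")
  expect_equal(back$topology$role, fr$topology$role)
  expect_equal(back$frames[[1]], fr$frames[[1]], tolerance = 1e-3)
})

test_that("mol2 reader extracts atoms, bonds and partial charges", {
  p <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "two-atom", " 2 1 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 O1  0.000 0.000 0.000 O.3  1 LIG  -0.8340",
    "  2 H1  0.960 0.000 0.000 H    1 LIG   0.8340",
    "@<TRIPOS>BOND",
    "  1 1 2 1"
  ), p)
  s <- read_mol2(p)
  expect_equal(s$element, c("O", "H"))
  expect_equal(s$bonds, matrix(c(1L, 2L), 1))
  # charge column sums to the molecule's formal charge
  expect_equal(sum(s$partial_charges), 0, tolerance = 1e-3)

  writeLines(c("@<TRIPOS>MOLECULE", "x", "@<TRIPOS>ATOM",
               "  1 C1 0 0 0 C 1 LIG 0.0"), p)
  expect_warning(s2 <- read_mol2(p), "BOND")
  expect_equal(nrow(s2$bonds), 0L)
  writeLines("nothing", p)
  expect_error(read_mol2(p), "ATOM")
})

test_that("orbital reader handles restricted files and Hartree conversion", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fixture", "2 -10.0", "2 -6.0", "0 -1.0", "0  2.0"), p)
  sp <- read_orbital_energies(p, unit = "eV")
  expect_false(sp$open_shell)
  expect_equal(sp$channels$restricted$energy, c(-10, -6, -1, 2))

  writeLines(c("2 -0.25", "0 0.10"), p)
  sph <- read_orbital_energies(p, unit = "hartree")
  expect_equal(sph$channels$restricted$energy[1], -6.8028465, tolerance = 1e-6)
})

test_that("orbital reader parses unequal alpha/beta channels and resorts", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("alpha", "1 -8.0", "1 -5.5", "0 -1.5",
               "beta", "1 -8.2", "0 -1.2"), p)
  sp <- read_orbital_energies(p, unit = "eV")
  expect_true(sp$open_shell)
  expect_equal(nrow(sp$channels$alpha), 3L)
  expect_equal(nrow(sp$channels$beta), 2L)

  writeLines(c("2 -6.0", "2 -10.0", "0 2.0"), p)
  expect_warning(sp2 <- read_orbital_energies(p, unit = "eV"), "resort")
  expect_false(is.unsorted(sp2$channels$restricted$energy))
  writeLines(c("0 1.0", "0 2.0"), p)
  expect_error(read_orbital_energies(p, unit = "eV"), "occupied")
})

test_that("packed Hessian reader reconstructs, symmetrises and converts", {
  p <- withr::local_tempfile(fileext = ".txt")
  # N = 1: 6 packed values, row-major lower triangle
  writeLines("1 2 4 3 5 6", p)
  h <- read_hessian(p)
  expect_equal(dim(h$matrix), c(3L, 3L))
  expect_identical(h$matrix, t(h$matrix))
  conv <- 627.5095 / 0.529177^2   # CODATA-derived factors
  expect_equal(h$matrix[2, 1], 2 * conv, tolerance = 1e-3 * conv)
  expect_equal(conv, 2240.87, tolerance = 0.001 * 2240.87)

  writeLines("1 2 3 4", p)
  expect_error(read_hessian(p), "triangular")
})

test_that("Hessian write/read round-trips matrix and geometry", {
  geom <- rbind(c(0, 0, 0), c(1.9, 0, 0), c(0, 2.1, 0))
  h <- make_harmonic_hessian(geom,
                             bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                                k = c(320, 410)))
  p <- withr::local_tempfile(fileext = ".txt")
  write_hessian(h, p, elements = c("Cu", "O", "N"))
  back <- read_hessian(p)
  expect_equal(back$matrix, h$matrix, tolerance = 1e-9)
  expect_equal(back$coords, geom, tolerance = 1e-9)
})

test_that("descriptor table writes a stable CSV that round-trips", {
  r1 <- data.frame(compound_id = "a", frontier_gap_eV = 5.25,
                   mpa_A2_mean = 51.2, stringsAsFactors = FALSE)
  r2 <- data.frame(compound_id = "b", frontier_gap_eV = 3.75,
                   mpa_A2_mean = NA_real_, stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(list(r1, r2), p)
  expect_length(readLines(p), 3L)
  back <- read_descriptor_table(p)
  expect_equal(back$frontier_gap_eV, c(5.25, 3.75))
  expect_true(is.na(back$mpa_A2_mean[2]))
  # mismatched schemas refuse to merge
  expect_error(write_descriptor_table(
    list(r1, data.frame(other = 1)), p), "schema")
})
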