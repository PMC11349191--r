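# Structure I/O: PDB and mmCIF parsing, PDB writing, DCD round trips,
# selections.

pdb_lines <- function(atoms) {
  # atoms: list of c(serial, name, resname, chain, resnum, x, y, z, occ, b)
  vapply(atoms, function(a) {
    sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            if (a[[3]] %in% c("HOH", "WAT")) "HETATM" else "ATOM",
            as.integer(a[[1]]), a[[2]], a[[3]], a[[4]], as.integer(a[[5]]),
            a[[6]], a[[7]], a[[8]], a[[9]], a[[10]])
  }, character(1))
}

five_atoms <- list(
  list(1, "N", "GLY", "A", 1, 0, 0, 0, 1, 10),
  list(2, "CA", "GLY", "A", 1, 1.5, 0, 0, 1, 10),
  list(3, "C", "GLY", "A", 1, 2.5, 1, 0, 1, 10),
  list(4, "O", "GLY", "A", 1, 2.5, 2.2, 0, 1, 10),
  list(5, "O", "HOH", "W", 101, 5, 0, 0, 1, 20))

test_that("single-model PDB parses with waters flagged and elements inferred", {
  s <- read_pdb(paste(pdb_lines(five_atoms), collapse = "\n"))
  expect_equal(nrow(s$atoms), 5)
  expect_equal(n_frames(s), 1)
  expect_equal(s$atoms$element, c("N", "C", "C", "O", "O"))
  expect_equal(s$atoms$is_water, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(s$atoms$is_hydrogen))
  expect_equal(frame_coords(s, 1)[5, ], c(5, 0, 0))
})

test_that("multi-MODEL PDB stacks frames over a shared atom table", {
  block <- pdb_lines(five_atoms)
  shift <- function(dz) pdb_lines(lapply(five_atoms, function(a) {
    a[[8]] <- a[[8]] + dz; a
  }))
  txt <- paste(c("MODEL        1", block, "ENDMDL",
                 "MODEL        2", shift(1), "ENDMDL",
                 "MODEL        3", shift(2), "ENDMDL", "END"),
               collapse = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 5)
  expect_equal(n_frames(s), 3)
  expect_equal(frame_coords(s, 3)[1, 3], 2)
})

test_that("PDB parse failures carry actionable diagnostics", {
  expect_error(read_pdb("HEADER    NOTHING HERE\nEND"), "ATOM")
  bad <- paste(c("MODEL        1", pdb_lines(five_atoms), "ENDMDL",
                 "MODEL        2", pdb_lines(five_atoms[1:4]), "ENDMDL"),
               collapse = "\n")
  expect_error(read_pdb(bad), "MODEL 2")
})

test_that("altloc duplicates reduce to the highest-occupancy conformer", {
  txt <- paste(c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40 10.00",
    "ATOM      1  N  BGLY A   1       9.000   0.000   0.000  0.60 10.00",
    "ATOM      2  O   GLY A   1       2.000   0.000   0.000  1.00 10.00"),
    collapse = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(frame_coords(s, 1)[1, 1], 9)  # occupancy 0.60 wins
})

test_that("write_pdb round-trips coordinates to 3 decimals", {
  fx <- make_bridge_fixture(fixture_spec(planted_depths = c(1, 2),
                                         n_decoy_waters = 3))
  s <- fx$structure
  s2 <- read_pdb(write_pdb(s))
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(s2$coords - s$coords)), 1e-3 + 1e-9)
})

test_that("write_pdb carries B-factor overrides and MODEL blocks", {
  s <- mini_structure(list("N", "N", "GLY", 1, "A", 0, 0, 0))
  txt <- write_pdb(s, bfactor_override = 0.57)
  expect_match(txt, " 0.57")
  expect_error(write_pdb(s, bfactor_override = c(1, 2)), "1 atom")

  tf <- make_trajectory_fixture(fixture_spec(planted_depths = 1,
                                             n_frames = 3, seed = 5))
  txt3 <- write_pdb(tf$structure)
  expect_equal(length(gregexpr("MODEL", txt3)[[1]]), 3)
  expect_equal(n_frames(read_pdb(txt3)), 3)
})

mmcif_text <- function(models = 1) {
  hdr <- c("data_test", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_PDB_model_num")
  rows <- unlist(lapply(seq_len(models), function(m) c(
    sprintf("ATOM 1 N N GLY A 1 0.000 0.000 %.3f 1.00 0.00 %d", m - 1, m),
    sprintf("ATOM 2 O O GLY A 1 2.500 0.000 %.3f 1.00 0.00 %d", m - 1, m),
    sprintf("HETATM 3 O O HOH W 101 5.000 0.000 %.3f 1.00 0.00 %d", m - 1, m))))
  paste(c(hdr, rows), collapse = "\n")
}

test_that("minimal mmCIF atom_site loop parses into the same model", {
  s <- read_mmcif(mmcif_text())
  expect_equal(nrow(s$atoms), 3)
  expect_equal(n_frames(s), 1)
  expect_true(s$atoms$is_water[3])
  expect_equal(frame_coords(s, 1)[3, 1], 5)

  s2 <- read_mmcif(mmcif_text(models = 2))
  expect_equal(n_frames(s2), 2)
  expect_equal(frame_coords(s2, 2)[1, 3], 1)

  # round trip through PDB preserves coordinates
  s3 <- read_pdb(write_pdb(s))
  expect_lt(max(abs(s3$coords - s$coords)), 1e-3 + 1e-9)
})

test_that("mmCIF without mandatory columns fails naming them", {
  broken <- gsub("_atom_site.Cartn_x", "_atom_site.something_else",
                 mmcif_text())
  expect_error(read_mmcif(broken), "Cartn_x|x")
  expect_error(read_mmcif("data_x\nloop_\n_other.id\n1"), "atom_site")
})

test_that("DCD write/read round-trips to single precision, both endians", {
  tf <- make_trajectory_fixture(fixture_spec(planted_depths = 1,
                                             n_frames = 4, seed = 11))
  topo <- tf$base$structure
  fl <- tempfile(fileext = ".dcd"); fb <- tempfile(fileext = ".dcd")
  write_dcd(tf$trajectory, fl, timestep = 2, endian = "little")
  write_dcd(tf$trajectory, fb, timestep = 2, endian = "big")
  rl <- read_dcd(fl, topo)
  rb <- read_dcd(fb, topo)
  expect_equal(rl$n_frames, 4)
  expect_lt(max(abs(rl$coords - tf$trajectory$coords)), 1e-5)
  expect_identical(rl$coords, rb$coords)   # byte-swapped copy agrees
  expect_equal(rl$timestep, 2, tolerance = 1e-6)
})

test_that("DCD reader agrees with bio3d on the fixture trajectory", {
  tf <- make_trajectory_fixture(fixture_spec(planted_depths = 1,
                                             n_frames = 3, seed = 2))
  f <- tempfile(fileext = ".dcd")
  write_dcd(tf$trajectory, f)
  ours <- read_dcd(f, tf$base$structure)
  ref <- bio3d::read.dcd(f, verbose = FALSE)
  for (fr in 1:3) {
    expect_equal(as.vector(t(frame_coords(ours, fr))),
                 as.vector(ref[fr, ]), tolerance = 1e-6)
  }
})

test_that("DCD errors: atom-count mismatch and truncation", {
  tf <- make_trajectory_fixture(fixture_spec(planted_depths = 1,
                                             n_frames = 2, seed = 3))
  f <- tempfile(fileext = ".dcd")
  write_dcd(tf$trajectory, f)
  small <- mini_structure(list("N", "N", "GLY", 1, "A", 0, 0, 0))
  expect_error(read_dcd(f, small), "does not match topology")

  bytes <- readBin(f, "raw", file.size(f))
  writeBin(bytes[1:(length(bytes) - 25)], sub <- tempfile())
  expect_error(read_dcd(sub, tf$base$structure), "frame 2")
})

test_that("selections pick the documented atom sets and stay disjoint", {
  s <- mini_structure(
    list("N", "N", "GLY", 1, "A", 0, 0, 0),
    list("CA", "C", "GLY", 1, "A", 1.5, 0, 0),
    list("C", "C", "GLY", 1, "A", 2.5, 1, 0),
    list("O", "O", "GLY", 1, "A", 2.5, 2.2, 0),
    list("O", "O", "HOH", 101, "W", 6, 0, 0),
    list("H1", "H", "HOH", 101, "W", 6.96, 0, 0),
    list("H2", "H", "HOH", 101, "W", 5.76, 0, 0.93))
  expect_equal(select_atoms(s, "water-oxygen"), 5)
  expect_equal(select_atoms(s, "protein-polar-heavy"), c(1, 4))
  expect_equal(select_atoms(s, "water-all"), 5:7)
  expect_equal(select_atoms(s, "hydrogens"), 6:7)
  expect_length(intersect(select_atoms(s, "water-oxygen"),
                          select_atoms(s, "protein-polar-heavy")), 0)
  expect_error(select_atoms(s, "everything"), "unknown selector")

  heavy <- mini_structure(list("N", "N", "GLY", 1, "A", 0, 0, 0))
  expect_length(select_atoms(heavy, "hydrogens"), 0)
})
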