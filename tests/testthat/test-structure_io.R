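test_that("receptor anchors resolve from a minimal constructed PDB", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  OG  SER A 203       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  CA  SER A 203      -1.000   0.500   0.000  1.00  0.00           C",
    "HETATM    3  P   POX A 901       3.000   0.000   0.000  1.00  0.00           P"),
    tmp)
  anchors <- anchor_spec(203, op_residue = "POX")
  cpx <- read_receptor_complex(tmp, anchors, "AChE")
  expect_equal(cpx$serine_O, c(0, 0, 0))
  expect_equal(cpx$op_P, c(3, 0, 0))
  expect_error(read_receptor_complex(tmp, anchor_spec(999, op_residue = "POX")),
               "anchor not found")
})

test_that("synthetic receptor round-trips its ground-truth anchors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  gt <- write_synthetic_receptor_pdb(tmp, seed = 7)
  cpx <- read_receptor_complex(tmp, gt$anchors, "AChE")
  expect_equal(cpx$serine_O, gt$serine_O, tolerance = 1e-6)
  expect_equal(cpx$op_P, gt$op_P, tolerance = 1e-6)
  # anchor resolution is independent of atom record order
  lines <- readLines(tmp)
  atoms <- grep("^(ATOM|HETATM)", lines)
  set.seed(1)
  shuffled <- lines
  shuffled[atoms] <- lines[sample(atoms)]
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(shuffled, tmp2)
  cpx2 <- read_receptor_complex(tmp2, gt$anchors, "AChE")
  expect_equal(cpx2$serine_O, cpx$serine_O)
  expect_equal(cpx2$op_P, cpx$op_P)
})

test_that("pose ensembles round-trip through PDB and SDF", {
  g <- generate_pose_ensemble(pose_scenario(n_poses = 3, seed = 5,
    energy_distribution = list("norm", -100, 5)))
  for (ext in c(".pdb", ".sdf")) {
    tmp <- withr::local_tempfile(fileext = ext)
    write_pose_ensemble(g$ensemble, tmp)
    ens2 <- read_pose_ensemble(tmp, g$ensemble$oxime, "AChE")
    expect_length(ens2$poses, 3L)
    expect_equal(ens2$atom_names, g$ensemble$atom_names)
    for (k in 1:3) {
      expect_equal(ens2$poses[[k]]$coords,
                   unname(g$ensemble$poses[[k]]$coords),
                   tolerance = 1e-3)
      # energies round-trip exactly through the text representation
      expect_identical(ens2$poses[[k]]$energy_total,
                       g$ensemble$poses[[k]]$energy_total)
    }
  }
})

test_that("single-pose files work and inconsistent models are rejected", {
  g <- generate_pose_ensemble(pose_scenario(n_poses = 1, seed = 9))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(g$ensemble, tmp)
  ens <- read_pose_ensemble(tmp, g$ensemble$oxime)
  expect_length(ens$poses, 1L)
  # corrupt: drop one atom from the second of two models
  g2 <- generate_pose_ensemble(pose_scenario(n_poses = 2, seed = 9))
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(g2$ensemble, tmp2)
  lines <- readLines(tmp2)
  atom_idx <- grep("^HETATM", lines)
  writeLines(lines[-atom_idx[length(atom_idx)]], tmp2)
  expect_error(read_pose_ensemble(tmp2, g2$ensemble$oxime),
               "differ in atom count")
})

test_that("missing energies require a sidecar or the no-energy mode", {
  g <- generate_pose_ensemble(pose_scenario(n_poses = 2, seed = 3))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(g$ensemble, tmp)
  lines <- readLines(tmp)
  writeLines(lines[!grepl("ENERGY_TOTAL", lines)], tmp)
  expect_error(read_pose_ensemble(tmp, g$ensemble$oxime), "missing pose energies")
  ens <- read_pose_ensemble(tmp, g$ensemble$oxime, no_energy = TRUE)
  expect_equal(vapply(ens$poses, function(p) p$energy_total, 0), c(0, 0))
  side <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(pose_index = 1:2, energy_total = c(-110, -95),
                       energy_hbond = c(-4, -2)), side, row.names = FALSE)
  ens2 <- read_pose_ensemble(tmp, g$ensemble$oxime, energy_csv = side)
  expect_equal(vapply(ens2$poses, function(p) p$energy_total, 0),
               c(-110, -95))
  expect_equal(ens2$poses[[1]]$energy_hbond, -4)
})

test_that("geometry tables validate ranges and preserve order", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # six best-pose rows in the shape of a published docking table
  writeLines(c("pose_index,d_op,theta_opo,energy",
               "1,8.644,153.35,-73.444",
               "2,4.260,155.00,-105.013",
               "3,7.102,147.64,-135.261",
               "4,4.111,144.47,-136.854",
               "5,3.864,141.70,-129.978",
               "6,6.777,147.81,-119.168"), tmp)
  tab <- read_geometry_table(tmp)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$d_op[2], 4.260)
  expect_equal(tab$theta_opo[2], 155.00)
  expect_equal(tab$energy[2], -105.013)
  expect_equal(tab$pose_index, 1:6)
  writeLines(c("pose_index,d_op,theta_opo,energy", "1,4.0,200,-100"), tmp)
  expect_error(read_geometry_table(tmp), "row 1")
  writeLines(c("pose_index,d_op,theta_opo,energy", "1,-2,150,-100"), tmp)
  expect_error(read_geometry_table(tmp), "d_op")
})
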