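# Structure data model, PDB round trips and C3 symmetry operations.

test_that("read_pdb parses minimal records and partitions waters", {
  line <- "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C"
  s <- read_pdb(line)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(nrow(protein_atoms(s)), 1)
  expect_equal(as.numeric(s$atoms[1, c("x", "y", "z")]), c(1, 2, 3))

  two <- c(line,
           "HETATM    2  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O")
  s2 <- read_pdb(two)
  expect_equal(nrow(water_atoms(s2)), 1)
  expect_equal(nrow(ligand_atoms(s2)), 0)
  expect_equal(nrow(protein_atoms(s2)), 1)
})

test_that("read_pdb rejects malformed and unsupported records", {
  expect_error(read_pdb("REMARK nothing here"), "empty structure")
  expect_error(read_pdb("ATOM      1  CA  GLY A   1     bad"), "line 1")
  ins <- "ATOM      1  CA  GLY A   1A      1.000   2.000   3.000  1.00  0.00           C"
  expect_error(read_pdb(ins), "insertion code")
})

test_that("write_pdb emits fixed columns, TER/END, and can omit virtuals", {
  expect_equal(write_pdb(new_structure()), "END\n")
  s <- new_structure(atom_row())
  txt <- write_pdb(s)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(sum(startsWith(lines, "ATOM")), 1)
  expect_equal(sum(startsWith(lines, "TER")), 1)
  expect_equal(lines[length(lines)], "END")

  sv <- new_structure(rbind(atom_row(),
                            atom_row(name = "VX", resno = 2L, virtual = TRUE,
                                     element = "X")))
  expect_equal(sum(grepl("^ATOM", strsplit(write_pdb(sv), "\n")[[1]])), 2)
  expect_equal(sum(grepl("^ATOM", strsplit(write_pdb(sv, omit_virtual = TRUE),
                                           "\n")[[1]])), 1)
  far <- new_structure(atom_row(x = 1e5))
  expect_error(write_pdb(far), "overflow")
})

test_that("PDB round trip preserves names and coordinates to 3 decimals", {
  set.seed(4)
  n <- 20
  s <- new_structure(data.frame(
    record = "ATOM", name = sprintf("A%d", 1:n), resid = "ALA", chain = "A",
    resno = 1:n, x = runif(n, -50, 50), y = runif(n, -50, 50),
    z = runif(n, -50, 50), occ = 1, b = 0, element = "C", virtual = FALSE,
    stringsAsFactors = FALSE))
  rt <- read_pdb(write_pdb(s))
  expect_equal(rt$atoms$name, s$atoms$name)
  expect_equal(as.matrix(rt$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # independent parser agrees on the emitted file
  tf <- tempfile(fileext = ".pdb")
  writeLines(write_pdb(s), tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               unname(round(as.matrix(s$atoms[, c("x", "y", "z")]), 3)))
})

test_that("apply_c3 places exact 120/240 degree copies", {
  on_axis <- new_structure(atom_row(z = 5))
  tri <- apply_c3(on_axis)
  expect_equal(max(dist(as.matrix(tri$atoms[, c("x", "y", "z")]))), 0)

  off <- new_structure(atom_row(x = 1))
  tri2 <- apply_c3(off)
  xyz <- as.matrix(tri2$atoms[, c("x", "y", "z")])
  expect_equal(xyz[2, ], c(-0.5, sqrt(3) / 2, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(xyz[3, ], c(-0.5, -sqrt(3) / 2, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(apply_c3(off, axis = c(0, 0, 0)), "non-zero")
  expect_error(apply_c3(new_structure()), "empty")
})

test_that("120-degree map applied three times is the identity", {
  for (seed in 1:5) {
    m <- random_monomer(10, seed)
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    out <- xyz
    for (k in 1:3) out <- rotate_coords(out, 120, c(0, 0, 1), c(0, 0, 0))
    expect_lt(max(abs(out - xyz)), 1e-9)
  }
})

test_that("check_c3_symmetry measures deviation and validates input", {
  for (seed in 1:5)
    expect_lt(check_c3_symmetry(apply_c3(random_monomer(8, seed))), 1e-9)
  tri <- apply_c3(random_monomer(6, 42))
  idx <- which(tri$atoms$chain == "B")[1]
  tri$atoms$x[idx] <- tri$atoms$x[idx] + 0.3
  tri$atoms$y[idx] <- tri$atoms$y[idx] + 0.4
  expect_equal(check_c3_symmetry(tri), 0.5, tolerance = 1e-9)
  expect_error(check_c3_symmetry(random_monomer(5, 1)), "3 chains")
})

test_that("amantadine template has ideal C3 adamantane-amine geometry", {
  amt <- build_amantadine()
  expect_equal(nrow(amt$atoms), 11)
  expect_equal(sum(amt$atoms$element == "C"), 10)
  expect_equal(sum(amt$atoms$element == "N"), 1)
  xyz <- as.matrix(amt$atoms[, c("x", "y", "z")])
  rot <- rotate_coords(xyz, 120, c(0, 0, 1), c(0, 0, 0))
  dev <- max(apply(c3bind:::cross_dist(rot, xyz), 1, min))
  expect_lt(dev, 1e-6)
  ax <- amt$atoms[amt$atoms$name %in% c("C1", "N1"), ]
  expect_lt(max(abs(c(ax$x, ax$y))), 1e-6)
  # bonds at ideal lengths
  rownames(xyz) <- amt$atoms$name
  bl <- apply(amt$bonds, 1, function(b) sqrt(sum((xyz[b[1], ] - xyz[b[2], ])^2)))
  expect_equal(sort(unique(round(bl, 3))), c(1.47, 1.54))
})

test_that("symmetrize_ligand keeps one third real plus virtual axis atoms", {
  amt <- build_amantadine()
  third <- symmetrize_ligand(amt)
  expect_equal(sum(!third$atoms$virtual), 3)
  expect_equal(sum(third$atoms$virtual), 2)
  expect_setequal(third$atoms$name[third$atoms$virtual], c("C1", "N1"))
  expect_equal(length(third$third_atoms), 3)

  # reconstruction: real atoms x 3 images + axis atoms reproduce all 11
  re <- as.matrix(third$atoms[!third$atoms$virtual, c("x", "y", "z")])
  ax <- as.matrix(third$atoms[third$atoms$virtual, c("x", "y", "z")])
  full <- rbind(re, rotate_coords(re, 120, c(0, 0, 1), c(0, 0, 0)),
                rotate_coords(re, 240, c(0, 0, 1), c(0, 0, 0)), ax)
  orig <- as.matrix(amt$atoms[, c("x", "y", "z")])
  expect_equal(nrow(full), 11)
  expect_lt(max(apply(c3bind:::cross_dist(full, orig), 1, min)), 1e-6)

  # partition sizes invariant to a prior rotation about the axis
  rotated <- amt
  rotated$atoms[, c("x", "y", "z")] <-
    rotate_coords(as.matrix(amt$atoms[, c("x", "y", "z")]), 77, c(0, 0, 1),
                  c(0, 0, 0))
  third2 <- symmetrize_ligand(rotated)
  expect_equal(sum(!third2$atoms$virtual), 3)
  expect_equal(sum(third2$atoms$virtual), 2)

  # axis-atoms-only template: everything virtual
  axial <- new_ligand_template("AXL", data.frame(
    name = c("X1", "X2"), element = c("C", "N"), x = 0, y = 0, z = c(0, 1.5),
    virtual = FALSE, stringsAsFactors = FALSE), symmetry_order = 3,
    axis_atoms = c("X1", "X2"))
  t3 <- symmetrize_ligand(axial)
  expect_equal(sum(!t3$atoms$virtual), 0)
  expect_equal(sum(t3$atoms$virtual), 2)

  # an asymmetric template is rejected
  bad <- amt
  bad$atoms$x[3] <- bad$atoms$x[3] + 1.0
  expect_error(symmetrize_ligand(bad), "asymmetry")
})

test_that("ligand topology text format round-trips", {
  amt <- build_amantadine()
  rt <- read_ligand_template(write_ligand_template(amt))
  expect_equal(rt$code, "AMT")
  expect_equal(rt$symmetry_order, 3)
  expect_setequal(rt$axis_atoms, c("C1", "N1"))
  expect_equal(as.matrix(rt$atoms[, c("x", "y", "z")]),
               as.matrix(amt$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(read_ligand_template("symmetry_order 3"), "no atom lines")
})
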