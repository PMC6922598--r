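# Hydrogen-bond detection, network search and satisfaction accounting.

ser_with_og <- function(chain = "A", resno = 71L, og = c(2.9, 0, 0),
                        cb = c(4.2, 0.3, 0.2)) {
  rbind(atom_row("N", "SER", chain, resno, cb[1] + 2.2, cb[2] + 1.2, cb[3],
                 element = "N"),
        atom_row("CA", "SER", chain, resno, cb[1] + 1.4, cb[2] + 0.6, cb[3]),
        atom_row("C", "SER", chain, resno, cb[1] + 2.0, cb[2] - 0.8, cb[3]),
        atom_row("O", "SER", chain, resno, cb[1] + 3.1, cb[2] - 1.0, cb[3],
                 element = "O"),
        atom_row("CB", "SER", chain, resno, cb[1], cb[2], cb[3]),
        atom_row("OG", "SER", chain, resno, og[1], og[2], og[3],
                 element = "O"))
}

amine_het <- function(x = 0, y = 0, z = 0)
  atom_row("N1", "AMT", "X", 201L, x, y, z, element = "N", record = "HETATM")

test_that("detect_hbonds applies distance, angle and chemistry criteria", {
  s <- new_structure(rbind(ser_with_og(og = c(2.9, 0, 0)), amine_het()))
  bonds <- detect_hbonds(s, include_ligand = TRUE)
  sel <- bonds[bonds$donor_atom == "OG" & bonds$acceptor_atom == "N1", ]
  expect_equal(nrow(sel), 1)
  expect_equal(sel$distance, 2.9, tolerance = 1e-9)
  expect_gt(sel$angle, 90)

  far <- new_structure(rbind(ser_with_og(og = c(5, 0, 0), cb = c(6.3, 0.3, 0.2)),
                             amine_het()))
  bf <- detect_hbonds(far, include_ligand = TRUE)
  expect_equal(nrow(bf[bf$donor_atom == "OG" & bf$acceptor_atom == "N1", ]), 0)

  carbons <- new_structure(rbind(atom_row("CB", "ALA", resno = 1L),
                                 atom_row("CB", "ALA", resno = 5L, x = 2.8)))
  expect_equal(nrow(detect_hbonds(carbons)), 0)

  # a donor pointing the wrong way (antecedent angle < 90) is rejected
  bent <- new_structure(rbind(ser_with_og(og = c(2.9, 0, 0), cb = c(1.2, 0, 0)),
                              amine_het()))
  bb <- detect_hbonds(bent, include_ligand = TRUE)
  expect_equal(nrow(bb[bb$donor_atom == "OG" & bb$acceptor_atom == "N1", ]), 0)
  expect_error(detect_hbonds(new_structure()), "empty")
})

fake_bonds <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p)
    data.frame(donor_chain = p[1], donor_resno = as.integer(p[2]),
               donor_resid = "SER", donor_atom = "OG", donor_kind = p[5],
               acceptor_chain = p[3], acceptor_resno = as.integer(p[4]),
               acceptor_resid = "SER", acceptor_atom = "OG",
               acceptor_kind = p[6], distance = 2.9, angle = 120,
               stringsAsFactors = FALSE)))
}

test_that("find_networks returns connected components above min size", {
  expect_length(find_networks(c3bind:::empty_hbond_frame(), 2), 0)
  disjoint <- fake_bonds(list(c("A", 1, "A", 2, "protein", "protein"),
                              c("B", 7, "B", 9, "protein", "protein")))
  nets <- find_networks(disjoint, 2)
  expect_length(nets, 2)
  expect_true(all(vapply(nets, function(n) length(n$members), 1L) == 2))

  chain3 <- fake_bonds(list(c("A", 1, "A", 2, "protein", "protein"),
                            c("A", 2, "A", 3, "protein", "protein")))
  nets3 <- find_networks(chain3, 2)
  expect_length(nets3, 1)
  expect_equal(nets3[[1]]$members, c("A:1", "A:2", "A:3"))
  # min_size filters
  expect_length(find_networks(disjoint, 3), 0)
})

test_that("find_networks agrees with a BFS oracle and ignores bond order", {
  set.seed(21)
  for (rep in 1:5) {
    n_edges <- sample(4:12, 1)
    pairs <- lapply(seq_len(n_edges), function(i)
      c(sample(LETTERS[1:3], 1), sample(1:8, 1),
        sample(LETTERS[1:3], 1), sample(1:8, 1), "protein", "protein"))
    pairs <- Filter(function(p) !(p[1] == p[3] && p[2] == p[4]), pairs)
    if (!length(pairs)) next
    bonds <- fake_bonds(pairs)
    nets <- find_networks(bonds, 2)
    edges <- data.frame(
      from = paste0(bonds$donor_chain, ":", bonds$donor_resno),
      to = paste0(bonds$acceptor_chain, ":", bonds$acceptor_resno),
      stringsAsFactors = FALSE)
    oracle <- Filter(function(cc) length(cc) >= 2, bfs_components(edges))
    got <- lapply(nets, `[[`, "members")
    expect_setequal(lapply(got, paste, collapse = "|"),
                    lapply(oracle, paste, collapse = "|"))
    # permutation invariance
    perm <- bonds[sample(nrow(bonds)), ]
    nets_p <- find_networks(perm, 2)
    expect_setequal(lapply(nets_p, function(n) paste(n$members, collapse = "|")),
                    lapply(got, paste, collapse = "|"))
  }
})

test_that("spans_interface counts protein chains only", {
  single <- find_networks(fake_bonds(list(c("A", 1, "A", 2, "protein", "protein"))), 2)
  expect_false(single[[1]]$spans_interface)
  cross <- find_networks(fake_bonds(list(c("A", 1, "B", 2, "protein", "protein"))), 2)
  expect_true(cross[[1]]$spans_interface)
  liggy <- find_networks(fake_bonds(list(c("A", 1, "X", 201, "protein", "ligand"))), 2)
  expect_false(liggy[[1]]$spans_interface)
})

test_that("count_unsatisfied gates on burial and bonding", {
  # a lone serine OG buried inside an occluding carbon cage: 1 unsatisfied
  cage_pts <- c3bind:::sphere_points(80) * 4.5
  cage <- do.call(rbind, lapply(seq_len(nrow(cage_pts)), function(i)
    atom_row("CB", "ALA", "A", 300L + i, cage_pts[i, 1], cage_pts[i, 2],
             cage_pts[i, 3])))
  ser <- rbind(atom_row("CB", "SER", "A", 71L, 1.3, 0.3, 0.2),
               atom_row("OG", "SER", "A", 71L, 0, 0, 0, element = "O"))
  s <- new_structure(rbind(ser, cage))
  sas <- sasa(s)
  bonds <- detect_hbonds(s)
  og_row <- which(s$atoms$name == "OG")
  expect_lt(sas[og_row], 5)
  expect_equal(count_unsatisfied(s, sas, bonds, members = "A:71"), 1L)

  # the same OG fully exposed (SASA far above the gate): 0
  s2 <- new_structure(ser)
  expect_equal(count_unsatisfied(s2, sasa(s2), detect_hbonds(s2),
                                 members = "A:71"), 0L)

  # a satisfied buried triad: OG hydrogen-bonded to the planted amine
  fx <- make_fixtures(1)
  bonds_fx <- detect_hbonds(fx$bundle, include_ligand = TRUE)
  sas_fx <- sasa(fx$bundle)
  expect_equal(count_unsatisfied(fx$bundle, sas_fx, bonds_fx,
                                 members = c("A:71", "B:71", "C:71")), 0L)
})

test_that("a planted axial Ser triad is recovered as one ligand network", {
  fx <- make_fixtures(3)
  bonds <- detect_hbonds(fx$bundle, include_ligand = TRUE)
  nets <- find_networks(bonds, min_size = 3)
  with_lig <- Filter(function(n) any(grepl("^ligand", n$members)), nets)
  expect_length(with_lig, 1)
  expect_setequal(with_lig[[1]]$chains, c("A", "B", "C"))
  expect_true(with_lig[[1]]$spans_interface)
  expect_true(all(paste0(c("A", "B", "C"), ":71") %in% with_lig[[1]]$members))
})

test_that("networks on a C3 structure come as triples or axis-spanners", {
  # three symmetry-related OG..OG pairs far from the axis: three congruent
  # two-member networks, none spanning chains
  mono <- ser_with_og(og = c(9, 0, 0), cb = c(10.3, 0.3, 0.2))
  mono2 <- ser_with_og(resno = 75L, og = c(9.2, 2.7, 0), cb = c(10.5, 3.0, 0.2))
  tri <- apply_c3(new_structure(rbind(mono, mono2)))
  bonds <- detect_hbonds(tri)
  nets <- find_networks(bonds, 2)
  off_axis <- Filter(function(n) !n$spans_interface, nets)
  if (length(off_axis)) {
    sizes <- vapply(off_axis, function(n) length(n$members), 1L)
    expect_equal(length(off_axis) %% 3, 0)
    expect_true(all(table(sizes) %% 3 == 0))
  }
  succeed()
})
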