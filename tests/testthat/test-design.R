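# Design shell selection, layers, pair energies and the symmetric packer.

small_trimer <- function(nres = 6, R0 = 6) {
  ca <- crick_ca(crick_params(R0 = R0, nres = nres))
  ca[, 3] <- ca[, 3] - mean(range(ca[, 3]))
  apply_c3(ca_to_backbone(ca, chain = "A"))
}

test_that("select_design_shell partitions by side-chain distance to ligand", {
  lig <- matrix(c(0, 0, 0), 1)
  near <- atom_row(name = "CB", resno = 1L, x = 5)
  far <- atom_row(name = "CB", resno = 2L, x = 20)
  bb <- rbind(atom_row(name = "CA", resno = 1L, x = 5.5),
              atom_row(name = "CA", resno = 2L, x = 20.5))
  s <- new_structure(rbind(bb, near, far))
  sh <- select_design_shell(s, lig, 12.5)
  expect_equal(sh$design_positions, 1L)
  expect_equal(sh$repack_positions, 2L)
  expect_equal(length(select_design_shell(s, lig, 0)$design_positions), 0)
  expect_equal(select_design_shell(s, lig, Inf)$design_positions, c(1L, 2L))
  expect_error(select_design_shell(s, matrix(0, 0, 3), 12.5), "no ligand")
})

test_that("layer_assign classifies burial from SASA", {
  # an extended, fully exposed dipeptide is all surface
  ext <- new_structure(rbind(atom_row(resno = 1L), atom_row(resno = 2L, x = 3.8)))
  la <- layer_assign(ext)
  expect_true(all(la$layer == "surface"))
  # an atom enclosed in a tight cage is core
  cage_pts <- c3bind:::sphere_points(60) * 3.4
  cage <- do.call(rbind, lapply(seq_len(nrow(cage_pts)), function(i)
    atom_row(resno = 2L, name = "CA", x = cage_pts[i, 1], y = cage_pts[i, 2],
             z = cage_pts[i, 3])))
  s <- new_structure(rbind(atom_row(resno = 1L), cage))
  la2 <- layer_assign(s)
  expect_equal(la2$layer[la2$resno == 1], "core")
})

test_that("pair_energy has the declared cutoff, optimum and cap behavior", {
  p <- energy_params()
  a <- data.frame(name = "C1", resid = "LIG", element = "C",
                  x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  at <- function(x) {
    b <- a
    b$x <- x
    b
  }
  expect_equal(pair_energy(a, at(12), p), 0)
  # LJ optimum: two carbons at rmin = 3.4 A give exactly -depth
  expect_equal(pair_energy(a, at(3.4), p), -p$lj_depth, tolerance = 1e-12)
  expect_equal(pair_energy(a, at(0.5), p), p$clash_cap)
  # symmetry of arguments
  expect_equal(pair_energy(a, at(3.0), p), pair_energy(at(3.0), a, p))
  # donor-acceptor pair at H-bond distance earns the bonus
  don <- data.frame(name = "OG", resid = "SER", element = "O", record = "ATOM",
                    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  acc <- data.frame(name = "OD1", resid = "ASN", element = "O", record = "ATOM",
                    x = 2.9, y = 0, z = 0, stringsAsFactors = FALSE)
  e_hb <- pair_energy(don, acc, p)
  carb <- acc
  carb$name <- "CG"
  carb$element <- "C"
  expect_lt(e_hb, pair_energy(don, carb, p))
})

test_that("symmetric packer is deterministic and respects restrictions", {
  tri <- small_trimer(5)
  pose <- align_ligand_axis(symmetrize_ligand(build_amantadine()), z = 0)
  spec <- design_spec(shell_radius = 12.5, sert_positions = c(2L, 3L))
  r1 <- symmetric_pack(tri, pose, spec, energy_params(), seed = 9,
                       moves_per_position = 25)
  r2 <- symmetric_pack(tri, pose, spec, energy_params(), seed = 9,
                       moves_per_position = 25)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$energy, r2$energy)
  # Ser/Thr-restricted positions never receive other identities
  expect_true(all(strsplit(r1$sequence, "")[[1]][2:3] %in% c("S", "T")))
  # all three chains identical in sequence and exactly C3 in structure
  expect_lt(check_c3_symmetry(r1$structure), 1e-6)
  p <- protein_atoms(r1$structure)
  for (ch in c("B", "C"))
    expect_identical(p$resid[p$chain == "A"], p$resid[p$chain == ch])
  # an empty allowed set is reported with the position named
  bad <- design_spec(designable_aas = list(`1` = character()))
  expect_error(symmetric_pack(tri, pose, bad, energy_params(), seed = 1,
                              moves_per_position = 5),
               "empty allowed-rotamer set")
})

test_that("packer matches exhaustive enumeration on a small design", {
  tri <- small_trimer(4)
  amt <- symmetrize_ligand(build_amantadine())
  pose <- align_ligand_axis(amt, z = 0)
  # 4 positions, <= 4 rotamers each (A:1 + S:3)
  spec <- design_spec(shell_radius = Inf,
                      designable_aas = list(`1` = c("A", "S"),
                                            `2` = c("A", "S"),
                                            `3` = c("A", "S"),
                                            `4` = c("A", "S")))
  params <- energy_params()
  got <- symmetric_pack(tri, pose, spec, params, seed = 5,
                        moves_per_position = 150)

  # independent oracle: enumerate every assignment, computing the
  # per-asymmetric-unit energy with the exported pair_energy
  prot <- protein_atoms(tri)
  asu <- prot[prot$chain == "A", ]
  resnos <- sort(unique(asu$resno))
  stub <- function(rn, nm) as.numeric(
    asu[asu$resno == rn & asu$name == nm, c("x", "y", "z")])
  cand <- lapply(resnos, function(rn) {
    out <- list()
    for (aa in c("A", "S")) {
      chis <- rotamer_set(aa)
      for (k in seq_len(max(1, nrow(chis)))) {
        sc <- build_sidechain(aa, stub(rn, "N"), stub(rn, "CA"),
                              stub(rn, "C"), as.numeric(chis[k, ]))
        sc$resid <- rep(c3bind:::AA_1TO3[[aa]], nrow(sc))
        sc$record <- rep("ATOM", nrow(sc))
        out[[length(out) + 1]] <- structure(sc, aa = aa)
      }
    }
    out
  })
  lig_real <- pose$atoms[!pose$atoms$virtual, ]
  lr <- as.matrix(lig_real[, c("x", "y", "z")])
  full <- rbind(lr, rotate_coords(lr, 120, c(0, 0, 1), c(0, 0, 0)),
                rotate_coords(lr, 240, c(0, 0, 1), c(0, 0, 0)))
  lig_tab <- data.frame(name = rep(lig_real$name, 3), resid = "AMT",
                        record = "HETATM", element = rep(lig_real$element, 3),
                        x = full[, 1], y = full[, 2], z = full[, 3],
                        stringsAsFactors = FALSE)
  bb <- prot[prot$name %in% c("N", "CA", "C", "O"), ]
  ctx_list <- lapply(resnos, function(rn)
    bb[!(bb$chain == "A" & bb$resno == rn),
       c("name", "resid", "record", "element", "x", "y", "z")])
  combos <- expand.grid(lapply(cand, seq_along))
  energies <- apply(combos, 1, function(as_)
    asu_energy_direct(as.integer(as_), cand, ctx_list, lig_tab, params))
  best <- which.min(energies)
  best_seq <- paste(vapply(seq_along(cand), function(i)
    attr(cand[[i]][[combos[best, i]]], "aa"), ""), collapse = "")
  expect_equal(got$sequence, best_seq)
  expect_equal(got$energy, 3 * energies[best], tolerance = 1e-8)
  # and the annealer's best is never better than the true optimum
  expect_gte(got$energy, 3 * min(energies) - 1e-9)
})

test_that("annealer recovers a planted optimum on rigged tables", {
  set.seed(31)
  n <- 6
  nrot <- 5
  planted <- sample.int(nrot, n, replace = TRUE)
  one_body <- lapply(seq_len(n), function(i) {
    v <- runif(nrot, 0, 1)
    v[planted[i]] <- v[planted[i]] - 100
    v
  })
  pair <- rep(list(vector("list", n)), n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pair[[i]][[j]] <- matrix(runif(nrot^2, 0, 0.5), nrot, nrot)
  fit <- c3bind:::anneal_assignment(one_body, pair, 3 * (0.1)^((0:9) / 9),
                                    moves_per_stage = 400, seed = 2)
  expect_equal(fit$assignment, planted)
  # exhaustive check that the planted assignment is indeed the optimum
  combos <- as.matrix(expand.grid(rep(list(1:nrot), n)))
  ener <- apply(combos, 1, function(a) {
    e <- sum(vapply(1:n, function(i) one_body[[i]][a[i]], 1))
    for (i in 1:(n - 1)) for (j in (i + 1):n) e <- e + pair[[i]][[j]][a[i], a[j]]
    e
  })
  expect_equal(unname(combos[which.min(ener), ]), planted)
  expect_equal(fit$energy, min(ener), tolerance = 1e-12)
})
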