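# Symmetric side-chain design: a discrete rotamer packer with a simplified
# physical energy. Identities and conformations are optimized inside a
# ligand-distance shell; outside it positions are repacked with fixed
# identity. Layer rules (from SASA) restrict the amino-acid alphabet, and
# positions hydrogen-bonding to the ligand can be pinned to Ser/Thr.
# Every move is applied simultaneously to the three symmetry-related chains.

LAYER_ALPHABETS <- list(core = strsplit("AVILMF", "")[[1]],
                        surface = strsplit("DEKRNQSTH", "")[[1]],
                        boundary = strsplit("AVILMFDEKRNQSTH", "")[[1]])

#' Design specification
#'
#' @param shell_radius Ligand-distance shell inside which identities are
#'   designed, Angstrom. 12.5 by default; the design stage can also be run
#'   with a 15 A shell.
#' @param designable_aas Optional named list mapping positions (residue
#'   numbers of the asymmetric unit) to allowed one-letter codes,
#'   overriding the layer alphabet at those positions.
#' @param sert_positions Positions restricted to Ser/Thr (ligand
#'   hydrogen-bonding positions).
#' @param frozen_positions Positions whose identity and conformation are
#'   locked (designated hydrogen-bond-network residues).
#' @param layer_rules Named list of allowed codes per layer
#'   (`core`/`boundary`/`surface`).
#' @return A `design_spec` list.
#' @export
design_spec <- function(shell_radius = 12.5, designable_aas = list(),
                        sert_positions = integer(),
                        frozen_positions = integer(),
                        layer_rules = LAYER_ALPHABETS) {
  if (length(intersect(names(designable_aas), as.character(frozen_positions))))
    stop("frozen and designable positions overlap")
  if (length(intersect(sert_positions, frozen_positions)))
    stop("frozen and Ser/Thr positions overlap")
  structure(list(shell_radius = shell_radius, designable_aas = designable_aas,
                 sert_positions = as.integer(sert_positions),
                 frozen_positions = as.integer(frozen_positions),
                 layer_rules = layer_rules),
            class = "design_spec")
}

#' Energy parameters for the simplified packing energy
#'
#' A capped 12-6 Lennard-Jones term over heavy-atom pairs within 10 A, a
#' geometric hydrogen-bond bonus, per-amino-acid reference energies and a
#' buried-unsatisfied-polar penalty (applied in reporting, not inside the
#' pairwise packer), plus the annealing temperature schedule.
#'
#' @param lj_depth Lennard-Jones well depth per atom pair (energy units).
#' @param hbond_bonus Bonus per detected hydrogen bond (negative).
#' @param clash_cap Upper cap on the per-pair repulsive energy.
#' @param buried_unsat_penalty Penalty per buried unsatisfied polar atom.
#' @param reference_energies Named per-AA reference energies (defaults 0).
#' @param kT_schedule Annealing temperatures, hottest first.
#' @return An `energy_params` list.
#' @export
energy_params <- function(lj_depth = 0.15, hbond_bonus = -2.0, clash_cap = 10,
                          buried_unsat_penalty = 1.5,
                          reference_energies = NULL,
                          kT_schedule = 3.0 * (0.3 / 3.0)^((0:9) / 9)) {
  stopifnot(clash_cap > 0, hbond_bonus < 0)
  ref <- setNames(rep(0, length(AA1)), AA1)
  if (!is.null(reference_energies)) ref[names(reference_energies)] <- reference_energies
  structure(list(lj_depth = lj_depth, hbond_bonus = hbond_bonus,
                 clash_cap = clash_cap,
                 buried_unsat_penalty = buried_unsat_penalty,
                 reference_energies = ref, kT_schedule = kT_schedule),
            class = "energy_params")
}

#' Partition positions into design and repack sets
#'
#' A position is designable iff any of its side-chain heavy atoms (CB, or
#' CA for residues without side-chain atoms) lies within `radius` of any
#' real ligand atom; all other non-frozen positions are repack-only.
#'
#' @param s A `c3_structure`.
#' @param lig_xyz Real-ligand-atom coordinate matrix (or `ligand_template`).
#' @param radius Shell radius, Angstrom; `Inf` makes everything designable.
#' @param chain Chain whose positions are reported (the asymmetric unit).
#' @return List with integer vectors `design_positions`, `repack_positions`.
#' @export
select_design_shell <- function(s, lig_xyz, radius = 12.5, chain = "A") {
  stopifnot(radius >= 0)
  if (inherits(lig_xyz, "ligand_template")) {
    lv <- lig_xyz$atoms$virtual
    lig_xyz <- as.matrix(lig_xyz$atoms[, c("x", "y", "z")])[!lv, , drop = FALSE]
  }
  lig_xyz <- matrix(lig_xyz, ncol = 3)
  if (nrow(lig_xyz) == 0) stop("no ligand atoms for shell selection")
  p <- protein_atoms(s)
  p <- p[p$chain == chain, , drop = FALSE]
  if (nrow(p) == 0) stop("chain ", chain, " has no atoms")
  resnos <- sort(unique(p$resno))
  is_design <- vapply(resnos, function(rn) {
    r <- p[p$resno == rn, , drop = FALSE]
    side <- r[!(r$name %in% c("N", "CA", "C", "O")) & !r$virtual, , drop = FALSE]
    if (nrow(side) == 0) side <- r[r$name == "CA", , drop = FALSE]
    if (nrow(side) == 0) return(FALSE)
    min(cross_dist(coords_of(side), lig_xyz)) <= radius
  }, logical(1))
  list(design_positions = resnos[is_design],
       repack_positions = resnos[!is_design])
}

#' Assign burial layers from solvent accessibility
#'
#' Classifies each residue by its summed per-residue SASA: `core` below
#' `core_cut` (20 A^2), `surface` above `surface_cut` (60 A^2), `boundary`
#' otherwise.
#'
#' @param s A `c3_structure`.
#' @param atom_sasa Optional precomputed per-atom SASA ([sasa()]).
#' @param core_cut,surface_cut Thresholds in A^2.
#' @return Data frame with `chain`, `resno`, `sasa`, `layer`.
#' @export
layer_assign <- function(s, atom_sasa = NULL, core_cut = 20, surface_cut = 60) {
  p_idx <- which(s$atoms$record == "ATOM")
  if (!length(p_idx)) stop("structure has no protein residues")
  if (is.null(atom_sasa)) atom_sasa <- sasa(s)
  a <- s$atoms[p_idx, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  tot <- tapply(atom_sasa[p_idx], key, sum)
  uk <- names(tot)
  idx <- match(uk, key)
  layer <- ifelse(tot < core_cut, "core",
                  ifelse(tot > surface_cut, "surface", "boundary"))
  out <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                    sasa = as.numeric(tot), layer = as.character(layer),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

# ---- pair energy -----------------------------------------------------------

# donor/acceptor capability lookup used by the energy's H-bond term: returns
# "D", "A", "B" or NA per atom row (data frame with resid/name/element)
atom_polar_role <- function(resid, name, element, record) {
  n <- length(name)
  role <- rep(NA_character_, n)
  role[record == "ATOM" & name == "N"] <- "D"
  role[record == "ATOM" & name == "O"] <- "A"
  for (i in seq_len(n)) {
    if (record[i] == "ATOM") {
      cap <- POLAR_SIDECHAIN[[resid[i]]][[name[i]]]
      if (!is.null(cap)) role[i] <- cap[1]
    } else if (resid[i] == "HOH") {
      role[i] <- "B"
    } else if (element[i] %in% c("N", "O")) {
      role[i] <- "B"
    }
  }
  role
}

#' Pairwise interaction energy between two atom sets
#'
#' Sum over atom pairs within 10 A of a 12-6 Lennard-Jones term (r_min =
#' sum of van der Waals radii, capped at `clash_cap` per pair) plus
#' `hbond_bonus` for every donor/acceptor N/O pair within hydrogen-bonding
#' distance (2.5-3.5 A). Symmetric in its arguments; virtual atoms
#' contribute nothing.
#'
#' @param a,b Atom data frames (columns `name`, `resid`, `element`, `x`,
#'   `y`, `z`, optional `virtual`, `record`).
#' @param p An [energy_params()] object.
#' @param cutoff Interaction cutoff, A.
#' @return A single energy value.
#' @export
pair_energy <- function(a, b, p = energy_params(), cutoff = 10) {
  for (nm in c("virtual")) {
    if (!(nm %in% names(a))) a[[nm]] <- FALSE
    if (!(nm %in% names(b))) b[[nm]] <- FALSE
  }
  if (!("record" %in% names(a))) a$record <- "SC"
  if (!("record" %in% names(b))) b$record <- "SC"
  a <- a[!a$virtual, , drop = FALSE]
  b <- b[!b$virtual, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  sel <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(sel)) return(0)
  ra <- VDW_RADII[a$element]
  ra[is.na(ra)] <- 1.7
  rb <- VDW_RADII[b$element]
  rb[is.na(rb)] <- 1.7
  rmin <- ra[sel[, 1]] + rb[sel[, 2]]
  r <- d[sel]
  x6 <- (rmin / r)^6
  e <- p$lj_depth * (x6^2 - 2 * x6)
  e[e > p$clash_cap] <- p$clash_cap
  total <- sum(e)
  # geometric H-bond bonus: donor/acceptor N,O pairs at H-bond distance
  role_a <- atom_polar_role(a$resid %||% rep("", nrow(a)), a$name, a$element, a$record)
  role_b <- atom_polar_role(b$resid %||% rep("", nrow(b)), b$name, b$element, b$record)
  hb <- (r >= 2.5 & r <= 3.5) &
    ((role_a[sel[, 1]] %in% c("D", "B") & role_b[sel[, 2]] %in% c("A", "B")) |
       (role_a[sel[, 1]] %in% c("A", "B") & role_b[sel[, 2]] %in% c("D", "B")))
  total + sum(hb, na.rm = TRUE) * p$hbond_bonus
}

# ---- symmetric packer ------------------------------------------------------

# numeric role codes for the fast energy kernel: 0 none, 1 donor, 2
# acceptor, 3 both (same assignments as atom_polar_role)
role_code <- function(resid, name, element, record) {
  r <- atom_polar_role(resid, name, element, record)
  code <- unname(c(D = 1, A = 2, B = 3)[r])
  code[is.na(code)] <- 0
  code
}

# flatten an atom data frame into the numeric arrays the kernel needs
atoms_pack <- function(df) {
  rad <- VDW_RADII[df$element]
  rad[is.na(rad)] <- 1.7
  list(xyz = as.matrix(df[, c("x", "y", "z")]), rad = unname(rad),
       role = role_code(df$resid, df$name, df$element,
                        df$record %||% rep("ATOM", nrow(df))),
       n = nrow(df))
}

# vectorized pair energy between two packed atom sets, optionally
# accumulated into groups (rotamer indices) of each side
kernel_energy <- function(pa, pb, params, ga = NULL, gb = NULL,
                          nga = 1L, ngb = 1L, cutoff = 10) {
  if (pa$n == 0 || pb$n == 0) return(matrix(0, nga, ngb))
  d <- cross_dist(pa$xyz, pb$xyz)
  sel <- which(d <= cutoff, arr.ind = TRUE)
  out <- matrix(0, nga, ngb)
  if (!nrow(sel)) return(out)
  i <- sel[, 1]
  j <- sel[, 2]
  r <- d[sel]
  x6 <- ((pa$rad[i] + pb$rad[j]) / r)^6
  e <- params$lj_depth * (x6^2 - 2 * x6)
  e[e > params$clash_cap] <- params$clash_cap
  ra <- pa$role[i]
  rb <- pb$role[j]
  hb <- (r >= 2.5 & r <= 3.5) &
    (((ra == 1 | ra == 3) & (rb == 2 | rb == 3)) |
       ((ra == 2 | ra == 3) & (rb == 1 | rb == 3)))
  e <- e + hb * params$hbond_bonus
  gi <- if (is.null(ga)) rep(1L, length(i)) else ga[i]
  gj <- if (is.null(gb)) rep(1L, length(j)) else gb[j]
  acc <- rowsum(e, group = (gi - 1L) * ngb + gj)
  idx <- as.integer(rownames(acc))
  out[cbind((idx - 1L) %/% ngb + 1L, (idx - 1L) %% ngb + 1L)] <- acc[, 1]
  out
}

# stack all candidate rotamers of one position (plus their 120/240 degree
# images) into packed arrays with a rotamer-index group vector
position_catalog <- function(cands) {
  dfs <- lapply(seq_along(cands), function(ri) {
    sc <- cands[[ri]]
    if (nrow(sc) == 0) return(NULL)
    sc$rot <- ri
    sc
  })
  df <- do.call(rbind, dfs)
  if (is.null(df))
    return(list(images = rep(list(list(xyz = matrix(0, 0, 3), rad = numeric(),
                                       role = numeric(), n = 0L)), 3),
                group = integer(), nrot = length(cands)))
  base <- atoms_pack(df)
  imgs <- lapply(0:2, function(m) {
    p <- base
    if (m > 0) p$xyz <- rotate_coords(p$xyz, 120 * m)
    p
  })
  list(images = imgs, group = df$rot, nrot = length(cands))
}

# assemble candidate rotamer atom sets for one position of the asymmetric
# unit: list of data.frames (side-chain atoms incl. CB) with aa + chi attrs
candidate_rotamers <- function(aa_codes, N, CA, C, resid_resno_chain) {
  out <- list()
  for (aa in aa_codes) {
    chis <- rotamer_set(aa)
    nr <- max(1L, nrow(chis))
    for (k in seq_len(nr)) {
      chi <- as.numeric(chis[k, , drop = TRUE])
      sc <- build_sidechain(aa, N, CA, C, chi)
      sc$resid <- rep(AA_1TO3[[aa]], nrow(sc))
      sc$record <- rep("ATOM", nrow(sc))
      sc$virtual <- rep(FALSE, nrow(sc))
      out[[length(out) + 1L]] <- structure(sc, aa = aa, chi = chi)
    }
  }
  out
}

# Metropolis simulated annealing over per-position rotamer indices.
# one_body: list over positions of numeric vectors; pair: list of lists of
# matrices pair[[i]][[j]] (i<j, NULL when non-interacting). Returns the
# best-seen assignment and its energy. Deterministic given seed.
anneal_assignment <- function(one_body, pair, kT_schedule, moves_per_stage,
                              seed) {
  n <- length(one_body)
  nrot <- vapply(one_body, length, 1L)
  if (any(nrot == 0)) stop("position ", which(nrot == 0)[1], " has no allowed rotamers")
  set.seed(seed)
  cur <- vapply(nrot, function(k) sample.int(k, 1), 1L)
  pair_e <- function(i, ri, j, rj) {
    if (i < j) {
      m <- pair[[i]][[j]]
      if (is.null(m)) 0 else m[ri, rj]
    } else {
      m <- pair[[j]][[i]]
      if (is.null(m)) 0 else m[rj, ri]
    }
  }
  energy_of <- function(assign) {
    e <- sum(vapply(seq_len(n), function(i) one_body[[i]][assign[i]], 1))
    if (n > 1)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        e <- e + pair_e(i, assign[i], j, assign[j])
    e
  }
  cur_e <- energy_of(cur)
  best <- cur
  best_e <- cur_e
  for (kT in kT_schedule) {
    for (mv in seq_len(moves_per_stage)) {
      i <- sample.int(n, 1)
      if (nrot[i] == 1) next
      ri_new <- sample.int(nrot[i], 1)
      if (ri_new == cur[i]) next
      delta <- one_body[[i]][ri_new] - one_body[[i]][cur[i]]
      for (j in seq_len(n)) {
        if (j == i) next
        delta <- delta + pair_e(i, ri_new, j, cur[j]) - pair_e(i, cur[i], j, cur[j])
      }
      if (delta <= 0 || runif(1) < exp(-delta / kT)) {
        cur[i] <- ri_new
        cur_e <- cur_e + delta
        if (cur_e < best_e) {
          best <- cur
          best_e <- cur_e
        }
      }
    }
  }
  list(assignment = best, energy = best_e)
}

#' Symmetric rotamer packing / sequence design
#'
#' Optimizes per-position amino-acid identities (inside the design shell)
#' and rotamers (everywhere) of the asymmetric unit by Metropolis simulated
#' annealing; every accepted move is applied simultaneously to all three
#' chains, so the output trimer is exactly C3-symmetric with identical
#' chain sequences. The total energy is three times the per-asymmetric-unit
#' energy, which counts each symmetry-distinct interaction once (one-third
#' of the ligand interaction per asymmetric unit).
#'
#' @param trimer A C3-symmetric `c3_structure` (about global z) with
#'   backbone atoms N, CA, C, O.
#' @param lig A `ligand_template` placed in the trimer frame (its real
#'   atoms are used; the full C3 ligand is reconstructed internally).
#' @param spec A [design_spec()].
#' @param params An [energy_params()].
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param moves_per_position Annealing moves per position per stage.
#' @param pair_cutoff CB-CB distance beyond which position pairs are
#'   treated as non-interacting, A.
#' @return List with `structure` (designed trimer), `energy` (total, =3x
#'   per-asymmetric-unit), `sequence` (one chain's designed sequence),
#'   `positions` (per-position summary data frame).
#' @export
symmetric_pack <- function(trimer, lig, spec = design_spec(),
                           params = energy_params(), seed = 1,
                           moves_per_position = 100, pair_cutoff = 14) {
  dev <- check_c3_symmetry(trimer)
  if (dev > 0.5) stop(sprintf("trimer deviates from C3 symmetry by %.3f A", dev))
  prot <- protein_atoms(trimer)
  chains <- sort(unique(prot$chain))
  asu <- prot[prot$chain == chains[1], , drop = FALSE]
  resnos <- sort(unique(asu$resno))
  # ligand real atoms; a one-third (symmetrized) template is expanded back
  # to the full C3 molecule for shell selection and energies
  lig_real <- lig$atoms[!lig$atoms$virtual, , drop = FALSE]
  if (nrow(lig_real) == 0) stop("ligand has no real atoms")
  lr <- as.matrix(lig_real[, c("x", "y", "z")])
  is_third <- !is.null(lig$third_atoms) &&
    all(lig_real$name %in% lig$third_atoms)
  full_xyz <- if (is_third)
    rbind(lr, rotate_coords(lr, 120), rotate_coords(lr, 240)) else lr
  reps <- nrow(full_xyz) / nrow(lig_real)
  lig_tab <- data.frame(name = rep(lig_real$name, reps),
                        resid = lig$code, record = "HETATM",
                        element = rep(lig_real$element, reps),
                        x = full_xyz[, 1], y = full_xyz[, 2], z = full_xyz[, 3],
                        virtual = FALSE, stringsAsFactors = FALSE)
  shell <- select_design_shell(trimer, full_xyz, spec$shell_radius,
                               chain = chains[1])
  layers <- layer_assign(trimer)
  layers <- layers[layers$chain == chains[1], , drop = FALSE]
  # candidate sets per position
  stub <- function(rn, what) {
    r <- asu[asu$resno == rn & asu$name == what, , drop = FALSE]
    if (nrow(r) == 0) stop("missing backbone atom ", what, " at position ", rn)
    as.numeric(r[1, c("x", "y", "z")])
  }
  native_aa <- vapply(resnos, function(rn) {
    code <- asu$resid[asu$resno == rn][1]
    if (code %in% names(AA_3TO1)) AA_3TO1[[code]] else "G"
  }, "")
  cand <- list()
  frozen_atoms <- list()
  for (k in seq_along(resnos)) {
    rn <- resnos[k]
    if (rn %in% spec$frozen_positions) {
      side <- asu[asu$resno == rn & !(asu$name %in% c("N", "CA", "C", "O")), ,
                  drop = FALSE]
      sc <- side[, c("name", "element", "x", "y", "z")]
      sc$resid <- asu$resid[asu$resno == rn][1]
      sc$record <- "ATOM"
      sc$virtual <- FALSE
      cand[[k]] <- list(structure(sc, aa = native_aa[k], chi = numeric()))
      next
    }
    allowed <- if (rn %in% spec$sert_positions) {
      c("S", "T")
    } else if (rn %in% shell$design_positions) {
      ov <- spec$designable_aas[[as.character(rn)]]
      if (!is.null(ov)) ov
      else spec$layer_rules[[layers$layer[layers$resno == rn][1]]]
    } else {
      native_aa[k]
    }
    allowed <- intersect(allowed, rotamer_aas())
    if (!length(allowed))
      stop("position ", rn, " has an empty allowed-rotamer set")
    cand[[k]] <- candidate_rotamers(allowed, stub(rn, "N"), stub(rn, "CA"),
                                    stub(rn, "C"), rn)
  }
  n <- length(resnos)
  # backbone atoms of the whole trimer + ligand for one-body energies
  bb <- prot[prot$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  bb_tab <- bb[, c("name", "resid", "record", "element", "x", "y", "z", "virtual")]
  # vectorized energy tables: per-position rotamer catalogs (with their
  # symmetry images) against context, ligand and each other
  catalogs <- lapply(cand, position_catalog)
  lig_pack <- atoms_pack(lig_tab)
  one_body <- vector("list", n)
  for (k in seq_len(n)) {
    rn <- resnos[k]
    own_bb <- bb$chain == chains[1] & bb$resno == rn
    ctx_pack <- atoms_pack(bb_tab[!own_bb, , drop = FALSE])
    ck <- catalogs[[k]]
    A <- ck$images[[1]]
    g <- ck$group
    nr <- ck$nrot
    e_ctx <- kernel_energy(A, ctx_pack, params, ga = g, nga = nr)[, 1]
    e_lig <- kernel_energy(A, lig_pack, params, ga = g, nga = nr)[, 1] / 3
    # same-rotamer contact across this position's own symmetry images,
    # counted once per asymmetric unit
    e_self <- diag(kernel_energy(A, ck$images[[2]], params, ga = g, gb = g,
                                 nga = nr, ngb = nr))
    ref <- vapply(cand[[k]], function(sc)
      params$reference_energies[[attr(sc, "aa")]], 1)
    one_body[[k]] <- e_ctx + e_lig + e_self + ref
  }
  # pairwise tables for interacting position pairs
  cb_xyz <- t(vapply(seq_len(n), function(k) stub(resnos[k], "CA"), numeric(3)))
  pair <- rep(list(vector("list", n)), n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ci <- catalogs[[i]]
      for (j in (i + 1):n) {
        dmin <- min(cross_dist(matrix(cb_xyz[i, ], 1), rbind(
          cb_xyz[j, ],
          rotate_coords(matrix(cb_xyz[j, ], 1), 120),
          rotate_coords(matrix(cb_xyz[j, ], 1), 240))))
        if (dmin > pair_cutoff) next
        cj <- catalogs[[j]]
        m <- matrix(0, ci$nrot, cj$nrot)
        for (im in 1:3)
          m <- m + kernel_energy(ci$images[[1]], cj$images[[im]], params,
                                 ga = ci$group, gb = cj$group,
                                 nga = ci$nrot, ngb = cj$nrot)
        pair[[i]][[j]] <- m
      }
    }
  }
  fit <- anneal_assignment(one_body, pair, params$kT_schedule,
                           moves_per_position * n, seed)
  # rebuild the designed trimer: backbone + chosen side chains on all chains
  chosen <- lapply(seq_len(n), function(k) cand[[k]][[fit$assignment[k]]])
  seq_out <- paste(vapply(chosen, attr, "", "aa"), collapse = "")
  new_atoms <- list(bb)
  for (k in seq_len(n)) {
    sc <- chosen[[k]]
    if (nrow(sc) == 0) next
    for (m in 0:2) {
      xyz <- rotate_coords(as.matrix(sc[, c("x", "y", "z")]), 120 * m)
      new_atoms[[length(new_atoms) + 1L]] <- data.frame(
        record = "ATOM", name = sc$name, resid = sc$resid[1],
        chain = chains[m + 1], resno = resnos[k],
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
        element = sc$element, virtual = FALSE, stringsAsFactors = FALSE)
    }
  }
  bb2 <- new_atoms[[1]]
  # update backbone residue codes to the designed identities
  for (k in seq_len(n))
    bb2$resid[bb2$resno == resnos[k]] <- AA_1TO3[[attr(chosen[[k]], "aa")]]
  new_atoms[[1]] <- bb2[, ATOM_COLS]
  het <- trimer$atoms[trimer$atoms$record == "HETATM", ATOM_COLS]
  if (nrow(het) == 0) {
    # embed the (full, real-atom) ligand into the designed structure
    het <- data.frame(record = "HETATM", name = make.unique(lig_tab$name),
                      resid = lig$code, chain = "X", resno = 1L,
                      x = lig_tab$x, y = lig_tab$y, z = lig_tab$z,
                      occ = 1, b = 0, element = lig_tab$element,
                      virtual = FALSE, stringsAsFactors = FALSE)
  }
  designed <- new_structure(do.call(rbind, c(new_atoms, list(het))))
  list(structure = designed, energy = 3 * fit$energy, sequence = seq_out,
       positions = data.frame(resno = resnos,
                              aa = vapply(chosen, attr, "", "aa"),
                              designable = resnos %in% shell$design_positions,
                              stringsAsFactors = FALSE))
}

transform_sc <- function(sc, xyz) {
  sc$x <- xyz[, 1]
  sc$y <- xyz[, 2]
  sc$z <- xyz[, 3]
  sc
}

#' Read a resfile-like design specification
#'
#' Lines of the form `<position> <chain> <PIKAA|NATRO|NATAA> [letters]`:
#' `PIKAA` restricts the position to the listed one-letter codes, `NATRO`
#' freezes identity and conformation, `NATAA` allows repacking only.
#' Comment lines start with `#`.
#'
#' @param text Resfile text (string or lines).
#' @param shell_radius Passed through to [design_spec()].
#' @return A `design_spec`.
#' @export
read_resfile <- function(text, shell_radius = 12.5) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  designable <- list()
  frozen <- integer()
  sert <- integer()
  for (ln in lines) {
    tk <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tk) < 3) stop("malformed resfile line: ", ln)
    pos <- as.integer(tk[1])
    mode <- toupper(tk[3])
    if (mode == "NATRO") {
      frozen <- c(frozen, pos)
    } else if (mode == "NATAA") {
      # repack-only is the default outside the shell; nothing to record
    } else if (mode == "PIKAA") {
      if (length(tk) < 4) stop("PIKAA without allowed letters: ", ln)
      letters_allowed <- strsplit(toupper(tk[4]), "")[[1]]
      if (setequal(letters_allowed, c("S", "T"))) sert <- c(sert, pos)
      else designable[[tk[1]]] <- letters_allowed
    } else stop("unknown resfile mode: ", mode)
  }
  design_spec(shell_radius = shell_radius, designable_aas = designable,
              sert_positions = sert, frozen_positions = frozen)
}
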