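# Pipeline orchestration and deterministic synthetic fixtures: the design
# workflow (generate -> place -> design -> network search -> evaluate) and
# the study-condition fixtures used throughout the test suite.

#' Deterministic synthetic fixtures
#'
#' Builds, from a seed alone (no downloads), the fixture set used by the
#' examples and tests:
#' \describe{
#'   \item{bundle}{A C3 trimer presenting a planted axial binding site:
#'     three symmetry-related serine hydroxyls 2.8-3.0 A from the amine
#'     nitrogen of an axially placed amantadine, backed by an
#'     isoleucine/leucine/alanine-like hydrophobic collar.}
#'   \item{ligand}{The ideal-geometry amantadine template.}
#'   \item{titration}{A synthetic methyl titration: 118 uM protein at
#'     ligand:protein ratios 1:0, 1:0.58, 1:1.35, 1:2.47, generated at
#'     KD 24.1 uM and koff 60.7 1/s with 2% amplitude noise.}
#'   \item{melt}{Thermofluor replicate tables on the 25-95 degC grid in
#'     0.5 degC steps (141 points): a sigmoidal unfolding transition plus
#'     flat background, three replicates each.}
#' }
#'
#' @param seed Integer seed controlling every stochastic element.
#' @return A `fixture_set` list with elements `bundle` (with the ligand
#'   placed, waters absent), `ligand`, `ligand_third`, `titration`
#'   (`titration_series`), `titration_params` (generating parameters),
#'   `melt` (list `sample`, `background` data frames).
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  amt <- build_amantadine()
  pose <- align_ligand_axis(amt, z = 0, theta = 0)
  n_xyz <- as.numeric(pose$atoms[pose$atoms$name == "N1", c("x", "y", "z")])
  # planted monomer: Ser whose OG sits 2.85 A from the amine N, plus an
  # Ile/Leu/Ala-like nonpolar collar around the cage, built per chain
  ser_og <- n_xyz + c(2.0, 0, 2.03)  # |offset| = 2.85 A
  ser_cb <- ser_og + c(1.2, 0.45, 0.55)
  ser_ca <- ser_cb + c(1.3, 0.5, 0.6)
  mk_res <- function(resno, resid, names, elements, coords) {
    data.frame(record = "ATOM", name = names, resid = resid, chain = "A",
               resno = resno, x = coords[, 1], y = coords[, 2],
               z = coords[, 3], occ = 1, b = 0, element = elements,
               virtual = FALSE, stringsAsFactors = FALSE)
  }
  bb_from <- function(ca) rbind(ca + c(-1.2, 0.7, 0.2), ca,
                                ca + c(1.2, 0.8, -0.1), ca + c(1.9, 1.7, 0.3))
  bb_names <- c("N", "CA", "C", "O")
  bb_el <- c("N", "C", "C", "O")
  res <- list()
  # collar residues (cage level, z ~ 0): CB/CG pseudo-side-chains 4 A out
  cage_c <- as.numeric(pose$atoms[pose$atoms$name == "C1", c("x", "y", "z")])
  collar <- list(list(64L, "ILE", "CD1"), list(67L, "LEU", "CD1"),
                 list(68L, "ALA", "CB"))
  for (i in seq_along(collar)) {
    cl <- collar[[i]]
    dirv <- rotate_coords(matrix(c(1, 0.15, 0), 1), 8 * (i - 2))[1, ]
    tip <- c(0, 0, cage_c[3] - 2.5 + 1.3 * (i - 2)) + unitv(dirv) * 4.2
    ca <- tip + unitv(dirv) * 2.6
    res[[length(res) + 1L]] <- rbind(
      mk_res(cl[[1]], cl[[2]], bb_names, bb_el, bb_from(ca)),
      mk_res(cl[[1]], cl[[2]], cl[[3]], "C", rbind(tip)))
  }
  # planted serine (resno 71)
  res[[length(res) + 1L]] <- rbind(
    mk_res(71L, "SER", bb_names, bb_el, bb_from(ser_ca)),
    mk_res(71L, "SER", c("CB", "OG"), c("C", "O"), rbind(ser_cb, ser_og)))
  mono <- new_structure(do.call(rbind, res))
  tri <- apply_c3(mono)
  bundle <- new_structure(rbind(tri$atoms,
                                ligand_to_atoms(pose, chain = "X", resno = 201L)))
  # titration fixture at the study conditions
  tp <- two_state_params(
    kd = 24.1e-6, koff = 60.7,
    delta_free = rbind(c(0.80, 13.5), c(0.52, 23.1), c(1.05, 17.4)),
    delta_bound = rbind(c(0.93, 13.8), c(0.41, 22.8), c(1.17, 17.1)),
    r2_free = 25, r2_bound = 30, scale = 1)
  titr <- make_titration_series(tp, p_tot = 118e-6,
                                ratios = c(0, 0.58, 1.35, 2.47),
                                noise_sd = 0.02, seed = seed)
  # thermofluor fixture: 25-95 degC in 0.5 degC steps, sigmoid + noise
  temp <- seq(25, 95, by = 0.5)
  sig <- function(tm) 1000 / (1 + exp(-(temp - tm) / 2.2)) + 150
  mk_reps <- function(base) {
    out <- data.frame(temperature = temp)
    for (r in 1:3) out[[paste0("rep", r)]] <- base + rnorm(length(temp), 0, 4)
    out
  }
  melt <- list(sample = mk_reps(sig(80)), background = mk_reps(rep(150, length(temp))))
  structure(list(bundle = bundle, ligand = amt,
                 ligand_third = symmetrize_ligand(amt),
                 titration = titr, titration_params = tp, melt = melt,
                 seed = seed), class = "fixture_set")
}

#' Run the full design pipeline
#'
#' Executes the design workflow: generate a C3 bundle, grid-search ligand
#' placements, design the top-k placements with the symmetric packer,
#' detect hydrogen-bond networks and report the ligand pocket for each
#' design. Deterministic for a given config.
#'
#' @param bundle_spec A [bundle_spec()].
#' @param lig A `ligand_template` (default: amantadine, one-third form used
#'   for design automatically).
#' @param grid A [placement_grid()].
#' @param spec A [design_spec()].
#' @param params An [energy_params()].
#' @param top_k Number of top placements forwarded to design.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes the designed PDBs,
#'   a ranked `placements.tsv` and a machine-readable `report.json`.
#' @return A run report list: `seed`, `placements` (ranked data frame),
#'   `designs` (list with sequence, energy, networks, pocket), `warnings`.
#' @export
run_design_pipeline <- function(bundle_spec = c3bind::bundle_spec(),
                                lig = build_amantadine(),
                                grid = placement_grid(),
                                spec = design_spec(),
                                params = energy_params(),
                                top_k = 5, seed = 1, out_dir = NULL) {
  bundle <- generate_bundle(bundle_spec)
  placements <- grid_search_placement(bundle, lig, grid)
  third <- if (lig$symmetry_order == 3 &&
               length(lig$third_atoms %||% character()) == 0)
    symmetrize_ligand(lig) else lig
  k <- min(top_k, nrow(placements))
  designs <- list()
  for (i in seq_len(k)) {
    pl <- placements[i, ]
    pose <- align_ligand_axis(third, pl$z, pl$theta, pl$direction)
    packed <- symmetric_pack(bundle, pose, spec, params, seed = seed + i - 1)
    st <- packed$structure
    bonds <- detect_hbonds(st, include_ligand = TRUE, include_waters = FALSE)
    nets <- find_networks(bonds, min_size = 3)
    pocket <- pocket_report(st)
    designs[[i]] <- list(
      placement = as.list(pl), sequence = packed$sequence,
      energy = packed$energy,
      n_hbonds = nrow(bonds), n_networks = length(nets),
      networks = lapply(nets, function(nt) list(
        members = nt$members, spans_interface = nt$spans_interface,
        n_bonds = nrow(nt$bonds))),
      pocket = pocket$lining_residues, structure = st)
  }
  report <- list(seed = seed,
                 config = list(top_k = top_k,
                               shell_radius = spec$shell_radius,
                               grid = unclass(grid)),
                 warnings = attr(bundle, "warnings") %||% character(),
                 placements = placements,
                 designs = lapply(designs, function(d) d[setdiff(names(d), "structure")]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(placements, file.path(out_dir, "placements.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (i in seq_along(designs))
      writeLines(write_pdb(designs[[i]]$structure),
                 file.path(out_dir, sprintf("design_%02d.pdb", i)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$structures <- lapply(designs, `[[`, "structure")
  invisible(report)
}
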