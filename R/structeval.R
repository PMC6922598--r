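# Structure comparison and binding-site evaluation: Kabsch superposition,
# Shrake-Rupley solvent accessibility, pocket composition, water-mediated
# hydrogen-bond paths, and sequence-derived NMR observables.

VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `A`
#' onto `B` (reflections excluded via the SVD determinant correction).
#'
#' @param A,B n x 3 coordinate matrices, n >= 3, non-degenerate.
#' @return A list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (A) and `n_atoms`; the transform maps A as
#'   `A %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in size")
  if (nrow(A) < 3) stop("need at least 3 points")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (sv$d[2] < 1e-10) stop("degenerate (collinear) coordinates")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Arot <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Arot - B0)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% t(R)),
       rmsd = rmsd, n_atoms = nrow(A))
}

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sphere-point counting: `n_points` test points are
#' placed on each atom's solvent-expanded sphere (van der Waals radius +
#' probe) and the accessible fraction is the share of points outside every
#' other atom's expanded sphere. Virtual atoms are skipped (SASA 0) and do
#' not occlude.
#'
#' @param s A `c3_structure`.
#' @param probe Probe radius, A (water: 1.4).
#' @param n_points Test points per atom.
#' @return Numeric vector of per-atom areas (A^2) in atom-table order.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960) {
  a <- s$atoms
  if (nrow(a) == 0) return(numeric(0))
  real <- which(!a$virtual)
  el <- a$element[real]
  unknown <- !(el %in% names(VDW_RADII))
  if (any(unknown))
    stop("unknown element '", el[unknown][1], "' for atom ",
         a$name[real][unknown][1], " (no van der Waals radius)")
  r <- VDW_RADII[el] + probe
  xyz <- coords_of(a[real, , drop = FALSE])
  pts <- sphere_points(n_points)
  out <- numeric(nrow(a))
  n <- length(real)
  if (n == 1) {
    out[real] <- 4 * pi * r^2
    return(out)
  }
  d2 <- cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < r[i] + r & seq_len(n) != i)
    test <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r[j]^2
      if (!any(acc)) break
    }
    out[real[i]] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  out
}

#' Residues and waters lining a ligand pocket
#'
#' Lists protein residues with any heavy atom within `radius` of any real
#' ligand atom (with the minimum distance), and waters within the same
#' radius.
#'
#' @param s A `c3_structure` containing a ligand.
#' @param lig_xyz Optional ligand coordinate matrix; defaults to the
#'   structure's own non-virtual ligand atoms.
#' @param radius Pocket radius, A (default 5).
#' @return A `pocket_report` list with `lining_residues` (chain, resno,
#'   resid, min_distance) and `bridging_waters` data frames.
#' @export
pocket_report <- function(s, lig_xyz = NULL, radius = 5.0) {
  if (is.null(lig_xyz)) {
    la <- ligand_atoms(s)
    la <- la[!la$virtual, , drop = FALSE]
    if (nrow(la) == 0) stop("no ligand present")
    lig_xyz <- coords_of(la)
  }
  lig_xyz <- matrix(lig_xyz, ncol = 3)
  p <- protein_atoms(s)
  lining <- data.frame(chain = character(), resno = integer(),
                       resid = character(), min_distance = numeric(),
                       stringsAsFactors = FALSE)
  if (nrow(p)) {
    d <- cross_dist(coords_of(p), lig_xyz)
    dmin <- apply(d, 1, min)
    key <- paste(p$chain, p$resno)
    res_min <- tapply(dmin, key, min)
    sel <- res_min <= radius
    if (any(sel)) {
      ks <- names(res_min)[sel]
      idx <- match(ks, key)
      lining <- data.frame(chain = p$chain[idx], resno = p$resno[idx],
                           resid = p$resid[idx],
                           min_distance = as.numeric(res_min[sel]),
                           stringsAsFactors = FALSE)
      lining <- lining[order(lining$chain, lining$resno), , drop = FALSE]
    }
  }
  w <- water_atoms(s)
  waters <- data.frame(chain = character(), resno = integer(),
                       min_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(w)) {
    dw <- apply(cross_dist(coords_of(w), lig_xyz), 1, min)
    sel <- dw <= radius
    waters <- data.frame(chain = w$chain[sel], resno = w$resno[sel],
                         min_distance = dw[sel], stringsAsFactors = FALSE)
  }
  structure(list(lining_residues = lining, bridging_waters = waters,
                 radius = radius), class = "pocket_report")
}

#' @export
print.pocket_report <- function(x, ...) {
  cat(sprintf("pocket_report (radius %.1f A): %d lining residues, %d waters\n",
              x$radius, nrow(x$lining_residues), nrow(x$bridging_waters)))
  if (nrow(x$lining_residues)) print(x$lining_residues, row.names = FALSE)
  invisible(x)
}

#' Water-mediated hydrogen-bond paths from ligand to protein
#'
#' Finds paths ligand-polar-atom -> water -> protein-polar-atom, and
#' two-water paths ligand -> water -> water -> protein, where every link
#' satisfies the heavy-atom hydrogen-bond criteria of [detect_hbonds()].
#'
#' @param s A `c3_structure` with waters and a ligand.
#' @return A data frame of bridges with the ligand atom, water id(s),
#'   protein partner and link distances; zero rows when no waters.
#' @export
water_mediated_hbonds <- function(s) {
  bonds <- detect_hbonds(s, include_ligand = TRUE, include_waters = TRUE)
  if (nrow(bonds) == 0) return(water_bridge_frame())
  # undirected link list between node classes
  ends <- data.frame(
    kind_a = bonds$donor_kind, id_a = paste0(bonds$donor_chain, ":", bonds$donor_resno),
    atom_a = bonds$donor_atom,
    kind_b = bonds$acceptor_kind, id_b = paste0(bonds$acceptor_chain, ":", bonds$acceptor_resno),
    atom_b = bonds$acceptor_atom,
    distance = bonds$distance, stringsAsFactors = FALSE)
  sym <- rbind(ends,
               data.frame(kind_a = ends$kind_b, id_a = ends$id_b, atom_a = ends$atom_b,
                          kind_b = ends$kind_a, id_b = ends$id_a, atom_b = ends$atom_a,
                          distance = ends$distance, stringsAsFactors = FALSE))
  lw <- sym[sym$kind_a == "ligand" & sym$kind_b == "water", , drop = FALSE]
  wp <- sym[sym$kind_a == "water" & sym$kind_b == "protein", , drop = FALSE]
  ww <- sym[sym$kind_a == "water" & sym$kind_b == "water", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(lw))) {
    hits <- wp[wp$id_a == lw$id_b[i], , drop = FALSE]
    for (j in seq_len(nrow(hits)))
      out[[length(out) + 1L]] <- data.frame(
        ligand_atom = lw$atom_a[i], water = lw$id_b[i], water2 = NA_character_,
        protein = hits$id_b[j], protein_atom = hits$atom_b[j],
        d_ligand_water = lw$distance[i], d_water_protein = hits$distance[j],
        stringsAsFactors = FALSE)
    # two-water paths
    w2 <- ww[ww$id_a == lw$id_b[i] & ww$id_b != lw$id_b[i], , drop = FALSE]
    for (k in seq_len(nrow(w2))) {
      hits2 <- wp[wp$id_a == w2$id_b[k], , drop = FALSE]
      for (j in seq_len(nrow(hits2)))
        out[[length(out) + 1L]] <- data.frame(
          ligand_atom = lw$atom_a[i], water = lw$id_b[i], water2 = w2$id_b[k],
          protein = hits2$id_b[j], protein_atom = hits2$atom_b[j],
          d_ligand_water = lw$distance[i], d_water_protein = hits2$distance[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(water_bridge_frame())
  unique(do.call(rbind, out))
}

water_bridge_frame <- function() {
  data.frame(ligand_atom = character(), water = character(),
             water2 = character(), protein = character(),
             protein_atom = character(), d_ligand_water = numeric(),
             d_water_protein = numeric(), stringsAsFactors = FALSE)
}

#' Hamming distance between aligned sequences
#'
#' @param seqA,seqB Equal-length sequences (strings).
#' @return Integer count of differing positions.
#' @export
mutation_count <- function(seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  sum(a != b)
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(seq) {
  a <- strsplit(toupper(seq), "")[[1]]
  if (!length(a)) stop("empty sequence")
  bad <- !(a %in% AA1)
  if (any(bad)) stop("invalid residue letter '", a[bad][1], "'")
  a
}

#' Backbone amide group count
#'
#' The number of peptide-bond amide linkages in a chain: sequence length
#' minus one. An alternative `mode = "NH"` counts amide protons observable
#' in an HSQC/HMQC (peptide bonds excluding those preceding proline).
#'
#' @param seq One-letter amino-acid sequence.
#' @param mode `"peptide"` (default) or `"NH"`.
#' @return Integer count.
#' @export
count_amide_groups <- function(seq, mode = c("peptide", "NH")) {
  mode <- match.arg(mode)
  a <- check_sequence(seq)
  n <- length(a) - 1L
  if (mode == "NH") n <- n - sum(a[-1] == "P")
  n
}

#' Methyl probe count for a labeling scheme
#'
#' Sums per-residue methyl counts over the sequence using a labeling-scheme
#' map. The default scheme is AILV methyl labeling (Ala Cbeta, Ile Cdelta1,
#' Leu Cdelta1/Cdelta2, Val Cgamma1/Cgamma2): A and I contribute one
#' observable methyl each, L and V two.
#'
#' @param seq One-letter amino-acid sequence.
#' @param scheme Named numeric vector mapping residue letters to methyl
#'   counts; unlisted residues count 0.
#' @return Integer count.
#' @export
count_methyl_probes <- function(seq, scheme = c(A = 1, I = 1, L = 2, V = 2)) {
  a <- check_sequence(seq)
  counts <- scheme[a]
  as.integer(sum(counts, na.rm = TRUE))
}

#' Expressed sequence of the amantadine-binding trimer design
#'
#' The designed amantadine-binding homo-trimer (ABP; deposited crystal
#' structure 6N9H) as expressed from a pET28b vector. The full construct
#' carries an N-terminal His tag removed by thrombin; the cleaved chain is
#' the five-residue GSHMG cloning scar followed by the 75-residue designed
#' sequence.
#'
#' @param cleaved Return the 80-residue thrombin-cleaved chain (default)
#'   rather than the full expressed construct.
#' @return A single character string.
#' @export
abp_sequence <- function(cleaved = TRUE) {
  designed <- paste0("DAQDKLKYLVKQLERALRELKKSLDELERSLEELEKNPSEDALVENNRLNV",
                     "ENNKIIVEVLRIILELAKASAKLA")
  if (cleaved) paste0("GSHMG", designed)
  else paste0("MGSSHHHHHHSSGLVPR", "GSHMG", designed)
}
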