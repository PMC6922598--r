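# Ligand placement: align a C3 ligand's symmetry axis with the bundle axis
# (global z) and grid-search the two remaining rigid-body degrees of freedom
# (axial translation z, rotation theta about the axis), scoring each node by
# geometric clash and contact counts.

#' Placement grid specification
#'
#' @param z_min,z_max,z_step Axial translation range and step, Angstrom,
#'   relative to the bundle's axial midpoint.
#' @param theta_min,theta_max,theta_step Rotation about the axis, degrees.
#'   For a C3 ligand any range beyond `[0, 120)` is redundant.
#' @param amine_direction `"+z"`, `"-z"`, or `"both"`: which way the amine
#'   end of the ligand points.
#' @return A `placement_grid` list.
#' @export
placement_grid <- function(z_min = -8, z_max = 8, z_step = 0.5,
                           theta_min = 0, theta_max = 115, theta_step = 5,
                           amine_direction = c("both", "+z", "-z")) {
  amine_direction <- match.arg(amine_direction)
  stopifnot(z_step > 0, theta_step > 0, z_max >= z_min, theta_max >= theta_min)
  if (theta_min < 0 || theta_max >= 120)
    stop("theta range must lie within [0, 120) for a C3 ligand")
  structure(list(z_min = z_min, z_max = z_max, z_step = z_step,
                 theta_min = theta_min, theta_max = theta_max,
                 theta_step = theta_step, amine_direction = amine_direction),
            class = "placement_grid")
}

# axis direction of a ligand template (unit vector), from its axis atoms
ligand_axis <- function(lig) {
  if (!length(lig$axis_atoms)) stop("ligand symmetry axis undefined (no axis atoms)")
  ax <- lig$atoms[lig$atoms$name %in% lig$axis_atoms, c("x", "y", "z"), drop = FALSE]
  if (nrow(ax) >= 2) {
    v <- as.numeric(ax[which.max(rowSums(ax^2)), ]) - as.numeric(ax[1, ])
    if (vnorm(v) > 1e-6) return(unitv(v))
  }
  c(0, 0, 1)
}

#' Place a C3 ligand on the global z axis
#'
#' Rotates the template so its symmetry axis coincides with global z,
#' optionally flips it so the amine end (the last axis atom, N for
#' amantadine) points along `direction`, rotates by `theta` about z, and
#' translates so the all-atom centroid sits at height `z`.
#'
#' @param lig A `ligand_template` with axis atoms defined.
#' @param z Target centroid z coordinate, Angstrom.
#' @param theta Rotation about z, degrees.
#' @param direction `"+z"` or `"-z"` for the amine end.
#' @return The template with transformed coordinates.
#' @export
align_ligand_axis <- function(lig, z = 0, theta = 0, direction = "+z") {
  u <- ligand_axis(lig)
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  if (abs(u[3]) < 1 - 1e-12) {
    ax <- c(u[2], -u[1], 0)
    xyz <- rotate_coords(xyz, acos(u[3]) * 180 / pi, ax)
  } else if (u[3] < 0) {
    xyz <- rotate_coords(xyz, 180, c(1, 0, 0))
  }
  # amine end = last-listed axis atom (N1 for the amantadine template)
  amine <- lig$axis_atoms[length(lig$axis_atoms)]
  other <- setdiff(lig$axis_atoms, amine)
  iam <- match(amine, lig$atoms$name)
  ioth <- match(other[1], lig$atoms$name)
  amine_up <- if (!is.na(ioth)) xyz[iam, 3] > xyz[ioth, 3] else TRUE
  if ((direction == "-z" && amine_up) || (direction == "+z" && !amine_up))
    xyz <- rotate_coords(xyz, 180, c(1, 0, 0))
  xyz <- rotate_coords(xyz, theta)
  xyz[, 3] <- xyz[, 3] - mean(xyz[, 3]) + z
  out <- lig
  out$atoms[, c("x", "y", "z")] <- xyz
  out
}

#' Count clashes and contacts between protein and ligand
#'
#' A clash is a (protein heavy atom, real ligand atom) pair closer than
#' `clash_cut`; a contact is a pair with distance in
#' `[clash_cut, contact_shell]`. Virtual ligand atoms are excluded from both
#' counts.
#'
#' @param protein A `c3_structure` (protein chains are used).
#' @param lig_xyz Matrix of ligand coordinates, or a `ligand_template`.
#' @param lig_virtual Logical vector marking virtual ligand atoms (taken
#'   from the template if one is supplied).
#' @param clash_cut,contact_shell Distance cutoffs in Angstrom.
#' @return Named integer vector `c(clash_count, contact_count)`.
#' @export
clash_and_contacts <- function(protein, lig_xyz, lig_virtual = NULL,
                               clash_cut = 2.8, contact_shell = 4.5) {
  stopifnot(clash_cut > 0, clash_cut < contact_shell)
  if (inherits(lig_xyz, "ligand_template")) {
    lig_virtual <- lig_xyz$atoms$virtual
    lig_xyz <- as.matrix(lig_xyz$atoms[, c("x", "y", "z")])
  }
  lig_xyz <- matrix(lig_xyz, ncol = 3)
  if (is.null(lig_virtual)) lig_virtual <- rep(FALSE, nrow(lig_xyz))
  lig_xyz <- lig_xyz[!lig_virtual, , drop = FALSE]
  p <- protein_atoms(protein)
  p <- p[!p$virtual, , drop = FALSE]
  if (nrow(p) == 0 || nrow(lig_xyz) == 0)
    return(c(clash_count = 0L, contact_count = 0L))
  d <- cross_dist(coords_of(p), lig_xyz)
  c(clash_count = sum(d < clash_cut),
    contact_count = sum(d >= clash_cut & d <= contact_shell))
}

#' Grid search of axial ligand placements
#'
#' Evaluates every node of the (z, theta, amine direction) grid, scoring
#' each placement as `contact_count - clash_weight * clash_count`. Results
#' are sorted by descending score, ties broken by smaller `|z|` then smaller
#' `theta`. The protein must be C3-symmetric about global z (checked to
#' `sym_tol`).
#'
#' @param protein A C3-symmetric `c3_structure`.
#' @param lig A `ligand_template`.
#' @param grid A [placement_grid()].
#' @param clash_cut,contact_shell Cutoffs passed to [clash_and_contacts()].
#' @param clash_weight Penalty weight per clash (default 100).
#' @param sym_tol Symmetry check tolerance, Angstrom.
#' @return A data frame of ranked placements with columns `z`, `theta`,
#'   `direction`, `clash_count`, `contact_count`, `score`.
#' @export
grid_search_placement <- function(protein, lig, grid = placement_grid(),
                                  clash_cut = 2.8, contact_shell = 4.5,
                                  clash_weight = 100, sym_tol = 0.5) {
  stopifnot(inherits(grid, "placement_grid"))
  dev <- check_c3_symmetry(protein)
  if (dev > sym_tol)
    stop(sprintf("protein deviates from C3 symmetry by %.3f A (> %.3f A)",
                 dev, sym_tol))
  zs <- seq(grid$z_min, grid$z_max, by = grid$z_step)
  ths <- seq(grid$theta_min, grid$theta_max, by = grid$theta_step)
  dirs <- switch(grid$amine_direction, both = c("+z", "-z"),
                 `+z` = "+z", `-z` = "-z")
  if (!length(zs) || !length(ths)) stop("empty placement grid")
  nodes <- expand.grid(z = zs, theta = ths, direction = dirs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # precompute one aligned pose per (theta, direction); z is a translation
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    pose <- align_ligand_axis(lig, nodes$z[i], nodes$theta[i], nodes$direction[i])
    cc <- clash_and_contacts(protein, pose, clash_cut = clash_cut,
                             contact_shell = contact_shell)
    data.frame(z = nodes$z[i], theta = nodes$theta[i],
               direction = nodes$direction[i],
               clash_count = cc[["clash_count"]],
               contact_count = cc[["contact_count"]],
               score = cc[["contact_count"]] - clash_weight * cc[["clash_count"]])
  })
  out <- do.call(rbind, res)
  out[order(-out$score, abs(out$z), out$theta), , drop = FALSE]
}
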