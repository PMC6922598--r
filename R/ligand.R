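# Ligand templates: C3-symmetric small molecules, the ideal-geometry
# amantadine builder, and the one-third symmetrized form used by the
# symmetric design machinery.

#' Construct a ligand template
#'
#' @param code Three-letter ligand code.
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z` and
#'   optionally `virtual`.
#' @param bonds Two-column character matrix (or data frame) of bonded atom
#'   name pairs.
#' @param symmetry_order Rotational symmetry order about the z axis (3 for
#'   amantadine).
#' @param axis_atoms Names of atoms lying on the symmetry axis.
#' @param third_atoms Names of the real atoms of one asymmetric unit; filled
#'   by [symmetrize_ligand()].
#' @return An object of class `ligand_template`.
#' @export
new_ligand_template <- function(code, atoms, bonds = NULL, symmetry_order = 1,
                                axis_atoms = character(), third_atoms = NULL) {
  stopifnot(symmetry_order >= 1)
  if (!("virtual" %in% names(atoms))) atoms$virtual <- FALSE
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in ligand template")
  if (any(!nzchar(atoms$element))) stop("empty element in ligand template")
  if (length(axis_atoms)) {
    ax <- atoms[atoms$name %in% axis_atoms, c("x", "y", "z"), drop = FALSE]
    rot <- rotate_coords(as.matrix(ax), 360 / symmetry_order)
    if (symmetry_order > 1 && max(sqrt(rowSums((as.matrix(ax) - rot)^2))) > 1e-6)
      stop("axis atoms do not map to themselves under the symmetry rotation")
  }
  structure(list(code = code, atoms = atoms, bonds = bonds,
                 symmetry_order = as.integer(symmetry_order),
                 axis_atoms = axis_atoms, third_atoms = third_atoms),
            class = "ligand_template")
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf("ligand_template %s: %d atoms (%d virtual), C%d, axis atoms: %s\n",
              x$code, nrow(x$atoms), sum(x$atoms$virtual), x$symmetry_order,
              paste(x$axis_atoms, collapse = " ")))
  invisible(x)
}

#' Ideal-geometry amantadine template
#'
#' Builds the 11 heavy atoms of amantadine (the C10 adamantane cage plus the
#' amine nitrogen) at ideal geometry: all C-C bonds 1.54 A, the C-N bond
#' 1.47 A, tetrahedral (109.47 degree) angles throughout. The carbon cage is
#' taken from the diamond lattice, so the three-fold axis through the
#' quaternary cage carbon (C1) and the nitrogen (N1) is exact; the template
#' is returned with that axis along global z and the cage centroid at the
#' origin, the amine pointing towards +z.
#'
#' @return A `ligand_template` with code `AMT`, `symmetry_order = 3` and axis
#'   atoms `C1`, `N1`.
#' @export
build_amantadine <- function() {
  s <- 1.54 / sqrt(3)
  # diamond-lattice adamantane: 4 methine + 6 methylene carbons
  lat <- rbind(
    C1 = c(1, 1, 1),                              # methine on the C3 axis
    C2 = c(2, 0, 0), C3 = c(0, 2, 0), C4 = c(0, 0, 2),   # CH2 bonded to C1
    C5 = c(1, -1, -1), C6 = c(-1, 1, -1), C7 = c(-1, -1, 1),  # methines
    C8 = c(-2, 0, 0), C9 = c(0, -2, 0), C10 = c(0, 0, -2))    # far CH2
  xyz <- lat * s
  # rotate so the (1,1,1) direction becomes +z
  u <- c(1, 1, 1) / sqrt(3)
  ax <- c(u[2], -u[1], 0)  # u x z
  ang <- acos(u[3]) * 180 / pi
  xyz <- rotate_coords(xyz, ang, ax, c(0, 0, 0))
  n1 <- xyz["C1", ] + c(0, 0, 1.47)
  xyz <- rbind(xyz, N1 = n1)
  xyz[abs(xyz) < 1e-12] <- 0
  atoms <- data.frame(name = rownames(xyz),
                      element = c(rep("C", 10), "N"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      virtual = FALSE, stringsAsFactors = FALSE,
                      row.names = NULL)
  # bonds: every C-C pair at the lattice bond length, plus C1-N1
  d <- cross_dist(xyz[1:10, ], xyz[1:10, ])
  idx <- which(upper.tri(d) & abs(d - 1.54) < 1e-6, arr.ind = TRUE)
  bonds <- cbind(rownames(xyz)[idx[, 1]], rownames(xyz)[idx[, 2]])
  bonds <- rbind(bonds, c("C1", "N1"))
  new_ligand_template("AMT", atoms, bonds, symmetry_order = 3,
                      axis_atoms = c("C1", "N1"))
}

#' Reduce a C3 ligand to one third with virtualized axis atoms
#'
#' Partitions the off-axis atoms of a C3-symmetric template into equivalence
#' classes under the 120-degree rotation about z, keeps one representative
#' per class as a real atom (the one whose azimuth falls in [0, 120)
#' degrees), and keeps every axis atom flagged as virtual. This is the form
#' used during symmetric design, where each asymmetric unit interacts with
#' one third of the ligand and the shared axis atoms carry no physical
#' interactions.
#'
#' @param t A `ligand_template` with `symmetry_order = 3`, C3-symmetric to
#'   within 0.1 A.
#' @return A `ligand_template` with `third_atoms` populated.
#' @export
symmetrize_ligand <- function(t) {
  stopifnot(inherits(t, "ligand_template"))
  if (t$symmetry_order != 3) stop("symmetrize_ligand requires symmetry_order 3")
  a <- t$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  raxial <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  on_axis <- raxial < 1e-3
  rot <- rotate_coords(xyz, 120)
  # map each off-axis atom to its image under the rotation
  d <- cross_dist(rot, xyz)
  partner <- apply(d, 1, which.min)
  mind <- d[cbind(seq_len(nrow(d)), partner)]
  if (any(!on_axis & mind > 0.1))
    stop("asymmetry error: atom ", a$name[which(!on_axis & mind > 0.1)[1]],
         " has no C3 partner within 0.1 A")
  theta <- (atan2(xyz[, 2], xyz[, 1]) * 180 / pi) %% 360
  keep_real <- !on_axis & theta >= 0 & theta < 120
  out <- a[keep_real | on_axis, , drop = FALSE]
  out$virtual[out$name %in% a$name[on_axis]] <- TRUE
  new_ligand_template(t$code, out, t$bonds, symmetry_order = 3,
                      axis_atoms = a$name[on_axis],
                      third_atoms = a$name[keep_real])
}

#' Read/write the plain-text ligand topology format
#'
#' A small key-value format: `atom <name> <element> <x> <y> <z>` lines,
#' `bond <name1> <name2>` lines, and `symmetry_order <k>` /
#' `axis_atoms <names...>` headers.
#'
#' @param text Topology text (single string or lines) for reading.
#' @param code Ligand code recorded in the parsed template.
#' @return `read_ligand_template()` returns a `ligand_template`;
#'   `write_ligand_template()` returns the topology text.
#' @export
read_ligand_template <- function(text, code = "LIG") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  key <- vapply(toks, `[`, "", 1)
  atoms <- do.call(rbind, lapply(toks[key == "atom"], function(tk) {
    data.frame(name = tk[2], element = tk[3], x = as.numeric(tk[4]),
               y = as.numeric(tk[5]), z = as.numeric(tk[6]),
               virtual = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(atoms)) stop("ligand topology contains no atom lines")
  bonds <- do.call(rbind, lapply(toks[key == "bond"], function(tk) tk[2:3]))
  sym <- if (any(key == "symmetry_order"))
    as.integer(toks[[which(key == "symmetry_order")[1]]][2]) else 1L
  axis <- if (any(key == "axis_atoms"))
    toks[[which(key == "axis_atoms")[1]]][-1] else character()
  cd <- if (any(key == "code")) toks[[which(key == "code")[1]]][2] else code
  new_ligand_template(cd, atoms, bonds, sym, axis)
}

#' @rdname read_ligand_template
#' @param t A `ligand_template` for writing.
#' @export
write_ligand_template <- function(t) {
  a <- t$atoms
  out <- c(sprintf("code %s", t$code),
           sprintf("symmetry_order %d", t$symmetry_order))
  if (length(t$axis_atoms))
    out <- c(out, paste("axis_atoms", paste(t$axis_atoms, collapse = " ")))
  out <- c(out, sprintf("atom %s %s %.6f %.6f %.6f",
                        a$name, a$element, a$x, a$y, a$z))
  if (!is.null(t$bonds))
    out <- c(out, sprintf("bond %s %s", t$bonds[, 1], t$bonds[, 2]))
  paste0(paste(out, collapse = "\n"), "\n")
}

# ligand template -> HETATM rows for embedding into a c3_structure
ligand_to_atoms <- function(t, chain = "X", resno = 1L) {
  a <- t$atoms
  data.frame(record = "HETATM", name = a$name, resid = t$code, chain = chain,
             resno = as.integer(resno), x = a$x, y = a$y, z = a$z,
             occ = 1, b = 0, element = a$element, virtual = a$virtual,
             stringsAsFactors = FALSE)
}
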