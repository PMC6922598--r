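# Structure data model and fixed-column PDB I/O.
#
# A `c3_structure` wraps a single atom table (one row per atom) with columns:
#   record  "ATOM" or "HETATM"
#   name    atom label (e.g. "CA", "OG", "N1")
#   resid   residue/ligand code ("ALA", "HOH", "AMT", ...)
#   chain   one-letter chain id
#   resno   1-based residue number (integer)
#   x, y, z Cartesian coordinates in Angstrom
#   occ, b  occupancy and B-factor
#   element chemical element symbol
#   virtual logical flag for virtualized atoms (no physical interactions)
#
# Protein atoms are ATOM records; waters are HETATM with code HOH; every
# other HETATM is treated as a ligand.

ATOM_COLS <- c("record", "name", "resid", "chain", "resno",
               "x", "y", "z", "occ", "b", "element", "virtual")

#' Construct a structure from an atom table
#'
#' @param atoms Data frame with (a subset of) the columns `record`, `name`,
#'   `resid`, `chain`, `resno`, `x`, `y`, `z`, `occ`, `b`, `element`,
#'   `virtual`. Missing bookkeeping columns are filled with defaults.
#' @return An object of class `c3_structure`.
#' @export
new_structure <- function(atoms = NULL) {
  if (is.null(atoms) || nrow(atoms) == 0) {
    atoms <- data.frame(record = character(), name = character(),
                        resid = character(), chain = character(),
                        resno = integer(), x = numeric(), y = numeric(),
                        z = numeric(), occ = numeric(), b = numeric(),
                        element = character(), virtual = logical(),
                        stringsAsFactors = FALSE)
  }
  if (!("record" %in% names(atoms))) atoms$record <- "ATOM"
  if (!("occ" %in% names(atoms))) atoms$occ <- 1
  if (!("b" %in% names(atoms))) atoms$b <- 0
  if (!("virtual" %in% names(atoms))) atoms$virtual <- FALSE
  if (!("element" %in% names(atoms))) atoms$element <- substr(atoms$name, 1, 1)
  missing <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element) & !atoms$virtual))
    stop("empty element symbol for a non-virtual atom")
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms[, ATOM_COLS]), class = "c3_structure")
}

#' @export
print.c3_structure <- function(x, ...) {
  a <- x$atoms
  prot <- a$record == "ATOM"
  wat <- a$record == "HETATM" & a$resid == "HOH"
  lig <- a$record == "HETATM" & a$resid != "HOH"
  cat(sprintf(
    "c3_structure: %d atoms (%d protein, %d water, %d ligand), chains: %s\n",
    nrow(a), sum(prot), sum(wat), sum(lig),
    paste(sort(unique(a$chain[prot])), collapse = " ")))
  invisible(x)
}

#' Atom-table accessors
#'
#' `protein_atoms()`, `water_atoms()` and `ligand_atoms()` return the rows of
#' the atom table belonging to the protein chains, the waters (HETATM/HOH)
#' and the non-water HETATM ligands respectively.
#'
#' @param s A `c3_structure`.
#' @return A data frame of atom rows.
#' @export
protein_atoms <- function(s) s$atoms[s$atoms$record == "ATOM", , drop = FALSE]

#' @rdname protein_atoms
#' @export
water_atoms <- function(s)
  s$atoms[s$atoms$record == "HETATM" & s$atoms$resid == "HOH", , drop = FALSE]

#' @rdname protein_atoms
#' @export
ligand_atoms <- function(s)
  s$atoms[s$atoms$record == "HETATM" & s$atoms$resid != "HOH", , drop = FALSE]

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Read a PDB-format string
#'
#' Parses the fixed-column (v3.3) ATOM/HETATM records of a PDB file into a
#' `c3_structure`. HETATM records with residue code HOH become waters; other
#' HETATMs become ligand atoms. Insertion codes and alternate locations are
#' rejected; hydrogen records are kept as parsed.
#'
#' @param text A single string (or character vector of lines) of PDB content.
#' @return A `c3_structure`.
#' @export
read_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records: empty structure")
  idx <- which(sel)
  rows <- lapply(idx, function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    altloc <- substr(ln, 17, 17)
    if (altloc != " " && altloc != "A")
      stop(sprintf("alternate location '%s' at line %d not supported", altloc, i))
    icode <- substr(ln, 27, 27)
    if (icode != " ")
      stop(sprintf("insertion code '%s' at line %d not supported", icode, i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(xyz)) || is.na(resno))
      stop(sprintf("malformed PDB record at line %d: bad numeric field", i))
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    b <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    el <- trimws(substr(ln, 77, 78))
    nm <- trimws(substr(ln, 13, 16))
    if (el == "") el <- substr(gsub("[^A-Za-z]", "", nm), 1, 1)
    data.frame(record = trimws(substr(ln, 1, 6)), name = nm,
               resid = trimws(substr(ln, 18, 20)),
               chain = substr(ln, 22, 22), resno = resno,
               x = xyz[1], y = xyz[2], z = xyz[3],
               occ = if (is.na(occ)) 1 else occ,
               b = if (is.na(b)) 0 else b,
               element = el, virtual = identical(el, "X"),
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  dup <- duplicated(atoms[, c("chain", "resno", "name", "record", "resid")])
  if (any(dup)) stop("duplicate atom (chain, residue, name) in PDB input")
  new_structure(atoms)
}

#' Write a structure as a PDB-format string
#'
#' Emits fixed-column ATOM/HETATM records, a TER after each protein chain,
#' and a final END. Virtual atoms are written with element symbol `X`, or
#' omitted entirely when `omit_virtual = TRUE`.
#'
#' @param s A `c3_structure`.
#' @param omit_virtual Drop virtual atoms from the output?
#' @return A single PDB-format string.
#' @export
write_pdb <- function(s, omit_virtual = FALSE) {
  a <- s$atoms
  if (omit_virtual) a <- a[!a$virtual, , drop = FALSE]
  if (nrow(a) == 0) return("END\n")
  if (any(abs(c(a$x, a$y, a$z)) > 9999.999))
    stop("coordinate overflow: |coordinate| > 9999.999 cannot be formatted")
  ord <- order(a$record != "ATOM", a$chain, a$resno, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  out <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    nm <- a$name[i]
    # atom-name column convention: 1-char elements start in column 14
    nm_fmt <- if (nchar(nm) < 4 && nchar(a$element[i]) == 1)
      sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    el <- if (a$virtual[i]) "X" else a$element[i]
    out <- c(out, sprintf("%-6s%5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                          a$record[i], serial, nm_fmt, a$resid[i], a$chain[i],
                          a$resno[i], a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i],
                          el))
    end_of_chain <- a$record[i] == "ATOM" &&
      (i == nrow(a) || a$record[i + 1] != "ATOM" || a$chain[i + 1] != a$chain[i])
    if (end_of_chain) {
      serial <- serial + 1L
      out <- c(out, sprintf("TER   %5d", serial))
    }
  }
  paste0(paste(out, collapse = "\n"), "\nEND\n")
}

#' Expand a monomer to a C3 trimer
#'
#' Returns the trimer obtained by adding copies of `monomer` rotated by 120
#' and 240 degrees about `axis` through `center`. The first copy keeps the
#' input coordinates bit-for-bit. Protein chains of the copies are relabeled
#' with the next letters of the alphabet (a single-chain monomer yields
#' chains A, B, C); HETATM records are copied and rotated unchanged.
#'
#' @param monomer A non-empty `c3_structure`.
#' @param axis Length-3 rotation axis (default global z).
#' @param center Point on the axis (default origin).
#' @return A `c3_structure` trimer.
#' @export
apply_c3 <- function(monomer, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  a <- monomer$atoms
  if (nrow(a) == 0) stop("monomer is empty")
  if (vnorm(axis) < 1e-12) stop("rotation axis must be non-zero")
  chains <- sort(unique(a$chain))
  k <- length(chains)
  all_labels <- LETTERS[seq_len(3 * k)]
  copies <- list(a)
  for (m in 1:2) {
    b <- a
    b[, c("x", "y", "z")] <- rotate_coords(coords_of(b), 120 * m, axis, center)
    b$chain <- all_labels[match(b$chain, chains) + m * k]
    copies[[m + 1]] <- b
  }
  new_structure(do.call(rbind, copies))
}

#' Measure deviation from C3 symmetry
#'
#' For a trimer whose three chains have equal atom counts in corresponding
#' order, returns the maximum over atoms of the distance between the
#' 120-degree image of chain 1 and chain 2, and the 240-degree image of
#' chain 1 and chain 3.
#'
#' @param trimer A `c3_structure` with exactly three protein chains.
#' @param axis,center Symmetry axis specification as in [apply_c3()].
#' @return Maximum deviation in Angstrom.
#' @export
check_c3_symmetry <- function(trimer, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  p <- protein_atoms(trimer)
  chains <- sort(unique(p$chain))
  if (length(chains) != 3)
    stop("expected 3 chains, found ", length(chains))
  xs <- lapply(chains, function(ch) p[p$chain == ch, , drop = FALSE])
  n <- vapply(xs, nrow, 1L)
  if (length(unique(n)) != 1)
    stop("chains differ in atom count: ", paste(n, collapse = ", "))
  A <- coords_of(xs[[1]])
  B <- coords_of(xs[[2]])
  C <- coords_of(xs[[3]])
  d1 <- sqrt(rowSums((rotate_coords(A, 120, axis, center) - B)^2))
  d2 <- sqrt(rowSums((rotate_coords(A, 240, axis, center) - C)^2))
  max(c(d1, d2))
}
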