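# Built-in backbone-independent rotamer library.
#
# Side-chain heavy atoms are grown from the N/CA/C backbone stub by internal
# coordinates (NeRF). Each amino acid carries a small Z-matrix: for every
# side-chain atom a bond length to its parent, a bond angle and a dihedral,
# the dihedral being either a fixed value or an expression in the chi
# angles (e.g. "chi2+120" for the second branch of a fork). Chi angles are
# sampled at the canonical staggered values, giving 1-9 rotamers per amino
# acid. This is a deliberately small idealized library, not a statistical
# (backbone-dependent) one.

# each row: atom, element, three reference atoms (NeRF frame), bond length
# to ref3, angle ref2-ref3-atom (deg), dihedral ref1-ref2-ref3-atom
SIDECHAIN_ZMAT <- list(
  G = NULL,
  A = list(),
  S = list(c("OG", "O", "N", "CA", "CB", "1.417", "110.8", "chi1")),
  T = list(c("OG1", "O", "N", "CA", "CB", "1.433", "109.5", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "chi1-120")),
  V = list(c("CG1", "C", "N", "CA", "CB", "1.527", "110.5", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.527", "110.5", "chi1-122")),
  I = list(c("CG1", "C", "N", "CA", "CB", "1.530", "110.4", "chi1"),
           c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "chi1-122"),
           c("CD1", "C", "CA", "CB", "CG1", "1.513", "113.8", "chi2")),
  L = list(c("CG", "C", "N", "CA", "CB", "1.530", "116.3", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.521", "110.7", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.521", "110.7", "chi2+122")),
  M = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("SD", "S", "CA", "CB", "CG", "1.803", "112.7", "chi2"),
           c("CE", "C", "CB", "CG", "SD", "1.791", "100.9", "180")),
  F = list(c("CG", "C", "N", "CA", "CB", "1.502", "113.8", "chi1"),
           c("CD1", "C", "CA", "CB", "CG", "1.384", "120.8", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.384", "120.8", "chi2+180"),
           c("CE1", "C", "CB", "CG", "CD1", "1.382", "120.8", "180"),
           c("CE2", "C", "CB", "CG", "CD2", "1.382", "120.8", "180"),
           c("CZ", "C", "CG", "CD1", "CE1", "1.372", "120.1", "0")),
  D = list(c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "chi1"),
           c("OD1", "O", "CA", "CB", "CG", "1.250", "118.4", "chi2"),
           c("OD2", "O", "CA", "CB", "CG", "1.250", "118.4", "chi2+180")),
  E = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "chi2"),
           c("OE1", "O", "CB", "CG", "CD", "1.250", "118.4", "0"),
           c("OE2", "O", "CB", "CG", "CD", "1.250", "118.4", "180")),
  N = list(c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "chi1"),
           c("OD1", "O", "CA", "CB", "CG", "1.231", "120.8", "chi2"),
           c("ND2", "N", "CA", "CB", "CG", "1.328", "116.4", "chi2+180")),
  Q = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "chi2"),
           c("OE1", "O", "CB", "CG", "CD", "1.231", "120.8", "0"),
           c("NE2", "N", "CB", "CG", "CD", "1.328", "116.4", "180")),
  K = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "chi2"),
           c("CE", "C", "CB", "CG", "CD", "1.520", "111.3", "180"),
           c("NZ", "N", "CG", "CD", "CE", "1.489", "111.9", "180")),
  R = list(c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "chi1"),
           c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "chi2"),
           c("NE", "N", "CB", "CG", "CD", "1.461", "111.7", "180"),
           c("CZ", "C", "CG", "CD", "NE", "1.329", "124.8", "180"),
           c("NH1", "N", "CD", "NE", "CZ", "1.326", "120.3", "0"),
           c("NH2", "N", "CD", "NE", "CZ", "1.326", "120.3", "180")),
  H = list(c("CG", "C", "N", "CA", "CB", "1.497", "113.7", "chi1"),
           c("ND1", "N", "CA", "CB", "CG", "1.378", "122.7", "chi2"),
           c("CD2", "C", "CA", "CB", "CG", "1.354", "131.0", "chi2+180"),
           c("CE1", "C", "CB", "CG", "ND1", "1.320", "109.2", "180"),
           c("NE2", "N", "CB", "CG", "CD2", "1.374", "107.2", "180")))

# chi-angle combinations per amino acid (canonical staggered values)
ROTAMER_CHIS <- local({
  stag <- c(-60, 60, 180)
  two <- expand.grid(chi1 = stag, chi2 = stag)
  list(
    G = data.frame(row.names = 1), A = data.frame(row.names = 1),
    S = data.frame(chi1 = stag), T = data.frame(chi1 = stag),
    V = data.frame(chi1 = stag),
    I = two, L = two, M = two, K = two, R = two, E = two, Q = two,
    N = two, D = two,
    F = data.frame(chi1 = stag, chi2 = 90),
    H = expand.grid(chi1 = stag, chi2 = c(-90, 90)))
})

#' Amino acids covered by the built-in rotamer library
#' @return Character vector of one-letter codes.
#' @export
rotamer_aas <- function() names(SIDECHAIN_ZMAT)

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_1TO3 <- setNames(names(AA_3TO1), AA_3TO1)

# NeRF: place atom D given A, B, C and internal coordinates (r = C-D bond,
# theta = B-C-D angle in deg, phi = A-B-C-D dihedral in deg)
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ideal CB from the backbone stub (tetrahedral, standard improper)
place_cb <- function(N, CA, C) {
  nerf_place(N, C, CA, 1.521, 110.1, 122.6)
}

#' Build side-chain heavy atoms for one rotamer
#'
#' Grows the side chain of amino acid `aa` on the N/CA/C backbone stub at
#' the given chi angles using the built-in ideal-geometry Z-matrix.
#'
#' @param aa One-letter amino-acid code (see [rotamer_aas()]).
#' @param N,CA,C Backbone stub coordinates (length-3 vectors).
#' @param chi Numeric vector of chi angles, degrees (may be empty).
#' @return Data frame of side-chain atoms (`name`, `element`, `x`, `y`,
#'   `z`); zero rows for glycine.
#' @export
build_sidechain <- function(aa, N, CA, C, chi = numeric()) {
  zmat <- SIDECHAIN_ZMAT[[aa]]
  if (is.null(zmat) && aa != "G")
    stop("amino acid '", aa, "' not in the rotamer library")
  if (aa == "G")
    return(data.frame(name = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  pos <- list(N = N, CA = CA, C = C, CB = place_cb(N, CA, C))
  el <- c(CB = "C")
  chiv <- if (length(chi))
    as.list(setNames(chi, paste0("chi", seq_along(chi)))) else list()
  for (row in zmat) {
    tors <- row[8]
    phi <- if (grepl("^chi", tors)) {
      parts <- regmatches(tors, regexec("^(chi[0-9])([+-][0-9.]+)?$", tors))[[1]]
      base <- chiv[[parts[2]]]
      if (is.null(base)) stop("missing ", parts[2], " for ", aa)
      base + if (nzchar(parts[3])) as.numeric(parts[3]) else 0
    } else as.numeric(tors)
    pos[[row[1]]] <- nerf_place(pos[[row[3]]], pos[[row[4]]], pos[[row[5]]],
                                as.numeric(row[6]), as.numeric(row[7]), phi)
    el[row[1]] <- row[2]
  }
  nm <- setdiff(names(pos), c("N", "CA", "C"))
  xyz <- do.call(rbind, pos[nm])
  data.frame(name = nm, element = unname(el[nm]),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Enumerate the rotamers of an amino acid
#'
#' @param aa One-letter code.
#' @return Data frame with one row per rotamer (columns `chi1`, `chi2`, ...
#'   as applicable; a single chi-less row for G/A).
#' @export
rotamer_set <- function(aa) {
  rs <- ROTAMER_CHIS[[aa]]
  if (is.null(rs)) stop("amino acid '", aa, "' not in the rotamer library")
  rs
}
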