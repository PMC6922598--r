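# Parametric generation of C3-symmetric two-ring helical bundles via the
# Crick coiled-coil equations.
#
# A helix is a minor helix of radius R1 and frequency omega1 wound on a
# superhelix of radius R0 and frequency omega0; the pitch angle alpha links
# the superhelical rise to the 3.8 A consecutive-CA spacing and is solved
# numerically for each parameter set.

#' Crick parameters for one helix
#'
#' @param R0 Superhelical radius, Angstrom.
#' @param omega0 Superhelical frequency, degrees per residue (negative for a
#'   left-handed supercoil).
#' @param phi0 Superhelical phase, degrees.
#' @param R1 Minor-helix radius, Angstrom (2.26 for an alpha helix).
#' @param omega1 Minor-helix frequency, degrees per residue (+102.85 gives
#'   ~3.5 residues per turn and a 7-residue heptad repeat).
#' @param phi1 Minor-helix phase, degrees.
#' @param nres Number of residues.
#' @param z_offset Axial offset, Angstrom.
#' @param direction `"up"` or `"down"`; `"down"` mirrors z and reverses the
#'   residue order (antiparallel helix).
#' @return A `crick_params` list.
#' @export
crick_params <- function(R0 = 7, omega0 = -2.85, phi0 = 0, R1 = 2.26,
                         omega1 = 102.85, phi1 = 0, nres = 28, z_offset = 0,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(R0 >= 0, R1 >= 0, nres >= 1)
  structure(list(R0 = R0, omega0 = omega0, phi0 = phi0, R1 = R1,
                 omega1 = omega1, phi1 = phi1, nres = as.integer(nres),
                 z_offset = z_offset, direction = direction),
            class = "crick_params")
}

crick_xyz <- function(p, alpha) {
  t <- seq_len(p$nres) - 1
  w0 <- p$omega0 * pi / 180
  w1 <- p$omega1 * pi / 180
  f0 <- p$phi0 * pi / 180
  f1 <- p$phi1 * pi / 180
  a0 <- w0 * t + f0
  a1 <- w1 * t + f1
  x <- p$R0 * cos(a0) + p$R1 * cos(a0) * cos(a1) -
    p$R1 * cos(alpha) * sin(a0) * sin(a1)
  y <- p$R0 * sin(a0) + p$R1 * sin(a0) * cos(a1) +
    p$R1 * cos(alpha) * cos(a0) * sin(a1)
  rise <- if (abs(w0) < 1e-12) 0 else p$R0 * w0 / tan(alpha)
  z <- rise * t - p$R1 * sin(alpha) * sin(a1) + p$z_offset
  cbind(x = x, y = y, z = z)
}

#' Generate the CA trace of a Crick helix
#'
#' Evaluates the Crick equations for `p$nres` residues, solving the pitch
#' angle alpha by bisection so that the mean consecutive CA-CA distance is
#' 3.8 A.
#'
#' @param p A [crick_params()] object.
#' @return An `nres` x 3 coordinate matrix.
#' @export
crick_ca <- function(p) {
  stopifnot(inherits(p, "crick_params"))
  degenerate <- p$R1 < 1e-9 && abs(p$omega0) < 1e-12
  if (p$nres == 1 || degenerate) {
    xyz <- crick_xyz(p, pi / 4)
  } else {
    dmean <- function(alpha) {
      xyz <- crick_xyz(p, alpha)
      mean(sqrt(rowSums(diff(xyz)^2)))
    }
    lo <- 0.1 * pi / 180
    hi <- 89.9 * pi / 180
    # mean spacing decreases monotonically with alpha (rise ~ 1/tan(alpha))
    if ((dmean(lo) - 3.8) * (dmean(hi) - 3.8) > 0)
      stop("no alpha solution in (0, 90) degrees for these parameters")
    alpha <- uniroot(function(a) dmean(a) - 3.8, c(lo, hi), tol = 1e-10)$root
    xyz <- crick_xyz(p, alpha)
  }
  if (p$direction == "down") {
    xyz[, 3] <- -xyz[, 3] + 2 * p$z_offset
    xyz <- xyz[rev(seq_len(nrow(xyz))), , drop = FALSE]
  }
  unname(xyz)
}

#' Build N, CA, C, O backbone atoms on a CA trace
#'
#' Places ideal-geometry backbone atoms (N-CA 1.458 A, CA-C 1.523 A,
#' C-O 1.231 A) in local frames derived from the CA trace. The construction
#' is deterministic; for a straight trace at 3.8 A spacing the inter-residue
#' peptide C-N distance comes out at the ideal 1.33 A.
#'
#' @param ca An n x 3 CA coordinate matrix with n >= 2.
#' @param chain Chain id for the emitted residues.
#' @param resno_start First residue number.
#' @param resid Residue code assigned to every residue (backbone only).
#' @return A `c3_structure` fragment with 4 atoms per residue.
#' @export
ca_to_backbone <- function(ca, chain = "A", resno_start = 1L, resid = "GLY") {
  ca <- matrix(ca, ncol = 3)
  n <- nrow(ca)
  if (n < 2) stop("need at least 2 CA positions")
  dseg <- sqrt(rowSums(diff(ca)^2))
  if (any(dseg < 2.8 | dseg > 4.2))
    stop("consecutive CA distance outside [2.8, 4.2] A")
  # unit chord of each segment i: residue i -> i+1
  u <- t(apply(diff(ca), 1, unitv))
  # per-segment in-plane perpendicular from the change of direction, with a
  # deterministic fallback for straight stretches
  w <- matrix(NA_real_, n - 1, 3)
  for (i in seq_len(n - 1)) {
    uprev <- u[max(i - 1, 1), ]
    unextv <- u[min(i + 1, n - 1), ]
    c_vec <- uprev - unextv
    c_perp <- c_vec - sum(c_vec * u[i, ]) * u[i, ]
    w[i, ] <- if (vnorm(c_perp) > 1e-8) unitv(c_perp) else any_perp(u[i, ])
  }
  # both flanking atoms of one peptide unit are placed in the same segment
  # frame, with the half-angle solved per segment so the C-N bond is ideal
  Npos <- matrix(NA_real_, n, 3)
  Cpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1)) {
    a <- acos(pmin(1, (dseg[i] - 1.329) / (1.523 + 1.458)))
    Cpos[i, ] <- ca[i, ] + 1.523 * (cos(a) * u[i, ] + sin(a) * w[i, ])
    Npos[i + 1, ] <- ca[i + 1, ] + 1.458 * (-cos(a) * u[i, ] + sin(a) * w[i, ])
  }
  a1 <- acos((3.8 - 1.329) / (1.523 + 1.458))
  Npos[1, ] <- ca[1, ] + 1.458 * (-cos(a1) * u[1, ] + sin(a1) * w[1, ])
  Cpos[n, ] <- ca[n, ] + 1.523 * (cos(a1) * u[n - 1, ] + sin(a1) * w[n - 1, ])
  Nnext <- rbind(Npos[-1, , drop = FALSE],
                 Npos[n, , drop = FALSE] + u[n - 1, ] * 3.8)
  Opos <- t(vapply(seq_len(n), function(i) {
    u1 <- unitv(Cpos[i, ] - ca[i, ])
    u2 <- unitv(Cpos[i, ] - Nnext[i, ])
    Cpos[i, ] + 1.231 * unitv(u1 + u2)
  }, numeric(3)))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(record = "ATOM", name = c("N", "CA", "C", "O"), resid = resid,
               chain = chain, resno = resno_start + i - 1L,
               x = c(Npos[i, 1], ca[i, 1], Cpos[i, 1], Opos[i, 1]),
               y = c(Npos[i, 2], ca[i, 2], Cpos[i, 2], Opos[i, 2]),
               z = c(Npos[i, 3], ca[i, 3], Cpos[i, 3], Opos[i, 3]),
               occ = 1, b = 0, element = c("N", "C", "C", "O"),
               virtual = FALSE, stringsAsFactors = FALSE)
  }))
  new_structure(atoms)
}

#' Two-ring C3 bundle specification
#'
#' @param inner,outer [crick_params()] for the inner and outer helix of one
#'   monomer; `inner$R0` must be smaller than `outer$R0`. The outer helix is
#'   antiparallel (direction `"down"`) by default.
#' @param connect_rings Emit the monomer as a single chain with a
#'   residue-numbering gap marking the (unbuilt) inter-helix loop, rather
#'   than as two chains.
#' @return A `bundle_spec` list with `symmetry = 3`.
#' @export
bundle_spec <- function(inner = crick_params(R0 = 7, phi1 = 0),
                        outer = crick_params(R0 = 14, omega0 = -1.43,
                                             phi0 = 20, direction = "down"),
                        connect_rings = TRUE) {
  stopifnot(inherits(inner, "crick_params"), inherits(outer, "crick_params"))
  if (!(inner$R0 < outer$R0)) stop("inner R0 must be smaller than outer R0")
  structure(list(inner = inner, outer = outer, symmetry = 3L,
                 connect_rings = connect_rings), class = "bundle_spec")
}

#' Generate a C3 two-ring helical bundle
#'
#' Builds one monomer (inner + outer helix, each axially centered about
#' z = 0 unless a `z_offset` is given) and expands it to a trimer with
#' [apply_c3()]. The result is exactly C3-symmetric by construction. If any
#' inter-ring CA pair comes closer than 3 A a `ring_clash` warning distance
#' is recorded in the `warnings` attribute (not an error).
#'
#' @param spec A [bundle_spec()].
#' @return A `c3_structure` trimer (three chains, each two helices).
#' @export
generate_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  center_ca <- function(p) {
    xyz <- crick_ca(p)
    xyz[, 3] <- xyz[, 3] - mean(range(xyz[, 3]))
    xyz
  }
  ca_in <- center_ca(spec$inner)
  ca_out <- center_ca(spec$outer)
  bb_in <- ca_to_backbone(ca_in, chain = "A", resno_start = 1L)
  start_out <- if (spec$connect_rings) spec$inner$nres + 3L else 1L
  ch_out <- if (spec$connect_rings) "A" else "B"
  bb_out <- ca_to_backbone(ca_out, chain = ch_out, resno_start = start_out)
  mono <- new_structure(rbind(bb_in$atoms, bb_out$atoms))
  tri <- apply_c3(mono)
  dmin <- min(cross_dist(ca_in, ca_out))
  warn <- character()
  if (dmin < 3.0)
    warn <- sprintf("ring_clash: min inter-ring CA distance %.2f A", dmin)
  attr(tri, "warnings") <- warn
  attr(tri, "min_interring_ca") <- dmin
  tri
}
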