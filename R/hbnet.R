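# Geometric hydrogen-bond detection and connected-network search.
#
# Heavy-atom criterion (no explicit hydrogens): donor-acceptor distance in
# [2.5, 3.5] A and antecedent-donor-acceptor angle >= 90 degrees, where the
# antecedent is the donor's bonded heavy atom. Donor/acceptor capability is
# assigned from residue type and atom name.

# side-chain polar atom capabilities: donor (D), acceptor (A), or both (B),
# and the bonded antecedent atom used for the angle test
POLAR_SIDECHAIN <- list(
  SER = list(OG  = c("B", "CB")),
  THR = list(OG1 = c("B", "CB")),
  TYR = list(OH  = c("B", "CZ")),
  CYS = list(SG  = c("D", "CB")),
  ASN = list(OD1 = c("A", "CG"), ND2 = c("D", "CG")),
  GLN = list(OE1 = c("A", "CD"), NE2 = c("D", "CD")),
  ASP = list(OD1 = c("A", "CG"), OD2 = c("A", "CG")),
  GLU = list(OE1 = c("A", "CD"), OE2 = c("A", "CD")),
  LYS = list(NZ  = c("D", "CE")),
  ARG = list(NE  = c("D", "CD"), NH1 = c("D", "CZ"), NH2 = c("D", "CZ")),
  HIS = list(ND1 = c("B", "CG"), NE2 = c("B", "CD2")),
  TRP = list(NE1 = c("D", "CD1")))

# polar-atom table for a structure: one row per donor/acceptor-capable heavy
# atom, with its antecedent coordinates (NA when no antecedent, e.g. waters)
polar_atom_table <- function(s, include_ligand = TRUE, include_waters = FALSE,
                             include_backbone = TRUE) {
  a <- s$atoms
  a$row <- seq_len(nrow(a))
  rows <- list()
  add <- function(sel, role, ante_name) {
    if (!any(sel)) return()
    sub <- a[sel, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      ante <- c(NA_real_, NA_real_, NA_real_)
      if (!is.na(ante_name[i])) {
        j <- which(a$chain == sub$chain[i] & a$resno == sub$resno[i] &
                     a$name == ante_name[i] & a$record == sub$record[i])
        if (length(j)) ante <- as.numeric(a[j[1], c("x", "y", "z")])
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = sub$chain[i], resno = sub$resno[i], resid = sub$resid[i],
        name = sub$name[i], role = role[i],
        x = sub$x[i], y = sub$y[i], z = sub$z[i],
        ax = ante[1], ay = ante[2], az = ante[3],
        kind = if (sub$record[i] == "ATOM") "protein"
               else if (sub$resid[i] == "HOH") "water" else "ligand",
        stringsAsFactors = FALSE)
    }
  }
  p <- a$record == "ATOM" & !a$virtual
  if (include_backbone) {
    add(p & a$name == "N", rep("D", sum(p & a$name == "N")),
        ifelse(rep(TRUE, sum(p & a$name == "N")), "CA", "CA"))
    add(p & a$name == "O", rep("A", sum(p & a$name == "O")),
        rep("C", sum(p & a$name == "O")))
  }
  for (res in names(POLAR_SIDECHAIN)) {
    for (nm in names(POLAR_SIDECHAIN[[res]])) {
      cap <- POLAR_SIDECHAIN[[res]][[nm]]
      sel <- p & a$resid == res & a$name == nm
      add(sel, rep(cap[1], sum(sel)), rep(cap[2], sum(sel)))
    }
  }
  if (include_waters) {
    sel <- a$record == "HETATM" & a$resid == "HOH" & a$element == "O"
    add(sel, rep("B", sum(sel)), rep(NA_character_, sum(sel)))
  }
  if (include_ligand) {
    sel <- a$record == "HETATM" & a$resid != "HOH" & !a$virtual &
      a$element %in% c("N", "O")
    add(sel, rep("B", sum(sel)), rep(NA_character_, sum(sel)))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

hb_geometry_ok <- function(don, acc, dmin = 2.5, dmax = 3.5, amin = 90) {
  dvec <- c(acc$x - don$x, acc$y - don$y, acc$z - don$z)
  d <- vnorm(dvec)
  if (d < dmin || d > dmax) return(NULL)
  ang <- NA_real_
  if (!is.na(don$ax)) {
    avec <- c(don$ax - don$x, don$ay - don$y, don$az - don$z)
    ang <- acos(pmin(1, pmax(-1, sum(avec * dvec) / (vnorm(avec) * d)))) * 180 / pi
    if (ang < amin) return(NULL)
  }
  list(distance = d, angle = ang)
}

#' Detect hydrogen bonds by heavy-atom geometry
#'
#' Tests every donor-capable N/O against every acceptor-capable N/O
#' (both directions for atoms that can do both). A bond requires
#' donor-acceptor distance in `[2.5, 3.5]` A and an
#' antecedent-donor-acceptor angle of at least 90 degrees; atoms without a
#' bonded antecedent (waters, ligand polar atoms) pass the angle test by
#' construction. Output ordering is deterministic (chain, residue, atom).
#'
#' @param s A `c3_structure`.
#' @param include_ligand Include ligand N/O atoms as polar nodes?
#' @param include_waters Include water oxygens? Off by default (matching
#'   design-stage evaluation); turn on for crystal-structure evaluation.
#' @param dmin,dmax,angle_min Geometry bounds.
#' @return A data frame of bonds: donor/acceptor chain, residue, atom,
#'   `distance` (A) and `angle` (degrees, NA when no antecedent).
#' @export
detect_hbonds <- function(s, include_ligand = TRUE, include_waters = FALSE,
                          dmin = 2.5, dmax = 3.5, angle_min = 90) {
  if (nrow(s$atoms) == 0) stop("empty structure")
  tab <- polar_atom_table(s, include_ligand, include_waters)
  if (is.null(tab)) return(empty_hbond_frame())
  tab <- tab[order(tab$chain, tab$resno, tab$name), , drop = FALSE]
  don_idx <- which(tab$role %in% c("D", "B"))
  acc_idx <- which(tab$role %in% c("A", "B"))
  if (!length(don_idx) || !length(acc_idx)) return(empty_hbond_frame())
  dmat <- cross_dist(as.matrix(tab[don_idx, c("x", "y", "z")]),
                     as.matrix(tab[acc_idx, c("x", "y", "z")]))
  cand <- which(dmat >= dmin & dmat <= dmax, arr.ind = TRUE)
  out <- list()
  if (nrow(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- don_idx[cand[k, 1]]
      j <- acc_idx[cand[k, 2]]
      if (i == j) next
      same_res <- tab$chain[i] == tab$chain[j] & tab$resno[i] == tab$resno[j] &
        tab$kind[i] == tab$kind[j]
      if (same_res && tab$kind[i] != "water") next
      g <- hb_geometry_ok(tab[i, ], tab[j, ], dmin, dmax, angle_min)
      if (is.null(g)) next
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = tab$chain[i], donor_resno = tab$resno[i],
        donor_resid = tab$resid[i], donor_atom = tab$name[i],
        donor_kind = tab$kind[i],
        acceptor_chain = tab$chain[j], acceptor_resno = tab$resno[j],
        acceptor_resid = tab$resid[j], acceptor_atom = tab$name[j],
        acceptor_kind = tab$kind[j],
        distance = g$distance, angle = g$angle, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hbond_frame())
  res <- do.call(rbind, out)
  res[order(res$donor_chain, res$donor_resno, res$donor_atom,
            res$acceptor_chain, res$acceptor_resno, res$acceptor_atom), ,
      drop = FALSE]
}

empty_hbond_frame <- function() {
  data.frame(donor_chain = character(), donor_resno = integer(),
             donor_resid = character(), donor_atom = character(),
             donor_kind = character(), acceptor_chain = character(),
             acceptor_resno = integer(), acceptor_resid = character(),
             acceptor_atom = character(), acceptor_kind = character(),
             distance = numeric(), angle = numeric(), stringsAsFactors = FALSE)
}

hb_node_id <- function(kind, chain, resno) {
  ifelse(kind == "protein", paste0(chain, ":", resno),
         paste0(kind, ":", chain, ":", resno))
}

#' Find connected hydrogen-bond networks
#'
#' Builds the graph whose nodes are polar groups (one node per residue,
#' water, or ligand) and whose edges are detected hydrogen bonds, and
#' returns its connected components with at least `min_size` members,
#' sorted by decreasing size then lexicographically.
#'
#' @param bonds A bond data frame from [detect_hbonds()].
#' @param min_size Minimum component size (>= 2).
#' @return A list of `hbond_network` objects, each with `members` (node
#'   ids), `chains` (protein chains represented), `bonds` (the edge rows)
#'   and `spans_interface`.
#' @export
find_networks <- function(bonds, min_size = 3) {
  stopifnot(min_size >= 2)
  if (nrow(bonds) == 0) return(list())
  from <- hb_node_id(bonds$donor_kind, bonds$donor_chain, bonds$donor_resno)
  to <- hb_node_id(bonds$acceptor_kind, bonds$acceptor_chain, bonds$acceptor_resno)
  keep <- from != to
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep]), directed = FALSE)
  comp <- igraph::components(g)
  nets <- lapply(seq_len(comp$no), function(k) {
    members <- sort(names(comp$membership)[comp$membership == k])
    in_net <- (from %in% members) | (to %in% members)
    net <- structure(list(members = members,
                          chains = sort(unique(c(
                            bonds$donor_chain[in_net & bonds$donor_kind == "protein"],
                            bonds$acceptor_chain[in_net & bonds$acceptor_kind == "protein"]))),
                          bonds = bonds[in_net, , drop = FALSE]),
                     class = "hbond_network")
    net$spans_interface <- spans_interface(net)
    net
  })
  nets <- nets[vapply(nets, function(n) length(n$members), 1L) >= min_size]
  ord <- order(-vapply(nets, function(n) length(n$members), 1L),
               vapply(nets, function(n) n$members[1], ""))
  nets[ord]
}

#' Does a network span a monomer-monomer interface?
#'
#' TRUE iff the network's protein members come from at least two distinct
#' chains; ligand and water nodes are ignored for chain counting.
#'
#' @param net An `hbond_network`.
#' @return Logical flag.
#' @export
spans_interface <- function(net) {
  stopifnot(inherits(net, "hbond_network"))
  length(net$chains) >= 2
}

#' @export
print.hbond_network <- function(x, ...) {
  cat(sprintf("hbond_network: %d members (%s), %d bonds, spans_interface=%s\n",
              length(x$members), paste(x$members, collapse = " "),
              nrow(x$bonds), x$spans_interface))
  invisible(x)
}

#' Count buried unsatisfied polar atoms
#'
#' Counts polar heavy atoms that are buried (SASA below `burial_cut`) and
#' participate in no detected hydrogen bond. When `members` is given, only
#' atoms of those (chain, residue) nodes are considered.
#'
#' @param s A `c3_structure`.
#' @param atom_sasa Per-atom SASA vector from [sasa()] (same atom order as
#'   `s$atoms`); computed on the fly if `NULL`.
#' @param bonds Bond data frame from [detect_hbonds()]; detected on the fly
#'   if `NULL`.
#' @param members Optional character vector of `chain:resno` node ids.
#' @param burial_cut SASA threshold in A^2 (default 5).
#' @param ... Passed to [detect_hbonds()] when bonds are detected here.
#' @return Integer count.
#' @export
count_unsatisfied <- function(s, atom_sasa = NULL, bonds = NULL,
                              members = NULL, burial_cut = 5, ...) {
  if (is.null(atom_sasa)) atom_sasa <- sasa(s)
  if (is.null(bonds)) bonds <- detect_hbonds(s, ...)
  tab <- polar_atom_table(s, include_ligand = TRUE, include_waters = TRUE)
  if (is.null(tab)) return(0L)
  if (!is.null(members)) {
    ids <- hb_node_id(tab$kind, tab$chain, tab$resno)
    tab <- tab[ids %in% members, , drop = FALSE]
  }
  if (nrow(tab) == 0) return(0L)
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$name, a$record)
  tkey <- paste(tab$chain, tab$resno, tab$name,
                ifelse(tab$kind == "protein", "ATOM", "HETATM"))
  tab$sasa <- atom_sasa[match(tkey, key)]
  bonded <- unique(c(paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom),
                     paste(bonds$acceptor_chain, bonds$acceptor_resno,
                           bonds$acceptor_atom)))
  unsat <- !(paste(tab$chain, tab$resno, tab$name) %in% bonded) &
    !is.na(tab$sasa) & tab$sasa < burial_cut
  sum(unsat)
}
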