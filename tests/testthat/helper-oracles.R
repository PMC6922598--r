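# Independent oracles used to cross-check the package implementations.

# connected components by breadth-first search over an edge list
# (data frame with columns from, to); returns a list of sorted member sets
bfs_components <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- lapply(setNames(nodes, nodes), function(n)
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n])))
  seen <- character()
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

# quaternion (Horn) least-squares superposition rmsd of A onto B
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  S <- crossprod(A0, B0)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# a random single-chain monomer structure for symmetry property tests
random_monomer <- function(n = 12, seed = 1) {
  set.seed(seed)
  new_structure(data.frame(
    record = "ATOM", name = paste0("CA", NULL),
    resid = "GLY", chain = "A", resno = seq_len(n),
    x = runif(n, -10, 10), y = runif(n, -10, 10), z = runif(n, -10, 10),
    occ = 1, b = 0, element = "C", virtual = FALSE,
    stringsAsFactors = FALSE))
}

# a one-atom c3_structure helper
atom_row <- function(name = "CA", resid = "GLY", chain = "A", resno = 1L,
                     x = 0, y = 0, z = 0, element = "C", record = "ATOM",
                     virtual = FALSE) {
  data.frame(record = record, name = name, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, occ = 1, b = 0,
             element = element, virtual = virtual, stringsAsFactors = FALSE)
}

# per-asymmetric-unit packing energy computed directly from atom sets with
# the exported pair_energy (reference route, independent of the packer's
# vectorized kernel): candidates is a list (positions) of lists (rotamers)
# of side-chain atom data frames; ctx_list gives each position's backbone
# context; lig_tab the full-ligand atom table
asu_energy_direct <- function(assign, candidates, ctx_list, lig_tab, params) {
  rot <- function(df, ang) {
    if (nrow(df) == 0) return(df)
    xyz <- rotate_coords(as.matrix(df[, c("x", "y", "z")]), ang)
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  n <- length(assign)
  e <- 0
  for (i in seq_len(n)) {
    sc <- candidates[[i]][[assign[i]]]
    e <- e + pair_energy(sc, ctx_list[[i]], params) +
      pair_energy(sc, lig_tab, params) / 3 +
      params$reference_energies[[attr(sc, "aa")]] +
      pair_energy(sc, rot(sc, 120), params)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sci <- candidates[[i]][[assign[i]]]
      scj <- candidates[[j]][[assign[j]]]
      e <- e + pair_energy(sci, scj, params) +
        pair_energy(sci, rot(scj, 120), params) +
        pair_energy(sci, rot(scj, 240), params)
    }
  }
  e
}

rotate_coords <- c3bind:::rotate_coords
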