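# Independent numerical oracles and fixture builders used across the suite.

# central finite-difference gradient of the cluster energy in a fixed chart
fd_gradient <- function(structure, interactions, repulsion = NULL, h = 1e-6) {
  ndof <- sum(vapply(structure$blocks,
                     function(b) if (b$block$isotropic) 3L else 6L,
                     integer(1)))
  vapply(seq_len(ndof), function(k) {
    e <- rep(0, ndof); e[k] <- h
    (cluster_energy(displace_structure(structure, e), interactions, repulsion) -
       cluster_energy(displace_structure(structure, -e), interactions, repulsion)) / (2 * h)
  }, numeric(1))
}

# chart-consistent second differences of the energy (the Hessian oracle)
fd_hessian <- function(structure, interactions, repulsion = NULL, h = 1e-4) {
  ndof <- sum(vapply(structure$blocks,
                     function(b) if (b$block$isotropic) 3L else 6L,
                     integer(1)))
  E <- function(xi) cluster_energy(displace_structure(structure, xi),
                                   interactions, repulsion)
  H <- matrix(0, ndof, ndof)
  for (j in seq_len(ndof)) for (k in j:ndof) {
    ej <- rep(0, ndof); ej[j] <- h
    ek <- rep(0, ndof); ek[k] <- h
    H[j, k] <- H[k, j] <-
      (E(ej + ek) - E(ej - ek) - E(-ej + ek) + E(-ej - ek)) / (4 * h^2)
  }
  H
}

# cluster of identical isotropic spheres with central attraction sites
make_iso_cluster <- function(positions, E_b = 3, alpha = 6, r0 = 1,
                             label = "iso") {
  blk <- building_block("S", c(0, 0, 0), 1, patches = c(0, 0, 0),
                        patch_types = "s", isotropic = TRUE)
  tbl <- interaction_table(
    data.frame(type_a = "s", type_b = "s", p_contact = 1),
    epsilon = E_b, alpha = alpha, r0 = r0)
  s <- cluster_structure(lapply(seq_len(nrow(positions)), function(i) {
    list(block = blk, pose = pose(positions[i, ]))
  }), label = label)
  list(structure = s, interactions = tbl)
}

tri_positions <- function(a = 1) {
  rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
}

tet_positions <- function(a = 1) {
  rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
        c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
}

# labeled brute-force count of block-to-cluster assignments for the
# two-species dimerizing system (independent of the closed formulas)
brute_dimer_assignments <- function(Nb, Nw, Nd) {
  pick <- function(k, from) if (k == 0) list(integer(0)) else
    utils::combn(from, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  count <- 0L
  for (bs in pick(Nd, seq_len(Nb))) for (ws in pick(Nd, seq_len(Nw))) {
    count <- count + length(perms(ws))   # one per labeled pairing
  }
  count
}

# a synthetic two-chain PDB file (text); chain A: 3 residues, chain B: 4
write_synthetic_pdb <- function(path) {
  fmt <- function(serial, name, resname, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, name, resname, chain, resno, x, y, z)
  }
  lines <- c(
    fmt(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    fmt(2, " CB ", "ALA", "A", 1, 2, 0, 0),
    fmt(3, " CA ", "GLY", "A", 2, 5, 0, 0),
    fmt(4, " CA ", "SER", "A", 3, 5, 5, 0),
    fmt(5, " CB ", "SER", "A", 3, 5, 7, 0),
    fmt(6, " CA ", "LEU", "B", 1, 10, 0, 0),
    fmt(7, " CA ", "LYS", "B", 2, 10, 5, 0),
    fmt(8, " CA ", "TRP", "B", 3, 10, 10, 0),
    fmt(9, " CA ", "PHE", "B", 4, 10, 15, 0),
    "END")
  writeLines(lines, path)
  path
}

# synthetic three-species complex with interfaces matching given totals
make_trap_like_model <- function(epsilon = 1,
                                 totals = c(MN = 15.7, NO = 6.7, MO = 1.9)) {
  sph <- function(ox) rbind(c(ox, 0, 0), c(ox, 1, 0), c(ox, 0, 1))
  M <- building_block("M", sph(0), 1)
  N <- building_block("N", sph(1.2), 1)
  O <- building_block("O", sph(0.6) + matrix(rep(c(0, 2, 0), 3), ncol = 3,
                                             byrow = TRUE), 1)
  split3 <- function(tot) tot * c(0.5, 0.3, 0.2)
  pmn <- place_contact_patches(M, N, data.frame(res_a = 1:3, res_b = 1:3,
                                                p_contact = split3(totals["MN"])),
                               epsilon = epsilon, prefix = "mn")
  M <- pmn$block_a; N <- pmn$block_b
  pno <- place_contact_patches(N, O, data.frame(res_a = 1:3, res_b = 1:3,
                                                p_contact = split3(totals["NO"])),
                               epsilon = epsilon, prefix = "no")
  N <- pno$block_a; O <- pno$block_b
  pmo <- place_contact_patches(M, O, data.frame(res_a = 1:3, res_b = 1:3,
                                                p_contact = split3(totals["MO"])),
                               epsilon = epsilon, prefix = "mo")
  M <- pmo$block_a; O <- pmo$block_b
  pairs <- rbind(pmn$interactions$pairs, pno$interactions$pairs,
                 pmo$interactions$pairs)
  tbl <- interaction_table(pairs, epsilon = epsilon, alpha = 2, r0 = 0)
  mk <- function(blocks, label) cluster_structure(
    lapply(blocks, function(b) list(block = b, pose = pose())), label = label)
  list(
    species = list(M = M, N = N, O = O), interactions = tbl,
    structures = list(mk(list(M), "M"), mk(list(N), "N"), mk(list(O), "O"),
                      mk(list(M, N), "MN"), mk(list(N, O), "NO"),
                      mk(list(M, O), "MO"), mk(list(M, N, O), "MNO")),
    interface_energy = c(MN = pmn$interface_energy,
                         NO = pno$interface_energy,
                         MO = pmo$interface_energy))
}
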