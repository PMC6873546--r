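# Hand-constructed fixtures shared across tests. Everything is built in
# code; no binary data.

# a structure from bare coordinates: one single-center residue per row
toy_structure <- function(xyz, codes, id = "toy", atom_name = "CA",
                          res_idx = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (is.null(res_idx)) res_idx <- seq_len(nrow(xyz)) - 1L
  protein_structure(id, "A", data.frame(
    res_idx = res_idx, res_code = codes,
    atom_name = atom_name, element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, stringsAsFactors = FALSE))
}

# minimal PDB text: two alanine residues with N/CA atoms
write_minimal_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       2.000   1.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       3.400   1.200   0.000  1.00  0.00           C",
    "TER", "END"), path)
  path
}

# altloc fixture: CA with conformers A (occ 0.60) and B (occ 0.40)
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.40  0.00           C",
    "ATOM      4  CA  GLY A   2       3.400   1.200   0.000  1.00  0.00           C",
    "TER", "END"), path)
  path
}

# selenomethionine as HETATM, plus a standard residue
write_mse_pdb <- function(path) {
  writeLines(c(
    "HETATM    1  CA  MSE A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 SE   MSE A   1       1.000   1.000   0.000  1.00  0.00          SE",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "TER", "END"), path)
  path
}

# brute-force contact oracle: double loop with the same filters,
# tessellation off
brute_contacts <- function(s, scheme) {
  a <- pripot:::.scheme_atoms(s, scheme)
  out <- NULL
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- sqrt(sum((unlist(a[i, c("x", "y", "z")]) -
                     unlist(a[j, c("x", "y", "z")]))^2))
    if (d >= scheme$cutoff) next
    if (abs(a$res_idx[i] - a$res_idx[j]) <= scheme$min_seq_sep) next
    out <- rbind(out, data.frame(res_i = a$res_idx[i],
                                 res_j = a$res_idx[j],
                                 code_i = a$res_code[i],
                                 code_j = a$res_code[j],
                                 atom_i = i, atom_j = j, distance = d))
  }
  if (is.null(out)) return(pripot:::.empty_contacts())
  out[order(out$res_i, out$res_j, out$atom_i, out$atom_j), , drop = FALSE]
}

# brute-force energy vector oracle: independent loop over atom pairs
brute_energy_vector <- function(s, table) {
  ct <- brute_contacts(s, table$scheme)
  labs <- rownames(table$energies)
  v <- stats::setNames(numeric(length(labs)), labs)
  for (r in seq_len(nrow(ct))) {
    k <- pair_index(ct$code_i[r], ct$code_j[r], table$alphabet)
    v[k] <- v[k] + pair_energy(table, ct$code_i[r], ct$code_j[r],
                               ct$distance[r])
  }
  v
}

# a decoy set with externally fixed RMSDs, for metric unit tests; the
# shared native is cached since only the RMSD labels matter
.fix_env <- new.env()
fixed_rmsd_set <- function(rmsd) {
  if (is.null(.fix_env$nat))
    .fix_env$nat <- generate_chain(chain_spec(10, seed = 90), id = "nat")
  decoys <- lapply(seq_along(rmsd), function(i) {
    s <- .fix_env$nat
    s$id <- paste0("d", i)
    s
  })
  decoy_set("t1", .fix_env$nat, decoys, rmsd)
}

# a small trained potential shared by scoring tests
small_potential <- function(seed = 11, n = 6, len = 20) {
  chains <- lapply(seq_len(n), function(i)
    generate_chain(chain_spec(len, seed = seed + i),
                   id = sprintf("fix%02d", i)))
  kbp(chains, contact_scheme(15, 2, atom_mode = "single-center"),
      distance_binning(0, 15, 3), reference_state("power-law", 2),
      pseudocount = 0.1)
}
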