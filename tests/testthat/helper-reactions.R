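# Shared toy reactions and utilities used across the suite.

ETHANE_DEHYDRO <- paste0(
  "[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]>>",
  "[C:1]([H:4])([H:5])=[C:2]([H:7])[H:8].[H:3][H:6]")

H_TRANSFER <- paste0(
  "[C:1]([H:2])([H:3])([H:4])[H:5].[O:6][H:7]>>",
  "[C:1]([H:2])([H:3])[H:4].[H:5][O:6][H:7]")

WATER_SWAP <- "[O:1]([H:2])[H:3]>>[O:1]([H:3])[H:2]"

# small balanced homolysis-style reactions with <= 6 atoms per side
TINY_RXNS <- c(
  "[O:1]([H:2])[H:3]>>[O:1][H:2].[H:3]",
  "[H:1][H:2]>>[H:1].[H:2]",
  "[N:1]([H:2])([H:3])[H:4]>>[N:1]([H:2])[H:3].[H:4]",
  "[C:1]([H:2])([H:3])[H:4]>>[C:1]([H:2])[H:3].[H:4]",
  "[O:1]=[O:2].[H:3][H:4]>>[O:1]([H:3])[O:2][H:4]",
  "[C:1]([H:2])([H:3])=[O:4].[H:5][H:6]>>[C:1]([H:2])([H:3])([H:5])[O:4][H:6]")

# consistently relabel the atom-map indices of a reaction SMILES
relabel_smiles <- function(s, perm) {
  toks <- regmatches(s, gregexpr(":[0-9]+\\]", s))[[1]]
  maps <- unique(as.integer(gsub("[^0-9]", "", toks)))
  out <- gsub(":([0-9]+)\\]", ":#\\1]", s)
  for (m in maps)
    out <- gsub(paste0(":#", m, "]"), paste0(":", perm[m], "]"), out,
                fixed = TRUE)
  out
}

random_rigid_motion <- function(xyz) {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(xyz %*% Q, 2, rnorm(3, sd = 3), "+")
}

# a random tiny record with optional random extras attached
tiny_record <- function(extra_atom = 0, extra_mol = 0) {
  g <- build_cgr(parse_reaction(sample(TINY_RXNS, 1)))
  if (extra_atom > 0)
    g <- attach_extra(g, extra_feature_set(
      g, atom_r = matrix(rnorm(g$n_atoms * extra_atom), g$n_atoms),
      atom_p = matrix(rnorm(g$n_atoms * extra_atom), g$n_atoms)))
  if (extra_mol > 0)
    g <- attach_extra(g, extra_feature_set(
      g, mol_r = rnorm(extra_mol), mol_p = rnorm(extra_mol)))
  list(cgr = g, y = rnorm(1), id = paste0("t", sample.int(1e6, 1)))
}
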