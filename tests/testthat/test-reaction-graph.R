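test_that("atom-mapped reaction SMILES parse with verified map bijection", {
  rxn <- parse_reaction(ETHANE_DEHYDRO)
  expect_equal(nrow(rxn$reactant$atoms), 8L)
  expect_equal(nrow(rxn$product$atoms), 8L)
  expect_setequal(rxn$reactant$atoms$map_index, 1:8)
  expect_setequal(rxn$product$atoms$map_index, 1:8)

  idr <- parse_reaction(paste0(
    "[C:1]([H:2])([H:3])([H:4])[H:5]>>[C:1]([H:2])([H:3])([H:4])[H:5]"))
  expect_identical(idr$reactant$atoms[order(idr$reactant$atoms$map_index), ],
                   idr$product$atoms[order(idr$product$atoms$map_index), ],
                   ignore_attr = TRUE)
})

test_that("parser rejects malformed, unmapped and unbalanced input", {
  expect_error(parse_reaction("not a smiles"), class = "cgrnn_parse_error")
  expect_error(parse_reaction("[C:1]([H:2]>>[C:1][H:2]"),
               class = "cgrnn_parse_error")
  expect_error(parse_reaction("[CH4:1].[H:2]>>[CH4:1].[H:2].[H:2]"),
               class = "cgrnn_mapping_error")
  expect_error(parse_reaction("[C:1]([H:2])([H:3])[H:4].C>>[C:1]([H:2])([H:3])[H:4].C"),
               class = "cgrnn_mapping_error")
  # hydrogen count differs between sides
  expect_error(parse_reaction("[CH4:1]>>[CH3:1]"),
               class = "cgrnn_balance_error")
  # map sets differ
  expect_error(parse_reaction("[O:1]([H:2])[H:3]>>[O:1]([H:2])[H:4]"),
               class = "cgrnn_balance_error")
  # element changes for a mapped atom
  expect_error(parse_reaction("[O:1]([H:2])[H:3]>>[N:1]([H:2])[H:3]"),
               class = "cgrnn_balance_error")
})

test_that("default atom features encode the documented slots", {
  rxn <- parse_reaction("[CH4:1]>>[CH4:1]")
  f <- default_atom_features(rxn$reactant$atoms)
  expect_equal(ncol(f), atom_feature_width())
  # mass slot is atomic mass / 100
  expect_equal(f[1, ncol(f)], 0.12011)
  # aromaticity slot is 0 for methane
  expect_equal(f[1, ncol(f) - 1L], 0)

  # atoms differing only in formal charge differ only in the charge block
  a1 <- parse_reaction("[N:1]([H:2])([H:3])[H:4]>>[N:1]([H:2])([H:3])[H:4]")
  a2 <- parse_reaction("[N+:1]([H:2])([H:3])[H:4]>>[N+:1]([H:2])([H:3])[H:4]")
  f1 <- default_atom_features(a1$reactant$atoms)[1, ]
  f2 <- default_atom_features(a2$reactant$atoms)[1, ]
  ne <- length(default_elements())
  charge_block <- ne + 6L + 1:7
  expect_true(any(f1[charge_block] != f2[charge_block]))
  expect_equal(f1[-charge_block], f2[-charge_block])

  expect_error(
    default_atom_features(data.frame(element = "Xe", degree = 0L,
                                     formal_charge = 0L, hybridization = "SP3",
                                     n_hydrogens = 0L, aromatic = FALSE,
                                     mass = 131.29)),
    class = "cgrnn_element_error")
})

test_that("default bond features: absent bond is the zero vector; slots localize", {
  expect_equal(default_bond_features(NULL),
               matrix(0, 0, bond_feature_width()))
  single <- data.frame(a = 1L, b = 2L, order = "single", conjugated = FALSE,
                       ring_size = NA_integer_)
  f <- default_bond_features(single)
  expect_equal(sum(f != 0), 1L)     # exactly the single-order slot
  expect_equal(f[1, 1], 1)

  # aromatic bond in a 6-ring: aromatic slot plus ring flag and size-6 slot
  ring <- parse_reaction(paste0(
    "[c:1]1([H:7])[c:2]([H:8])[c:3]([H:9])[c:4]([H:10])[c:5]([H:11])[c:6]1[H:12]>>",
    "[c:1]1([H:7])[c:2]([H:8])[c:3]([H:9])[c:4]([H:10])[c:5]([H:11])[c:6]1[H:12]"))
  rb <- ring$reactant$bonds
  arom <- rb[rb$order == "aromatic", ][1, ]
  fa <- default_bond_features(arom)
  expect_equal(fa[1, 4], 1)                      # aromatic order slot
  expect_equal(arom$ring_size, 6L)
  expect_equal(fa[1, 6], 1)                      # in-ring flag
  expect_equal(fa[1, 6 + 4], 1)                  # size-6 slot (3..8 block)
})

test_that("CGR edge set is the union of both sides with per-side halves", {
  g <- build_cgr(parse_reaction(ETHANE_DEHYDRO))
  # union of bond sets: 5 shared, C1-H3 and C2-H6 reactant-only, H3-H6
  # product-only, C1-C2 order-changed -> 8 undirected edges
  expect_equal(nrow(g$edges), 8L)
  pairs <- paste(g$map_index[g$edges[, 1]], g$map_index[g$edges[, 2]], sep = "-")
  expect_setequal(pairs, c("1-2", "1-3", "1-4", "1-5", "2-6", "2-7", "2-8",
                           "3-6"))
  bw <- bond_feature_width()
  # reactant-only bond C1-H3: product half all zero
  i13 <- which(pairs == "1-3")
  expect_true(any(g$bond_features[i13, 1:bw] != 0))
  expect_equal(g$bond_features[i13, bw + 1:bw], rep(0, bw))
  # product-only bond H3-H6: reactant half all zero
  i36 <- which(pairs == "3-6")
  expect_equal(g$bond_features[i36, 1:bw], rep(0, bw))
  expect_true(any(g$bond_features[i36, bw + 1:bw] != 0))
  # C1-C2 changes order: single slot on reactant half, double slot on product
  i12 <- which(pairs == "1-2")
  expect_equal(g$bond_features[i12, 1], 1)
  expect_equal(g$bond_features[i12, bw + 2], 1)
})

test_that("identity reaction gives equal halves everywhere", {
  g <- build_cgr(parse_reaction(
    "[C:1]([H:2])([H:3])([H:4])[H:5]>>[C:1]([H:2])([H:3])([H:4])[H:5]"))
  aw <- atom_feature_width(); bw <- bond_feature_width()
  expect_equal(g$atom_features[, 1:aw], g$atom_features[, aw + 1:aw])
  expect_equal(g$bond_features[, 1:bw], g$bond_features[, bw + 1:bw])
})

test_that("consistent atom relabeling permutes rows and preserves edges", {
  set.seed(21)
  for (s in c(ETHANE_DEHYDRO, H_TRANSFER)) {
    g <- build_cgr(parse_reaction(s))
    n <- g$n_atoms
    perm <- sample(n)   # new map of old index m is perm[m]
    g2 <- build_cgr(parse_reaction(relabel_smiles(s, perm)))
    # row for old map m now sits at position perm[m]
    expect_equal(g2$atom_features[perm[g$map_index], ], g$atom_features)
    ek <- function(gg) sort(apply(gg$bond_features, 1, paste, collapse = ","))
    expect_equal(ek(g2), ek(g))
  }
})

test_that("directed edge features concatenate source atom and bond blocks", {
  g <- build_cgr(parse_reaction(H_TRANSFER))
  de <- directed_edge_features(g)
  aw <- ncol(g$atom_features); bw <- ncol(g$bond_features)
  expect_equal(ncol(de$features), aw + bw)
  expect_equal(length(de$src), 2L * nrow(g$edges))
  for (k in seq_along(de$src)) {
    expect_equal(de$features[k, 1:aw], g$atom_features[de$src[k], ])
    expect_equal(de$features[k, aw + 1:bw], g$bond_features[de$eid[k], ])
    # reverse edge shares the bond block, swaps the atom block
    r <- de$rev[k]
    expect_equal(de$src[r], de$dst[k])
    expect_equal(de$features[r, aw + 1:bw], de$features[k, aw + 1:bw])
  }
})
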