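check_partition <- function(sp, ids) {
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
}

test_that("random split: 90/5/5 sizes, determinism, degenerate fractions", {
  ids <- sprintf("r%03d", 1:100)
  sp <- random_split(ids, seed = 42)
  check_partition(sp, ids)
  expect_length(sp$train, 90)
  expect_length(sp$validation, 5)
  expect_length(sp$test, 5)
  expect_identical(random_split(ids, seed = 42), sp)
  expect_false(identical(random_split(ids, seed = 43)$train, sp$train))
  all_train <- random_split(ids, fractions = c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 100)
  expect_error(random_split(ids, fractions = c(0.5, 0.2, 0.2), seed = 1),
               class = "cgrnn_config_error")
})

test_that("reaction core keys capture changed bonds and survive relabeling", {
  rxn <- parse_reaction(ETHANE_DEHYDRO)
  key <- reaction_core_key(rxn)
  # the core is {C1,C2,H3,H6} with broken C-H x2, changed C-C, formed H-H:
  # two C and two H labels, four core edges
  expect_equal(lengths(regmatches(key, gregexpr("\\|", key))), 8L)  # 4 edges
  expect_true(grepl("r:single", key))    # broken bonds
  expect_true(grepl("p:single", key))    # formed H-H
  expect_true(grepl("rp:single>double", key))  # order change

  set.seed(9)
  perm <- sample(8)
  rxn2 <- parse_reaction(relabel_smiles(ETHANE_DEHYDRO, perm))
  expect_equal(as.character(reaction_core_key(rxn2)), as.character(key))

  expect_error(reaction_core_key(parse_reaction(
    "[O:1]([H:2])[H:3]>>[O:1]([H:2])[H:3]")), class = "cgrnn_core_error")
})

test_that("core split never separates reactions sharing a core", {
  cfg <- fixture_config(n_reactions = 120, sigma = 0, seed = 5)
  recs <- generate_fixtures(cfg)
  rxns <- lapply(recs, `[[`, "reaction")
  ids <- sapply(recs, `[[`, "id")
  sp <- core_split(rxns, seed = 11)
  check_partition(sp, ids)
  keys <- sapply(rxns, function(r) as.character(reaction_core_key(r)))
  names(keys) <- ids
  expect_length(intersect(keys[sp$train], keys[sp$validation]), 0)
  expect_length(intersect(keys[sp$train], keys[sp$test]), 0)
  expect_length(intersect(keys[sp$validation], keys[sp$test]), 0)
  expect_identical(core_split(rxns, seed = 11)$train, sp$train)
})

test_that("a dominant core cluster lands in train with deviations reported", {
  # one cluster holds ~96% of the data: it cannot fit the held-out deficits
  base <- parse_reaction(H_TRANSFER)
  rxns <- c(replicate(96, base, simplify = FALSE),
            lapply(generate_fixtures(
              fixture_config(n_reactions = 4, sigma = 0, seed = 2)),
              `[[`, "reaction"))
  for (i in 1:96) rxns[[i]]$id <- sprintf("dup%02d", i)
  sp <- core_split(rxns, seed = 3)
  expect_true(all(sprintf("dup%02d", 1:96) %in% sp$train))
  expect_true(sp$provenance$realized_fractions[1] >= 0.96)
})

test_that("unique cores behave like a random split over singletons", {
  cfg <- fixture_config(n_reactions = 40, sigma = 0, seed = 6)
  recs <- generate_fixtures(cfg)
  rxns <- lapply(recs, `[[`, "reaction")
  keys <- sapply(rxns, function(r) as.character(reaction_core_key(r)))
  # keep one representative per core: all clusters are singletons
  keep <- !duplicated(keys)
  sp <- core_split(rxns[keep], fractions = c(0.6, 0.2, 0.2), seed = 1)
  check_partition(sp, sapply(rxns[keep], `[[`, "id"))
})

test_that("barrier split sandwiches the training range inside the extremes", {
  ids <- sprintf("b%03d", 1:100)
  targets <- setNames(as.numeric(1:100), ids)
  sp <- barrier_split(targets)
  expect_setequal(sp$train, ids[6:95])
  expect_setequal(sp$validation, ids[1:5])
  expect_setequal(sp$test, ids[96:100])
  expect_lte(max(targets[sp$validation]), min(targets[sp$train]))
  expect_lte(max(targets[sp$train]), min(targets[sp$test]))
  # configurable extreme routing
  sp2 <- barrier_split(targets, low_to = "test")
  expect_setequal(sp2$test, ids[1:5])
  expect_setequal(sp2$validation, ids[96:100])
  # all-equal targets: deterministic tie-break by id
  tie <- setNames(rep(1, 10), sprintf("t%02d", 1:10))
  spt <- barrier_split(tie, fractions = c(0.8, 0.1, 0.1))
  expect_identical(spt$validation, "t01")
  expect_identical(spt$test, "t10")
  expect_error(barrier_split(setNames(c(1, NA, 3), c("a", "b", "c"))),
               class = "cgrnn_value_error")
})

test_that("splits round-trip through JSON files", {
  ids <- sprintf("r%02d", 1:40)
  sp <- random_split(ids, seed = 2)
  path <- tempfile(fileext = ".json")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_identical(sp2$train, sp$train)
  expect_identical(sp2$validation, sp$validation)
  expect_identical(sp2$test, sp$test)
  expect_identical(sp2$strategy, sp$strategy)
})
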