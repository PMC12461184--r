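test_that("every generated reaction parses, builds a CGR and yields a core", {
  recs <- generate_fixtures(fixture_config(n_reactions = 40, seed = 1))
  expect_length(recs, 40)
  for (r in recs) {
    expect_s3_class(r$reaction, "cgrnn_reaction")
    expect_s3_class(r$cgr, "cgrnn_cgr")
    expect_s3_class(reaction_core_key(r$reaction), "cgrnn_core_key")
    # conformers align to the reaction's atoms under shuffled file order
    expect_setequal(r$conformers$ts$map_order, r$cgr$map_index)
  }
  # deterministic per seed
  recs2 <- generate_fixtures(fixture_config(n_reactions = 40, seed = 1))
  expect_identical(lapply(recs, `[[`, "y"), lapply(recs2, `[[`, "y"))
  expect_identical(recs[[7]]$rxn_smiles, recs2[[7]]$rxn_smiles)
  expect_false(identical(
    recs[[1]]$y,
    generate_fixtures(fixture_config(n_reactions = 1, seed = 99))[[1]]$y))
})

test_that("degenerate generative formulas behave as stated", {
  # sigma = 0, gamma = 0: barrier is an exact function of the bond changes
  ng <- generate_fixtures(fixture_config(n_reactions = 30, sigma = 0,
                                         gamma = 0, seed = 2))
  for (r in ng) expect_equal(r$y, r$components$graph_term)
  # sigma = 0, beta = 0, gamma = 1: barrier equals the TS distance in Angstrom
  zero_beta <- list(intercept = 0, broken = c(C = 0, N = 0, O = 0),
                    formed = c(C = 0, N = 0, O = 0))
  gd <- generate_fixtures(fixture_config(n_reactions = 30, sigma = 0,
                                         gamma = 1, beta = zero_beta, seed = 3))
  for (r in gd) expect_equal(r$y, r$components$d_ts)
})

test_that("the barrier oracle round-trips and responds linearly to geometry", {
  cfg <- fixture_config(n_reactions = 25, seed = 4)
  recs <- generate_fixtures(cfg)
  for (r in recs) expect_equal(barrier_oracle(r, cfg), r$y, tolerance = 1e-10)
  # zeroing the stored noise removes exactly the noise component
  r <- recs[[5]]
  r0 <- r; r0$components$noise <- 0
  expect_equal(barrier_oracle(r0, cfg, verify = FALSE),
               r$components$graph_term + r$components$geometry_term,
               tolerance = 1e-10)
  # stretching the forming bond by +0.1 A shifts the oracle by 0.1 * gamma
  rs <- r
  ts <- rs$conformers$ts
  fb_h <- which(ts$map_order == 2L)          # transferred hydrogen
  rxn <- r$reaction
  pb <- rxn$product$bonds
  formed <- pb[!paste(pb$a, pb$b) %in%
                 paste(rxn$reactant$bonds$a, rxn$reactant$bonds$b), ]
  acc_map <- setdiff(c(formed$a, formed$b), 2L)
  fb_y <- which(ts$map_order == acc_map)
  dir <- ts$coordinates[fb_y, ] - ts$coordinates[fb_h, ]
  dir <- dir / sqrt(sum(dir^2))
  rs$conformers$ts$coordinates[fb_y, ] <- ts$coordinates[fb_y, ] + 0.1 * dir
  expect_equal(barrier_oracle(rs, cfg, verify = FALSE) - r$y,
               0.1 * cfg$gamma, tolerance = 1e-6)
  # tampering with the stored barrier is caught
  bad <- r; bad$y <- bad$y + 1
  expect_error(barrier_oracle(bad, cfg), class = "cgrnn_consistency_error")
})

test_that("geometry signal is uncorrelated with everything the CGR sees", {
  recs <- generate_fixtures(fixture_config(n_reactions = 2000, seed = 7))
  d <- sapply(recs, function(r) r$components$d_ts)
  graph <- sapply(recs, function(r) r$components$graph_term)
  expect_lt(abs(cor(d, graph)), 0.06)
  # against every varying CGR-derived column (pooled atom features)
  pooled <- t(sapply(recs, function(r) colMeans(r$cgr$atom_features)))
  varying <- which(apply(pooled, 2, sd) > 0)
  cors <- abs(cor(d, pooled[, varying]))
  expect_lt(max(cors), 0.08)
})

test_that("the analytic no-coordinate MAE floor matches simulation", {
  cfg <- fixture_config(gamma = 6, sigma = 0.5, d_range = c(1.0, 2.2))
  floor <- geometry_mae_floor(cfg)
  set.seed(123)
  z <- 6 * (runif(2e5, 1.0, 2.2) - 1.6) + rnorm(2e5, 0, 0.5)
  expect_equal(floor, mean(abs(z)), tolerance = 0.01)
  # noise-free closed form: gamma * width / 4
  expect_equal(geometry_mae_floor(fixture_config(gamma = 6, sigma = 0)),
               6 * 1.2 / 4, tolerance = 1e-10)
})

test_that("fixture output round-trips through the CSV and XYZ readers", {
  recs <- generate_fixtures(fixture_config(n_reactions = 6, seed = 9))
  csv <- tempfile(fileext = ".csv")
  write_reactions(recs, csv)
  bundle <- read_reactions(csv)
  expect_length(bundle$records, 6)
  for (i in seq_along(recs)) {
    expect_identical(bundle$records[[i]]$id, recs[[i]]$id)
    expect_identical(bundle$records[[i]]$rxn_smiles, recs[[i]]$rxn_smiles)
    expect_equal(bundle$records[[i]]$y, recs[[i]]$y, tolerance = 1e-12)
    expect_equal(bundle$records[[i]]$cgr$atom_features,
                 recs[[i]]$cgr$atom_features)
  }
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(recs[[1]]$conformers$ts, xyz)
  conf <- read_xyz(xyz)
  expect_identical(conf$elements, recs[[1]]$conformers$ts$elements)
  expect_identical(conf$map_order, recs[[1]]$conformers$ts$map_order)
  expect_identical(conf$role, "ts")
  expect_equal(conf$coordinates, recs[[1]]$conformers$ts$coordinates,
               tolerance = 1e-12, ignore_attr = TRUE)
})
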