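#' Synthetic fixture configuration
#'
#' Configures the toy hydrogen-transfer reaction generator
#' (R1-H + R2 -> R1 + R2-H over a small element alphabet) whose barriers
#' follow a known generative formula with separable graph-level and
#' geometry-level signal:
#' `barrier = intercept + beta_broken[donor] + beta_formed[acceptor]
#'  + gamma * d_ts + noise`,
#' where `d_ts` is the forming-bond (H...acceptor) distance in the transition
#' state, drawn uniformly from `d_range`, and `noise` is Gaussian with sd
#' `sigma`. The defaults put the geometry term's standard deviation near
#' 2 kcal/mol against 0.5 kcal/mol noise.
#'
#' @param n_reactions number of reactions to generate
#' @param elements heavy-atom alphabet for the reacting centers (subset of
#'   C, N, O)
#' @param beta list with `intercept` and named `broken`/`formed` coefficient
#'   vectors (kcal/mol) for the bond-change terms
#' @param gamma geometry coefficient, kcal/mol per Angstrom of TS
#'   forming-bond distance
#' @param sigma Gaussian noise sd (kcal/mol)
#' @param d_range uniform range of the TS forming-bond distance (Angstrom)
#' @param seed integer seed; generation is deterministic per seed
#' @return object of class `cgrnn_fixture_config`
#' @export
fixture_config <- function(n_reactions = 2000L, elements = c("C", "N", "O"),
                           beta = list(intercept = 8,
                                       broken = c(C = 10, N = 7, O = 4),
                                       formed = c(C = -6, N = -3, O = 0)),
                           gamma = 6, sigma = 0.5, d_range = c(1.0, 2.2),
                           seed = 0L) {
  stopifnot(sigma >= 0, all(is.finite(unlist(beta))), is.finite(gamma))
  bad <- setdiff(elements, c("C", "N", "O"))
  if (length(bad))
    abort_cgrnn("fixture element alphabet supports C, N, O reacting centers",
                "cgrnn_config_error")
  if (!all(elements %in% names(beta$broken)) ||
      !all(elements %in% names(beta$formed)))
    abort_cgrnn("beta$broken/beta$formed must cover the element alphabet",
                "cgrnn_config_error")
  structure(list(n_reactions = as.integer(n_reactions), elements = elements,
                 beta = beta, gamma = gamma, sigma = sigma,
                 d_range = d_range, seed = as.integer(seed)),
            class = "cgrnn_fixture_config")
}

.valence <- c(C = 4L, N = 3L, O = 2L)

# tetrahedral-ish unit directions for substituent placement
.tet_dirs <- rbind(c(1, 0, 0), c(-1 / 3, 2 * sqrt(2) / 3, 0),
                   c(-1 / 3, -sqrt(2) / 3, sqrt(2 / 3)),
                   c(-1 / 3, -sqrt(2) / 3, -sqrt(2 / 3)))

# fragment = reacting center with nh hydrogens and optionally a methyl group;
# emits mapped SMILES, bond list and crude 3D coordinates.
# dir_sign = +1 places substituents on +x side, -1 on -x side.
.build_fragment <- function(element, nh, methyl, maps, center_pos, dir_sign,
                            reserve_first_dir = FALSE) {
  # maps: center, then nh hydrogens, then (methyl C, 3 methyl H)
  cmap <- maps[1]
  hmaps <- if (nh > 0) maps[1 + seq_len(nh)] else integer(0)
  atoms <- data.frame(map = cmap, element = element)
  coords <- matrix(center_pos, 1, 3)
  bonds <- data.frame(a = integer(0), b = integer(0))
  smi_branches <- character(0)
  dirs <- .tet_dirs * dir_sign
  di <- if (reserve_first_dir) 2L else 1L
  for (hm in hmaps) {
    atoms <- rbind(atoms, data.frame(map = hm, element = "H"))
    coords <- rbind(coords, center_pos + 1.02 * dirs[di, ])
    bonds <- rbind(bonds, data.frame(a = cmap, b = hm))
    smi_branches <- c(smi_branches, paste0("([H:", hm, "])"))
    di <- di + 1L
  }
  if (methyl) {
    mm <- maps[1 + nh + 1L]
    mh <- maps[1 + nh + 1L + 1:3]
    mpos <- center_pos + 1.52 * dirs[di, ]
    atoms <- rbind(atoms, data.frame(map = mm, element = "C"))
    coords <- rbind(coords, mpos)
    bonds <- rbind(bonds, data.frame(a = cmap, b = mm))
    hdirs <- rbind(dirs[di, ], .tet_dirs[2, c(3, 1, 2)], -.tet_dirs[3, c(3, 1, 2)])
    for (k in 1:3) {
      atoms <- rbind(atoms, data.frame(map = mh[k], element = "H"))
      coords <- rbind(coords, mpos + 1.02 * hdirs[k, ] / sqrt(sum(hdirs[k, ]^2)))
      bonds <- rbind(bonds, data.frame(a = mm, b = mh[k]))
    }
    smi_branches <- c(smi_branches,
                      paste0("([C:", mm, "]([H:", mh[1], "])([H:", mh[2],
                             "])[H:", mh[3], "])"))
  }
  smiles <- paste0("[", element, ":", cmap, "]",
                   paste(smi_branches, collapse = ""))
  list(atoms = atoms, coords = coords, bonds = bonds, smiles = smiles,
       center_map = cmap, n_atoms = nrow(atoms))
}

.rigid_jitter <- function(coords) {
  # seeded random rotation + translation (descriptors are invariant; this
  # exercises that invariance throughout the pipeline)
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(coords %*% Q, 2, stats::rnorm(3, sd = 2), "+")
}

.shuffled_conformer <- function(atoms, coords, role, id) {
  ord <- sample.int(nrow(atoms))
  conformer(atoms$element[ord], coords[ord, , drop = FALSE],
            atoms$map[ord], role = role, id = id)
}

#' Generate synthetic fixture reactions
#'
#' Produces balanced, explicit-hydrogen, atom-mapped hydrogen-transfer
#' reactions with reactant/TS/product conformers and barriers from the
#' generative formula in [fixture_config()]. Reaction cores repeat across
#' records (one core per donor/acceptor element pair), the TS forming-bond
#' distance is statistically independent of the graph, and conformer file
#' order is shuffled per record to exercise alignment handling.
#'
#' @param config a [fixture_config()]
#' @return list of records (`id`, `rxn_smiles`, `reaction`, `cgr`,
#'   `conformers`, `y`, `components`), with the config stored as an attribute
#' @export
generate_fixtures <- function(config = fixture_config()) {
  stopifnot(inherits(config, "cgrnn_fixture_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  els <- config$elements
  # fragment menu: plain radical X(H_{v-1}); methylated CH3-X(H_{v-2})
  menu <- list()
  for (e in els) {
    menu[[length(menu) + 1L]] <- list(element = e, methyl = FALSE)
    if ("C" %in% els && .valence[e] >= 2L)
      menu[[length(menu) + 1L]] <- list(element = e, methyl = TRUE)
  }
  records <- vector("list", config$n_reactions)
  for (i in seq_len(config$n_reactions)) {
    don <- menu[[sample.int(length(menu), 1)]]
    acc <- menu[[sample.int(length(menu), 1)]]
    X <- don$element; Y <- acc$element
    # radical hydrogen counts on each center
    nh_don_rad <- .valence[X] - 1L - if (don$methyl) 1L else 0L
    nh_acc_rad <- .valence[Y] - 1L - if (acc$methyl) 1L else 0L
    n_don <- 1L + (nh_don_rad + 1L) + if (don$methyl) 4L else 0L
    n_acc <- 1L + nh_acc_rad + if (acc$methyl) 4L else 0L
    # layout: center=1, transferred H=2, other donor Hs 3.., methyl after
    don_maps <- c(1L, seq.int(2L, length.out = nh_don_rad + 1L))
    if (don$methyl) don_maps <- c(don_maps, seq.int(max(don_maps) + 1L,
                                                    length.out = 4L))
    acc_start <- n_don + 1L
    acc_maps <- c(acc_start,
                  if (nh_acc_rad > 0) seq.int(acc_start + 1L,
                                              length.out = nh_acc_rad))
    if (acc$methyl) acc_maps <- c(acc_maps, seq.int(max(acc_maps) + 1L,
                                                    length.out = 4L))
    hT <- 2L  # transferred hydrogen's map index
    d_ts <- stats::runif(1, config$d_range[1], config$d_range[2])
    noise <- if (config$sigma > 0) stats::rnorm(1, 0, config$sigma) else 0

    # reactant: donor with all hydrogens, acceptor radical 7 A away
    don_r <- .build_fragment(X, nh_don_rad + 1L, don$methyl, don_maps,
                             c(0, 0, 0), -1)
    acc_r <- .build_fragment(Y, nh_acc_rad, acc$methyl, acc_maps,
                             c(7, 0, 0), +1, reserve_first_dir = TRUE)
    # product: donor radical, acceptor with the transferred hydrogen
    don_p <- .build_fragment(X, nh_don_rad, don$methyl,
                             don_maps[-2L], c(0, 0, 0), -1)
    acc_p <- .build_fragment(Y, nh_acc_rad + 1L, acc$methyl,
                             c(acc_maps[1], hT,
                               acc_maps[-1L]), c(7, 0, 0), +1)
    # product acceptor places the new H first: direction +x toward donor
    # TS: donor radical at origin, H on the axis, acceptor center beyond it
    don_t <- .build_fragment(X, nh_don_rad, don$methyl, don_maps[-2L],
                             c(0, 0, 0), -1)
    acc_t <- .build_fragment(Y, nh_acc_rad, acc$methyl, acc_maps,
                             c(1.2 + d_ts, 0, 0), +1,
                             reserve_first_dir = TRUE)
    ts_atoms <- rbind(don_t$atoms, data.frame(map = hT, element = "H"),
                      acc_t$atoms)
    ts_coords <- rbind(don_t$coords, c(1.2, 0, 0), acc_t$coords)
    r_atoms <- rbind(don_r$atoms, acc_r$atoms)
    r_coords <- rbind(don_r$coords, acc_r$coords)
    p_atoms <- rbind(don_p$atoms, acc_p$atoms)
    p_coords <- rbind(don_p$coords, acc_p$coords)

    rxn_smiles <- paste0(don_r$smiles, ".", acc_r$smiles, ">>",
                         don_p$smiles, ".", acc_p$smiles)
    id <- sprintf("fix%05d", i)
    reaction <- parse_reaction(rxn_smiles, id = id)

    graph_term <- config$beta$intercept + config$beta$broken[[X]] +
      config$beta$formed[[Y]]
    y <- graph_term + config$gamma * d_ts + noise
    conformers <- list(
      r = .shuffled_conformer(r_atoms, .rigid_jitter(r_coords), "r", id),
      ts = .shuffled_conformer(ts_atoms, .rigid_jitter(ts_coords), "ts", id),
      p = .shuffled_conformer(p_atoms, .rigid_jitter(p_coords), "p", id))
    reaction$barrier <- y
    records[[i]] <- list(
      id = id, rxn_smiles = rxn_smiles, reaction = reaction,
      cgr = build_cgr(reaction), conformers = conformers, y = y,
      components = list(graph_term = unname(graph_term),
                        geometry_term = unname(config$gamma * d_ts),
                        noise = noise, d_ts = d_ts,
                        donor = X, acceptor = Y))
  }
  attr(records, "config") <- config
  records
}

#' Recompute a fixture barrier from its stored reaction and conformers
#'
#' Independent round-trip of the generative formula: the broken/formed bonds
#' are re-derived by diffing the reaction's bond sets, the forming-bond
#' distance is re-measured in the TS conformer, and the stored noise draw is
#' added back. Raises a consistency error if the result does not match the
#' record's barrier.
#'
#' @param record one record from [generate_fixtures()]
#' @param config the generating [fixture_config()]
#' @param verify if TRUE (default), error on mismatch with the stored barrier
#' @return the recomputed barrier (kcal/mol)
#' @export
barrier_oracle <- function(record, config, verify = TRUE) {
  rxn <- record$reaction
  key <- function(b) stats::setNames(b$order, paste(b$a, b$b, sep = "-"))
  rb <- key(rxn$reactant$bonds); pb <- key(rxn$product$bonds)
  broken <- setdiff(names(rb), names(pb))
  formed <- setdiff(names(pb), names(rb))
  el_of <- function(map) rxn$reactant$atoms$element[
    match(map, rxn$reactant$atoms$map_index)]
  heavy_end <- function(k) {
    ends <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    els <- el_of(ends)
    els[els != "H"][1]
  }
  g <- config$beta$intercept +
    sum(vapply(broken, function(k) config$beta$broken[[heavy_end(k)]], 0)) +
    sum(vapply(formed, function(k) config$beta$formed[[heavy_end(k)]], 0))
  # forming-bond distance in the TS conformer
  fb <- as.integer(strsplit(formed[1], "-", fixed = TRUE)[[1]])
  ts <- record$conformers$ts
  pos <- ts$coordinates[match(fb, ts$map_order), , drop = FALSE]
  d <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  val <- unname(g + config$gamma * d + record$components$noise)
  if (verify && abs(val - record$y) > 1e-8)
    abort_cgrnn(sprintf("record %s inconsistent: oracle %.6f vs stored %.6f",
                        record$id, val, record$y), "cgrnn_consistency_error")
  val
}

#' Analytic MAE floor of a coordinate-blind model on the fixture
#'
#' The TS forming-bond distance is independent of everything a 2D model can
#' see, so the best possible no-coordinate predictor is the conditional mean
#' and its residual is `gamma * (d - mean(d)) + noise` with d uniform on
#' `d_range`. Returns E|residual| by numerical integration.
#'
#' @param config a [fixture_config()]
#' @return expected MAE (kcal/mol)
#' @export
geometry_mae_floor <- function(config) {
  w <- config$gamma * (config$d_range[2] - config$d_range[1])
  s <- config$sigma
  if (w == 0 && s == 0) return(0)
  if (s == 0) return(w / 4)
  f <- function(z) z * (stats::pnorm((z + w / 2) / s) -
                          stats::pnorm((z - w / 2) / s)) / w
  2 * stats::integrate(f, 0, w / 2 + 8 * s)$value
}

#' Synthetic molecule-level extra features for importance testing
#'
#' Emits `n_cols` molecule-level extra columns per record (named
#' `synth_01`...), where one informative column carries the record's barrier
#' and the rest are standard-normal noise, and attaches them to each record
#' (fields `extra` and re-featurized `cgr`).
#'
#' @param records fixture records
#' @param n_cols number of columns
#' @param informative index of the informative column
#' @param seed RNG seed for the noise columns
#' @return records with molecule-level extras attached
#' @export
synthetic_extra_features <- function(records, n_cols = 8L, informative = 1L,
                                     seed = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  nms <- sprintf("synth_%02d", seq_len(n_cols))
  for (i in seq_along(records)) {
    v <- stats::rnorm(n_cols)
    v[informative] <- records[[i]]$y
    records[[i]]$extra <- extra_feature_set(
      records[[i]]$cgr, mol_r = v, mol_p = stats::rnorm(n_cols),
      names_mol = nms)
  }
  featurize_records(records)
}
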