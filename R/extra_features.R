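#' The ml-QM descriptor schema
#'
#' Registry of the 37 machine-learned quantum-chemical descriptors: 13
#' atom-level properties (NPA charges, Parr functions, NMR shielding
#' constants, valence orbital occupancies, ...), 4 bond-level features (bond
#' order, bond length, bonding electrons, natural ionicity) and 20
#' molecular-level descriptors (energy gaps, ionization potential, electron
#' affinity, dipole and quadrupole moments, ...). Entries whose published
#' names are not fixed carry stable indexed placeholder names so column ids
#' remain usable.
#'
#' @return data.frame with columns `name` and `level`
#'   (atom/bond/molecule); 13/4/20 rows per level
#' @export
mlqm_schema <- function() {
  atom <- c("npa_charge", "parr_electrophilic", "parr_nucleophilic",
            "nmr_shielding", "valence_occ_s", "valence_occ_p",
            sprintf("mlqm_atom_%02d", 7:13))
  bond <- c("bond_order", "bond_length", "bonding_electrons",
            "natural_ionicity")
  mol <- c("homo_lumo_gap", "ionization_potential", "electron_affinity",
           "dipole_moment", "quadrupole_moment",
           sprintf("mlqm_mol_%02d", 6:20))
  out <- data.frame(
    name = c(atom, bond, mol),
    level = c(rep("atom", length(atom)), rep("bond", length(bond)),
              rep("molecule", length(mol))),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$name), nrow(out) == 37L)
  out
}

#' Construct a per-reaction extra-feature set
#'
#' Holds reactant-side and product-side auxiliary feature tables at the atom,
#' bond and/or molecule level for one reaction, aligned to a CGR. Atom tables
#' are keyed by atom-map index, bond tables by the CGR's undirected edge
#' order, molecule tables are one vector per side.
#'
#' @param cgr the reaction's `cgrnn_cgr`
#' @param atom_r,atom_p matrices (n_atoms x k_atom) in CGR atom order, or NULL
#' @param bond_r,bond_p matrices (n_edges x k_bond) in CGR edge order, or NULL
#' @param mol_r,mol_p numeric vectors of length k_mol, or NULL
#' @param names_atom,names_bond,names_mol column names per level (schema ids)
#' @return object of class `cgrnn_extra`
#' @export
extra_feature_set <- function(cgr, atom_r = NULL, atom_p = NULL,
                              bond_r = NULL, bond_p = NULL,
                              mol_r = NULL, mol_p = NULL,
                              names_atom = NULL, names_bond = NULL,
                              names_mol = NULL) {
  stopifnot(inherits(cgr, "cgrnn_cgr"))
  chk <- function(m, nrows, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nrows)
      abort_cgrnn(sprintf("%s table has %d rows, need %d (coverage)",
                          what, nrow(m), nrows), "cgrnn_coverage_error")
    m
  }
  atom_r <- chk(atom_r, cgr$n_atoms, "atom_r")
  atom_p <- chk(atom_p, cgr$n_atoms, "atom_p")
  bond_r <- chk(bond_r, nrow(cgr$edges), "bond_r")
  bond_p <- chk(bond_p, nrow(cgr$edges), "bond_p")
  if (xor(is.null(atom_r), is.null(atom_p)) ||
      xor(is.null(bond_r), is.null(bond_p)) ||
      xor(is.null(mol_r), is.null(mol_p)))
    abort_cgrnn("extras must be given for both sides or neither",
                "cgrnn_coverage_error")
  if (!is.null(atom_r) && ncol(atom_r) != ncol(atom_p))
    abort_cgrnn("atom extras: side column counts differ", "cgrnn_schema_error")
  dims <- list(atom = if (is.null(atom_r)) 0L else ncol(atom_r),
               bond = if (is.null(bond_r)) 0L else ncol(bond_r),
               molecule = if (is.null(mol_r)) 0L else length(mol_r))
  nm <- function(given, k, prefix) {
    if (k == 0L) return(character(0))
    if (is.null(given)) sprintf("%s_%02d", prefix, seq_len(k))
    else if (length(given) != k)
      abort_cgrnn("column names do not match column count (schema)",
                  "cgrnn_schema_error")
    else given
  }
  structure(list(
    atom_r = atom_r, atom_p = atom_p, bond_r = bond_r, bond_p = bond_p,
    mol_r = if (is.null(mol_r)) NULL else as.numeric(mol_r),
    mol_p = if (is.null(mol_p)) NULL else as.numeric(mol_p),
    names = list(atom = nm(names_atom, dims$atom, "xatom"),
                 bond = nm(names_bond, dims$bond, "xbond"),
                 molecule = nm(names_mol, dims$molecule, "xmol"))
  ), class = "cgrnn_extra")
}

#' Attach extra features to a CGR
#'
#' Concatenates reactant-side then product-side extra vectors onto the
#' corresponding CGR feature rows: atom-level extras widen `atom_features`
#' (the appended column range is recorded in `extra_atom_cols` so embedding
#' routes can process the block separately), bond-level extras widen
#' `bond_features`, and molecule-level extras are stored on the graph for
#' post-pooling concatenation.
#'
#' @param cgr a `cgrnn_cgr`
#' @param extra a `cgrnn_extra` for the same reaction
#' @param levels which levels to attach (default: all present)
#' @return the augmented `cgrnn_cgr`
#' @export
attach_extra <- function(cgr, extra,
                         levels = c("atom", "bond", "molecule")) {
  stopifnot(inherits(cgr, "cgrnn_cgr"), inherits(extra, "cgrnn_extra"))
  levels <- match.arg(levels, several.ok = TRUE)
  if ("atom" %in% levels && !is.null(extra$atom_r)) {
    blk <- cbind(extra$atom_r, extra$atom_p)
    start <- ncol(cgr$atom_features) + 1L
    cgr$atom_features <- cbind(cgr$atom_features, blk)
    cgr$extra_atom_cols <- c(cgr$extra_atom_cols,
                             seq.int(start, length.out = ncol(blk)))
  }
  if ("bond" %in% levels && !is.null(extra$bond_r)) {
    cgr$bond_features <- cbind(cgr$bond_features, extra$bond_r, extra$bond_p)
  }
  if ("molecule" %in% levels && !is.null(extra$mol_r)) {
    cgr$extra_mol <- c(cgr$extra_mol, extra$mol_r, extra$mol_p)
  }
  cgr
}

# locate an extra column by schema name across records; returns level
.extra_level_of <- function(records, column_id) {
  for (rec in records) {
    ex <- rec$extra
    if (is.null(ex)) next
    for (lv in c("atom", "bond", "molecule"))
      if (column_id %in% ex$names[[lv]]) return(lv)
  }
  abort_cgrnn(paste0("unknown extra-feature column '", column_id, "'"),
              "cgrnn_key_error")
}

#' Permute one extra-feature column across a dataset
#'
#' Shuffles the named column's values across all records (reactant-side and
#' product-side tables shuffled with independent draws from the seeded RNG),
#' preserving the value multiset and leaving every other column untouched.
#' Used by permutation feature importance. A single-record dataset is
#' returned unchanged.
#'
#' @param records list of dataset records, each with an `extra` field
#'   (`cgrnn_extra`)
#' @param column_id schema name of the column
#' @param seed integer seed; the shuffle is deterministic per seed
#' @return the records with that one column permuted
#' @export
permute_feature_column <- function(records, column_id, seed) {
  lv <- .extra_level_of(records, column_id)
  if (length(records) < 2L) return(records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fields <- switch(lv, atom = c("atom_r", "atom_p"),
                   bond = c("bond_r", "bond_p"),
                   molecule = c("mol_r", "mol_p"))
  for (fld in fields) {
    vals <- list(); where <- list()
    for (ri in seq_along(records)) {
      ex <- records[[ri]]$extra
      if (is.null(ex) || !(column_id %in% ex$names[[lv]])) next
      ci <- match(column_id, ex$names[[lv]])
      v <- if (lv == "molecule") ex[[fld]][ci] else ex[[fld]][, ci]
      vals[[length(vals) + 1L]] <- v
      where[[length(where) + 1L]] <- list(ri = ri, ci = ci, n = length(v))
    }
    pool <- unlist(vals)
    pool <- pool[sample.int(length(pool))]
    pos <- 0L
    for (w in where) {
      take <- pool[pos + seq_len(w$n)]
      pos <- pos + w$n
      if (lv == "molecule") records[[w$ri]]$extra[[fld]][w$ci] <- take
      else records[[w$ri]]$extra[[fld]][, w$ci] <- take
    }
  }
  records
}

#' Restrict a dataset to a subset of extra-feature columns
#'
#' Keeps only the named extra columns at every level; default CGR features
#' are untouched. Selecting all columns is the identity; selecting none
#' removes the extras entirely.
#'
#' @param records list of dataset records with `extra` fields
#' @param column_ids character vector of schema names to keep
#' @return records with narrowed extras
#' @export
select_feature_subset <- function(records, column_ids) {
  all_names <- unique(unlist(lapply(records, function(r)
    if (is.null(r$extra)) NULL else unlist(r$extra$names))))
  bad <- setdiff(column_ids, all_names)
  if (length(bad))
    abort_cgrnn(paste0("unknown extra-feature column(s): ",
                       paste(bad, collapse = ", ")), "cgrnn_key_error")
  for (ri in seq_along(records)) {
    ex <- records[[ri]]$extra
    if (is.null(ex)) next
    keep_m <- function(m, keep) {
      if (is.null(m)) return(NULL)
      if (length(keep) == 0L) return(NULL)
      m[, keep, drop = FALSE]
    }
    ka <- which(ex$names$atom %in% column_ids)
    kb <- which(ex$names$bond %in% column_ids)
    km <- which(ex$names$molecule %in% column_ids)
    ex$atom_r <- keep_m(ex$atom_r, ka); ex$atom_p <- keep_m(ex$atom_p, ka)
    ex$bond_r <- keep_m(ex$bond_r, kb); ex$bond_p <- keep_m(ex$bond_p, kb)
    if (length(km) == 0L) { ex$mol_r <- NULL; ex$mol_p <- NULL }
    else { ex$mol_r <- ex$mol_r[km]; ex$mol_p <- ex$mol_p[km] }
    ex$names$atom <- ex$names$atom[ka]
    ex$names$bond <- ex$names$bond[kb]
    ex$names$molecule <- ex$names$molecule[km]
    records[[ri]]$extra <- ex
  }
  records
}

#' Z-score extra-feature columns with training-set statistics
#'
#' Computes per-column mean and standard deviation over the records named in
#' `train_ids` (both sides pooled) and standardizes every record with those
#' statistics. Columns with zero variance are centered only.
#'
#' @param records dataset records with `extra` fields
#' @param train_ids record ids defining the statistics
#' @return list with standardized `records` and the `stats` used
#' @export
scale_extra_features <- function(records, train_ids) {
  ids <- vapply(records, function(r) r$id, character(1))
  tr <- which(ids %in% train_ids)
  if (!length(tr)) abort_cgrnn("no training records found", "cgrnn_data_error")
  stats <- list()
  for (lv in c("atom", "bond", "molecule")) {
    fields <- switch(lv, atom = c("atom_r", "atom_p"),
                     bond = c("bond_r", "bond_p"),
                     molecule = c("mol_r", "mol_p"))
    nms <- NULL
    for (i in tr) if (!is.null(records[[i]]$extra)) {
      nms <- records[[i]]$extra$names[[lv]]; if (length(nms)) break
    }
    if (!length(nms)) next
    pool <- do.call(rbind, unlist(lapply(tr, function(i) {
      ex <- records[[i]]$extra
      lapply(fields, function(f)
        if (lv == "molecule") matrix(ex[[f]], nrow = 1) else ex[[f]])
    }), recursive = FALSE))
    mu <- colMeans(pool)
    sd <- apply(pool, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    stats[[lv]] <- list(mean = mu, sd = sd)
    for (ri in seq_along(records)) {
      ex <- records[[ri]]$extra
      if (is.null(ex)) next
      for (f in fields) {
        if (is.null(ex[[f]])) next
        if (lv == "molecule") ex[[f]] <- (ex[[f]] - mu) / sd
        else ex[[f]] <- sweep(sweep(ex[[f]], 2, mu), 2, sd, "/")
      }
      records[[ri]]$extra <- ex
    }
  }
  list(records = records, stats = stats)
}

# RNG bookkeeping so seeded helpers do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
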