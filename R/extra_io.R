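#' Load extra-feature tables and attach them to a dataset bundle
#'
#' Reads delimited tables of auxiliary (e.g. ml-QM) descriptor values and
#' builds each record's extra-feature set. Table layouts (CSV, header
#' required):
#' * atom level: columns `id`, `side` (`r`/`p`), `map_index`, then one column
#'   per descriptor;
#' * bond level: `id`, `side`, `map_index_1`, `map_index_2`, descriptors
#'   (pairs are unordered);
#' * molecule level: `id`, `side`, descriptors.
#'
#' Every atom (bond) of every reaction must be covered on both sides at a
#' supplied level; missing rows raise a coverage error.
#'
#' @param bundle from [read_reactions()] (or any list of records with
#'   `id`, `reaction`, `cgr`)
#' @param atom_path,bond_path,mol_path optional file paths per level
#' @return the bundle with `extra` fields set and `cgr`s re-featurized
#' @export
attach_extra_tables <- function(bundle, atom_path = NULL, bond_path = NULL,
                                mol_path = NULL) {
  records <- if (!is.null(bundle$records)) bundle$records else bundle
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  atom_tab <- if (!is.null(atom_path)) rd(atom_path)
  bond_tab <- if (!is.null(bond_path)) rd(bond_path)
  mol_tab <- if (!is.null(mol_path)) rd(mol_path)

  for (i in seq_along(records)) {
    rec <- records[[i]]
    cgr <- build_cgr(rec$reaction)
    args <- list(cgr = cgr)
    if (!is.null(atom_tab)) {
      cols <- setdiff(names(atom_tab), c("id", "side", "map_index"))
      for (side in c("r", "p")) {
        sub <- atom_tab[atom_tab$id == rec$id & atom_tab$side == side, ]
        hit <- match(cgr$map_index, sub$map_index)
        if (anyNA(hit))
          abort_cgrnn(sprintf(
            "atom extras: missing row(s) for reaction %s side %s", rec$id,
            side), "cgrnn_coverage_error")
        args[[if (side == "r") "atom_r" else "atom_p"]] <-
          as.matrix(sub[hit, cols, drop = FALSE])
      }
      args$names_atom <- cols
    }
    if (!is.null(bond_tab)) {
      cols <- setdiff(names(bond_tab),
                      c("id", "side", "map_index_1", "map_index_2"))
      ek <- paste(pmin(cgr$map_index[cgr$edges[, 1]],
                       cgr$map_index[cgr$edges[, 2]]),
                  pmax(cgr$map_index[cgr$edges[, 1]],
                       cgr$map_index[cgr$edges[, 2]]))
      for (side in c("r", "p")) {
        sub <- bond_tab[bond_tab$id == rec$id & bond_tab$side == side, ]
        sk <- paste(pmin(sub$map_index_1, sub$map_index_2),
                    pmax(sub$map_index_1, sub$map_index_2))
        hit <- match(ek, sk)
        if (anyNA(hit))
          abort_cgrnn(sprintf(
            "bond extras: missing row(s) for reaction %s side %s", rec$id,
            side), "cgrnn_coverage_error")
        args[[if (side == "r") "bond_r" else "bond_p"]] <-
          as.matrix(sub[hit, cols, drop = FALSE])
      }
      args$names_bond <- cols
    }
    if (!is.null(mol_tab)) {
      cols <- setdiff(names(mol_tab), c("id", "side"))
      for (side in c("r", "p")) {
        sub <- mol_tab[mol_tab$id == rec$id & mol_tab$side == side, ]
        if (nrow(sub) != 1L)
          abort_cgrnn(sprintf(
            "molecule extras: need exactly one row for reaction %s side %s",
            rec$id, side), "cgrnn_coverage_error")
        args[[if (side == "r") "mol_r" else "mol_p"]] <-
          as.numeric(sub[1, cols])
      }
      args$names_mol <- cols
    }
    records[[i]]$extra <- do.call(extra_feature_set, args)
  }
  records <- featurize_records(records)
  if (!is.null(bundle$records)) { bundle$records <- records; bundle }
  else records
}

#' Positional-descriptor provider backed by a table
#'
#' Builds a provider function for [positional_features()] from a delimited
#' table of externally computed per-atom vectors (e.g. hidden states of a
#' pretrained force-field model), keyed by (`id`, `role`, `map_index`) with
#' one column per descriptor dimension.
#'
#' @param path CSV path
#' @return function(conformer) returning the per-atom matrix in conformer
#'   file order
#' @export
positional_provider_from_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "role", "map_index")
  if (!all(need %in% names(tab)))
    abort_cgrnn("provider table needs columns id, role, map_index",
                "cgrnn_format_error")
  cols <- setdiff(names(tab), need)
  function(conf) {
    sub <- tab[tab$id == conf$id & tab$role == conf$role, ]
    hit <- match(conf$map_order, sub$map_index)
    if (anyNA(hit))
      abort_cgrnn(sprintf("provider table misses atoms for id %s role %s",
                          conf$id, conf$role), "cgrnn_coverage_error")
    as.matrix(sub[hit, cols, drop = FALSE])
  }
}
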