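#' Build the condensed graph of reaction (CGR)
#'
#' Superimposes the reactant and product graphs of a balanced, atom-mapped
#' reaction into a single graph. Atoms are ordered by ascending atom-map
#' index. Per-atom features are the reactant-side vector concatenated with the
#' product-side vector; per-edge features likewise, with the half belonging to
#' a side where the bond is absent set to all zeros. The edge set is the union
#' of the two sides' bond sets, so formed, broken and order-changed bonds stay
#' explicit.
#'
#' @param reaction a `cgrnn_reaction` from [parse_reaction()]
#' @param elements supported element list for the one-hot encoding
#' @return an object of class `cgrnn_cgr`: `n_atoms`, `map_index` (ascending),
#'   `atom_features` (n_atoms x 2*atom width), `edges` (matrix of atom-index
#'   pairs, first < second), `bond_features` (one row per edge, reactant-half
#'   then product-half), `id`
#' @export
build_cgr <- function(reaction, elements = default_elements()) {
  stopifnot(inherits(reaction, "cgrnn_reaction"))
  maps <- sort(reaction$reactant$atoms$map_index)
  n <- length(maps)

  side_feats <- lapply(c("reactant", "product"), function(s) {
    at <- reaction[[s]]$atoms
    default_atom_features(at, elements)[order(at$map_index), , drop = FALSE]
  })
  atom_features <- cbind(side_feats[[1]], side_feats[[2]])

  key <- function(b) paste(b$a, b$b, sep = "-")
  rb <- reaction$reactant$bonds
  pb <- reaction$product$bonds
  rkey <- key(rb); pkey <- key(pb)
  all_keys <- union(rkey, pkey)
  pair <- do.call(rbind, strsplit(all_keys, "-", fixed = TRUE))
  edges_map <- matrix(as.integer(pair), ncol = 2)
  o <- order(edges_map[, 1], edges_map[, 2])
  edges_map <- edges_map[o, , drop = FALSE]
  all_keys <- all_keys[o]

  half <- function(bonds, keys) {
    m <- matrix(0, length(all_keys), bond_feature_width())
    hit <- match(keys, all_keys)
    if (length(hit)) m[hit, ] <- default_bond_features(bonds)
    m
  }
  bond_features <- cbind(half(rb, rkey), half(pb, pkey))

  edges <- cbind(match(edges_map[, 1], maps), match(edges_map[, 2], maps))

  structure(list(
    n_atoms = n,
    map_index = maps,
    atom_features = atom_features,
    edges = edges,
    bond_features = bond_features,
    id = reaction$id
  ), class = "cgrnn_cgr")
}

#' Directed edge features of a CGR
#'
#' Expands each undirected CGR edge \{v, w\} into the two directed edges
#' v->w and w->v with feature vector `cat(x_v, e_vw)`: the source atom's CGR
#' feature vector concatenated with the (direction-independent) bond feature
#' vector.
#'
#' @param cgr a `cgrnn_cgr`
#' @return list with `src`, `dst` (atom indices), `eid` (undirected edge id),
#'   `rev` (index of the reverse directed edge) and `features` (matrix, one
#'   row per directed edge)
#' @export
directed_edge_features <- function(cgr) {
  stopifnot(inherits(cgr, "cgrnn_cgr"))
  ne <- nrow(cgr$edges)
  if (ne == 0L) {
    return(list(src = integer(0), dst = integer(0), eid = integer(0),
                rev = integer(0),
                features = matrix(0, 0, ncol(cgr$atom_features) +
                                    ncol(cgr$bond_features))))
  }
  src <- as.vector(rbind(cgr$edges[, 1], cgr$edges[, 2]))
  dst <- as.vector(rbind(cgr$edges[, 2], cgr$edges[, 1]))
  eid <- rep(seq_len(ne), each = 2L)
  rev <- as.vector(rbind(seq_len(ne) * 2L, seq_len(ne) * 2L - 1L))
  features <- cbind(cgr$atom_features[src, , drop = FALSE],
                    cgr$bond_features[eid, , drop = FALSE])
  list(src = src, dst = dst, eid = eid, rev = rev, features = features)
}

#' @export
print.cgrnn_cgr <- function(x, ...) {
  cat("<cgrnn_cgr>", x$n_atoms, "atoms,", nrow(x$edges), "edges,",
      ncol(x$atom_features), "atom feature dims\n")
  invisible(x)
}
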