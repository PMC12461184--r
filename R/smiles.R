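#' @keywords internal
abort_cgrnn <- function(msg, class) {
  stop(structure(
    class = c(class, "cgrnn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Default valences used to assign implicit hydrogens on organic-subset atoms.
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

.atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)

#' Parse one side of an atom-mapped SMILES string
#'
#' Restricted SMILES reader for mapped, balanced, explicit-hydrogen reaction
#' input: bracket atoms with map numbers, the organic subset (incl. aromatic
#' lowercase), branches, ring closures (single digit and `%nn`), bond symbols
#' `- = # :` and dot-separated fragments. Stereo markers (`/ \ @`) are read
#' and ignored; isotopes are ignored.
#'
#' @param smiles a molecule (one reaction side) SMILES string
#' @return a list with data.frames `atoms` (map_index, element, aromatic,
#'   formal_charge, implicit_h, idx) and `bonds` (i, j atom indices into
#'   `atoms`, order in single/double/triple/aromatic)
#' @keywords internal
parse_mapped_smiles <- function(smiles) {
  n <- nchar(smiles)
  atoms <- list()
  bonds <- list()
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring_open <- list()  # closure label -> list(atom, bond)
  i <- 1L

  add_atom <- function(element, aromatic, charge, implicit_h, map) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, formal_charge = charge,
      implicit_h = implicit_h, map_index = map)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    if (is.na(sym)) {
      ar_a <- atoms[[a]]$aromatic; ar_b <- atoms[[b]]$aromatic
      order <- if (ar_a && ar_b) "aromatic" else "single"
    } else {
      order <- switch(sym, "-" = "single", "=" = "double", "#" = "triple",
                      ":" = "aromatic", "/" = "single", "\\" = "single",
                      abort_cgrnn(paste0("unsupported bond symbol '", sym, "'"),
                                  "cgrnn_parse_error"))
    }
    bonds[[length(bonds) + 1L]] <<- list(i = a, j = b, order = order)
  }

  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (close < 0) abort_cgrnn("unterminated bracket atom", "cgrnn_parse_error")
      body <- substr(smiles, i + 1L, i + close - 2L)
      m <- regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*)?(:([0-9]+))?$",
        body)[[1]]
      if (m[1] < 0)
        abort_cgrnn(paste0("cannot parse bracket atom [", body, "]"),
                    "cgrnn_parse_error")
      parts <- regmatches(body, list(m))[[1]]
      sym <- parts[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      hspec <- parts[5]
      implicit_h <- if (hspec == "") 0L
        else if (hspec == "H") 1L
        else as.integer(substring(hspec, 2))
      cspec <- parts[6]
      charge <- if (cspec == "") 0L
        else if (cspec == "+") 1L
        else if (cspec == "-") -1L
        else as.integer(cspec)
      map <- if (parts[8] == "") NA_integer_ else as.integer(parts[8])
      a <- add_atom(element, aromatic, charge, implicit_h, map)
      if (!is.na(prev)) add_bond(prev, a, pending_bond)
      pending_bond <- NA_character_
      prev <- a
      i <- i + close
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) abort_cgrnn("branch with no preceding atom", "cgrnn_parse_error")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) abort_cgrnn("unmatched ')'", "cgrnn_parse_error")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        label <- substr(smiles, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", label))
          abort_cgrnn("bad %nn ring closure", "cgrnn_parse_error")
        i <- i + 3L
      } else {
        label <- ch
        i <- i + 1L
      }
      if (is.na(prev)) abort_cgrnn("ring closure with no atom", "cgrnn_parse_error")
      if (!is.null(ring_open[[label]])) {
        op <- ring_open[[label]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring_open[[label]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring_open[[label]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NA_character_
      }
    } else {
      # organic subset, two-letter halogens first
      two <- substr(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        sym <- two; i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                           "b", "c", "n", "o", "p", "s")) {
        sym <- ch; i <- i + 1L
      } else {
        abort_cgrnn(paste0("unexpected character '", ch, "' in SMILES"),
                    "cgrnn_parse_error")
      }
      aromatic <- sym == tolower(sym)
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      a <- add_atom(element, aromatic, 0L, NA_integer_, NA_integer_)
      if (!is.na(prev)) add_bond(prev, a, pending_bond)
      pending_bond <- NA_character_
      prev <- a
    }
  }
  if (length(stack) > 0L) abort_cgrnn("unmatched '('", "cgrnn_parse_error")
  if (length(ring_open) > 0L) abort_cgrnn("unclosed ring bond", "cgrnn_parse_error")
  if (length(atoms) == 0L) abort_cgrnn("empty SMILES", "cgrnn_parse_error")

  atoms_df <- data.frame(
    idx = seq_along(atoms),
    map_index = vapply(atoms, function(a) a$map_index, integer(1)),
    element = vapply(atoms, function(a) a$element, character(1)),
    aromatic = vapply(atoms, function(a) a$aromatic, logical(1)),
    formal_charge = vapply(atoms, function(a) a$formal_charge, integer(1)),
    implicit_h = vapply(atoms, function(a) a$implicit_h, integer(1)),
    stringsAsFactors = FALSE)
  bonds_df <- if (length(bonds)) data.frame(
    i = vapply(bonds, function(b) b$i, integer(1)),
    j = vapply(bonds, function(b) b$j, integer(1)),
    order = vapply(bonds, function(b) b$order, character(1)),
    stringsAsFactors = FALSE)
  else data.frame(i = integer(0), j = integer(0), order = character(0))

  # organic-subset atoms (implicit_h NA): assign hydrogens by default valence
  na_h <- is.na(atoms_df$implicit_h)
  if (any(na_h)) {
    bsum <- numeric(nrow(atoms_df))
    if (nrow(bonds_df)) {
      w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)[bonds_df$order]
      for (k in seq_len(nrow(bonds_df))) {
        bsum[bonds_df$i[k]] <- bsum[bonds_df$i[k]] + w[k]
        bsum[bonds_df$j[k]] <- bsum[bonds_df$j[k]] + w[k]
      }
    }
    for (a in which(na_h)) {
      val <- .default_valence[atoms_df$element[a]]
      atoms_df$implicit_h[a] <-
        if (is.na(val)) 0L else max(0L, as.integer(val - ceiling(bsum[a])))
    }
  }
  list(atoms = atoms_df, bonds = bonds_df)
}

# hybridization heuristic: triple or cumulated double -> SP; any double or
# aromatic -> SP2; hydrogens -> S; hypervalent degree 5/6 -> SP3D/SP3D2;
# everything else SP3.
.assign_hybridization <- function(atoms, bonds, degree) {
  n_double <- n_triple <- n_arom <- integer(nrow(atoms))
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    for (a in c(bonds$i[k], bonds$j[k])) {
      if (bonds$order[k] == "double") n_double[a] <- n_double[a] + 1L
      if (bonds$order[k] == "triple") n_triple[a] <- n_triple[a] + 1L
      if (bonds$order[k] == "aromatic") n_arom[a] <- n_arom[a] + 1L
    }
  }
  hyb <- rep("SP3", nrow(atoms))
  hyb[n_double >= 1L | n_arom >= 1L | atoms$aromatic] <- "SP2"
  hyb[n_triple >= 1L | n_double >= 2L] <- "SP"
  hyb[degree >= 5L] <- "SP3D"
  hyb[degree >= 6L] <- "SP3D2"
  hyb[atoms$element == "H"] <- "S"
  hyb
}

# smallest ring through each bond: BFS between endpoints with the bond removed
.bond_ring_sizes <- function(n_atoms, bonds, max_size = 12L) {
  if (nrow(bonds) == 0L) return(integer(0))
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  vapply(seq_len(nrow(bonds)), function(k) {
    src <- bonds$i[k]; dst <- bonds$j[k]
    dist <- rep(NA_integer_, n_atoms)
    dist[src] <- 0L
    frontier <- src
    removed_once <- FALSE
    while (length(frontier) && is.na(dist[dst])) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          # skip the bond itself (one traversal of src-dst in either direction)
          if ((v == src && w == dst) || (v == dst && w == src)) next
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      if (length(nxt) && min(dist[nxt]) >= max_size) break
      frontier <- nxt
    }
    if (is.na(dist[dst]) || dist[dst] + 1L > max_size) NA_integer_
    else dist[dst] + 1L
  }, integer(1))
}

.build_side <- function(parsed) {
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  n <- nrow(atoms)
  degree <- integer(n)
  n_h_neighbors <- integer(n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    degree[bonds$i[k]] <- degree[bonds$i[k]] + 1L
    degree[bonds$j[k]] <- degree[bonds$j[k]] + 1L
    if (atoms$element[bonds$j[k]] == "H")
      n_h_neighbors[bonds$i[k]] <- n_h_neighbors[bonds$i[k]] + 1L
    if (atoms$element[bonds$i[k]] == "H")
      n_h_neighbors[bonds$j[k]] <- n_h_neighbors[bonds$j[k]] + 1L
  }
  hyb <- .assign_hybridization(atoms, bonds, degree)
  ring <- .bond_ring_sizes(n, bonds)
  conj <- if (nrow(bonds))
    (hyb[bonds$i] %in% c("SP", "SP2")) & (hyb[bonds$j] %in% c("SP", "SP2"))
  else logical(0)

  atom_records <- data.frame(
    map_index = atoms$map_index,
    element = atoms$element,
    degree = degree,
    formal_charge = atoms$formal_charge,
    hybridization = hyb,
    n_hydrogens = n_h_neighbors + atoms$implicit_h,
    aromatic = atoms$aromatic | hyb == "SP2" & atoms$aromatic,
    mass = unname(.atomic_mass[atoms$element]),
    stringsAsFactors = FALSE)
  bond_records <- data.frame(
    a = pmin(atoms$map_index[bonds$i], atoms$map_index[bonds$j]),
    b = pmax(atoms$map_index[bonds$i], atoms$map_index[bonds$j]),
    order = bonds$order,
    conjugated = conj,
    ring_size = ring,
    stringsAsFactors = FALSE)
  list(atoms = atom_records, bonds = bond_records,
       implicit_h_total = sum(atoms$implicit_h))
}

#' Parse an atom-mapped reaction SMILES
#'
#' The reaction must be balanced and carry explicit hydrogens: both sides must
#' have identical atom-map index sets, matching elements per map index, and no
#' change in implicit hydrogen counts. Atom and bond attribute tables
#' (degree, hybridization, hydrogen count, aromaticity, conjugation, smallest
#' ring size) are derived during parsing.
#'
#' @param rxn_smiles string of the form `reactants>>products`, every atom
#'   mapped (`[C:1]` style)
#' @param id optional reaction identifier carried through the pipeline
#' @param barrier optional barrier height (kcal/mol)
#' @return an object of class `cgrnn_reaction` with components `reactant` and
#'   `product` (each a list of `atoms` and `bonds` data.frames keyed by atom
#'   map index), `id` and `barrier`
#' @examples
#' rxn <- parse_reaction(
#'   "[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]>>[C:1]([H:4])([H:5])=[C:2]([H:7])[H:8].[H:3][H:6]")
#' nrow(rxn$reactant$atoms)  # 8
#' @export
parse_reaction <- function(rxn_smiles, id = NULL, barrier = NA_real_) {
  if (!is.character(rxn_smiles) || length(rxn_smiles) != 1L)
    abort_cgrnn("rxn_smiles must be a single string", "cgrnn_parse_error")
  if (!grepl(">>", rxn_smiles, fixed = TRUE))
    abort_cgrnn("reaction SMILES must contain '>>'", "cgrnn_parse_error")
  parts <- strsplit(rxn_smiles, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts)))
    abort_cgrnn("reaction SMILES must have reactant and product sides",
                "cgrnn_parse_error")

  sides <- lapply(parts, function(p) .build_side(parse_mapped_smiles(p)))
  names(sides) <- c("reactant", "product")

  for (nm in names(sides)) {
    maps <- sides[[nm]]$atoms$map_index
    if (anyNA(maps))
      abort_cgrnn(paste0("unmapped atom(s) on ", nm, " side"),
                  "cgrnn_mapping_error")
    if (anyDuplicated(maps))
      abort_cgrnn(paste0("duplicate atom-map index on ", nm, " side"),
                  "cgrnn_mapping_error")
  }
  rmap <- sides$reactant$atoms$map_index
  pmap <- sides$product$atoms$map_index
  if (!setequal(rmap, pmap))
    abort_cgrnn("atom-map index sets differ between sides (unbalanced reaction)",
                "cgrnn_balance_error")
  rel <- sides$reactant$atoms$element[order(rmap)]
  pel <- sides$product$atoms$element[order(pmap)]
  if (!identical(rel, pel))
    abort_cgrnn("element identity differs for a mapped atom between sides",
                "cgrnn_balance_error")
  if (sides$reactant$implicit_h_total != sides$product$implicit_h_total)
    abort_cgrnn("hydrogen count differs between sides (unbalanced reaction)",
                "cgrnn_balance_error")

  structure(list(reactant = sides$reactant, product = sides$product,
                 id = if (is.null(id)) rxn_smiles else id,
                 barrier = barrier),
            class = "cgrnn_reaction")
}

#' @export
print.cgrnn_reaction <- function(x, ...) {
  cat("<cgrnn_reaction> id:", x$id, "\n",
      " atoms per side:", nrow(x$reactant$atoms),
      " reactant bonds:", nrow(x$reactant$bonds),
      " product bonds:", nrow(x$product$bonds), "\n")
  if (!is.na(x$barrier)) cat("  barrier:", x$barrier, "kcal/mol\n")
  invisible(x)
}
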