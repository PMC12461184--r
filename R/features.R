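#' Default supported element list
#'
#' Covers the element alphabets of the common barrier-height benchmark sets
#' (CHNO core plus sulfur and the halogens). Out-of-list elements raise an
#' error rather than being bucketed silently.
#' @export
default_elements <- function() c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I")

.hyb_levels <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "other")
.bond_orders <- c("single", "double", "triple", "aromatic")

.one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Width of the per-side atom feature vector
#' @param elements supported element list
#' @export
atom_feature_width <- function(elements = default_elements()) {
  length(elements) + 6L + 7L + length(.hyb_levels) + 6L + 1L + 1L
}

#' Width of the per-side bond feature vector
#' @export
bond_feature_width <- function() length(.bond_orders) + 1L + 1L + 6L

#' Default atom features
#'
#' Encodes, per atom: element (one-hot over the supported list), degree
#' (one-hot 0-4 plus overflow), formal charge (one-hot -2..+2 plus low/high
#' overflow), hybridization (one-hot S/SP/SP2/SP3/SP3D/SP3D2/other),
#' hydrogen count (one-hot 0-4 plus overflow), an aromaticity flag, and the
#' atomic mass divided by 100.
#'
#' @param atoms an atom record data.frame (as in a `cgrnn_reaction` side)
#' @param elements supported element list; atoms outside it raise an error
#' @return numeric matrix, one row per atom
#' @export
default_atom_features <- function(atoms, elements = default_elements()) {
  bad <- setdiff(unique(atoms$element), elements)
  if (length(bad))
    abort_cgrnn(paste0("unsupported element(s): ", paste(bad, collapse = ", ")),
                "cgrnn_element_error")
  el <- .one_hot(match(atoms$element, elements), length(elements))
  deg <- .one_hot(pmin(atoms$degree, 5L) + 1L, 6L)
  fc <- atoms$formal_charge
  fc_idx <- ifelse(fc < -2L, 1L, ifelse(fc > 2L, 7L, fc + 4L))
  charge <- .one_hot(fc_idx, 7L)
  hyb_idx <- match(atoms$hybridization, .hyb_levels)
  hyb_idx[is.na(hyb_idx)] <- length(.hyb_levels)
  hyb <- .one_hot(hyb_idx, length(.hyb_levels))
  nh <- .one_hot(pmin(atoms$n_hydrogens, 5L) + 1L, 6L)
  cbind(el, deg, charge, hyb, nh,
        as.numeric(atoms$aromatic), atoms$mass / 100)
}

#' Default bond features
#'
#' Encodes bond order (one-hot single/double/triple/aromatic), conjugation,
#' an in-ring flag and smallest-ring size (one-hot 3-8; larger rings set only
#' the flag). An absent bond is the all-zero vector: the empty bond-order
#' block uniquely signals absence, so no extra presence bit is used.
#'
#' @param bonds a bond record data.frame, or `NULL` for zero rows
#' @return numeric matrix, one row per bond
#' @export
default_bond_features <- function(bonds = NULL) {
  if (is.null(bonds) || nrow(bonds) == 0L)
    return(matrix(0, 0L, bond_feature_width()))
  ord <- .one_hot(match(bonds$order, .bond_orders), length(.bond_orders))
  in_ring <- !is.na(bonds$ring_size)
  size_idx <- ifelse(in_ring & bonds$ring_size >= 3L & bonds$ring_size <= 8L,
                     bonds$ring_size - 2L, NA_integer_)
  cbind(ord, as.numeric(bonds$conjugated), as.numeric(in_ring),
        .one_hot(size_idx, 6L))
}
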