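.mk_split <- function(train, validation, test, strategy, fractions, seed,
                      provenance = list()) {
  sp <- structure(list(train = train, validation = validation, test = test,
                       strategy = strategy, fractions = fractions,
                       seed = seed, provenance = provenance),
                  class = "cgrnn_split")
  all <- c(train, validation, test)
  if (anyDuplicated(all))
    abort_cgrnn("split partitions overlap", "cgrnn_split_error")
  sp
}

.check_fractions <- function(fractions) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0))
    abort_cgrnn("fractions must be three nonnegative numbers summing to 1",
                "cgrnn_config_error")
}

#' Random train/validation/test split
#'
#' Shuffles ids with the given seed and cuts them into train, validation and
#' test partitions. Validation and test sizes are floors of their fractions;
#' the remainder goes to train (100 ids at 0.90/0.05/0.05 gives 90/5/5).
#'
#' @param ids character or integer vector of reaction ids
#' @param fractions train/validation/test fractions, summing to 1
#' @param seed integer seed; the assignment is deterministic per seed
#' @return object of class `cgrnn_split`
#' @export
random_split <- function(ids, fractions = c(0.90, 0.05, 0.05), seed = 0L) {
  .check_fractions(fractions)
  if (length(ids) < 3L)
    abort_cgrnn("need at least 3 ids to split", "cgrnn_data_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ids <- as.character(ids)
  perm <- ids[sample.int(length(ids))]
  n <- length(ids)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  test <- perm[seq_len(n_test)]
  validation <- perm[n_test + seq_len(n_val)]
  train <- perm[n_test + n_val + seq_len(n - n_test - n_val)]
  .mk_split(train, validation, test, "random", fractions, as.integer(seed))
}

#' Canonical reaction-core key
#'
#' The reaction core is the set of bonds formed, broken, or changed in order
#' between the reactant and product sides, together with their endpoint atoms
#' (environment radius 0). The key is a canonical serialization of the
#' two-sided core subgraph, built from Weisfeiler-Lehman-refined atom labels,
#' so it is stable under consistent atom relabeling.
#'
#' @param reaction a `cgrnn_reaction`
#' @return character key of class `cgrnn_core_key`
#' @export
reaction_core_key <- function(reaction) {
  stopifnot(inherits(reaction, "cgrnn_reaction"))
  bond_map <- function(b) {
    if (nrow(b) == 0L) return(character(0))
    stats::setNames(b$order, paste(b$a, b$b, sep = "-"))
  }
  rb <- bond_map(reaction$reactant$bonds)
  pb <- bond_map(reaction$product$bonds)
  keys <- union(names(rb), names(pb))
  changed <- keys[is.na(rb[keys]) | is.na(pb[keys]) |
                    rb[keys] != pb[keys]]
  if (!length(changed))
    abort_cgrnn("identity reaction has no changed bonds (degenerate core)",
                "cgrnn_core_error")
  ends <- do.call(rbind, strsplit(changed, "-", fixed = TRUE))
  core_atoms <- sort(unique(as.integer(ends)))
  elem <- reaction$reactant$atoms$element[
    match(core_atoms, reaction$reactant$atoms$map_index)]

  # edges of the core multigraph, tagged "r:order"/"p:order"/"rp:o1>o2"
  tag <- vapply(changed, function(k) {
    r <- rb[k]; p <- pb[k]
    if (is.na(r)) paste0("p:", p)
    else if (is.na(p)) paste0("r:", r)
    else paste0("rp:", r, ">", p)
  }, character(1))
  ei <- match(as.integer(ends[, 1]), core_atoms)
  ej <- match(as.integer(ends[, 2]), core_atoms)

  # Weisfeiler-Lehman label refinement on the tagged core graph
  lab <- elem
  for (it in seq_len(length(core_atoms))) {
    nbr <- lapply(seq_along(core_atoms), function(a) {
      k <- which(ei == a | ej == a)
      other <- ifelse(ei[k] == a, ej[k], ei[k])
      sort(paste(tag[k], lab[other], sep = "~"))
    })
    new_lab <- vapply(seq_along(core_atoms), function(a)
      paste0(lab[a], "(", paste(nbr[[a]], collapse = ","), ")"),
      character(1))
    new_lab <- match(new_lab, sort(unique(new_lab)))
    new_lab <- paste0(elem, new_lab)
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  edge_str <- sort(vapply(seq_along(ei), function(k) {
    a <- sort(c(lab[ei[k]], lab[ej[k]]))
    paste0(a[1], "|", tag[k], "|", a[2])
  }, character(1)))
  key <- paste0(paste(sort(lab), collapse = "."), ">>",
                paste(edge_str, collapse = ";"))
  structure(key, class = c("cgrnn_core_key", "character"))
}

#' Reaction-core-clustered split
#'
#' Clusters reactions by their canonical core key and assigns whole clusters
#' to partitions, so no core is shared across train/validation/test. Clusters
#' are shuffled with the seed and greedily routed: a cluster goes to
#' validation or test only while it fits the remaining deficit of that
#' partition; everything else goes to train. Realized fractions are recorded
#' in the provenance (a dominant cluster can make them deviate from the
#' targets).
#'
#' @param reactions list of `cgrnn_reaction` objects (with unique `id`s)
#' @param fractions target fractions
#' @param seed integer seed
#' @return a `cgrnn_split`
#' @export
core_split <- function(reactions, fractions = c(0.90, 0.05, 0.05), seed = 0L) {
  .check_fractions(fractions)
  ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids))
    abort_cgrnn("duplicate reaction ids", "cgrnn_data_error")
  keys <- vapply(reactions, function(r) as.character(reaction_core_key(r)),
                 character(1))
  clusters <- split(ids, keys)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  clusters <- clusters[sample.int(length(clusters))]
  n <- length(ids)
  deficit <- c(validation = floor(fractions[2] * n),
               test = floor(fractions[3] * n))
  part <- list(train = character(0), validation = character(0),
               test = character(0))
  for (cl in clusters) {
    if (length(cl) <= deficit["validation"]) {
      part$validation <- c(part$validation, cl)
      deficit["validation"] <- deficit["validation"] - length(cl)
    } else if (length(cl) <= deficit["test"]) {
      part$test <- c(part$test, cl)
      deficit["test"] <- deficit["test"] - length(cl)
    } else {
      part$train <- c(part$train, cl)
    }
  }
  realized <- c(length(part$train), length(part$validation),
                length(part$test)) / n
  .mk_split(part$train, part$validation, part$test, "reaction_core",
            fractions, as.integer(seed),
            provenance = list(n_clusters = length(clusters),
                              realized_fractions = realized))
}

#' Barrier-height extreme split
#'
#' Sorts reactions by barrier height (ties broken by id), routes the lowest
#' extreme to one held-out partition and the highest to the other (by default
#' lower 5% to validation, upper 5% to test), with the middle 90% as the
#' training set. The training range is therefore sandwiched strictly inside
#' the extremes.
#'
#' @param targets named numeric vector: barrier height (kcal/mol) per id
#' @param fractions train/validation/test fractions
#' @param low_to where the low extreme goes (`validation` default or `test`)
#' @return a `cgrnn_split`
#' @export
barrier_split <- function(targets, fractions = c(0.90, 0.05, 0.05),
                          low_to = c("validation", "test")) {
  .check_fractions(fractions)
  low_to <- match.arg(low_to)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    abort_cgrnn("targets must be named by reaction id", "cgrnn_value_error")
  if (anyNA(targets) || any(!is.finite(targets)))
    abort_cgrnn("missing or non-finite barrier target", "cgrnn_value_error")
  ids <- names(targets)
  o <- order(targets, ids)
  n <- length(targets)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_low <- if (low_to == "validation") n_val else n_test
  n_high <- if (low_to == "validation") n_test else n_val
  low <- ids[o][seq_len(n_low)]
  high <- if (n_high > 0) ids[o][n - n_high + seq_len(n_high)] else character(0)
  train <- setdiff(ids[o], c(low, high))
  validation <- if (low_to == "validation") low else high
  test <- if (low_to == "validation") high else low
  .mk_split(train, validation, test, "barrier_height", fractions, NA_integer_,
            provenance = list(low_extreme_to = low_to))
}

#' @export
print.cgrnn_split <- function(x, ...) {
  cat("<cgrnn_split>", x$strategy, "- train:", length(x$train),
      "val:", length(x$validation), "test:", length(x$test), "\n")
  invisible(x)
}
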