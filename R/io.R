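#' Read a reaction table
#'
#' Reads a delimited text table (comma default, header required, UTF-8) with
#' columns `id`, `rxn_smiles` (atom-mapped) and optionally `dE0` (kcal/mol)
#' and `is_reverse`. Every row is parsed and validated via [parse_reaction()];
#' a malformed row raises an error naming its line.
#'
#' @param path file path
#' @param forward_only if TRUE, drop rows flagged `is_reverse` (truthy values
#'   in an `is_reverse` column)
#' @param sep field separator
#' @return a dataset bundle: list with `records` (each `id`, `rxn_smiles`,
#'   `reaction`, `cgr`, `y`) and `provenance`
#' @export
read_reactions <- function(path, forward_only = FALSE, sep = ",") {
  if (!file.exists(path))
    abort_cgrnn(paste0("no such file: ", path), "cgrnn_io_error")
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         encoding = "UTF-8")
  need <- c("id", "rxn_smiles")
  if (!all(need %in% names(tab)))
    abort_cgrnn("reaction table must have columns id and rxn_smiles",
                "cgrnn_io_error")
  if (anyDuplicated(tab$id))
    abort_cgrnn(paste0("duplicate reaction id(s): ",
                       paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")),
                "cgrnn_id_error")
  dropped <- 0L
  if (forward_only && "is_reverse" %in% names(tab)) {
    rev_flag <- tab$is_reverse %in% c(TRUE, 1, "1", "true", "TRUE", "yes")
    dropped <- sum(rev_flag)
    tab <- tab[!rev_flag, , drop = FALSE]
  }
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rxn <- tryCatch(
      parse_reaction(tab$rxn_smiles[i], id = as.character(tab$id[i]),
                     barrier = if ("dE0" %in% names(tab)) tab$dE0[i]
                               else NA_real_),
      cgrnn_error = function(e)
        abort_cgrnn(sprintf("line %d (id %s): %s", i + 1L, tab$id[i],
                            conditionMessage(e)), class(e)[1]))
    records[[i]] <- list(id = as.character(tab$id[i]),
                         rxn_smiles = tab$rxn_smiles[i],
                         reaction = rxn, cgr = build_cgr(rxn),
                         y = rxn$barrier)
  }
  list(records = records,
       provenance = list(path = path, forward_only = forward_only,
                         rows_dropped = dropped))
}

#' Write records to a reaction table
#' @param records dataset records with `id`, `rxn_smiles` and optional `y`
#' @param path output path
#' @export
write_reactions <- function(records, path) {
  tab <- data.frame(
    id = vapply(records, function(r) r$id, character(1)),
    rxn_smiles = vapply(records, function(r) r$rxn_smiles, character(1)),
    dE0 = vapply(records, function(r)
      if (is.null(r$y)) NA_real_ else r$y, 0))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a conformer from an XYZ file
#'
#' Standard XYZ layout: atom-count line; a comment line carrying
#' `id=<reaction id> role=<r|ts|p> maps=<comma-separated atom-map indices>`;
#' then one `element x y z` line per atom (Angstrom).
#'
#' @param path file path
#' @return a `cgrnn_conformer`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    abort_cgrnn("XYZ file too short", "cgrnn_format_error")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n))
    abort_cgrnn("XYZ first line must be the atom count", "cgrnn_format_error")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    abort_cgrnn(sprintf("XYZ declares %d atoms but has %d atom lines",
                        n, length(body)), "cgrnn_format_error")
  meta <- lines[2]
  get_meta <- function(key) {
    m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
    if (length(m) < 2L)
      abort_cgrnn(paste0("XYZ comment line lacks ", key, "="),
                  "cgrnn_format_error")
    m[2]
  }
  id <- get_meta("id")
  role <- get_meta("role")
  if (!role %in% c("r", "ts", "p"))
    abort_cgrnn("XYZ role must be r, ts or p", "cgrnn_format_error")
  maps <- suppressWarnings(as.integer(strsplit(get_meta("maps"), ",")[[1]]))
  if (anyNA(maps) || length(maps) != n)
    abort_cgrnn("XYZ maps metadata must list one atom-map index per atom",
                "cgrnn_format_error")
  if (anyDuplicated(maps))
    abort_cgrnn("XYZ maps metadata is not a permutation (duplicates)",
                "cgrnn_alignment_error")
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(parts) != 4L))
    abort_cgrnn("XYZ atom lines must be: element x y z", "cgrnn_format_error")
  el <- vapply(parts, `[[`, character(1), 1L)
  xyz <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
  if (anyNA(xyz))
    abort_cgrnn("non-numeric coordinate in XYZ file", "cgrnn_format_error")
  conformer(el, xyz, maps, role = role, id = id)
}

#' Write a conformer to an XYZ file
#' @param conf a `cgrnn_conformer`
#' @param path output path
#' @export
write_xyz <- function(conf, path) {
  stopifnot(inherits(conf, "cgrnn_conformer"))
  lines <- c(
    as.character(length(conf$elements)),
    sprintf("id=%s role=%s maps=%s",
            if (is.null(conf$id)) "NA" else conf$id, conf$role,
            paste(conf$map_order, collapse = ",")),
    sprintf("%-2s %18.12f %18.12f %18.12f", conf$elements,
            conf$coordinates[, 1], conf$coordinates[, 2],
            conf$coordinates[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Attach conformers from XYZ files to a dataset bundle
#' @param bundle from [read_reactions()]
#' @param paths XYZ file paths
#' @return the bundle with `conformers` fields filled per record
#' @export
add_conformers <- function(bundle, paths) {
  ids <- vapply(bundle$records, function(r) r$id, character(1))
  for (p in paths) {
    conf <- read_xyz(p)
    i <- match(conf$id, ids)
    if (is.na(i))
      abort_cgrnn(paste0("conformer references unknown reaction id ", conf$id),
                  "cgrnn_id_error")
    bundle$records[[i]]$conformers[[conf$role]] <- conf
  }
  bundle
}

#' Write / read a split assignment as JSON
#' @param split a `cgrnn_split`
#' @param path JSON path
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(strategy = split$strategy, seed = split$seed,
         fractions = split$fractions, train = split$train,
         validation = split$validation, test = split$test,
         provenance = split$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .mk_split(as.character(x$train), as.character(x$validation),
            as.character(x$test), x$strategy, x$fractions,
            if (is.null(x$seed)) NA_integer_ else x$seed,
            if (is.null(x$provenance)) list() else x$provenance)
}

#' Save / load a model checkpoint
#'
#' Portable JSON archive: model configuration, target scaling statistics and
#' every named weight array with its dimensions.
#' @param state a `cgrnn_model_state`
#' @param path JSON path
#' @export
save_model <- function(state, path) {
  pr <- lapply(state$params, function(p)
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p)))
  jsonlite::write_json(
    list(config = unclass(state$config), dims = state$dims,
         p_width = state$p_width, d_in_atom = state$d_in_atom,
         y_mean = state$y_mean, y_sd = state$y_sd, params = pr),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  config <- model_config(cfg$hidden_dim, cfg$depth, cfg$activation,
                         cfg$dropout, cfg$pooling, cfg$ffn_layers,
                         cfg$ffn_hidden, cfg$extra_route,
                         cfg$extra_placement, cfg$extra_embed_dim)
  params <- lapply(x$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = config, dims = as.list(x$dims),
                 p_width = x$p_width, d_in_atom = x$d_in_atom,
                 y_mean = x$y_mean, y_sd = x$y_sd),
            class = "cgrnn_model_state")
}

#' Write predictions as delimited text
#' @param ids reaction ids
#' @param preds predicted barriers (kcal/mol)
#' @param path output path
#' @export
write_predictions <- function(ids, preds, path) {
  utils::write.csv(data.frame(id = ids, predicted_dE0 = preds), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
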