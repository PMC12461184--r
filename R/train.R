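#' Training configuration
#'
#' Optimization protocol: AdamW with beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8, cosine-annealing learning-rate schedule with a 10-step linear
#' warmup (one scheduler step per epoch), batch size 50. Weight decay is
#' decoupled (AdamW) and defaults to 0.
#'
#' @param epochs training epochs
#' @param batch_size reactions per gradient step
#' @param lr peak learning rate
#' @param lr_floor_frac final learning rate as a fraction of the peak
#' @param warmup_steps scheduler steps of linear warmup
#' @param beta1,beta2,eps AdamW moment parameters
#' @param weight_decay decoupled weight decay coefficient
#' @param grad_clip optional L2 norm bound on the per-step gradient (NULL off)
#' @param seed RNG seed controlling init, shuffling and dropout
#' @param verbose if TRUE, writes one line per epoch to stderr
#' @return object of class `cgrnn_train_config`
#' @export
train_config <- function(epochs = 100L, batch_size = 50L, lr = 1e-3,
                         lr_floor_frac = 0.01, warmup_steps = 10L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0, grad_clip = NULL,
                         seed = 0L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_floor_frac = lr_floor_frac,
                 warmup_steps = as.integer(warmup_steps),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "cgrnn_train_config")
}

# cosine annealing with linear warmup; one step per epoch
.lr_at <- function(step, tc) {
  if (step <= tc$warmup_steps && tc$warmup_steps > 0)
    return(tc$lr * step / tc$warmup_steps)
  floor_lr <- tc$lr * tc$lr_floor_frac
  span <- max(1L, tc$epochs - tc$warmup_steps)
  prog <- min(1, (step - tc$warmup_steps) / span)
  floor_lr + 0.5 * (tc$lr - floor_lr) * (1 + cos(pi * prog))
}

.adamw_step <- function(state, grads, opt, lr, tc) {
  for (nm in names(state$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- tc$beta1 * opt$m[[nm]] + (1 - tc$beta1) * g
    opt$v[[nm]] <- tc$beta2 * opt$v[[nm]] + (1 - tc$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - tc$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - tc$beta2^opt$t)
    state$params[[nm]] <- state$params[[nm]] -
      lr * (mhat / (sqrt(vhat) + tc$eps) +
              tc$weight_decay * state$params[[nm]])
  }
  list(state = state, opt = opt)
}

#' Train a D-MPNN barrier-height model
#'
#' Minimizes mean squared error on z-scored targets with AdamW and a
#' cosine-annealed learning rate (10 warmup steps). Targets are standardized
#' with training-partition statistics; the checkpoint with the lowest
#' validation MAE is returned. Fully reproducible for a fixed seed.
#'
#' @param records dataset records, each with `id`, `cgr` and `y` (kcal/mol)
#' @param split a `cgrnn_split` from one of the splitters (test partition is
#'   not touched)
#' @param config a [model_config()]
#' @param tc a [train_config()]
#' @return list with `state` (best checkpoint), `history` (data.frame of
#'   per-epoch train loss and validation MAE), `best_epoch`
#' @export
train_dmpnn <- function(records, split, config, tc = train_config()) {
  ids <- vapply(records, function(r) r$id, character(1))
  tr <- which(ids %in% split$train)
  va <- which(ids %in% split$validation)
  if (!length(tr) || !length(va))
    abort_cgrnn("empty train or validation partition", "cgrnn_data_error")
  y_tr <- vapply(records[tr], function(r) r$y, 0)
  if (anyNA(y_tr)) abort_cgrnn("missing target in training data",
                               "cgrnn_data_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(tc$seed)

  state <- dmpnn_init(config, records[[tr[1]]]$cgr, seed = tc$seed)
  state$y_mean <- mean(y_tr)
  state$y_sd <- if (stats::sd(y_tr) > 0) stats::sd(y_tr) else 1

  opt <- list(m = lapply(state$params, function(x) x * 0),
              v = lapply(state$params, function(x) x * 0), t = 0L)
  val_records <- records[va]
  best <- list(mae = Inf, state = state, epoch = 0L)
  hist_loss <- hist_vmae <- hist_lr <- numeric(tc$epochs)

  for (epoch in seq_len(tc$epochs)) {
    lr <- .lr_at(epoch, tc)
    perm <- sample(length(tr))
    batches <- split(tr[perm], ceiling(seq_along(perm) / tc$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      batch <- collate_graphs(records[b])
      ys <- (batch$y - state$y_mean) / state$y_sd
      fwd <- dmpnn_forward(batch, state, training = TRUE)
      resid <- fwd$out - ys
      loss <- mean(resid^2)
      if (!is.finite(loss))
        abort_cgrnn(paste0("non-finite training loss at epoch ", epoch),
                    "cgrnn_training_error")
      ep_loss <- ep_loss + loss * length(b); ep_n <- ep_n + length(b)
      grads <- dmpnn_backward(batch, state, fwd, 2 * resid / length(b))
      if (!is.null(tc$grad_clip)) {
        nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
        if (nrm > tc$grad_clip)
          grads <- lapply(grads, function(g) g * tc$grad_clip / nrm)
      }
      opt$t <- opt$t + 1L
      upd <- .adamw_step(state, grads, opt, lr, tc)
      state <- upd$state; opt <- upd$opt
    }
    vm <- evaluate_model(state, val_records)
    hist_loss[epoch] <- ep_loss / ep_n
    hist_vmae[epoch] <- vm$mae
    hist_lr[epoch] <- lr
    if (vm$mae < best$mae)
      best <- list(mae = vm$mae, state = state, epoch = epoch)
    if (tc$verbose)
      message(sprintf("epoch %3d  lr %.2e  train_mse %.4f  val_mae %.4f",
                      epoch, lr, hist_loss[epoch], vm$mae))
  }
  list(state = best$state, best_epoch = best$epoch,
       history = data.frame(epoch = seq_len(tc$epochs), lr = hist_lr,
                            train_loss = hist_loss, val_mae = hist_vmae))
}

#' Evaluate a model: MAE and RMSE in kcal/mol
#'
#' @param state a `cgrnn_model_state`
#' @param records dataset records with `cgr` and `y`
#' @return list with `mae`, `rmse`, `n`
#' @export
evaluate_model <- function(state, records) {
  if (!length(records)) abort_cgrnn("empty dataset", "cgrnn_data_error")
  y <- vapply(records, function(r) r$y, 0)
  pred <- predict_barriers(state, records)
  err <- pred - y
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), n = length(y))
}

#' Permutation feature importance
#'
#' For each extra-feature column, permutes that column's values across the
#' dataset (several seeded repeats) and reports the mean increase in MAE over
#' the unpermuted baseline. Positive delta-MAE marks a feature the model
#' relies on; negative values (feature hurt the model) are permitted.
#'
#' @param state trained model
#' @param records evaluation records with extras attached via `extra` fields
#'   and featurized `cgr`s (see [featurize_records()])
#' @param columns schema names to test (default: all extra columns present)
#' @param seed base seed; repeat r for column c uses a deterministic
#'   derived seed
#' @param repeats permutation repeats per column
#' @return data.frame with `column`, `delta_mae`, `rank`, plus the baseline
#'   MAE as attribute `baseline_mae`
#' @export
permutation_importance <- function(state, records, columns = NULL,
                                   seed = 0L, repeats = 5L) {
  all_cols <- unique(unlist(lapply(records, function(r)
    if (is.null(r$extra)) NULL else unlist(r$extra$names))))
  if (is.null(columns)) columns <- all_cols
  if (!length(columns))
    abort_cgrnn("no extra-feature columns to permute", "cgrnn_schema_error")
  bad <- setdiff(columns, all_cols)
  if (length(bad))
    abort_cgrnn(paste0("unknown column(s): ", paste(bad, collapse = ", ")),
                "cgrnn_schema_error")
  baseline <- evaluate_model(state, records)$mae
  delta <- vapply(seq_along(columns), function(ci) {
    dm <- vapply(seq_len(repeats), function(r) {
      s <- (as.integer(seed) * 1009L + ci * 131L + r) %% .Machine$integer.max
      perm <- permute_feature_column(records, columns[ci], s)
      perm <- featurize_records(perm)
      evaluate_model(state, perm)$mae - baseline
    }, 0)
    mean(dm)
  }, 0)
  out <- data.frame(column = columns, delta_mae = delta)
  out$rank <- rank(-out$delta_mae, ties.method = "first")
  attr(out, "baseline_mae") <- baseline
  out[order(out$rank), ]
}

#' Re-featurize records after their extras changed
#'
#' Rebuilds each record's `cgr` from its `reaction` and re-attaches the
#' (possibly permuted or subsetted) extras and positional features.
#' @param records dataset records carrying `reaction`, optional `extra` and
#'   optional `positional` fields
#' @param elements supported element list
#' @return records with fresh `cgr` fields
#' @export
featurize_records <- function(records, elements = default_elements()) {
  for (i in seq_along(records)) {
    r <- records[[i]]
    cgr <- build_cgr(r$reaction, elements)
    if (!is.null(r$positional)) cgr <- attach_positional(cgr, r$positional)
    if (!is.null(r$extra) &&
        (!is.null(r$extra$atom_r) || !is.null(r$extra$bond_r) ||
         !is.null(r$extra$mol_r)))
      cgr <- attach_extra(cgr, r$extra)
    records[[i]]$cgr <- cgr
  }
  records
}

#' Run a declarative grid of model/training configurations
#'
#' Plain exhaustive hook over configuration combinations: each grid entry
#' overrides [model_config()]/[train_config()] defaults; models are trained
#' on the same split and ranked by validation MAE.
#'
#' @param records dataset records
#' @param split a `cgrnn_split`
#' @param grid list of lists; each entry may carry `model` and `train`
#'   override lists
#' @return data.frame of configurations and their validation MAE, best first
#' @export
config_grid_search <- function(records, split, grid) {
  res <- lapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    mc <- do.call(model_config, if (is.null(g$model)) list() else g$model)
    tc <- do.call(train_config, if (is.null(g$train)) list() else g$train)
    fit <- train_dmpnn(records, split, mc, tc)
    data.frame(config = i, val_mae = min(fit$history$val_mae),
               best_epoch = fit$best_epoch)
  })
  out <- do.call(rbind, res)
  out[order(out$val_mae), ]
}
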