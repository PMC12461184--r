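#' D-MPNN model configuration
#'
#' @param hidden_dim hidden dimensionality h of the directed-edge states
#' @param depth number of message-passing steps T (0 allowed)
#' @param activation activation for all nonlinear layers (currently `relu`)
#' @param dropout dropout rate applied after each message-passing step and
#'   between FFN layers (0 disables)
#' @param pooling `mean` (default) or `sum` aggregation of atom embeddings
#' @param ffn_layers number of FFN layers (>= 1; the last is linear to 1)
#' @param ffn_hidden width of FFN hidden layers
#' @param extra_route how per-atom extra features enter the network:
#'   `none`, `route2_plain` (direct concatenation), `route1_linear_relu`
#'   (linear + ReLU embedding), or `route1_linear_relu_attention`
#'   (additionally one residual self-attention pass over the molecule's atoms)
#' @param extra_placement concatenate processed extras `before_mpnn` (they
#'   propagate through message passing) or `after_mpnn` (onto the atom
#'   embeddings just before pooling)
#' @param extra_embed_dim output width of the Route 1 embedding
#' @return object of class `cgrnn_model_config`
#' @export
model_config <- function(hidden_dim = 300L, depth = 3L, activation = "relu",
                         dropout = 0, pooling = c("mean", "sum"),
                         ffn_layers = 2L, ffn_hidden = hidden_dim,
                         extra_route = c("none", "route2_plain",
                                         "route1_linear_relu",
                                         "route1_linear_relu_attention"),
                         extra_placement = c("before_mpnn", "after_mpnn"),
                         extra_embed_dim = 64L) {
  pooling <- match.arg(pooling)
  extra_route <- match.arg(extra_route)
  extra_placement <- match.arg(extra_placement)
  stopifnot(hidden_dim > 0, depth >= 0, ffn_layers >= 1,
            dropout >= 0, dropout < 1, activation == "relu")
  structure(list(hidden_dim = as.integer(hidden_dim), depth = as.integer(depth),
                 activation = activation, dropout = dropout, pooling = pooling,
                 ffn_layers = as.integer(ffn_layers),
                 ffn_hidden = as.integer(ffn_hidden),
                 extra_route = extra_route, extra_placement = extra_placement,
                 extra_embed_dim = as.integer(extra_embed_dim)),
            class = "cgrnn_model_config")
}

.relu <- function(x) x * (x > 0)

.uinit <- function(nr, nc, bound) matrix(stats::runif(nr * nc, -bound, bound), nr, nc)

# feature dimensions of a dataset record/batch as the model sees them
.model_dims <- function(cgr) {
  xe <- length(cgr$extra_atom_cols)
  list(atom = ncol(cgr$atom_features) - xe,
       bond = ncol(cgr$bond_features),
       extra_atom = xe,
       extra_mol = length(cgr$extra_mol))
}

#' Initialize model weights
#'
#' All linear maps carry bias terms; weights are drawn from a seeded uniform
#' fan-in scheme (U(-1/sqrt(fan_in), +1/sqrt(fan_in))) so runs are exactly
#' reproducible.
#'
#' @param config a [model_config()]
#' @param dims list with `atom`, `bond`, `extra_atom`, `extra_mol` input
#'   widths (see [build_cgr()] / [attach_extra()]), or a `cgrnn_cgr` whose
#'   dimensions are taken
#' @param seed integer RNG seed
#' @return object of class `cgrnn_model_state`
#' @export
dmpnn_init <- function(config, dims, seed = 0L) {
  stopifnot(inherits(config, "cgrnn_model_config"))
  if (inherits(dims, "cgrnn_cgr")) dims <- .model_dims(dims)
  if (config$extra_route == "none" && dims$extra_atom > 0)
    abort_cgrnn("extra atom features present but extra_route is 'none'",
                "cgrnn_config_error")
  if (config$extra_route != "none" && dims$extra_atom == 0)
    abort_cgrnn("extra_route set but no extra atom features attached",
                "cgrnn_config_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  h <- config$hidden_dim
  p_width <- switch(config$extra_route,
                    none = 0L, route2_plain = dims$extra_atom,
                    config$extra_embed_dim)
  d_in_atom <- dims$atom +
    if (config$extra_placement == "before_mpnn") p_width else 0L
  d_edge <- d_in_atom + dims$bond
  d_pool <- h + if (config$extra_placement == "after_mpnn") p_width else 0L
  d_ffn_in <- d_pool + dims$extra_mol

  lin <- function(din, dout) {
    b <- 1 / sqrt(din)
    list(W = .uinit(din, dout, b), b = stats::runif(dout, -b, b))
  }
  params <- list()
  ei <- lin(d_edge, h); params$W_i <- ei$W; params$b_i <- ei$b
  wh <- lin(h, h); params$W_h <- wh$W; params$b_h <- wh$b
  w0 <- lin(d_in_atom + h, h); params$W_0 <- w0$W; params$b_0 <- w0$b
  if (config$extra_route %in% c("route1_linear_relu",
                                "route1_linear_relu_attention")) {
    we <- lin(dims$extra_atom, config$extra_embed_dim)
    params$W_e <- we$W; params$b_e <- we$b
  }
  if (config$extra_route == "route1_linear_relu_attention") {
    p <- config$extra_embed_dim
    for (nm in c("q", "k", "v")) {
      l <- lin(p, p)
      params[[paste0("W_att_", nm)]] <- l$W
      params[[paste0("b_att_", nm)]] <- l$b
    }
  }
  din <- d_ffn_in
  for (l in seq_len(config$ffn_layers)) {
    dout <- if (l == config$ffn_layers) 1L else config$ffn_hidden
    ff <- lin(din, dout)
    params[[paste0("ffn_W", l)]] <- ff$W
    params[[paste0("ffn_b", l)]] <- ff$b
    din <- dout
  }
  structure(list(params = params, config = config, dims = dims,
                 p_width = p_width, d_in_atom = d_in_atom,
                 y_mean = 0, y_sd = 1),
            class = "cgrnn_model_state")
}

#' Collate dataset records into one disjoint-union batch graph
#'
#' @param records list of records, each with a `cgr` (`cgrnn_cgr`) and
#'   optionally `y`
#' @return batch structure consumed by [dmpnn_forward()]
#' @export
collate_graphs <- function(records) {
  n_mol <- length(records)
  Xs <- list(); Bs <- list(); src <- dst <- eid <- rev <- integer(0)
  atom_mol <- integer(0)
  mol_extra <- list()
  xe_cols <- NULL
  a_off <- 0L; e_off <- 0L; de_off <- 0L
  y <- rep(NA_real_, n_mol)
  for (m in seq_len(n_mol)) {
    cgr <- records[[m]]$cgr
    stopifnot(inherits(cgr, "cgrnn_cgr"))
    Xs[[m]] <- cgr$atom_features
    Bs[[m]] <- cgr$bond_features
    if (is.null(xe_cols)) xe_cols <- cgr$extra_atom_cols
    else if (!identical(xe_cols, cgr$extra_atom_cols))
      abort_cgrnn("records disagree on extra atom feature columns",
                  "cgrnn_config_error")
    de <- directed_edge_features(cgr)
    src <- c(src, de$src + a_off); dst <- c(dst, de$dst + a_off)
    eid <- c(eid, de$eid + e_off); rev <- c(rev, de$rev + de_off)
    atom_mol <- c(atom_mol, rep(m, cgr$n_atoms))
    mol_extra[[m]] <- if (is.null(cgr$extra_mol)) numeric(0) else cgr$extra_mol
    if (!is.null(records[[m]]$y)) y[m] <- records[[m]]$y
    a_off <- a_off + cgr$n_atoms
    e_off <- e_off + nrow(cgr$edges)
    de_off <- de_off + length(de$src)
  }
  d_xm <- unique(lengths(mol_extra))
  if (length(d_xm) != 1L)
    abort_cgrnn("records disagree on molecule-level extra width",
                "cgrnn_config_error")
  Xfull <- do.call(rbind, Xs)
  Xe <- NULL; X <- Xfull
  if (length(xe_cols)) {
    Xe <- Xfull[, xe_cols, drop = FALSE]
    X <- Xfull[, -xe_cols, drop = FALSE]
  }
  list(X = X, Xe = Xe, B = do.call(rbind, Bs),
       src = src, dst = dst, eid = eid, rev = rev,
       atom_mol = atom_mol, n_atoms = a_off, n_mol = n_mol,
       counts = tabulate(atom_mol, n_mol),
       mol_extra = if (d_xm > 0) do.call(rbind, mol_extra)
                   else matrix(0, n_mol, 0),
       y = y)
}

.rowsum_all <- function(M, group, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M)) {
    rs <- rowsum(M, group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

.affine <- function(X, W, b) sweep(X %*% W, 2, b, "+")

.dropmask <- function(nr, nc, p) {
  if (p <= 0) NULL else matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# process the extra atomic feature block through the configured route;
# returns list(P, cache) where P is the processed block
.embed_extra_forward <- function(Xe, batch, state, config) {
  route <- config$extra_route
  if (route == "route2_plain") return(list(P = Xe, cache = NULL))
  Z1 <- .affine(Xe, state$params$W_e, state$params$b_e)
  R1 <- .relu(Z1)
  if (route == "route1_linear_relu")
    return(list(P = R1, cache = list(Z1 = Z1, R1 = R1)))
  # residual single-head scaled dot-product self-attention per molecule
  p <- ncol(R1)
  Qm <- .affine(R1, state$params$W_att_q, state$params$b_att_q)
  Km <- .affine(R1, state$params$W_att_k, state$params$b_att_k)
  Vm <- .affine(R1, state$params$W_att_v, state$params$b_att_v)
  P <- R1
  att <- vector("list", batch$n_mol)
  for (m in seq_len(batch$n_mol)) {
    I <- which(batch$atom_mol == m)
    S <- Qm[I, , drop = FALSE] %*% t(Km[I, , drop = FALSE]) / sqrt(p)
    S <- S - apply(S, 1, max)
    Wsm <- exp(S); Wsm <- Wsm / rowSums(Wsm)
    P[I, ] <- R1[I, , drop = FALSE] + Wsm %*% Vm[I, , drop = FALSE]
    att[[m]] <- Wsm
  }
  list(P = P, cache = list(Z1 = Z1, R1 = R1, Qm = Qm, Km = Km, Vm = Vm,
                           att = att))
}

#' Forward pass of the D-MPNN
#'
#' Directed edge states are initialized by a linear layer over
#' `cat(x_v, e_vw)`, updated for `depth` steps with
#' `h_vw^(t+1) = relu(h_vw^0 + W_h %*% sum of incoming states excluding the
#' reverse edge)`, aggregated per atom as `h_v = relu(W_0 cat(x_v, sum of
#' incoming final states))`, pooled per molecule, concatenated with any
#' molecule-level extras, and mapped to a scalar by the FFN.
#'
#' @param batch from [collate_graphs()]
#' @param state a `cgrnn_model_state`
#' @param training if TRUE, applies dropout (using the current RNG stream)
#'   and returns the caches needed by [dmpnn_backward()]
#' @return list with `pred` (kcal/mol, unscaled), `out` (model-scale output)
#'   and, when `training`, `cache`
#' @export
dmpnn_forward <- function(batch, state, training = FALSE) {
  config <- state$config
  pr <- state$params
  h <- config$hidden_dim
  dp <- if (training) config$dropout else 0

  if (is.null(batch$Xe) != (config$extra_route == "none"))
    abort_cgrnn("extra_route and attached extra features are inconsistent",
                "cgrnn_config_error")
  emb <- NULL; P <- NULL
  if (!is.null(batch$Xe) && config$extra_route != "none") {
    emb <- .embed_extra_forward(batch$Xe, batch, state, config)
    P <- emb$P
  }
  x_in <- if (!is.null(P) && config$extra_placement == "before_mpnn")
    cbind(batch$X, P) else batch$X

  E <- cbind(x_in[batch$src, , drop = FALSE],
             batch$B[batch$eid, , drop = FALSE])
  H0 <- .affine(E, pr$W_i, pr$b_i)
  H <- H0
  Hs <- vector("list", config$depth)      # post-activation states per step
  Ms <- vector("list", config$depth)      # aggregated messages per step
  masks <- vector("list", config$depth)   # relu masks
  dmasks <- vector("list", config$depth)  # dropout masks
  if (config$depth > 0 && nrow(H0) > 0) {
    for (t in seq_len(config$depth)) {
      SUM <- .rowsum_all(H, batch$dst, batch$n_atoms)
      M <- SUM[batch$src, , drop = FALSE] - H[batch$rev, , drop = FALSE]
      PRE <- sweep(M %*% pr$W_h, 2, pr$b_h, "+") + H0
      mask <- PRE > 0
      H <- PRE * mask
      dm <- .dropmask(nrow(H), ncol(H), dp)
      if (!is.null(dm)) H <- H * dm
      Hs[[t]] <- H; Ms[[t]] <- M; masks[[t]] <- mask; dmasks[t] <- list(dm)
    }
  }
  INC <- .rowsum_all(H, batch$dst, batch$n_atoms)
  Q <- cbind(x_in, INC)
  A_pre <- .affine(Q, pr$W_0, pr$b_0)
  A <- .relu(A_pre)
  dmA <- .dropmask(nrow(A), ncol(A), dp)
  if (!is.null(dmA)) A <- A * dmA
  A2 <- if (!is.null(P) && config$extra_placement == "after_mpnn")
    cbind(A, P) else A

  Mm <- .rowsum_all(A2, batch$atom_mol, batch$n_mol)
  if (config$pooling == "mean") Mm <- Mm / batch$counts
  Z <- if (ncol(batch$mol_extra) > 0) cbind(Mm, batch$mol_extra) else Mm

  Zs <- list(Z); Ss <- list(); dmF <- list()
  L <- config$ffn_layers
  for (l in seq_len(L)) {
    S <- .affine(Z, pr[[paste0("ffn_W", l)]], pr[[paste0("ffn_b", l)]])
    if (l < L) {
      Z <- .relu(S)
      dm <- .dropmask(nrow(Z), ncol(Z), dp)
      if (!is.null(dm)) Z <- Z * dm
      Ss[[l]] <- S; dmF[l] <- list(dm); Zs[[l + 1L]] <- Z
    } else {
      Z <- S
    }
  }
  out <- as.vector(Z)
  res <- list(pred = out * state$y_sd + state$y_mean, out = out)
  if (training)
    res$cache <- list(emb = emb, P = P, x_in = x_in, E = E, H0 = H0,
                      Hs = Hs, Ms = Ms, masks = masks, dmasks = dmasks,
                      H_final = H, INC = INC, Q = Q, A_pre = A_pre, A = A,
                      dmA = dmA, A2 = A2, Mm = Mm, Zs = Zs, Ss = Ss, dmF = dmF)
  res
}

#' Backward pass: gradients of a scalar loss wrt all parameters
#'
#' @param batch the collated batch used in the forward pass
#' @param state the model state
#' @param fwd result of `dmpnn_forward(batch, state, training = TRUE)`
#' @param dout gradient of the loss wrt the model-scale output `out`
#'   (length n_mol)
#' @return named list of gradients, shaped like `state$params`
#' @export
dmpnn_backward <- function(batch, state, fwd, dout) {
  config <- state$config
  pr <- state$params
  ca <- fwd$cache
  if (is.null(ca)) abort_cgrnn("forward pass was not run with training=TRUE",
                               "cgrnn_config_error")
  h <- config$hidden_dim
  grads <- lapply(pr, function(x) if (is.matrix(x)) x * 0 else numeric(length(x)))
  L <- config$ffn_layers
  dZ <- matrix(dout, ncol = 1)
  for (l in rev(seq_len(L))) {
    Wn <- paste0("ffn_W", l); bn <- paste0("ffn_b", l)
    if (l < L) {
      if (!is.null(ca$dmF[[l]])) dZ <- dZ * ca$dmF[[l]]
      dZ <- dZ * (ca$Ss[[l]] > 0)
    }
    grads[[Wn]] <- t(ca$Zs[[l]]) %*% dZ
    grads[[bn]] <- colSums(dZ)
    dZ <- dZ %*% t(pr[[Wn]])
  }
  d_pool <- ncol(ca$A2)
  dMm <- dZ[, seq_len(d_pool), drop = FALSE]  # molecule-extra block is input
  if (config$pooling == "mean") dMm <- dMm / batch$counts
  dA2 <- dMm[batch$atom_mol, , drop = FALSE]

  dP <- NULL
  if (!is.null(ca$P) && config$extra_placement == "after_mpnn") {
    dA <- dA2[, seq_len(ncol(ca$A)), drop = FALSE]
    dP <- dA2[, ncol(ca$A) + seq_len(ncol(ca$P)), drop = FALSE]
  } else dA <- dA2

  if (!is.null(ca$dmA)) dA <- dA * ca$dmA
  dA_pre <- dA * (ca$A_pre > 0)
  grads$W_0 <- t(ca$Q) %*% dA_pre
  grads$b_0 <- colSums(dA_pre)
  dQ <- dA_pre %*% t(pr$W_0)
  d_in_atom <- ncol(ca$x_in)
  dx_in <- dQ[, seq_len(d_in_atom), drop = FALSE]
  dINC <- dQ[, d_in_atom + seq_len(h), drop = FALSE]

  ne <- length(batch$src)
  dH0 <- matrix(0, ne, h)
  if (ne > 0) {
    dH <- dINC[batch$dst, , drop = FALSE]
    if (config$depth > 0) {
      for (t in rev(seq_len(config$depth))) {
        if (!is.null(ca$dmasks[[t]])) dH <- dH * ca$dmasks[[t]]
        dPRE <- dH * ca$masks[[t]]
        dH0 <- dH0 + dPRE
        grads$b_h <- grads$b_h + colSums(dPRE)
        grads$W_h <- grads$W_h + t(ca$Ms[[t]]) %*% dPRE
        dM <- dPRE %*% t(pr$W_h)
        G <- .rowsum_all(dM, batch$src, batch$n_atoms)
        dH <- G[batch$dst, , drop = FALSE] - dM[batch$rev, , drop = FALSE]
      }
      dH0 <- dH0 + dH  # H at step 0 is H0 itself
    } else {
      dH0 <- dH
    }
    grads$W_i <- t(ca$E) %*% dH0
    grads$b_i <- colSums(dH0)
    dE <- dH0 %*% t(pr$W_i)
    dx_in <- dx_in + .rowsum_all(dE[, seq_len(d_in_atom), drop = FALSE],
                                 batch$src, batch$n_atoms)
  }

  if (!is.null(ca$P) && config$extra_placement == "before_mpnn") {
    dX_base <- ncol(batch$X)
    dP <- dx_in[, dX_base + seq_len(ncol(ca$P)), drop = FALSE]
  }

  if (!is.null(dP) && config$extra_route != "route2_plain" &&
      config$extra_route != "none") {
    ec <- ca$emb$cache
    if (config$extra_route == "route1_linear_relu_attention") {
      p <- ncol(ec$R1)
      dR1 <- dP  # residual path
      dQm <- matrix(0, nrow(dP), p); dKm <- dQm; dVm <- dQm
      for (m in seq_len(batch$n_mol)) {
        I <- which(batch$atom_mol == m)
        Wsm <- ec$att[[m]]
        dO <- dP[I, , drop = FALSE]
        dVm[I, ] <- t(Wsm) %*% dO
        dWsm <- dO %*% t(ec$Vm[I, , drop = FALSE])
        dS <- Wsm * (dWsm - rowSums(dWsm * Wsm))
        dQm[I, ] <- dS %*% ec$Km[I, , drop = FALSE] / sqrt(p)
        dKm[I, ] <- t(dS) %*% ec$Qm[I, , drop = FALSE] / sqrt(p)
      }
      grads$W_att_q <- t(ec$R1) %*% dQm; grads$b_att_q <- colSums(dQm)
      grads$W_att_k <- t(ec$R1) %*% dKm; grads$b_att_k <- colSums(dKm)
      grads$W_att_v <- t(ec$R1) %*% dVm; grads$b_att_v <- colSums(dVm)
      dR1 <- dR1 + dQm %*% t(pr$W_att_q) + dKm %*% t(pr$W_att_k) +
        dVm %*% t(pr$W_att_v)
    } else {
      dR1 <- dP
    }
    dZ1 <- dR1 * (ec$Z1 > 0)
    grads$W_e <- t(batch$Xe) %*% dZ1
    grads$b_e <- colSums(dZ1)
  }
  grads
}

#' Naive per-edge reference evaluation of the D-MPNN
#'
#' Independent re-implementation used as a correctness oracle: neighbor sets
#' are rediscovered by scanning the edge list, messages are accumulated in
#' explicit per-edge loops, and no indexing machinery is shared with
#' [dmpnn_forward()]. Single-graph, no dropout.
#'
#' @param cgr a `cgrnn_cgr` (extras attached as for the fast path)
#' @param state a `cgrnn_model_state`
#' @return scalar prediction in kcal/mol
#' @export
dmpnn_forward_reference <- function(cgr, state) {
  config <- state$config
  pr <- state$params
  n <- cgr$n_atoms
  xe_cols <- cgr$extra_atom_cols
  Xfull <- cgr$atom_features
  if (length(xe_cols)) {
    Xe <- Xfull[, xe_cols, drop = FALSE]
    X <- Xfull[, -xe_cols, drop = FALSE]
  } else { Xe <- NULL; X <- Xfull }

  P <- NULL
  if (!is.null(Xe) && config$extra_route != "none") {
    if (config$extra_route == "route2_plain") P <- Xe
    else {
      P <- matrix(0, n, config$extra_embed_dim)
      for (v in seq_len(n))
        P[v, ] <- pmax(0, as.vector(Xe[v, ] %*% pr$W_e) + pr$b_e)
      if (config$extra_route == "route1_linear_relu_attention") {
        p <- ncol(P)
        Qm <- Km <- Vm <- matrix(0, n, p)
        for (v in seq_len(n)) {
          Qm[v, ] <- as.vector(P[v, ] %*% pr$W_att_q) + pr$b_att_q
          Km[v, ] <- as.vector(P[v, ] %*% pr$W_att_k) + pr$b_att_k
          Vm[v, ] <- as.vector(P[v, ] %*% pr$W_att_v) + pr$b_att_v
        }
        Pnew <- P
        for (v in seq_len(n)) {
          sc <- vapply(seq_len(n), function(w) sum(Qm[v, ] * Km[w, ]), 0) / sqrt(p)
          w_ <- exp(sc - max(sc)); w_ <- w_ / sum(w_)
          acc <- numeric(p)
          for (w in seq_len(n)) acc <- acc + w_[w] * Vm[w, ]
          Pnew[v, ] <- P[v, ] + acc
        }
        P <- Pnew
      }
    }
  }
  x_in <- if (!is.null(P) && config$extra_placement == "before_mpnn")
    cbind(X, P) else X

  # directed edges: for undirected edge k (v,w) make v->w and w->v
  ne <- nrow(cgr$edges)
  de_src <- integer(0); de_dst <- integer(0); de_bond <- integer(0)
  for (k in seq_len(ne)) {
    de_src <- c(de_src, cgr$edges[k, 1], cgr$edges[k, 2])
    de_dst <- c(de_dst, cgr$edges[k, 2], cgr$edges[k, 1])
    de_bond <- c(de_bond, k, k)
  }
  nde <- length(de_src)
  H <- matrix(0, nde, config$hidden_dim)
  for (e in seq_len(nde)) {
    feat <- c(x_in[de_src[e], ], cgr$bond_features[de_bond[e], ])
    H[e, ] <- as.vector(feat %*% pr$W_i) + pr$b_i
  }
  H0 <- H
  if (config$depth > 0) for (t in seq_len(config$depth)) {
    Hn <- H
    for (e in seq_len(nde)) {
      v <- de_src[e]; w <- de_dst[e]
      msg <- numeric(config$hidden_dim)
      for (e2 in seq_len(nde)) {
        # incoming edges k->v, excluding the reverse edge w->v
        if (de_dst[e2] == v && de_src[e2] != w) msg <- msg + H[e2, ]
      }
      Hn[e, ] <- pmax(0, H0[e, ] + as.vector(msg %*% pr$W_h) + pr$b_h)
    }
    H <- Hn
  }
  A <- matrix(0, n, config$hidden_dim)
  for (v in seq_len(n)) {
    inc <- numeric(config$hidden_dim)
    for (e in seq_len(nde)) if (de_dst[e] == v) inc <- inc + H[e, ]
    q <- c(x_in[v, ], inc)
    A[v, ] <- pmax(0, as.vector(q %*% pr$W_0) + pr$b_0)
  }
  if (!is.null(P) && config$extra_placement == "after_mpnn") A <- cbind(A, P)
  hm <- if (config$pooling == "mean") colMeans(A) else colSums(A)
  if (!is.null(cgr$extra_mol)) hm <- c(hm, cgr$extra_mol)
  z <- hm
  for (l in seq_len(config$ffn_layers)) {
    z <- as.vector(z %*% pr[[paste0("ffn_W", l)]]) + pr[[paste0("ffn_b", l)]]
    if (l < config$ffn_layers) z <- pmax(0, z)
  }
  z * state$y_sd + state$y_mean
}

#' Predict barrier heights for a set of records
#'
#' @param state trained `cgrnn_model_state`
#' @param records dataset records with `cgr` fields
#' @param batch_size records per forward batch
#' @return numeric vector of predictions (kcal/mol), in record order
#' @export
predict_barriers <- function(state, records, batch_size = 50L) {
  n <- length(records)
  preds <- numeric(n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (b in idx) {
    batch <- collate_graphs(records[b])
    preds[b] <- dmpnn_forward(batch, state)$pred
  }
  preds
}
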