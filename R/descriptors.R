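#' Construct a conformer
#'
#' @param elements character vector of element symbols, in file order
#' @param coordinates n x 3 matrix of Cartesian coordinates (Angstrom)
#' @param map_order integer vector: atom-map index of each row, linking the
#'   conformer to the reaction's atoms
#' @param role one of "r", "ts", "p"
#' @param id reaction id the conformer belongs to
#' @return object of class `cgrnn_conformer`
#' @export
conformer <- function(elements, coordinates, map_order,
                      role = c("r", "ts", "p"), id = NULL) {
  role <- match.arg(role)
  coordinates <- as.matrix(coordinates)
  if (length(elements) != nrow(coordinates) ||
      length(elements) != length(map_order))
    abort_cgrnn("elements, coordinates and map_order lengths differ",
                "cgrnn_alignment_error")
  if (anyDuplicated(map_order))
    abort_cgrnn("duplicate atom-map index in conformer", "cgrnn_alignment_error")
  structure(list(elements = as.character(elements), coordinates = coordinates,
                 map_order = as.integer(map_order), role = role, id = id),
            class = "cgrnn_conformer")
}

#' AEV descriptor configuration
#'
#' Atomic environment vector built from modified Behler-Parrinello symmetry
#' functions (radial and angular) with a smooth cosine cutoff, as used in the
#' ANI potentials. Defaults follow the reference implementation's grids:
#' radial cutoff 5.2 A with 16 shifts, angular cutoff 3.5 A with 8 angle and
#' 4 distance shifts.
#'
#' @param elements species list; descriptor blocks are per species (radial)
#'   and per unordered species pair (angular)
#' @param radial_cutoff,angular_cutoff cutoff radii (Angstrom)
#' @param eta_radial,eta_angular Gaussian widths (1/A^2)
#' @param n_radial,n_ang_radial,n_theta grid resolutions
#' @param zeta angular sharpness exponent
#' @return object of class `cgrnn_descriptor_config`
#' @export
aev_config <- function(elements = default_elements(),
                       radial_cutoff = 5.2, eta_radial = 16, n_radial = 16,
                       angular_cutoff = 3.5, eta_angular = 8,
                       n_ang_radial = 4, n_theta = 8, zeta = 32) {
  stopifnot(radial_cutoff > 0, angular_cutoff > 0)
  s <- length(elements)
  width <- s * n_radial + (s * (s + 1L) / 2L) * n_theta * n_ang_radial
  structure(list(kind = "aev", elements = elements,
                 radial_cutoff = radial_cutoff, eta_radial = eta_radial,
                 radial_shifts = seq(0.9, radial_cutoff,
                                     length.out = n_radial + 1L)[seq_len(n_radial)],
                 angular_cutoff = angular_cutoff, eta_angular = eta_angular,
                 ang_radial_shifts = seq(0.9, angular_cutoff,
                                         length.out = n_ang_radial + 1L)[seq_len(n_ang_radial)],
                 theta_shifts = (seq_len(n_theta) - 0.5) * pi / n_theta,
                 zeta = zeta, width = as.integer(width)),
            class = "cgrnn_descriptor_config")
}

#' SOAP descriptor configuration
#'
#' Smooth-overlap power-spectrum descriptor in the point-density limit:
#' the neighbor density is expanded in a Gaussian radial basis times real
#' spherical harmonics, and the rotation-invariant power spectrum
#' p(Z1 n, Z2 n', l) = sum_m c(Z1 n l m) c(Z2 n' l m) is reported per
#' species pair.
#'
#' @param elements species list
#' @param cutoff cutoff radius (Angstrom)
#' @param n_max number of radial basis functions
#' @param l_max maximum spherical-harmonic degree
#' @return object of class `cgrnn_descriptor_config`
#' @export
soap_config <- function(elements = default_elements(), cutoff = 5.0,
                        n_max = 6, l_max = 4) {
  stopifnot(cutoff > 0, n_max >= 1, l_max >= 0)
  s <- length(elements)
  per_l_same <- n_max * (n_max + 1L) / 2L
  width <- (l_max + 1L) *
    (s * per_l_same + (s * (s - 1L) / 2L) * n_max * n_max)
  structure(list(kind = "soap", elements = elements, cutoff = cutoff,
                 n_max = as.integer(n_max), l_max = as.integer(l_max),
                 radial_centers = seq(0, cutoff, length.out = n_max + 1L)[-1L],
                 radial_width = cutoff / n_max,
                 width = as.integer(width)),
            class = "cgrnn_descriptor_config")
}

.cosine_cutoff <- function(r, rc) ifelse(r < rc, 0.5 * cos(pi * r / rc) + 0.5, 0)

.check_conformer_elements <- function(conf, config) {
  bad <- setdiff(unique(conf$elements), config$elements)
  if (length(bad))
    abort_cgrnn(paste0("conformer element(s) outside descriptor species set: ",
                       paste(bad, collapse = ", ")), "cgrnn_element_error")
}

#' Atomic environment vectors (AEV)
#'
#' Per-atom radial and angular symmetry functions. Radial block, per species
#' Z and shift Rs: sum over neighbors j of species Z of
#' exp(-eta (r_ij - Rs)^2) fc(r_ij). Angular block, per unordered species
#' pair and (theta_s, Rs) grid point: 2^(1-zeta) sum over neighbor pairs of
#' (1 + cos(theta_ijk - theta_s))^zeta
#' exp(-eta_a ((r_ij + r_ik)/2 - Rs)^2) fc(r_ij) fc(r_ik).
#' Atoms beyond the cutoff contribute nothing (smooth cosine cutoff).
#'
#' @param conf a `cgrnn_conformer`
#' @param config an [aev_config()]
#' @return numeric matrix, one row per atom (conformer file order)
#' @export
aev <- function(conf, config) {
  stopifnot(inherits(conf, "cgrnn_conformer"), config$kind == "aev")
  .check_conformer_elements(conf, config)
  n <- length(conf$elements)
  out <- matrix(0, n, config$width)
  if (n == 0L) return(out)
  xyz <- conf$coordinates
  d <- as.matrix(stats::dist(xyz))
  spec <- match(conf$elements, config$elements)
  s <- length(config$elements)
  nr <- length(config$radial_shifts)
  nth <- length(config$theta_shifts)
  nar <- length(config$ang_radial_shifts)
  pair_index <- matrix(0L, s, s)  # unordered species pair -> block id
  k <- 0L
  for (a in seq_len(s)) for (b in a:s) {
    k <- k + 1L
    pair_index[a, b] <- k; pair_index[b, a] <- k
  }
  radial_len <- s * nr

  for (i in seq_len(n)) {
    nb <- which(d[i, ] < config$radial_cutoff & seq_len(n) != i)
    if (!length(nb)) next
    r <- d[i, nb]
    fc <- .cosine_cutoff(r, config$radial_cutoff)
    # radial: species-blocked sums over the shift grid
    g <- exp(-config$eta_radial *
               outer(r, config$radial_shifts, "-")^2) * fc  # nb x nr
    for (zi in unique(spec[nb])) {
      rows <- spec[nb] == zi
      cols <- (zi - 1L) * nr + seq_len(nr)
      out[i, cols] <- out[i, cols] + colSums(g[rows, , drop = FALSE])
    }
    # angular: neighbor pairs within the angular cutoff
    nba <- nb[d[i, nb] < config$angular_cutoff]
    if (length(nba) >= 2L) {
      ra <- d[i, nba]
      fca <- .cosine_cutoff(ra, config$angular_cutoff)
      vec <- sweep(xyz[nba, , drop = FALSE], 2, xyz[i, ])
      prs <- utils::combn(seq_along(nba), 2L)
      for (pi_ in seq_len(ncol(prs))) {
        j <- prs[1, pi_]; kk <- prs[2, pi_]
        ct <- sum(vec[j, ] * vec[kk, ]) / (ra[j] * ra[kk])
        ct <- max(-1, min(1, ct))
        # interior scaling of the cosine (as in the ANI implementations):
        # keeps acos away from its singular endpoints so the angular terms
        # stay numerically stable for collinear triples
        theta <- acos(0.95 * ct)
        rad <- exp(-config$eta_angular *
                     ((ra[j] + ra[kk]) / 2 - config$ang_radial_shifts)^2)
        ang <- (1 + cos(theta - config$theta_shifts))^config$zeta
        blk <- pair_index[spec[nba[j]], spec[nba[kk]]]
        cols <- radial_len + (blk - 1L) * nth * nar +
          seq_len(nth * nar)
        contrib <- 2^(1 - config$zeta) * as.vector(outer(ang, rad)) *
          fca[j] * fca[kk]
        out[i, cols] <- out[i, cols] + contrib
      }
    }
  }
  out
}

# real spherical harmonics Y_lm for one l over unit directions;
# pracma::legendre includes the Condon-Shortley phase
.real_sph_harm <- function(l, cos_theta, phi) {
  nj <- length(cos_theta)
  if (l == 0L) return(matrix(sqrt(1 / (4 * pi)), 1, nj))
  P <- pracma::legendre(l, cos_theta)           # (l+1) x nj, m = 0..l
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  Y <- matrix(0, 2L * l + 1L, nj)               # rows: m = -l..l
  Y[l + 1L, ] <- sqrt((2 * l + 1) / (4 * pi)) * P[1L, ]
  for (m in seq_len(l)) {
    N <- sqrt((2 * l + 1) / (2 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    Y[l + 1L + m, ] <- N * P[m + 1L, ] * cos(m * phi)
    Y[l + 1L - m, ] <- N * P[m + 1L, ] * sin(m * phi)
  }
  Y
}

#' SOAP power-spectrum descriptors
#'
#' Expands each atom's neighbor density (point contributions weighted by a
#' Gaussian radial basis and the smooth cosine cutoff) in real spherical
#' harmonics and reports the per-species-pair power spectrum, which is exactly
#' invariant to rigid rotations and translations of the conformer.
#'
#' @param conf a `cgrnn_conformer`
#' @param config a [soap_config()]
#' @return numeric matrix, one row per atom (conformer file order)
#' @export
soap <- function(conf, config) {
  stopifnot(inherits(conf, "cgrnn_conformer"), config$kind == "soap")
  .check_conformer_elements(conf, config)
  n <- length(conf$elements)
  out <- matrix(0, n, config$width)
  if (n == 0L) return(out)
  xyz <- conf$coordinates
  d <- as.matrix(stats::dist(xyz))
  spec <- match(conf$elements, config$elements)
  s <- length(config$elements)
  nmax <- config$n_max; lmax <- config$l_max
  tri <- which(upper.tri(matrix(0, nmax, nmax), diag = TRUE))

  for (i in seq_len(n)) {
    nb <- which(d[i, ] < config$cutoff & seq_len(n) != i)
    # c[[Z]][[l]] : nmax x (2l+1) expansion coefficients
    cz <- lapply(seq_len(s), function(z)
      lapply(0:lmax, function(l) matrix(0, nmax, 2L * l + 1L)))
    if (length(nb)) {
      r <- d[i, nb]
      vec <- sweep(xyz[nb, , drop = FALSE], 2, xyz[i, ])
      cos_theta <- vec[, 3] / r
      cos_theta <- pmax(-1, pmin(1, cos_theta))
      phi <- atan2(vec[, 2], vec[, 1])
      fc <- .cosine_cutoff(r, config$cutoff)
      Rn <- exp(-(outer(config$radial_centers, r, "-")^2) /
                  (2 * config$radial_width^2)) *
        rep(fc, each = nmax)                     # nmax x nb
      for (z in unique(spec[nb])) {
        sel <- spec[nb] == z
        for (l in 0:lmax) {
          Y <- .real_sph_harm(l, cos_theta[sel], phi[sel])  # (2l+1) x nsel
          cz[[z]][[l + 1L]] <- Rn[, sel, drop = FALSE] %*% t(Y)
        }
      }
    }
    # power spectrum, fixed (Z1<=Z2, l, n<=n' | n,n') ordering
    feats <- numeric(0)
    for (z1 in seq_len(s)) for (z2 in z1:s) {
      for (l in 0:lmax) {
        norm <- pi * sqrt(8 / (2 * l + 1))
        p <- norm * (cz[[z1]][[l + 1L]] %*% t(cz[[z2]][[l + 1L]]))
        feats <- c(feats, if (z1 == z2) p[tri] else as.vector(p))
      }
    }
    out[i, ] <- feats
  }
  out
}

#' Compute a descriptor for a conformer
#' @param conf a `cgrnn_conformer`
#' @param config an [aev_config()] or [soap_config()]
#' @return per-atom descriptor matrix in conformer file order
#' @export
compute_descriptor <- function(conf, config) {
  switch(config$kind,
         aev = aev(conf, config),
         soap = soap(conf, config),
         abort_cgrnn("unknown descriptor kind", "cgrnn_config_error"))
}

#' Assemble positional features across reaction roles
#'
#' Computes (or looks up, via `provider`) per-atom descriptors for each
#' requested role and concatenates the blocks in the fixed order r, ts, p.
#' Rows are re-ordered from conformer file order to CGR atom order (ascending
#' atom-map index) using each conformer's `map_order`.
#'
#' @param conformers named list with elements among `r`, `ts`, `p`
#' @param roles_used subset of c("r","ts","p") to include
#' @param config descriptor configuration (ignored when `provider` given)
#' @param provider optional function(conformer) returning a per-atom matrix in
#'   conformer file order (external learned descriptors enter here)
#' @param maps optional atom-map index set of the reaction, used to validate
#'   alignment
#' @param impute_missing if TRUE, a missing role contributes an all-zero
#'   block instead of raising an error (ablation use only)
#' @return matrix (n_atoms x width), with attributes `roles_used` and
#'   `role_width`
#' @export
positional_features <- function(conformers, roles_used = c("r", "ts", "p"),
                                config = NULL, provider = NULL, maps = NULL,
                                impute_missing = FALSE) {
  roles_used <- intersect(c("r", "ts", "p"), roles_used)  # fixed order
  if (!length(roles_used))
    abort_cgrnn("roles_used must name at least one role", "cgrnn_config_error")
  blocks <- list()
  width <- NULL
  for (role in roles_used) {
    conf <- conformers[[role]]
    if (is.null(conf)) {
      if (!impute_missing)
        abort_cgrnn(paste0("missing conformer for role '", role, "'"),
                    "cgrnn_missing_conformer_error")
      blocks[[role]] <- NA  # placeholder, filled once width known
      next
    }
    if (!is.null(maps) && !setequal(conf$map_order, maps))
      abort_cgrnn("conformer map_order does not match the reaction's atoms",
                  "cgrnn_alignment_error")
    m <- if (is.null(provider)) compute_descriptor(conf, config)
         else as.matrix(provider(conf))
    if (nrow(m) != length(conf$map_order))
      abort_cgrnn("descriptor row count does not match conformer atoms",
                  "cgrnn_alignment_error")
    blocks[[role]] <- m[order(conf$map_order), , drop = FALSE]
    if (is.null(width)) width <- ncol(m)
    else if (width != ncol(m))
      abort_cgrnn("descriptor widths differ across roles", "cgrnn_config_error")
  }
  if (is.null(width))
    abort_cgrnn("no conformer available for any requested role",
                "cgrnn_missing_conformer_error")
  n <- nrow(blocks[[which(!vapply(blocks, function(b) all(is.na(b)), logical(1)))[1]]])
  blocks <- lapply(blocks, function(b)
    if (all(is.na(b))) matrix(0, n, width) else b)
  out <- do.call(cbind, blocks[roles_used])
  attr(out, "roles_used") <- roles_used
  attr(out, "role_width") <- width
  out
}

#' Attach positional features to a CGR
#'
#' Appends the positional block to `atom_features`, recording the appended
#' columns in `extra_atom_cols` so the model's embedding routes can treat
#' them as the extra atomic feature vector.
#' @param cgr a `cgrnn_cgr`
#' @param pos matrix from [positional_features()] (rows in CGR atom order)
#' @return augmented `cgrnn_cgr`
#' @export
attach_positional <- function(cgr, pos) {
  stopifnot(inherits(cgr, "cgrnn_cgr"))
  if (nrow(pos) != cgr$n_atoms)
    abort_cgrnn("positional feature rows do not match CGR atoms",
                "cgrnn_alignment_error")
  start <- ncol(cgr$atom_features) + 1L
  cgr$atom_features <- cbind(cgr$atom_features, pos)
  cgr$extra_atom_cols <- c(cgr$extra_atom_cols,
                           seq.int(start, length.out = ncol(pos)))
  cgr
}
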