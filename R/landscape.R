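#' Conformational-landscape embedding: alignment, PCA, TICA, density, DCC
#'
#' The landscape is built on the flattened Cartesian coordinates of the
#' membrane-embedded backbone particles (HP1 u HP2): BB beads for
#' coarse-grained trajectories, C-alpha for atomistic/static models. That 1:1
#' residue mapping lets static predictor models be projected into a space
#' trained on trajectories. Frames are rigid-body aligned to a common
#' reference first, so the principal components describe internal (packing)
#' motion, not diffusion of the bundle as a whole.
#'
#' @name landscape
NULL

#' Rigid-body align every frame onto a reference
#'
#' Each frame is Kabsch-superposed onto the reference coordinates using the
#' fit selection; the resulting transform is applied to all particles.
#'
#' @param traj a [trajectory()].
#' @param reference frame index into `traj`, or an `n_fit x 3` coordinate
#'   matrix for the fit selection.
#' @param fit_idx particle indices used for the fit (default: all particles).
#' @return An aligned [trajectory()].
#' @export
align_trajectory <- function(traj, reference = 1L, fit_idx = NULL) {
  fit_idx <- fit_idx %||% seq_len(nrow(traj$particles))
  if (length(fit_idx) < 3L) stopf("fit selection needs >= 3 particles")
  ref <- if (is.matrix(reference)) reference else
    frame_coords(traj, reference)[fit_idx, , drop = FALSE]
  if (nrow(ref) != length(fit_idx))
    stopf("reference has %d rows but fit selection has %d particles",
          nrow(ref), length(fit_idx))
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    fit <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref)
    out[i, , ] <- xyz %*% fit$rotation +
      matrix(fit$translation, nrow(xyz), 3L, byrow = TRUE)
  }
  trajectory(traj$particles, out, dt = traj$dt,
             representation = traj$representation)
}

#' Feature matrix: flattened coordinates of a particle selection
#'
#' @param traj a [trajectory()].
#' @param idx particle indices (default all); features are ordered
#'   x1,y1,z1,x2,... following `idx`.
#' @return `n_frames x (3 * length(idx))` matrix.
#' @export
traj_features <- function(traj, idx = NULL) {
  idx <- idx %||% seq_len(nrow(traj$particles))
  n <- n_frames(traj)
  X <- matrix(NA_real_, n, 3L * length(idx))
  for (i in seq_len(n)) X[i, ] <- t(frame_coords(traj, i)[idx, , drop = FALSE])
  X
}

fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    p <- which.max(abs(V[, j]))
    if (V[p, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Principal component analysis of a feature matrix
#'
#' Eigendecomposition of the feature covariance; components are ordered by
#' decreasing eigenvalue and carry a deterministic sign (largest-magnitude
#' loading positive). `reference` records the coordinates frames were aligned
#' to, so static models can be superposed before projection.
#'
#' @param X `n_frames x n_features` matrix of aligned coordinates.
#' @param reference optional `n_particles x 3` reference coordinate matrix.
#' @return list of class `PCAModel`: `$mean`, `$vectors` (orthonormal
#'   columns), `$values` (non-negative, non-increasing), `$fractions`
#'   (explained-variance fractions summing to 1), `$reference`.
#' @export
fit_pca <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 frames, got %d", nrow(X))
  if (ncol(X) < 2L) stopf("need feature dimension >= 2")
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(mean = mu, vectors = fix_eigen_signs(e$vectors),
                 values = vals, fractions = vals / sum(vals),
                 reference = reference),
            class = "PCAModel")
}

#' Project coordinates into a PCA space
#'
#' For raw feature rows, projection is `(x - mean) %*% vectors`. A
#' [structure_model()] is first mapped to the feature particle set (residue
#' -> C-alpha/BB bead) and Kabsch-fitted onto the PCA reference coordinates,
#' then projected; without that superposition a static model would land at an
#' arbitrary spot of the landscape.
#'
#' @param pca a [fit_pca()] model.
#' @param x feature row(s) (vector or matrix) or a [structure_model()].
#' @param residues residue numbers of the feature particles, in feature order;
#'   required when `x` is a structure model.
#' @param k number of components to return (default all).
#' @return matrix of PC coordinates (one row per input frame/model).
#' @export
project <- function(pca, x, residues = NULL, k = NULL) {
  k <- k %||% ncol(pca$vectors)
  if (inherits(x, "StructureModel")) {
    if (is.null(residues)) stopf("projecting a structure requires `residues`")
    xyz <- ca_coords(x, residues = residues)
    ref <- pca$reference %||% matrix(pca$mean, ncol = 3L, byrow = TRUE)
    fit <- kabsch_superpose(xyz, ref)
    xyz <- xyz %*% fit$rotation +
      matrix(fit$translation, nrow(xyz), 3L, byrow = TRUE)
    x <- as.numeric(t(xyz))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(pca$mean))
    stopf("feature dimension mismatch: %d vs %d", ncol(x), length(pca$mean))
  sweep(x, 2L, pca$mean) %*% pca$vectors[, seq_len(k), drop = FALSE]
}

#' Time-lagged independent component analysis (symmetrized estimator)
#'
#' Solves the generalized eigenproblem of the symmetrized lagged covariance
#' against the instantaneous covariance, using lagged pairs drawn within
#' segments only (never across replica boundaries). Whitening drops
#' near-null covariance directions. Under this estimator all eigenvalues lie
#' in `[-1, 1]` (up to round-off) and time-reversing the input changes
#' nothing.
#'
#' @param segments a feature matrix or a list of per-replica feature matrices.
#' @param lag lag time in frames; must be shorter than every segment.
#' @return list of class `TICAModel`: `$lag`, `$values` (decreasing),
#'   `$vectors` (generalized eigenvectors in feature space), `$timescales`
#'   (implied, `-lag / log(|lambda|)`), `$mean`.
#' @export
fit_tica <- function(segments, lag = 100L) {
  if (is.matrix(segments)) segments <- list(segments)
  lens <- vapply(segments, nrow, integer(1L))
  if (any(lens <= lag))
    stopf("lag (%d) must be shorter than every segment (min length %d)",
          lag, min(lens))
  d <- ncol(segments[[1L]])
  mu_n <- 0L; mu <- numeric(d)
  for (S in segments) {
    idx0 <- seq_len(nrow(S) - lag); idx1 <- idx0 + lag
    mu <- mu + colSums(S[idx0, , drop = FALSE]) + colSums(S[idx1, , drop = FALSE])
    mu_n <- mu_n + 2L * length(idx0)
  }
  mu <- mu / mu_n
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (S in segments) {
    idx0 <- seq_len(nrow(S) - lag); idx1 <- idx0 + lag
    A <- sweep(S[idx0, , drop = FALSE], 2L, mu)
    B <- sweep(S[idx1, , drop = FALSE], 2L, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B) + crossprod(B, A)
  }
  C0 <- C0 / mu_n
  Ct <- Ct / mu_n
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-10
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  ew <- eigen(crossprod(W, Ct %*% W), symmetric = TRUE)
  vals <- ew$values
  vecs <- fix_eigen_signs(W %*% ew$vectors)
  structure(list(lag = lag, values = vals, vectors = vecs,
                 timescales = ifelse(abs(vals) >= 1, Inf,
                                     -lag / log(pmin(abs(vals), 1))),
                 mean = mu),
            class = "TICAModel")
}

#' Project features onto TICA components
#' @param tica a [fit_tica()] model.
#' @param x feature row(s).
#' @param k number of components.
#' @export
project_tica <- function(tica, x, k = 2L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(x, 2L, tica$mean) %*% tica$vectors[, seq_len(k), drop = FALSE]
}

#' Dynamical cross-correlation matrix
#'
#' Normalized correlation of per-particle displacement vectors about their
#' trajectory means: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Particles that do not move get correlation 0 (with a warning).
#'
#' @param traj a [trajectory()] (aligned; rigid-body motion should be removed
#'   first).
#' @param idx particle indices (default all).
#' @return symmetric matrix in `[-1, 1]` with unit diagonal (0 diagonal for
#'   immobile particles).
#' @export
dcc <- function(traj, idx = NULL) {
  idx <- idx %||% seq_len(nrow(traj$particles))
  if (n_frames(traj) < 10L) stopf("need >= 10 frames for DCC")
  n <- length(idx)
  nf <- n_frames(traj)
  # <dr_i . dr_j> accumulated per Cartesian component
  C <- matrix(0, n, n)
  for (k in 1:3) {
    M <- matrix(traj$coords[, idx, k], nrow = nf, ncol = n)
    M <- sweep(M, 2L, colMeans(M))
    C <- C + crossprod(M) / nf
  }
  v <- diag(C)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero))
    warning(sprintf("%d zero-variance particle(s); correlations set to 0",
                    sum(zero)), call. = FALSE)
  denom <- sqrt(outer(v, v))
  out <- matrix(0, n, n)
  ok <- denom > 0
  out[ok] <- C[ok] / denom[ok]
  out[zero, ] <- 0; out[, zero] <- 0
  pmin(pmax(out, -1), 1)
}

#' 2-D density grid over PC coordinates
#'
#' Normalized 2-D histogram (integrates to 1 over the grid area), with basin
#' modes reported. Modes are found on a Gaussian kernel density estimate of
#' the same domain (normal-reference bandwidth) and filtered by topological
#' persistence: a peak only counts as a basin when it rises at least
#' `mode_rel_min` of the global maximum above the saddle connecting it to a
#' higher peak. This keeps sampling noise and shoulder satellites from being
#' reported as separate basins; tiny inputs fall back to the raw histogram.
#'
#' @param points `n x 2` matrix of (PC1, PC2) coordinates.
#' @param bins number of bins per axis (default 60).
#' @param pad fractional padding of the data range.
#' @param mode_rel_min minimum persistence of a reported mode, relative to
#'   the global maximum of the mode-finding surface.
#' @return list of class `DensityGrid`: `$density` (bins x bins, integrates
#'   to 1), `$xbreaks`, `$ybreaks`, `$modes` (data.frame x, y, density;
#'   density is the KDE height at the mode).
#' @export
density2d <- function(points, bins = 60L, pad = 0.05, mode_rel_min = 0.1) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stopf("need at least one point")
  rng <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w <- 1
    r + c(-1, 1) * pad * w
  }
  xb <- seq(rng(points[, 1L])[1L], rng(points[, 1L])[2L], length.out = bins + 1L)
  yb <- seq(rng(points[, 2L])[1L], rng(points[, 2L])[2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(points[, 1L], xb, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(points[, 2L], yb, all.inside = TRUE), 1L), bins)
  H <- matrix(0, bins, bins)
  for (r in seq_len(nrow(points))) H[ix[r], iy[r]] <- H[ix[r], iy[r]] + 1
  area <- diff(xb)[1L] * diff(yb)[1L]
  dens <- H / (sum(H) * area)
  modes <- find_modes(points, dens, xb, yb, mode_rel_min)
  structure(list(density = dens, xbreaks = xb, ybreaks = yb, modes = modes),
            class = "DensityGrid")
}

find_modes <- function(points, dens, xb, yb, rel_min) {
  kde_ok <- nrow(points) >= 10L &&
    diff(range(points[, 1L])) > 0 && diff(range(points[, 2L])) > 0
  if (kde_ok) {
    kd <- MASS::kde2d(points[, 1L], points[, 2L], n = nrow(dens),
                      lims = c(range(xb), range(yb)))
    surf <- kd$z
    xc <- kd$x; yc <- kd$y
  } else {
    surf <- dens
    xc <- (utils::head(xb, -1L) + xb[-1L]) / 2
    yc <- (utils::head(yb, -1L) + yb[-1L]) / 2
  }
  pk <- persistent_peaks(surf, max(surf) * rel_min)
  if (nrow(pk) == 0L)
    return(data.frame(x = numeric(), y = numeric(), density = numeric()))
  out <- data.frame(x = xc[pk$i], y = yc[pk$j], density = pk$height)
  out[order(-out$density), , drop = FALSE]
}

# Topological persistence of grid peaks: sweep cells by decreasing value,
# union-find over 8-connected components; when a component merges into a
# higher one, its peak dies at the current (saddle) level. Peaks whose
# height - saddle >= min_persistence survive; the global maximum always does.
persistent_peaks <- function(surf, min_persistence) {
  n <- nrow(surf); m <- ncol(surf)
  ord <- order(surf, decreasing = TRUE)
  ord <- ord[surf[ord] > 0]
  parent <- integer(n * m)              # 0 = not yet seen
  peak_cell <- integer(n * m)           # representative -> its peak cell
  peak_height <- numeric(n * m)
  alive <- logical(n * m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  out <- list()
  for (cell in ord) {
    i <- (cell - 1L) %% n + 1L
    j <- (cell - 1L) %/% n + 1L
    v <- surf[cell]
    parent[cell] <- cell
    peak_cell[cell] <- cell; peak_height[cell] <- v; alive[cell] <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > n || jj < 1L || jj > m) next
      nb <- (jj - 1L) * n + ii
      if (nb == cell || parent[nb] == 0L) next
      ra <- find(cell); rb <- find(nb)
      if (ra == rb) next
      # lower peak dies at this saddle
      lo <- if (peak_height[ra] <= peak_height[rb]) ra else rb
      hi <- if (lo == ra) rb else ra
      pers <- peak_height[lo] - v
      if (alive[lo] && pers >= min_persistence) {
        pc <- peak_cell[lo]
        out[[length(out) + 1L]] <- data.frame(
          i = (pc - 1L) %% n + 1L, j = (pc - 1L) %/% n + 1L,
          height = peak_height[lo])
      }
      alive[lo] <- FALSE
      parent[lo] <- hi
    }
  }
  # surviving components (incl. the global maximum) persist fully
  roots <- unique(vapply(which(parent > 0), find, integer(1L)))
  for (r in roots[alive[roots]]) {
    if (peak_height[r] >= min_persistence) {
      pc <- peak_cell[r]
      out[[length(out) + 1L]] <- data.frame(
        i = (pc - 1L) %% n + 1L, j = (pc - 1L) %/% n + 1L,
        height = peak_height[r])
    }
  }
  if (length(out) == 0L) return(data.frame(i = integer(), j = integer(),
                                           height = numeric()))
  do.call(rbind, out)
}
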