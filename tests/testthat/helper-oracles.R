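# Independent oracles, deliberately naive: nested loops, grids, exhaustive
# enumeration. They must never share code paths with the implementation.

# Rotation matrix from unit axis + angle (Rodrigues).
axis_angle_rotation <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Minimum RMSD over rigid transforms by brute-force rotation search:
# coarse axis/angle grid, then local refinement to 0.5 degree steps.
# Both point sets are centred, removing translation exactly.
grid_rmsd_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2L, colMeans(mobile))
  Q <- sweep(reference, 2L, colMeans(reference))
  cost <- function(R) sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  best <- list(rmsd = Inf)
  axes <- fib_sphere(300)
  for (k in seq_len(nrow(axes))) {
    for (th in seq(0, pi, by = 5 * pi / 180)) {
      r <- cost(axis_angle_rotation(axes[k, ], th))
      if (r < best$rmsd) best <- list(rmsd = r, axis = axes[k, ], angle = th)
    }
  }
  step <- 0.5 * pi / 180
  for (pass in 1:3) {
    improved <- FALSE
    for (dth in seq(-10, 10) * step) {
      for (da in seq_len(60)) {
        pert <- best$axis + stats::rnorm(3, 0, 0.02 * pass)
        r <- cost(axis_angle_rotation(pert, best$angle + dth))
        if (r < best$rmsd) {
          best <- list(rmsd = r, axis = pert / sqrt(sum(pert^2)),
                       angle = best$angle + dth)
          improved <- TRUE
        }
      }
      r0 <- cost(axis_angle_rotation(best$axis, best$angle + dth))
      if (r0 < best$rmsd) {
        best$rmsd <- r0; best$angle <- best$angle + dth; improved <- TRUE
      }
    }
    if (!improved && pass > 1) break
  }
  best$rmsd
}

# Nested-loop pairwise distance between two coordinate sets.
loop_distance_oracle <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  out
}

# Nested-loop mass-weighted residue centre of mass from an atom table.
loop_com_oracle <- function(atoms, resno, masses) {
  rows <- which(atoms$resno == resno)
  num <- c(0, 0, 0); den <- 0
  for (r in rows) {
    num <- num + masses[r] * c(atoms$x[r], atoms$y[r], atoms$z[r])
    den <- den + masses[r]
  }
  num / den
}

# Nested-loop PAE block means/mins.
loop_pae_block_oracle <- function(pae, lens) {
  ends <- cumsum(lens); starts <- c(1, head(ends, -1) + 1)
  out <- list()
  for (i in seq_along(lens)) for (j in seq_along(lens)) {
    s <- 0; mn <- Inf; n <- 0
    for (r in starts[i]:ends[i]) for (cc in starts[j]:ends[j]) {
      s <- s + pae[r, cc]; n <- n + 1
      if (pae[r, cc] < mn) mn <- pae[r, cc]
    }
    out[[paste0(i, "_", j)]] <- c(mean = s / n, min = mn)
  }
  out
}

# Best-of-restarts k-medoids cost, mirroring elbow_select's restart policy
# (one greedy max-min start, the rest seeded random subsets).
best_kmedoids_cost <- function(pts, k, n_restarts = 10L) {
  min(vapply(seq_len(n_restarts), function(r)
    kmedoids(pts, k, seed = r,
             init_method = if (r == 1L) "maxmin" else "random")$cost,
    numeric(1)))
}

# Exhaustive k-medoids: minimum cost over all medoid subsets of size k.
exhaustive_kmedoids_oracle <- function(points, k) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  combos <- utils::combn(n, k)
  best <- Inf
  for (c in seq_len(ncol(combos))) {
    meds <- combos[, c]
    cost <- sum(apply(D[, meds, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# Loop-accumulated covariance + dense eigensolver PCA oracle.
loop_pca_oracle <- function(X) {
  n <- nrow(X); d <- ncol(X)
  mu <- numeric(d)
  for (i in seq_len(n)) mu <- mu + X[i, ]
  mu <- mu / n
  C <- matrix(0, d, d)
  for (i in seq_len(n)) {
    v <- X[i, ] - mu
    C <- C + outer(v, v)
  }
  C <- C / (n - 1)
  eigen(C, symmetric = TRUE)
}

# Adjusted Rand index from the pair-counting contingency formula.
adjusted_rand_oracle <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  exp_idx <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Direct scan ejection oracle: first index i such that frames i..i+p-1 are
# all outside the slab + margin.
scan_ejection_oracle <- function(z, upper, lower, margin, persistence) {
  out <- z > upper + margin | z < lower - margin
  for (i in seq_len(length(z) - persistence + 1L)) {
    if (all(out[i:(i + persistence - 1L)])) return(i)
  }
  NA_integer_
}
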