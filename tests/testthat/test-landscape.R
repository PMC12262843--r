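test_that("align_trajectory collapses rigid-body motion and is idempotent", {
  set.seed(11)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  frames <- lapply(1:20, function(i)
    base %*% t(random_rotation()) + matrix(rnorm(3, sd = 8), 10, 3,
                                           byrow = TRUE))
  traj <- traj_from_frames(c(list(base), frames))
  al <- align_trajectory(traj, reference = 1L)
  for (i in seq_len(n_frames(al)))
    expect_lt(kabsch_superpose(frame_coords(al, i), base)$rmsd, 1e-8)
  # total post-alignment variance of a rigidly moving trajectory ~ 0
  X <- traj_features(al)
  expect_lt(sum(apply(X, 2, var)), 1e-10)
  # idempotence
  al2 <- align_trajectory(al, reference = 1L)
  expect_equal(al2$coords, al$coords, tolerance = 1e-10)
  expect_error(align_trajectory(traj, fit_idx = 1:2), ">= 3")
})

test_that("per-frame alignment RMSD equals the kabsch oracle on a wobble trajectory", {
  sm <- make_subdomain_map()
  sim <- simulate_trajectory(synthetic_spec(n_frames = 30, seed = 13))
  idx <- default_feature_idx(sim$traj)
  ref <- frame_coords(sim$traj, 1)[idx, ]
  al <- align_trajectory(sim$traj, reference = ref, fit_idx = idx)
  for (f in c(2L, 15L, 30L)) {
    direct <- kabsch_superpose(frame_coords(sim$traj, f)[idx, ], ref)$rmsd
    aligned_rmsd <- sqrt(mean(rowSums((frame_coords(al, f)[idx, ] - ref)^2)))
    expect_equal(aligned_rmsd, direct, tolerance = 1e-8)
  }
})

test_that("fit_pca matches the loop-covariance dense-eigensolver oracle", {
  set.seed(21)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% diag(c(5, 3, 2, 1, 0.5, 0.1))
  p <- fit_pca(X)
  orc <- loop_pca_oracle(X)
  expect_equal(p$values, pmax(orc$values, 0), tolerance = 1e-8)
  for (j in 1:6)
    expect_equal(abs(sum(p$vectors[, j] * orc$vectors[, j])), 1,
                 tolerance = 1e-8)
  # invariants: fractions sum to 1, orthonormal columns, decreasing values
  expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  expect_equal(crossprod(p$vectors), diag(6), tolerance = 1e-8)
  expect_true(all(diff(p$values) <= 1e-12))
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:6) expect_gt(p$vectors[which.max(abs(p$vectors[, j])), j], 0)
})

test_that("fit_pca handles degenerate and isotropic inputs", {
  # variance only along x
  X <- cbind(rnorm(100), 0, 0)
  p <- fit_pca(X)
  expect_equal(p$fractions[1], 1, tolerance = 1e-12)
  # isotropic 3-D Gaussian: three near-equal fractions
  set.seed(99)
  p3 <- fit_pca(matrix(rnorm(3e4), 1e4, 3))
  expect_true(all(abs(p3$fractions - 1 / 3) < 0.02))
  expect_error(fit_pca(matrix(1, 1, 5)), "at least 2")
})

test_that("project is centred, complete, and maps static models via Kabsch", {
  set.seed(31)
  X <- matrix(rnorm(50 * 9, sd = 2), 50, 9)
  p <- fit_pca(X)
  expect_equal(as.numeric(project(p, p$mean)), rep(0, 9), tolerance = 1e-10)
  # full-basis reconstruction of a training frame is exact
  y <- project(p, X[7, ])
  rec <- p$mean + as.numeric(y %*% t(p$vectors))
  expect_equal(rec, X[7, ], tolerance = 1e-8)
  expect_error(project(p, rnorm(5)), "dimension")

  # a structure equal to the reference projects like its feature row
  ref <- matrix(X[3, ], ncol = 3, byrow = TRUE)
  p2 <- fit_pca(X, reference = ref)
  m <- model_from_coords(ref, resno = 1:3)
  moved <- model_from_coords(ref %*% t(random_rotation()) + 5, resno = 1:3)
  expect_equal(as.numeric(project(p2, m, residues = 1:3)),
               as.numeric(project(p2, X[3, ])), tolerance = 1e-8)
  expect_equal(as.numeric(project(p2, moved, residues = 1:3)),
               as.numeric(project(p2, X[3, ])), tolerance = 1e-6)
  expect_error(project(p2, m), "residues")
})

test_that("fit_tica recovers the relaxation of a two-state jump process", {
  set.seed(41)
  n <- 1e5
  flip <- 0.02                       # symmetric switch probability per step
  s <- integer(n); s[1] <- 1L
  r <- runif(n)
  for (t in 2:n) s[t] <- if (r[t] < flip) 3L - s[t - 1L] else s[t - 1L]
  X <- cbind(ifelse(s == 1L, 1, -1) + rnorm(n, 0, 0.05),
             rnorm(n, 0, 0.05))
  lag <- 10L
  tm <- fit_tica(X, lag = lag)
  lam_expected <- (1 - 2 * flip)^lag
  expect_equal(tm$values[1], lam_expected, tolerance = 0.1 * lam_expected)
  expect_true(all(abs(tm$values) <= 1 + 1e-6))
  # implied timescale tracks -1/log(1-2p)
  expect_equal(tm$timescales[1], -1 / log(1 - 2 * flip),
               tolerance = 0.15 * -1 / log(1 - 2 * flip))
})

test_that("TICA is symmetric under time reversal and refuses long lags", {
  set.seed(43)
  X <- matrix(rnorm(500 * 4), 500, 4)
  for (j in 2:500) X[j, ] <- 0.8 * X[j - 1, ] + X[j, ]
  f <- fit_tica(X, lag = 5L)
  b <- fit_tica(X[nrow(X):1, ], lag = 5L)
  expect_equal(f$values, b$values, tolerance = 1e-10)
  # white noise: no slow modes
  W <- matrix(rnorm(5e4), 1e4, 5)
  tw <- fit_tica(W, lag = 10L)
  expect_true(all(tw$timescales < 10))
  expect_error(fit_tica(X[1:10, ], lag = 50L), "lag")
  # lagged pairs never cross segment boundaries: two copies of one segment
  # give the same estimate as that segment alone
  one <- fit_tica(X, lag = 5L)
  two <- fit_tica(list(X, X), lag = 5L)
  expect_equal(one$values, two$values, tolerance = 1e-10)
})

test_that("leading TICA component separates two planted architectures", {
  sm <- make_subdomain_map()
  spec <- synthetic_spec(architecture = c("TM2-TM3", "separated"),
                         switch_rate = 0.005, n_frames = 1500, seed = 17)
  sim <- simulate_trajectory(spec, sm)
  idx <- default_feature_idx(sim$traj)
  al <- align_trajectory(sim$traj, fit_idx = idx)
  X <- traj_features(al, idx)
  tm <- fit_tica(X, lag = 50L)
  ic1 <- project_tica(tm, X, k = 1L)
  km <- kmedoids(cbind(as.numeric(ic1), 0), 2, seed = 1)
  purity <- max(mean((km$labels == 1) == (sim$truth$state_index == 1)),
                mean((km$labels == 2) == (sim$truth$state_index == 1)))
  expect_gt(purity, 0.9)
})

test_that("dcc matches its defining formula and flags immobile particles", {
  set.seed(51)
  n <- 200
  base <- rnorm(n, sd = 2)
  frames <- lapply(1:n, function(t) rbind(
    c(base[t], 0, 0),       # particle 1
    c(base[t], 0, 0),       # identical motion
    c(-base[t], 0, 0),      # opposite motion
    c(5, 5, 5)))            # immobile
  traj <- traj_from_frames(frames)
  expect_warning(C <- dcc(traj), "zero-variance")
  expect_equal(diag(C)[1:3], rep(1, 3), tolerance = 1e-12)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  expect_equal(C[4, ], rep(0, 4))
  expect_true(all(C >= -1 & C <= 1))
  expect_equal(C, t(C))
})

test_that("dcc shows coherent intra-hairpin blocks on the synthetic bundle", {
  sm <- make_subdomain_map()
  sim <- simulate_trajectory(synthetic_spec(n_frames = 400, seed = 19,
                                            sigma = 1.5))
  idx <- default_feature_idx(sim$traj)
  al <- align_trajectory(sim$traj, fit_idx = idx)
  C <- dcc(al, idx)
  res <- al$particles$resno[idx]
  tm1 <- which(res %in% interval_residues(sm$intervals$TM1))
  tm2 <- which(res %in% interval_residues(sm$intervals$TM2))
  # beads of one helix move as a unit -> strong positive intra-helix block
  expect_gt(mean(C[tm1, tm1]), 0.5)
  expect_gt(mean(C[tm2, tm2]), 0.5)
})

test_that("density2d normalizes, finds modes, and flattens uniform input", {
  # single point -> one occupied bin carrying all mass
  g1 <- density2d(matrix(c(0.5, 0.5), 1), bins = 10)
  area <- diff(g1$xbreaks)[1] * diff(g1$ybreaks)[1]
  expect_equal(sum(g1$density) * area, 1, tolerance = 1e-12)
  expect_equal(sum(g1$density > 0), 1L)

  # two well-separated blobs -> two modes
  set.seed(61)
  pts <- rbind(matrix(rnorm(4000, 0, 0.5), ncol = 2),
               matrix(rnorm(4000, 10, 0.5), ncol = 2))
  g2 <- density2d(pts, bins = 40)
  expect_equal(sum(g2$density) * diff(g2$xbreaks)[1] * diff(g2$ybreaks)[1], 1,
               tolerance = 1e-9)
  expect_equal(nrow(g2$modes), 2L)
  # modes sit near the planted blob centres
  expect_true(any(abs(g2$modes$x) < 1 & abs(g2$modes$y) < 1))
  expect_true(any(abs(g2$modes$x - 10) < 1 & abs(g2$modes$y - 10) < 1))

  # uniform grid -> near-flat density
  u <- as.matrix(expand.grid(seq(0, 1, length.out = 40),
                             seq(0, 1, length.out = 40)))
  g3 <- density2d(u, bins = 8, pad = 0)
  occ <- g3$density[g3$density > 0]
  expect_lt(max(occ) / min(occ), 1.5)
})

test_that("2-D PCA projection separates two architectures almost linearly", {
  sm <- make_subdomain_map()
  # one replica pinned per architecture, pooled into one PCA
  sims <- lapply(c("TM2-TM3", "separated"), function(a)
    simulate_trajectory(synthetic_spec(architecture = a, n_frames = 600,
                                       seed = 23), sm))
  idx <- default_feature_idx(sims[[1]]$traj)
  ref <- frame_coords(sims[[1]]$traj, 1)[idx, ]
  X <- do.call(rbind, lapply(sims, function(s)
    traj_features(align_trajectory(s$traj, reference = ref, fit_idx = idx),
                  idx)))
  pca <- fit_pca(X)
  pcs <- project(pca, X, k = 2L)
  lab <- rep(1:2, each = 600)
  # a 1-D threshold on the dominant PC should split the states
  best <- 0
  for (pc in 1:2) {
    m1 <- median(pcs[lab == 1, pc]); m2 <- median(pcs[lab == 2, pc])
    thr <- (m1 + m2) / 2
    acc <- mean((pcs[, pc] > thr) == (lab == 1))
    best <- max(best, acc, 1 - acc)
  }
  expect_gte(best, 0.95)
})
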