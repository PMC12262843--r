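test_that("kmedoids honours degenerate limits and determinism", {
  set.seed(71)
  pts <- matrix(rnorm(20), 10, 2)
  cm <- kmedoids(pts, k = 10, seed = 1)
  expect_equal(cm$cost, 0)
  expect_equal(sort(cm$medoids), 1:10)
  expect_error(kmedoids(pts, 11), "exceeds")
  expect_error(kmedoids(pts, 0), ">= 1")
  # deterministic given seed; medoids are data points
  a <- kmedoids(pts, 3, seed = 42)
  b <- kmedoids(pts, 3, seed = 42)
  expect_identical(a$medoids, b$medoids)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$medoids %in% 1:10))
  # each medoid minimises summed in-cluster distance at convergence
  D <- as.matrix(dist(pts))
  for (c in seq_len(a$k)) {
    members <- which(a$labels == c)
    costs <- colSums(D[members, members, drop = FALSE])
    expect_equal(min(costs), costs[as.character(a$medoids[c])][[1]],
                 tolerance = 1e-12)
  }
})

test_that("kmedoids cost equals exhaustive enumeration on small fixtures", {
  set.seed(73)
  for (rep in 1:50) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(2 * n, sd = 3), n, 2)
    oracle <- exhaustive_kmedoids_oracle(pts, k)
    # best over mixed restarts, matching how the package scans k
    expect_equal(best_kmedoids_cost(pts, k), oracle, tolerance = 1e-9)
  }
})

test_that("two planted blobs at 6 sigma are recovered perfectly over 20 seeds", {
  for (seed in 1:20) {
    set.seed(seed + 100)
    blob1 <- matrix(rnorm(100, 0, 1), ncol = 2)
    blob2 <- matrix(rnorm(100, 6, 1), ncol = 2)
    pts <- rbind(blob1, blob2)
    truth <- rep(1:2, each = 50)
    cm <- kmedoids(pts, 2, seed = seed)
    purity <- max(mean((cm$labels == 1) == (truth == 1)),
                  mean((cm$labels == 2) == (truth == 1)))
    expect_equal(purity, 1)
  }
})

test_that("label permutation invariance: relabeling leaves cost and medoids fixed", {
  set.seed(77)
  pts <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
               matrix(rnorm(60, 8, 1), ncol = 2),
               matrix(rnorm(60, c(0, 16), 1), ncol = 2))
  cm <- kmedoids(pts, 3, seed = 5)
  D <- as.matrix(dist(pts))
  # recompute cost from labels+medoids directly
  direct <- sum(vapply(seq_len(nrow(pts)), function(i)
    D[i, cm$medoids[cm$labels[i]]], numeric(1)))
  expect_equal(cm$cost, direct, tolerance = 1e-9)
  # shuffling the cluster ids changes neither the medoid set nor the cost
  perm <- c(3, 1, 2)
  relabeled <- perm[cm$labels]
  direct2 <- sum(vapply(seq_len(nrow(pts)), function(i)
    D[i, cm$medoids[match(relabeled[i], perm)]], numeric(1)))
  expect_equal(direct2, cm$cost, tolerance = 1e-9)
})

test_that("elbow_select finds planted blob counts and audits its curve", {
  set.seed(81)
  mk_blobs <- function(centers, n = 60, sd = 0.6)
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      cbind(rnorm(n, centers[i, 1], sd), rnorm(n, centers[i, 2], sd))))
  five <- mk_blobs(rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 20)))
  e5 <- elbow_select(five, k_range = 2:8, seed = 3)
  expect_equal(e5$k, 5L)
  expect_length(e5$costs, 7L)
  expect_true(all(diff(e5$costs) <= 1e-9))  # non-increasing curve
  two <- mk_blobs(rbind(c(0, 0), c(12, 0)))
  expect_equal(elbow_select(two, k_range = 2:6, seed = 3)$k, 2L)
  # no structure: flat-ish curve must not crash; single duplicated point
  flat <- matrix(1, 10, 2)
  expect_warning(ef <- elbow_select(flat, k_range = 2:4, seed = 1), "flat")
  expect_equal(ef$k, 2L)
  single <- matrix(rnorm(200), 100, 2)
  es <- elbow_select(single, k_range = 2:6, seed = 1)
  expect_lte(es$k, 4L)
  expect_error(elbow_select(single, k_range = 2:200), "k_range")
})

test_that("representatives deliver medoid structures and planted fingerprints", {
  sm <- make_subdomain_map()
  sim_a <- simulate_trajectory(synthetic_spec(architecture = "TM2-TM3",
                                              n_frames = 150, seed = 91))
  sim_e <- simulate_trajectory(synthetic_spec(architecture = "separated",
                                              n_frames = 150, seed = 92))
  idx <- default_feature_idx(sim_a$traj)
  ref <- frame_coords(sim_a$traj, 1)[idx, ]
  al_a <- align_trajectory(sim_a$traj, reference = ref, fit_idx = idx)
  al_e <- align_trajectory(sim_e$traj, reference = ref, fit_idx = idx)
  concat <- concat_trajectories(list(al_a, al_e))
  X <- traj_features(concat, idx)
  pca <- fit_pca(X, reference = ref)
  pcs <- project(pca, X, k = 2)
  cm <- kmedoids(pcs, 2, seed = 1)
  reps <- representatives(cm, concat, sm, metric = "CA")
  labels <- vapply(reps, function(r) r$interface$label, character(1))
  expect_setequal(labels, c("TM2-TM3", "none"))
  ia <- which(labels == "TM2-TM3"); ie <- which(labels == "none")
  # contact-architecture fingerprint: TM2-TM3 block occupied vs empty map
  hp1res <- interval_residues(sm$HP1)
  tm2rows <- as.character(intersect(hp1res, interval_residues(sm$intervals$TM2)))
  tm3cols <- as.character(interval_residues(sm$intervals$TM3))
  expect_gt(mean(reps[[ia]]$fingerprint[tm2rows, tm3cols]), 0.2)
  # separated basin: fingerprint near-empty (rare grazing contacts only)
  expect_lt(mean(reps[[ie]]$fingerprint), 0.01)
  expect_gt(mean(reps[[ia]]$fingerprint), 10 * mean(reps[[ie]]$fingerprint))
  expect_equal(sum(vapply(reps, function(r) r$size, integer(1))), 300L)

  # single-member cluster: fingerprint equals that frame's boolean map
  pts1 <- rbind(pcs[1:5, ], c(1e4, 1e4))
  cm1 <- kmedoids(pts1, 2, seed = 1)
  solo <- which(vapply(1:2, function(c) sum(cm1$labels == c), integer(1)) == 1)
  # the far point is index 6 but there is no frame 6+ problem: 6 <= n_frames
  reps1 <- representatives(cm1, concat, sm, metric = "CA")
  expect_equal(reps1[[solo]]$size, 1L)
  fs <- frame_structure(concat, cm1$medoids[solo])
  direct <- contact_map(distance_map(fs, sm$HP1, sm$HP2, metric = "CA"), 12)$m
  expect_equal(reps1[[solo]]$fingerprint, direct + 0)

  bad <- cm; bad$medoids[1] <- n_frames(concat) + 5L
  expect_error(representatives(bad, concat, sm), "not resolvable")
})
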