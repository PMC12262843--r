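#' K-medoids (PAM-style) clustering of the PC projection
#'
#' Deterministic given a seed: medoids are initialised by a greedy max-min
#' heuristic from the seeded RNG and refined by alternating assignment
#' (nearest medoid, Euclidean) and medoid update (in-cluster summed-distance
#' minimiser) until the labels stabilise. All ties break to the lowest point
#' index, and the total cost is checked to be non-increasing at every
#' iteration.
#'
#' @param points `n x d` coordinate matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed RNG seed.
#' @param init optional integer vector of `k` initial medoid indices
#'   (overrides the seeded initialisation).
#' @param init_method `"maxmin"` (greedy max-min heuristic, default) or
#'   `"random"` (seeded random subset); restart schemes mix both because the
#'   max-min heuristic yields at most n distinct starts.
#' @param max_iter iteration cap.
#' @param swap_max apply the full PAM swap-refinement phase (O(k n^2) per
#'   sweep) only when `n <= swap_max`; beyond that the alternation plus
#'   seeded restarts stand alone.
#' @return list of class `ClusterModel`: `$k`, `$medoids` (point indices,
#'   sorted), `$labels` (per point, 1..k in medoid order), `$cost` (summed
#'   point-to-medoid distance), `$seed`.
#' @export
kmedoids <- function(points, k, seed = 1L, init = NULL, max_iter = 100L,
                     swap_max = 500L, init_method = c("maxmin", "random")) {
  init_method <- match.arg(init_method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L) stopf("k must be >= 1")
  if (k > n) stopf("k (%d) exceeds number of points (%d)", k, n)
  medoids <- if (!is.null(init)) {
    if (length(unique(init)) != k) stopf("init must hold %d distinct indices", k)
    as.integer(init)
  } else if (init_method == "maxmin") {
    greedy_maxmin_init(points, k, seed)
  } else {
    with_seed(seed, sample.int(n, k))
  }
  # subtraction-based distances: slower than the crossprod trick but free of
  # its cancellation error, so reported costs match direct recomputation
  dist_to <- function(meds) {
    D <- matrix(0, n, length(meds))
    for (c in seq_along(meds))
      D[, c] <- sqrt(rowSums(sweep(points, 2L, points[meds[c], ])^2))
    D
  }
  assign_cost <- function(meds) {
    D <- dist_to(meds)
    labels <- max.col(-D, ties.method = "first")
    list(labels = labels, cost = sum(D[cbind(seq_len(n), labels)]))
  }
  alternate <- function(medoids, labels, cost) {
    for (it in seq_len(max_iter)) {
      new_medoids <- medoids
      for (c in seq_len(k)) {
        members <- which(labels == c)
        if (length(members) == 0L) next
        dd <- as.matrix(stats::dist(points[members, , drop = FALSE]))
        new_medoids[c] <- members[which.min(colSums(dd))] # lowest index on tie
      }
      upd <- assign_cost(new_medoids)
      if (upd$cost > cost + 1e-9)
        stopf("internal error: PAM cost increased (%g -> %g)", cost, upd$cost)
      converged <- identical(upd$labels, labels) &&
        identical(new_medoids, medoids)
      no_gain <- upd$cost > cost - 1e-12    # equal-cost relabelling: stop too
      medoids <- new_medoids; labels <- upd$labels; cost <- upd$cost
      if (converged || no_gain) break
    }
    list(medoids = medoids, labels = labels, cost = cost)
  }
  st <- assign_cost(medoids)
  st <- alternate(medoids, st$labels, st$cost)
  if (n <= swap_max) {
    # PAM swap phase: steepest-descent medoid <-> non-medoid swaps, with a
    # bounded, cycle-safe walk along equal-cost plateaus (equal-cost swaps
    # often unlock a strictly improving one on small data sets).
    Dfull <- as.matrix(stats::dist(points))
    visited <- new.env(parent = emptyenv())
    set_key <- function(meds) paste(sort(meds), collapse = ",")
    assign(set_key(st$medoids), TRUE, envir = visited)
    plateau_budget <- 10L
    repeat {
      cand_cost <- matrix(Inf, k, n)
      for (ci in seq_len(k)) {
        others <- st$medoids[-ci]
        dmin_rest <- if (length(others) > 0L)
          do.call(pmin, lapply(others, function(m) Dfull[, m]))
        else rep(Inf, n)
        cc <- colSums(pmin(Dfull, dmin_rest))
        cc[st$medoids] <- Inf
        cand_cost[ci, ] <- cc
      }
      j <- which.min(cand_cost)        # lowest linear index on ties
      ci <- (j - 1L) %% k + 1L; pj <- (j - 1L) %/% k + 1L
      if (cand_cost[ci, pj] < st$cost - 1e-9) {
        meds <- st$medoids; meds[ci] <- pj
        upd <- assign_cost(meds)
        cand <- alternate(meds, upd$labels, upd$cost)
        # accept only a verified improvement (Dfull-based gain can disagree
        # with assign_cost at round-off level)
        if (cand$cost < st$cost - 1e-9) {
          st <- cand
          assign(set_key(st$medoids), TRUE, envir = visited)
          plateau_budget <- 10L
          next
        }
      }
      if (plateau_budget <= 0L) break
      # equal-cost plateau move to the first unvisited medoid set
      moved <- FALSE
      flat <- which(cand_cost <= st$cost + 1e-9)
      for (f in flat) {
        ci <- (f - 1L) %% k + 1L; pj <- (f - 1L) %/% k + 1L
        meds <- st$medoids; meds[ci] <- pj
        key <- set_key(meds)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          upd <- assign_cost(meds)
          # plateau step: take the swapped set as-is (no Voronoi update,
          # which would walk straight back)
          if (upd$cost <= st$cost + 1e-9) {
            st <- list(medoids = meds, labels = upd$labels, cost = upd$cost)
            assign(key, TRUE, envir = visited)
            plateau_budget <- plateau_budget - 1L
            moved <- TRUE
            break
          }
          assign(key, TRUE, envir = visited)  # dead end, don't retry
        }
      }
      if (!moved) break
    }
    # restore the Voronoi/medoid-optimality invariant (cannot raise cost)
    st <- alternate(st$medoids, st$labels, st$cost)
  }
  ord <- order(st$medoids)           # relabel so cluster 1 = lowest medoid index
  lab_map <- match(seq_len(k), ord)  # old cluster id -> new id
  structure(list(k = k, medoids = st$medoids[ord],
                 labels = lab_map[st$labels], cost = st$cost, seed = seed),
            class = "ClusterModel")
}

# Greedy max-min initialisation: seeded first pick, then repeatedly add the
# point farthest from the chosen set (ties to the lowest index).
greedy_maxmin_init <- function(points, k, seed) {
  n <- nrow(points)
  first <- with_seed(seed, sample.int(n, 1L))
  meds <- first
  if (k > 1L) {
    dmin <- sqrt(rowSums(sweep(points, 2L, points[first, ])^2))
    while (length(meds) < k) {
      dm <- dmin; dm[meds] <- -Inf   # never re-pick a chosen point
      nxt <- which.max(dm)
      meds <- c(meds, nxt)
      dmin <- pmin(dmin, sqrt(rowSums(sweep(points, 2L, points[nxt, ])^2)))
    }
  }
  as.integer(meds)
}

#' Elbow-based selection of the number of clusters
#'
#' For each k in `k_range`, takes the best cost over `n_seeds` seeded
#' restarts of [kmedoids()] plus one warm start from the previous k's best
#' medoid set extended by the farthest point (which guarantees a
#' non-increasing cost curve). The chosen k maximises the second difference
#' of the log-cost curve (the knee); the logarithm makes the knee a
#' scale-free statement about successive cost ratios, so a huge but
#' structureless first drop does not drown out the true plateau onset. So
#' that a knee at the smallest scanned k is detectable, the cost at
#' `min(k_range) - 1` is computed internally as an anchor. A flat curve
#' returns the smallest k with a warning.
#'
#' @param points `n x d` coordinate matrix.
#' @param k_range candidate k values (default 2..10).
#' @param n_seeds restarts per k.
#' @param seed base seed; restart r of k uses `seed + 1000 * k + r`.
#' @return list with `$k` (chosen), `$costs` (named cost curve), `$models`
#'   (best [kmedoids()] fit per k).
#' @export
elbow_select <- function(points, k_range = 2:10, n_seeds = 5L, seed = 1L) {
  points <- as.matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1L || max(k_range) > nrow(points))
    stopf("k_range must lie within [1, %d]", nrow(points))
  costs <- setNames(numeric(length(k_range)), k_range)
  models <- vector("list", length(k_range))
  prev_meds <- NULL
  anchor <- NA_real_
  if (k_range[1L] > 1L)
    anchor <- kmedoids(points, k_range[1L] - 1L, seed = seed)$cost
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits <- lapply(seq_len(n_seeds), function(r)
      kmedoids(points, k, seed = seed + 1000L * k + r,
               init_method = if (r == 1L) "maxmin" else "random"))
    if (!is.null(prev_meds) && length(prev_meds) == k - 1L) {
      dmin <- Reduce(pmin, lapply(prev_meds, function(m)
        sqrt(rowSums(sweep(points, 2L, points[m, ])^2))))
      avail <- setdiff(seq_len(nrow(points)), prev_meds)
      warm <- c(prev_meds, avail[which.max(dmin[avail])])
      fits <- c(fits, list(kmedoids(points, k, seed = seed, init = warm)))
    }
    best <- fits[[which.min(vapply(fits, function(f) f$cost, numeric(1L)))]]
    costs[i] <- best$cost
    models[[i]] <- best
    prev_meds <- best$medoids
  }
  curve <- c(anchor, costs)
  if (diff(range(costs)) < 1e-12 && (is.na(anchor) || anchor - costs[1L] < 1e-12)) {
    warning("flat cost curve; returning smallest k", call. = FALSE)
    chosen <- k_range[1L]
  } else {
    floor_cost <- max(curve, na.rm = TRUE) * 1e-9
    lcurve <- log(pmax(curve, floor_cost))
    # second differences at interior points of the anchored log curve
    d2 <- rep(-Inf, length(k_range))
    for (i in seq_along(k_range)) {
      if (i + 2L <= length(lcurve) && !is.na(lcurve[i]))
        d2[i] <- lcurve[i] - 2 * lcurve[i + 1L] + lcurve[i + 2L]
    }
    chosen <- if (all(!is.finite(d2))) k_range[which.min(costs)] else
      k_range[which.max(d2)]
  }
  list(k = chosen, costs = costs, models = models,
       model = models[[match(chosen, k_range)]])
}

#' Cluster representatives with contact fingerprints
#'
#' For each cluster: the medoid's structure, the mean cross-hairpin contact
#' map (HP1 x HP2) over the cluster's trajectory members (subsampled
#' deterministically to at most `max_frames` frames), and an interface call
#' on the medoid. Points are assumed to be trajectory frames first, followed
#' by any appended static models.
#'
#' @param cm a [kmedoids()] model whose point indices map to `traj` frames
#'   (indices `1..n_frames`) then to `static_models` (in order).
#' @param traj the concatenated, aligned [trajectory()].
#' @param submap a [make_subdomain_map()].
#' @param static_models optional list of [structure_model()]s appended after
#'   the trajectory frames.
#' @param metric,cutoff,min_fraction contact parameters.
#' @param max_frames per-cluster subsample cap for the fingerprint.
#' @return list per cluster: `$medoid_structure`, `$fingerprint` (mean
#'   contact frequency matrix, or `NULL` for clusters without trajectory
#'   members), `$interface` ([classify_interface()] on the medoid), `$size`.
#' @export
representatives <- function(cm, traj, submap, static_models = list(),
                            metric = "residue_COM", cutoff = 12,
                            min_fraction = 0.05, max_frames = 500L) {
  nf <- n_frames(traj)
  n_total <- nf + length(static_models)
  if (max(cm$medoids) > n_total)
    stopf("medoid index %d not resolvable (%d frames + %d static models)",
          max(cm$medoids), nf, length(static_models))
  resolve <- function(i) {
    if (i <= nf) frame_structure(traj, i) else static_models[[i - nf]]
  }
  out <- vector("list", cm$k)
  for (c in seq_len(cm$k)) {
    med <- cm$medoids[c]
    members <- which(cm$labels == c)
    traj_members <- members[members <= nf]
    if (length(traj_members) > max_frames) {
      stride <- ceiling(length(traj_members) / max_frames)
      traj_members <- traj_members[seq(1L, length(traj_members), by = stride)]
    }
    fp <- if (length(traj_members) > 0L) {
      mean_contact_map(traj, traj_members, submap$HP1, submap$HP2,
                       metric = metric, cutoff = cutoff)
    } else NULL
    med_structure <- resolve(med)
    out[[c]] <- list(
      medoid_index = med,
      medoid_structure = med_structure,
      fingerprint = fp,
      interface = classify_interface(med_structure, submap, metric = metric,
                                     cutoff = cutoff,
                                     min_fraction = min_fraction),
      size = length(members))
  }
  out
}
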