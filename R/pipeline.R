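#' End-to-end pipelines: model consensus and trajectory landscape
#'
#' `run_consensus()` reproduces the static-model arm of the analysis: pairwise
#' RMSD matrices (whole model and TM region), per-model interface calls with
#' a majority vote, and per-region confidence summaries. `run_landscape()`
#' runs the trajectory arm: ejection QC and replica exclusion, alignment to a
#' common reference, pooled PCA, projection of trajectories and static
#' models, TICA over replica segments, 2-D density, elbow-selected K-medoids
#' and cluster representatives with contact fingerprints.
#'
#' @name pipeline
NULL

#' Consensus analysis of a model ensemble
#'
#' @param models list of [structure_model()]s (>= 2).
#' @param submap a [make_subdomain_map()].
#' @param region residue interval for the region RMSD matrix (default the
#'   submap's TMR interval).
#' @param metric,cutoff,min_fraction contact parameters ([classify_interface()]).
#' @return list of class `ConsensusReport`: `$rmsd_whole`, `$rmsd_region`,
#'   `$interfaces` (per model), `$votes` (named counts), `$consensus`
#'   (majority label), `$confidence` (per model per region mean pLDDT, NA
#'   when a model has no confidence channel).
#' @export
run_consensus <- function(models, submap = make_subdomain_map(),
                          region = NULL, metric = "CA", cutoff = 12,
                          min_fraction = 0.05) {
  if (length(models) < 2L) stopf("need at least 2 models")
  region <- region %||% submap$tmr_interval
  ids <- vapply(models, function(m) m$model_id, character(1L))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  rmsd_whole <- stage("rmsd_whole", pairwise_rmsd_matrix(models, region = NULL))
  rmsd_region <- stage("rmsd_region", pairwise_rmsd_matrix(models, region = region))
  interfaces <- lapply(seq_along(models), function(i)
    stage(sprintf("interface[%s]", ids[i]),
          classify_interface(models[[i]], submap, metric = metric,
                             cutoff = cutoff, min_fraction = min_fraction)))
  names(interfaces) <- ids
  labels <- vapply(interfaces, function(x) x$label, character(1L))
  votes <- sort(table(labels), decreasing = TRUE)
  regions <- c(list(HP1 = submap$HP1, HP2 = submap$HP2),
               submap$intervals)
  confidence <- do.call(rbind, lapply(seq_along(models), function(i) {
    row <- vapply(regions, function(iv) {
      prof <- tryCatch(extract_confidence(models[[i]], iv),
                       error = function(e) NULL)
      if (is.null(prof)) NA_real_ else mean(prof$plddt)
    }, numeric(1L))
    data.frame(model = ids[i], t(row), check.names = FALSE)
  }))
  structure(list(rmsd_whole = rmsd_whole, rmsd_region = rmsd_region,
                 interfaces = interfaces,
                 votes = as.list(setNames(as.integer(votes), names(votes))),
                 consensus = names(votes)[1L],
                 confidence = confidence),
            class = "ConsensusReport")
}

#' @export
print.ConsensusReport <- function(x, ...) {
  cat(sprintf("ConsensusReport: %d models, consensus interface %s (votes: %s)\n",
              nrow(x$rmsd_whole$rmsd), x$consensus,
              paste(sprintf("%s=%d", names(x$votes), unlist(x$votes)),
                    collapse = ", ")))
  invisible(x)
}

#' Landscape analysis of a trajectory ensemble
#'
#' @param trajs named list of replica [trajectory()]s.
#' @param slabs list of [slab_series()], parallel to `trajs`.
#' @param submap a [make_subdomain_map()].
#' @param static_models optional list of [structure_model()]s projected into
#'   the trained space and appended to the clustered point set.
#' @param margin,persistence QC parameters ([detect_ejection()]).
#' @param tica_lag TICA lag in frames (skipped with a message when no
#'   retained segment is long enough).
#' @param k_range,n_seeds,seed clustering parameters ([elbow_select()]).
#' @param bins density grid resolution.
#' @param metric,cutoff contact-fingerprint parameters.
#' @return list of class `LandscapeReport`: `$qc`, `$retained`, `$pca`,
#'   `$projection` (data.frame: source, frame, PC1, PC2), `$tica`,
#'   `$density`, `$clusters` ([elbow_select()] result), `$representatives`.
#' @export
run_landscape <- function(trajs, slabs, submap = make_subdomain_map(),
                          static_models = list(),
                          margin = 5, persistence = 50L,
                          tica_lag = 100L, k_range = 2:8, n_seeds = 5L,
                          seed = 1L, bins = 60L,
                          metric = "residue_COM", cutoff = 12) {
  if (length(trajs) == 0L) stopf("landscape requires at least one trajectory")
  ids <- names(trajs) %||% sprintf("replica_%d", seq_along(trajs))
  reports <- lapply(seq_along(trajs), function(i)
    qc_replica(trajs[[i]], slabs[[i]], submap, replica_id = ids[i],
               margin = margin, persistence = persistence))
  retained <- filter_replicas(reports)
  if (length(retained) == 0L)
    stopf("all %d replicas excluded by membrane-ejection QC; see QC report",
          length(trajs))
  keep <- match(retained, ids)
  feat_res <- intersect(
    c(interval_residues(submap$HP1), interval_residues(submap$HP2)),
    trajs[[keep[1L]]]$particles$resno)
  fit_idx <- particle_indices(trajs[[keep[1L]]], feat_res)
  ref <- frame_coords(trajs[[keep[1L]]], 1L)[fit_idx, , drop = FALSE]
  aligned <- lapply(keep, function(i) {
    idx <- particle_indices(trajs[[i]], feat_res)
    align_trajectory(trajs[[i]], reference = ref, fit_idx = idx)
  })
  seg_feats <- lapply(seq_along(aligned), function(j)
    traj_features(aligned[[j]], particle_indices(aligned[[j]], feat_res)))
  X <- do.call(rbind, seg_feats)
  pca <- fit_pca(X, reference = ref)
  pcs <- project(pca, X, k = 2L)
  proj <- data.frame(
    source = rep(retained, vapply(seg_feats, nrow, integer(1L))),
    frame = unlist(lapply(seg_feats, function(s) seq_len(nrow(s)))),
    PC1 = pcs[, 1L], PC2 = pcs[, 2L])
  if (length(static_models) > 0L) {
    sp <- t(vapply(static_models, function(m)
      as.numeric(project(pca, m, residues = feat_res, k = 2L)), numeric(2L)))
    proj <- rbind(proj, data.frame(
      source = vapply(static_models, function(m) m$model_id, character(1L)),
      frame = NA_integer_, PC1 = sp[, 1L], PC2 = sp[, 2L]))
  }
  tica <- NULL
  if (min(vapply(seg_feats, nrow, integer(1L))) > tica_lag) {
    tica <- fit_tica(seg_feats, lag = tica_lag)
  } else {
    message("TICA skipped: lag exceeds the shortest retained segment")
  }
  pts <- as.matrix(proj[, c("PC1", "PC2")])
  dens <- density2d(pts[seq_len(nrow(pcs)), , drop = FALSE], bins = bins)
  clusters <- elbow_select(pts, k_range = k_range, n_seeds = n_seeds,
                           seed = seed)
  concat <- concat_trajectories(aligned)
  reps <- representatives(clusters$model, concat, submap,
                          static_models = static_models,
                          metric = metric, cutoff = cutoff)
  structure(list(qc = reports, retained = retained, pca = pca,
                 projection = proj, tica = tica, density = dens,
                 clusters = clusters, representatives = reps,
                 feature_residues = feat_res),
            class = "LandscapeReport")
}

#' Concatenate trajectories sharing one particle set
#' @param trajs list of [trajectory()]s with identical particle tables.
#' @export
concat_trajectories <- function(trajs) {
  p0 <- trajs[[1L]]$particles
  for (t in trajs[-1L])
    if (!identical(t$particles$resno, p0$resno) ||
        !identical(t$particles$atom, p0$atom))
      stopf("particle sets differ between replicas")
  coords <- do.call(abind3, lapply(trajs, function(t) t$coords))
  trajectory(p0, coords, dt = trajs[[1L]]$dt,
             representation = trajs[[1L]]$representation)
}

abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(a) dim(a)[1L], integer(1L)))
  out <- array(NA_real_, c(n, dim(parts[[1L]])[2L], 3L))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Write a landscape report to a directory with a hashed manifest
#'
#' Emits projections, explained variance, density, labels, medoid PDBs,
#' fingerprints and the QC report as plain-text files, plus `manifest.json`
#' listing every file with its md5 hash.
#'
#' @param report a [run_landscape()] result.
#' @param dir output directory (created).
#' @return The manifest path, invisibly.
#' @export
write_landscape_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  utils::write.table(report$projection, fp("projection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(component = seq_along(report$pca$fractions),
               fraction = report$pca$fractions),
    fp("explained_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$density$density, fp("density.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(point = seq_along(report$clusters$model$labels),
               cluster = report$clusters$model$labels),
    fp("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_qc_report(report$qc, fp("qc.json"))
  for (i in seq_along(report$representatives)) {
    r <- report$representatives[[i]]
    write_structure(r$medoid_structure, fp(sprintf("medoid_%d.pdb", i)))
    if (!is.null(r$fingerprint))
      write_map(r$fingerprint, fp(sprintf("fingerprint_%d.tsv", i)),
                meta = list(cluster = i, interface = r$interface$label))
  }
  jsonlite::write_json(list(
    retained = report$retained,
    k = report$clusters$k,
    costs = as.list(report$clusters$costs),
    interfaces = vapply(report$representatives,
                        function(r) r$interface$label, character(1L))),
    fp("summary.json"), auto_unbox = TRUE)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(fp(f)))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(fp("manifest.json"))
}

#' Parse a flat key = value run-configuration file
#'
#' Lines of `key = value`; `#` comments and blank lines ignored; repeated
#' keys accumulate into vectors (used for `model` and `trajectory` entries).
#' Documented keys: `model` (PDB path, repeatable), `trajectory` (multi-model
#' PDB path, repeatable), `cutoff`, `min_fraction`, `metric`, `margin`,
#' `persistence`, `tica_lag`, `k_min`, `k_max`, `out_dir`.
#'
#' @param path config file.
#' @return named list; numeric-looking values are converted.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    cfg[[key]] <- c(cfg[[key]], val)
  }
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic trajectory + truth),
#' `compare-models` (consensus report over PDB models), `landscape`
#' (trajectory landscape). Each takes `--config <file>`, `--seed <int>` and
#' `--out <dir>`. See [parse_run_config()] for config keys. Installed as
#' `inst/cli/tmrscape.R`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return 0 on success (invisibly).
#' @export
tmr_cli <- function(args) {
  if (length(args) < 1L)
    stopf("usage: tmrscape <simulate|compare-models|landscape> --config FILE --seed N --out DIR")
  cmd <- args[1L]
  if (!cmd %in% c("simulate", "compare-models", "landscape"))
    stopf("unknown subcommand '%s'", cmd)
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    args[i[1L] + 1L]
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "tmrscape_out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (!is.null(opt("--config"))) parse_run_config(opt("--config")) else list()
  submap <- make_subdomain_map()
  t0 <- Sys.time()
  if (cmd == "simulate") {
    arch <- strsplit(as.character(cfg$architecture %||% "TM2-TM3"), ",")[[1L]]
    spec <- synthetic_spec(architecture = arch,
                           n_frames = as.integer(cfg$n_frames %||% 500L),
                           switch_rate = as.numeric(cfg$switch_rate %||% 0),
                           seed = seed)
    sim <- simulate_trajectory(spec, submap)
    write_trajectory_pdb(sim$traj, file.path(out, "trajectory.pdb"))
    jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                         auto_unbox = TRUE, null = "null")
  } else if (cmd == "compare-models") {
    paths <- as.character(cfg$model)
    if (length(paths) < 2L) stopf("compare-models needs >= 2 'model' entries")
    models <- lapply(paths, read_structure)
    rep <- run_consensus(models, submap,
                         cutoff = as.numeric(cfg$cutoff %||% 12),
                         min_fraction = as.numeric(cfg$min_fraction %||% 0.05))
    write_rmsd_matrix(rep$rmsd_whole, file.path(out, "rmsd_whole.tsv"))
    write_rmsd_matrix(rep$rmsd_region, file.path(out, "rmsd_region.tsv"))
    jsonlite::write_json(list(
      consensus = rep$consensus, votes = rep$votes,
      interfaces = lapply(rep$interfaces, function(x)
        list(label = x$label, fractions = as.list(x$fractions)))),
      file.path(out, "consensus.json"), auto_unbox = TRUE)
  } else if (cmd == "landscape") {
    paths <- as.character(cfg$trajectory)
    if (length(paths) < 1L) stopf("landscape needs >= 1 'trajectory' entry")
    trajs <- lapply(paths, read_trajectory_pdb)
    names(trajs) <- basename(paths)
    slab_hw <- as.numeric(cfg$slab_half_width %||% 20)
    slabs <- lapply(trajs, function(t) slab_series(slab_hw, -slab_hw, n_frames(t)))
    rep <- run_landscape(trajs, slabs, submap,
                         margin = as.numeric(cfg$margin %||% 5),
                         persistence = as.integer(cfg$persistence %||% 50L),
                         tica_lag = as.integer(cfg$tica_lag %||% 100L),
                         k_range = seq(as.integer(cfg$k_min %||% 2L),
                                       as.integer(cfg$k_max %||% 8L)),
                         seed = seed)
    write_landscape_report(rep, out)
  }
  message(sprintf("[%s] done in %.1f s; outputs in %s", cmd,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")), out))
  invisible(0L)
}
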