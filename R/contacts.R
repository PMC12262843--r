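#' Inter-residue distance and contact maps
#'
#' Distances between residue sets are computed either between C-alpha atoms
#' (`metric = "CA"`; BB beads count as C-alpha for coarse-grained models) or
#' between residue centres of mass (`metric = "residue_COM"`, mass-weighted;
#' beads get unit mass). The 12 Angstrom default contact cutoff is deliberately
#' generous so that helix-helix interactions survive the coarser effective
#' radii of CG representations.
#'
#' @name contacts
NULL

residue_metric_coords <- function(model, interval, metric, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  residues <- interval_residues(interval)
  present <- intersect(residues, a$resno)
  miss <- setdiff(residues, a$resno)
  if (length(present) == 0L)
    stopf("no residues of [%s, %s) resolved in model '%s'",
          interval[1L], interval[2L], model$model_id)
  if (metric == "CA") {
    a <- a[a$atom %in% c("CA", "BB"), , drop = FALSE]
    a <- a[!duplicated(a$resno), , drop = FALSE]
    miss2 <- setdiff(present, a$resno)
    if (length(miss2) > 0L)
      stopf("residue(s) without CA/BB particle: %s",
            paste(utils::head(miss2, 8L), collapse = ", "))
    a <- a[match(present, a$resno), , drop = FALSE]
    m <- as.matrix(a[, c("x", "y", "z")])
  } else {
    m <- t(vapply(present, function(r) {
      ar <- a[a$resno == r, , drop = FALSE]
      w <- guess_mass(ar$atom)
      colSums(as.matrix(ar[, c("x", "y", "z")]) * w) / sum(w)
    }, numeric(3L)))
  }
  rownames(m) <- present
  m
}

#' Distance map between two residue sets
#'
#' @param model a [structure_model()] (convert trajectory frames with
#'   [frame_structure()]).
#' @param setA,setB half-open residue intervals.
#' @param metric `"CA"` or `"residue_COM"`.
#' @param chain optional chain.
#' @return list of class `DistanceMap`: `$d` (|A| x |B| matrix, Angstrom, with
#'   residue-number dimnames), `$metric`.
#' @export
distance_map <- function(model, setA, setB, metric = c("CA", "residue_COM"),
                         chain = NULL) {
  metric <- match.arg(metric)
  ca <- residue_metric_coords(model, setA, metric, chain)
  cb <- residue_metric_coords(model, setB, metric, chain)
  d <- sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                   2 * tcrossprod(ca, cb), 0))
  dimnames(d) <- list(rownames(ca), rownames(cb))
  structure(list(d = d, metric = metric), class = "DistanceMap")
}

#' Threshold a distance map into a contact map
#'
#' A pair is in contact when its distance is `<= cutoff` (boundary inclusive),
#' so contacts at a smaller cutoff are always a subset of contacts at a larger
#' one.
#'
#' @param dmap a [distance_map()].
#' @param cutoff contact cutoff in Angstrom (default 12).
#' @return list of class `ContactMap`: `$m` boolean matrix, `$cutoff`,
#'   `$metric`.
#' @export
contact_map <- function(dmap, cutoff = 12) {
  if (!is.numeric(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  structure(list(m = dmap$d <= cutoff, cutoff = cutoff, metric = dmap$metric),
            class = "ContactMap")
}

#' Fraction of residue pairs in contact
#' @param cmap a [contact_map()].
#' @export
contact_fraction <- function(cmap) mean(cmap$m)

cross_hairpin_pairs <- function() {
  list(`TM1-TM3` = c("TM1", "TM3"), `TM1-TM4` = c("TM1", "TM4"),
       `TM2-TM3` = c("TM2", "TM3"), `TM2-TM4` = c("TM2", "TM4"))
}

#' Classify the cross-hairpin contact interface of a bundle
#'
#' Computes the contact fraction of the four cross-hairpin helix pairs
#' (TM1-TM3, TM1-TM4, TM2-TM3, TM2-TM4). Pairs with fraction `>=
#' min_fraction` count as "in contact". The call is `TM2-TM3` or `TM1-TM4`
#' when that pair is the unique dominant in-contact pair (dominant = maximal
#' fraction at least `1.5x` the runner-up among in-contact pairs), `none` when
#' no pair passes, and `other` otherwise (several pairs without a dominant
#' one, or a dominant pair that is neither of the two canonical interfaces).
#'
#' The fraction threshold and dominance factor are analysis parameters, not
#' experimental observables; they stand in for the visual contact-map reading
#' used when interfaces are typed by eye.
#'
#' @param model a [structure_model()].
#' @param submap a [make_subdomain_map()].
#' @param metric `"CA"` or `"residue_COM"`.
#' @param cutoff contact cutoff (Angstrom).
#' @param min_fraction minimum contact fraction for a pair to count.
#' @param dominance dominance factor over the runner-up.
#' @param chain optional chain.
#' @return list of class `InterfaceCall`: `$label`, `$fractions` (named,
#'   all four pairs), `$min_distance` (named, Angstrom).
#' @export
classify_interface <- function(model, submap, metric = "CA", cutoff = 12,
                               min_fraction = 0.05, dominance = 1.5,
                               chain = NULL) {
  pairs <- cross_hairpin_pairs()
  fr <- md <- setNames(numeric(length(pairs)), names(pairs))
  for (nm in names(pairs)) {
    iv <- submap$intervals[pairs[[nm]]]
    if (any(vapply(iv, is.null, logical(1L))))
      stopf("subdomain map lacks interval(s) for pair %s", nm)
    dm <- distance_map(model, iv[[1L]], iv[[2L]], metric = metric, chain = chain)
    fr[nm] <- contact_fraction(contact_map(dm, cutoff))
    md[nm] <- min(dm$d)
  }
  passing <- fr[fr >= min_fraction]
  label <- if (length(passing) == 0L) {
    "none"
  } else {
    ord <- sort(passing, decreasing = TRUE)
    dominant <- length(ord) == 1L || ord[1L] >= dominance * ord[2L]
    top <- names(ord)[1L]
    if (dominant && top %in% c("TM2-TM3", "TM1-TM4")) top else "other"
  }
  structure(list(label = label, fractions = fr, min_distance = md,
                 cutoff = cutoff, metric = metric, min_fraction = min_fraction,
                 dominance = dominance),
            class = "InterfaceCall")
}

#' @export
print.InterfaceCall <- function(x, ...) {
  cat(sprintf("InterfaceCall: %s (cutoff %g A, metric %s)\n",
              x$label, x$cutoff, x$metric))
  print(round(rbind(fraction = x$fractions, min_dist = x$min_distance), 3))
  invisible(x)
}

#' Intra- vs inter-chain contact decomposition of a dimer
#'
#' For a two-chain model: per-chain intra maps over HP1 x HP2 and an
#' inter-chain map over the full TM region of chain 1 vs chain 2. The summary
#' lists, per category, the TM helix pairs whose contact fraction passes
#' `min_fraction` (intra: the four cross-hairpin pairs; inter: all 16 ordered
#' TM(chain1)-TM(chain2) pairs).
#'
#' @inheritParams classify_interface
#' @param dimer a two-chain [structure_model()].
#' @return list with `$intra` (per-chain [contact_map()]s), `$inter`
#'   (inter-chain [contact_map()]), and `$summary` (data.frame: category,
#'   pair, fraction).
#' @export
chain_contact_decomposition <- function(dimer, submap, metric = "CA",
                                        cutoff = 12, min_fraction = 0.05) {
  chains <- unique(dimer$atoms$chain)
  if (length(chains) != 2L)
    stopf("expected exactly 2 chains, found %d (%s)",
          length(chains), paste(chains, collapse = ", "))
  tm_region <- c(submap$intervals$TM1[1L], submap$intervals$TM4[2L])
  intra <- lapply(chains, function(ch)
    contact_map(distance_map(dimer, submap$HP1, submap$HP2,
                             metric = metric, chain = ch), cutoff))
  names(intra) <- chains
  inter <- contact_map(
    inter_chain_distance_map(dimer, tm_region, tm_region, metric,
                             chains[1L], chains[2L]), cutoff)
  rows <- list()
  for (ch in chains) {
    for (nm in names(cross_hairpin_pairs())) {
      iv <- submap$intervals[cross_hairpin_pairs()[[nm]]]
      f <- contact_fraction(contact_map(
        distance_map(dimer, iv[[1L]], iv[[2L]], metric = metric, chain = ch),
        cutoff))
      if (f >= min_fraction)
        rows[[length(rows) + 1L]] <-
          data.frame(category = paste0("intra_", ch), pair = nm, fraction = f)
    }
  }
  tms <- c("TM1", "TM2", "TM3", "TM4")
  for (ti in tms) for (tj in tms) {
    f <- contact_fraction(contact_map(
      inter_chain_distance_map(dimer, submap$intervals[[ti]],
                               submap$intervals[[tj]], metric,
                               chains[1L], chains[2L]), cutoff))
    if (f >= min_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        category = "inter",
        pair = sprintf("%s(%s)-%s(%s)", ti, chains[1L], tj, chains[2L]),
        fraction = f)
  }
  summary <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(category = character(), pair = character(), fraction = numeric())
  list(intra = intra, inter = inter, summary = summary)
}

inter_chain_distance_map <- function(model, setA, setB, metric, chainA, chainB) {
  ca <- residue_metric_coords(model, setA, metric, chain = chainA)
  cb <- residue_metric_coords(model, setB, metric, chain = chainB)
  d <- sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                   2 * tcrossprod(ca, cb), 0))
  dimnames(d) <- list(rownames(ca), rownames(cb))
  structure(list(d = d, metric = metric), class = "DistanceMap")
}

#' Mean contact map over trajectory frames
#'
#' Elementwise mean of per-frame boolean contact maps; entries are contact
#' frequencies in `[0, 1]`.
#'
#' @param traj a [trajectory()].
#' @param frames frame indices to average over.
#' @param setA,setB half-open residue intervals.
#' @param metric `"CA"` or `"residue_COM"`.
#' @param cutoff contact cutoff (Angstrom).
#' @return matrix of per-pair contact frequencies with residue dimnames.
#' @export
mean_contact_map <- function(traj, frames = seq_len(n_frames(traj)),
                             setA, setB, metric = "residue_COM", cutoff = 12) {
  if (length(frames) == 0L) stopf("empty frame set")
  p <- traj$particles
  resolve <- function(interval) {
    res <- interval_residues(interval)
    if (metric == "CA") {
      idx <- which(p$resno %in% res & p$atom %in% c("CA", "BB"))
      idx <- idx[!duplicated(p$resno[idx])]
      idx <- idx[order(p$resno[idx])]
      if (length(idx) == 0L)
        stopf("no residues of [%s, %s) resolved in trajectory",
              interval[1L], interval[2L])
      list(idx = idx, ids = p$resno[idx], grp = NULL, w = NULL)
    } else {
      idx <- which(p$resno %in% res)
      if (length(idx) == 0L)
        stopf("no residues of [%s, %s) resolved in trajectory",
              interval[1L], interval[2L])
      list(idx = idx, ids = sort(unique(p$resno[idx])),
           grp = p$resno[idx], w = guess_mass(p$atom[idx]))
    }
  }
  A <- resolve(setA); B <- resolve(setB)
  res_coords <- function(xyz, sel) {
    if (is.null(sel$grp)) return(xyz[sel$idx, , drop = FALSE])
    # mass-weighted per-residue centres (rowsum orders groups ascending)
    num <- rowsum(xyz[sel$idx, , drop = FALSE] * sel$w, sel$grp)
    num / as.numeric(rowsum(sel$w, sel$grp))
  }
  acc <- matrix(0, length(A$ids), length(B$ids),
                dimnames = list(A$ids, B$ids))
  for (i in frames) {
    xyz <- frame_coords(traj, i)
    ca <- res_coords(xyz, A); cb <- res_coords(xyz, B)
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
    acc <- acc + (d2 <= cutoff^2)
  }
  acc / length(frames)
}

#' Write a distance/contact/frequency map as TSV with a JSON sidecar
#' @param m matrix with residue dimnames, or a `DistanceMap`/`ContactMap`.
#' @param path output TSV; metadata goes to `<path>.json`.
#' @param meta extra metadata fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(m, path, meta = list()) {
  if (inherits(m, "DistanceMap")) { meta$metric <- m$metric; m <- m$d }
  if (inherits(m, "ContactMap")) {
    meta$metric <- m$metric; meta$cutoff <- m$cutoff; m <- m$m + 0
  }
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
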