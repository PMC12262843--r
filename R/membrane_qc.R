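#' Membrane-ejection quality control
#'
#' Coarse-grained hairpins occasionally leave the bilayer irreversibly during
#' long simulations; such replicas distort every downstream ensemble average
#' and are excluded. Ejection is called on the hairpin centre-of-mass z-series
#' against the phosphate slab: the hairpin must leave the slab (plus a margin)
#' and stay out for a sustained run of frames. Detection is sticky - once a
#' sustained exit is seen the replica stays flagged, which matches the
#' observation that ejected hairpins never re-enter.
#'
#' @name membrane_qc
NULL

#' Membrane slab series from explicit leaflet planes
#'
#' @param upper,lower per-frame z of the upper/lower phosphate planes
#'   (Angstrom); recycled if length 1.
#' @param n_frames series length when both planes are scalars.
#' @return list of class `MembraneSlabSeries` with `$upper`, `$lower`.
#' @export
slab_series <- function(upper, lower, n_frames = max(length(upper), length(lower))) {
  upper <- rep_len(upper, n_frames); lower <- rep_len(lower, n_frames)
  if (any(upper <= lower)) stopf("upper plane must exceed lower plane every frame")
  structure(list(upper = upper, lower = lower), class = "MembraneSlabSeries")
}

#' Membrane slab series from per-frame phosphate z-coordinates
#'
#' Leaflets are assigned once, by the sign of each phosphate's z relative to
#' the frame-0 midplane; each plane is the per-frame mean z of its leaflet.
#'
#' @param z matrix `n_frames x n_phosphates` of phosphate z (Angstrom).
#' @return A [slab_series()].
#' @export
slab_from_phosphates <- function(z) {
  if (!is.matrix(z) || ncol(z) < 2L) stopf("need a frames x phosphates matrix")
  mid <- mean(z[1L, ])
  up <- z[1L, ] > mid
  if (!any(up) || all(up)) stopf("cannot split phosphates into two leaflets")
  slab_series(rowMeans(z[, up, drop = FALSE]),
              rowMeans(z[, !up, drop = FALSE]))
}

#' Per-frame z of a hairpin's centre of mass
#'
#' Mass-weighted over all particles of the hairpin's residues (unit masses for
#' coarse-grained beads).
#'
#' @param traj a [trajectory()].
#' @param submap a [make_subdomain_map()].
#' @param hairpin `"HP1"` or `"HP2"`.
#' @return numeric vector, one z per frame.
#' @export
hairpin_z_series <- function(traj, submap, hairpin = c("HP1", "HP2")) {
  hairpin <- match.arg(hairpin)
  iv <- if (hairpin == "HP1") submap$HP1 else submap$HP2
  idx <- which(traj$particles$resno >= iv[1L] & traj$particles$resno < iv[2L])
  if (length(idx) == 0L)
    stopf("no particles of %s [%s, %s) in trajectory", hairpin, iv[1L], iv[2L])
  w <- guess_mass(traj$particles$atom[idx])
  zm <- matrix(traj$coords[, idx, 3L], nrow = n_frames(traj), ncol = length(idx))
  as.numeric(zm %*% (w / sum(w)))
}

#' Detect a sustained membrane exit in a z-series
#'
#' Ejected iff z leaves `[lower - margin, upper + margin]` and stays outside
#' for at least `persistence` consecutive frames; `first_frame` is the first
#' frame of that run. Single-frame spikes and shorter excursions do not count.
#'
#' @param z_series per-frame z (Angstrom), e.g. from [hairpin_z_series()].
#' @param slab a [slab_series()] of the same length.
#' @param margin tolerance beyond the phosphate planes (Angstrom).
#' @param persistence minimum run length in frames (`>= 1`).
#' @return list with `$ejected` (logical) and `$first_frame` (integer or
#'   `NA`).
#' @export
detect_ejection <- function(z_series, slab, margin = 5, persistence = 50L) {
  if (length(z_series) != length(slab$upper))
    stopf("z-series length (%d) != slab length (%d)",
          length(z_series), length(slab$upper))
  if (persistence < 1L) stopf("persistence must be >= 1")
  outside <- z_series > slab$upper + margin | z_series < slab$lower - margin
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(list(ejected = FALSE, first_frame = NA_integer_))
  list(ejected = TRUE, first_frame = starts[hit[1L]])
}

#' Ejection report for one replica
#'
#' @param replica_id identifier.
#' @param hp1,hp2 results of [detect_ejection()] for each hairpin.
#' @return list of class `EjectionReport`; `$excluded` is TRUE iff any
#'   hairpin ejected.
#' @export
ejection_report <- function(replica_id, hp1, hp2) {
  structure(list(replica_id = replica_id, HP1 = hp1, HP2 = hp2,
                 excluded = isTRUE(hp1$ejected) || isTRUE(hp2$ejected)),
            class = "EjectionReport")
}

#' Run ejection QC on a replica trajectory
#'
#' @param traj a [trajectory()].
#' @param slab a [slab_series()].
#' @param submap a [make_subdomain_map()].
#' @param replica_id identifier.
#' @inheritParams detect_ejection
#' @return An [ejection_report()].
#' @export
qc_replica <- function(traj, slab, submap, replica_id = "replica",
                       margin = 5, persistence = 50L) {
  ejection_report(
    replica_id,
    detect_ejection(hairpin_z_series(traj, submap, "HP1"), slab,
                    margin, persistence),
    detect_ejection(hairpin_z_series(traj, submap, "HP2"), slab,
                    margin, persistence))
}

#' Apply the replica-exclusion rule
#'
#' Retains the replicas with no ejected hairpin; one message per exclusion
#' naming the hairpin(s) and first frame, and a warning when nothing is left.
#'
#' @param reports list of [ejection_report()]s.
#' @return character vector of retained replica ids.
#' @export
filter_replicas <- function(reports) {
  retained <- character()
  for (rep in reports) {
    if (rep$excluded) {
      culprits <- c(
        if (isTRUE(rep$HP1$ejected))
          sprintf("HP1 (frame %d)", rep$HP1$first_frame),
        if (isTRUE(rep$HP2$ejected))
          sprintf("HP2 (frame %d)", rep$HP2$first_frame))
      message(sprintf("excluding replica %s: ejected %s",
                      rep$replica_id, paste(culprits, collapse = ", ")))
    } else {
      retained <- c(retained, rep$replica_id)
    }
  }
  if (length(retained) == 0L && length(reports) > 0L)
    warning("all replicas excluded by membrane-ejection QC", call. = FALSE)
  retained
}

#' Serialise ejection reports as JSON
#' @param reports list of [ejection_report()]s.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(reports, path) {
  jsonlite::write_json(lapply(reports, function(r) list(
    replica_id = r$replica_id,
    HP1 = list(ejected = r$HP1$ejected, first_frame = r$HP1$first_frame),
    HP2 = list(ejected = r$HP2$ejected, first_frame = r$HP2$first_frame),
    excluded = r$excluded)), path, auto_unbox = TRUE, na = "null")
  invisible(path)
}
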