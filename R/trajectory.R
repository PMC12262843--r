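#' Trajectories of a fixed particle set
#'
#' A `Trajectory` holds ordered frames of coordinates for a fixed set of
#' particles (atoms or coarse-grained beads), with frame spacing and a
#' representation tag.
#'
#' @param particles data.frame with columns `resno`, `atom` (and optionally
#'   `chain`, `resname`).
#' @param coords numeric array `n_frames x n_particles x 3` (Angstrom).
#' @param dt frame spacing (arbitrary but declared time units), `> 0`.
#' @param representation `"CG"` (bead) or `"AA"` (atomistic).
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(particles, coords, dt = 1, representation = c("CG", "AA")) {
  representation <- match.arg(representation)
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stopf("coords must be an n_frames x n_particles x 3 array")
  if (dim(coords)[2L] != nrow(particles))
    stopf("coords second dimension (%d) != particle count (%d)",
          dim(coords)[2L], nrow(particles))
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be > 0")
  if (is.null(particles$chain)) particles$chain <- "A"
  if (is.null(particles$resname)) particles$resname <- "ALA"
  structure(list(particles = particles, coords = coords, dt = dt,
                 representation = representation),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d frames x %d particles, dt = %g\n",
              x$representation, n_frames(x), nrow(x$particles), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' Coordinates of one frame as an `n_particles x 3` matrix
#' @param traj a [trajectory()].
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stopf("frame %d out of range", i)
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' View one trajectory frame as a StructureModel
#' @param traj a [trajectory()].
#' @param i frame index.
#' @param model_id identifier for the resulting model.
#' @export
frame_structure <- function(traj, i, model_id = sprintf("frame_%d", i)) {
  xyz <- frame_coords(traj, i)
  a <- data.frame(chain = traj$particles$chain, resno = traj$particles$resno,
                  resname = traj$particles$resname, atom = traj$particles$atom,
                  x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  structure_model(a, model_id = model_id, predictor = "trajectory")
}

#' Keep a subset of particles
#' @param traj a [trajectory()].
#' @param idx particle row indices to retain.
#' @export
subset_particles <- function(traj, idx) {
  trajectory(traj$particles[idx, , drop = FALSE],
             traj$coords[, idx, , drop = FALSE],
             dt = traj$dt, representation = traj$representation)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Every MODEL...ENDMDL block becomes one frame; the particle set is taken
#' from the first frame and every frame must match it.
#'
#' @param path multi-model PDB file.
#' @param dt frame spacing.
#' @param representation `"CG"` or `"AA"`.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = 1, representation = "CG") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(starts) == 0L) { starts <- 1L; ends <- length(lines) }
  if (length(starts) != length(ends))
    stopf("unbalanced MODEL/ENDMDL records in %s", path)
  frames <- lapply(seq_along(starts), function(k)
    parse_pdb_atoms(lines[starts[k]:ends[k]], path))
  p0 <- frames[[1L]]
  if (nrow(p0) == 0L) stopf("no ATOM records in first frame of %s", path)
  coords <- array(NA_real_, c(length(frames), nrow(p0), 3L))
  for (k in seq_along(frames)) {
    fk <- frames[[k]]
    if (nrow(fk) != nrow(p0) || !all(fk$resno == p0$resno & fk$atom == p0$atom))
      stopf("frame %d particle set differs from frame 1 in %s", k, path)
    coords[k, , ] <- as.matrix(fk[, c("x", "y", "z")])
  }
  trajectory(p0[, c("chain", "resno", "resname", "atom")], coords,
             dt = dt, representation = representation)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", i), con)
    m <- frame_structure(traj, i)
    a <- m$atoms
    name4 <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
                    sprintf("%-4s", a$atom))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)) %% 100000L, name4, substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resno %% 10000L, a$x, a$y, a$z, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Particle indices for a residue set (optionally restricted to backbone)
#' @param traj a [trajectory()].
#' @param residues residue numbers to select.
#' @param backbone_only keep only CA/BB particles.
#' @export
particle_indices <- function(traj, residues, backbone_only = TRUE) {
  p <- traj$particles
  sel <- p$resno %in% residues
  if (backbone_only) sel <- sel & p$atom %in% c("CA", "BB")
  which(sel)
}
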