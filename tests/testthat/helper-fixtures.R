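# In-code fixtures: tiny hand-written PDB texts and convenience builders.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z, b = 0) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name4, resname, chain, resno, x, y, z, 1, b)
}

# 4-residue single-chain CA-only fixture with chosen B-factors.
write_tiny_pdb <- function(path, b = c(10, 20, 30, 40)) {
  lines <- vapply(1:4, function(i)
    pdb_line(i, "CA", "ALA", "A", i, i * 1.0, 0, 0, b[i]), character(1L))
  writeLines(c(lines, "END"), path)
  path
}

# Two-chain dimer fixture: chains A and B, 3 CA residues each.
write_dimer_pdb <- function(path) {
  lines <- c(
    vapply(1:3, function(i)
      pdb_line(i, "CA", "GLY", "A", 10 + i, i, 0, 0, 50 + i), character(1L)),
    vapply(1:3, function(i)
      pdb_line(3 + i, "CA", "GLY", "B", 10 + i, i, 5, 0, 60 + i), character(1L)))
  writeLines(c(lines, "END"), path)
  path
}

# StructureModel from a bare coordinate matrix (CA atoms, chain A).
model_from_coords <- function(xyz, resno = seq_len(nrow(xyz)), conf = NA,
                              chain = "A", id = "fixture") {
  structure_model(data.frame(chain = chain, resno = resno, resname = "ALA",
                             atom = "CA", x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3], conf = conf), model_id = id)
}

# Trajectory from a list of n x 3 coordinate matrices (one per frame).
traj_from_frames <- function(frames, resno = seq_len(nrow(frames[[1]])),
                             atom = "BB") {
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  trajectory(data.frame(chain = "A", resno = resno, resname = "ALA",
                        atom = atom), coords)
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  axis_angle_rotation(axis, stats::runif(1, 0, pi))
}

default_feature_idx <- function(traj, sm = make_subdomain_map()) {
  particle_indices(traj, c(interval_residues(sm$HP1),
                           interval_residues(sm$HP2)))
}

# interval_residues is internal to the package; tests reach it via :::
interval_residues <- function(iv) seq.int(iv[1], iv[2] - 1)
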