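# Plain-text exports: single- and multi-MODEL PDB, XYZ trajectories, and
# run provenance JSON. Coordinates are stored in nm internally and written
# as Angstrom in PDB records.

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz_nm,
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, name, resid, chain, resno,
          xyz_nm[1] * 10, xyz_nm[2] * 10, xyz_nm[3] * 10)
}

structure_pdb_lines <- function(x) {
  at <- x$atoms
  lines <- vapply(seq_len(nrow(at)), function(i)
    pdb_atom_line(i, "CA", at$resid[i], at$chain[i], at$resno[i],
                  c(at$x[i], at$y[i], at$z[i])), "")
  if (nrow(x$ligands) > 0L) {
    lg <- x$ligands
    lines <- c(lines, vapply(seq_len(nrow(lg)), function(i)
      pdb_atom_line(nrow(at) + i, lg$atom[i], lg$ligand[i], "X", 9000 + i,
                    c(lg$x[i], lg$y[i], lg$z[i]), record = "HETATM"), ""))
  }
  lines
}

#' Write a C-alpha structure as a PDB file
#' @param x `calpha` structure.
#' @param path Output file.
#' @export
write_calpha_pdb <- function(x, path) {
  writeLines(c(structure_pdb_lines(x), "TER", "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj `trajectory`.
#' @param template `calpha` structure providing chain/residue metadata.
#' @param path Output file.
#' @param stride Write every `stride`-th frame.
#' @export
write_trajectory_pdb <- function(traj, template, path, stride = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  ks <- seq(1L, n_frames(traj), by = stride)
  for (m in seq_along(ks)) {
    fr <- frame_coords(traj, ks[m])
    tmp <- template
    tmp$atoms[, c("x", "y", "z")] <- fr
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(structure_pdb_lines(tmp), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' One block per frame: bead count, a comment with the reduced time, then
#' `CA x y z` lines in nm.
#'
#' @param traj `trajectory`.
#' @param path Output file.
#' @param stride Write every `stride`-th frame.
#' @export
write_trajectory_xyz <- function(traj, path, stride = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$frames)[1]
  for (k in seq(1L, n_frames(traj), by = stride)) {
    fr <- frame_coords(traj, k)
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6g tau_L", traj$times[k]), con)
    writeLines(sprintf("CA %.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Write run provenance as JSON
#'
#' Records everything needed to regenerate a run: config, toggles, force
#' spec, seed and package version.
#'
#' @param traj `trajectory`.
#' @param path Output file.
#' @param extra Named list merged into the record.
#' @export
write_provenance <- function(traj, path, extra = list()) {
  rec <- c(list(
    package = "motorgo",
    version = as.character(utils::packageVersion("motorgo")),
    config = unclass(traj$config),
    toggles = traj$toggles,
    pi_removed = traj$pi_removed,
    force = if (!is.null(traj$force))
      list(magnitude = traj$force$magnitude, units = traj$force$units,
           direction = traj$force$direction, target = traj$force$target)),
    extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
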