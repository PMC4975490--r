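# Deterministic toy fixtures: a two-conformation two-domain "toy motor", a
# linear filament surrogate, and a pseudo-phosphate pocket. The toy motor
# reproduces the structural logic of the real system at miniature scale:
#
#   * core  (beads 1..n_core)        -- helical motor-head "big subunit"
#   * tail  (beads n_core+1..n_body) -- compact pocket flap ("small
#     subunit") folded against the core and clamped there by contacts that
#     are all bridged by the pseudo-phosphate ligand
#   * converter (beads n_body+1..N)  -- linker + compact helix; docks
#     against the tail in the pre pose and against the core in the post
#     pose (rigid rotation about the hinge bead)
#
# Core and tail coordinates are identical between the two conformations, so
# the motor-head-internal contact set is shared; the converter-head contact
# sets of the two poses are disjoint. Removing the phosphate-mediated
# clamp frees the tail, which lets the converter carry its pre-pose
# contacts along into the post pose -- the energetic coupling that makes
# phosphate release drive the pre -> post switch in the dual-basin model.

#' Toy motor specification
#'
#' Geometry parameters of the deterministic two-conformation toy motor.
#' Generation is a pure function of the spec (the seed is recorded for
#' provenance only; no randomness is used).
#'
#' @param n_body Beads in the motor-head-like domain (core + 7-bead tail),
#'   >= 12.
#' @param n_conv Beads in the converter-like domain, >= 6.
#' @param hinge_angle_pre,hinge_angle_post Rotation (rad) of the converter
#'   about the hinge bead for the two conformations; must differ by >= 0.3.
#' @param bead_spacing Consecutive C-alpha spacing, nm.
#' @param seed Recorded in provenance.
#' @return List of class `toy_motor_spec`.
#' @export
toy_motor_spec <- function(n_body = 40L, n_conv = 12L,
                           hinge_angle_pre = 0, hinge_angle_post = -2.0,
                           bead_spacing = 0.38, seed = 1L) {
  if (n_body < 12L) stop("n_body must be >= 12")
  if (n_conv < 6L) stop("n_conv must be >= 6")
  dang <- abs(hinge_angle_post - hinge_angle_pre)
  # equal angles are allowed as a degenerate control (the two conformations
  # coincide); a small non-zero difference gives ill-separated basins
  if (dang > 0 && dang < 0.3)
    stop("hinge angles must be equal or differ by at least 0.3 rad")
  structure(list(
    n_body = as.integer(n_body), n_conv = as.integer(n_conv),
    hinge_angle_pre = hinge_angle_pre, hinge_angle_post = hinge_angle_post,
    bead_spacing = bead_spacing, seed = as.integer(seed),
    # internal geometry (nm / rad); tuned so the default toy satisfies the
    # structural properties the pipeline assumes (see vignette)
    n_tail = 5L,
    core_radius = 0.23, core_omega = 100 * pi / 180,
    tail_radius = 0.21, tail_omega = 120 * pi / 180,
    core_pair_dist = 0.95,
    tail_axis_offset = 0.88,
    conv_tangent_offset = 0.74,
    conv_radial_offset = -0.30,
    min_clearance = 0.38),
    class = "toy_motor_spec")
}

helix_rise <- function(spacing, radius, omega) {
  chord <- 2 * radius * sin(omega / 2)
  if (chord >= spacing) stop("helix parameters give non-positive rise")
  sqrt(spacing^2 - chord^2)
}

# n points on a helix: centre (x, y), phase/omega in rad, rise per bead
# (negative to descend).
helix_points <- function(n, radius, omega, rise, phase, z0, centre = c(0, 0)) {
  k <- seq_len(n) - 1L
  cbind(centre[1] + radius * cos(phase + omega * k),
        centre[2] + radius * sin(phase + omega * k),
        z0 + rise * k)
}

rotation_about_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c <- cos(angle); s <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c + ux^2 * (1 - c), ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
    uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c), uy * uz * (1 - c) - ux * s,
    uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)),
    3, 3, byrow = TRUE)
}

# Non-bonded means beyond the model's local exclusion (|i - j| > 3).
min_nonbonded_distance <- function(xyz, exclude_sep = 3L) {
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  min(d[upper.tri(d) & sep > exclude_sep])
}

.toy_coords <- function(spec, conv_phase_nudge = 0) {
  s <- spec$bead_spacing
  n_tail <- spec$n_tail
  n_core <- spec$n_body - n_tail
  om <- spec$core_omega
  a <- spec$core_radius

  # core: three helices packed as a triangular bundle (up, down, up), every
  # strand pair in contact -- the tertiary packing keeps the body folded at
  # the simulation temperature. Proper helices keep all bond angles well
  # away from pi (collinear chains make angle/dihedral terms singular).
  rise <- helix_rise(s, a, om)
  d <- spec$core_pair_dist
  P1 <- c(0, 0); P2 <- c(d, 0); P3 <- c(d / 2, d * sqrt(3) / 2)
  az <- function(from, to) atan2(to[2] - from[2], to[1] - from[1])
  centroid <- (P1 + P2 + P3) / 3
  rdir <- (P3 - centroid) / sqrt(sum((P3 - centroid)^2))
  psi <- atan2(rdir[2], rdir[1])
  n_str <- n_core - 3L                 # one top turn bead, two bottom
  n3 <- n_str %/% 3L
  n1 <- (n_str - n3 + 1L) %/% 2L
  n2 <- n_str - n3 - n1
  # phases: strand 1 ends facing strand 2; strand 3 ends facing the tail
  s1 <- helix_points(n1, a, om, rise, phase = az(P1, P2) - om * (n1 - 1L),
                     z0 = 0, centre = P1)
  s2 <- helix_points(n2, a, om, -rise, phase = az(P2, P1), z0 = s1[n1, 3],
                     centre = P2)
  t1 <- (s1[n1, ] + s2[1, ]) / 2 + c(0, 0, 0.30)
  s3 <- helix_points(n3, a, om, rise, phase = psi - om * (n3 - 1L),
                     z0 = s2[n2, 3], centre = P3)
  p <- s2[n2, ]; q <- s3[1, ]
  ch <- (q - p) / sqrt(sum((q - p)^2))
  t2 <- rbind(p + (q - p) / 3 - 0.10 * ch + c(0, 0, -0.32),
              p + 2 * (q - p) / 3 + 0.10 * ch + c(0, 0, -0.32))
  core <- rbind(s1, t1, s2, t2, s3)

  # tail: compact descending helix clamped against the outer face of the
  # third strand, near its top
  at <- spec$tail_radius; omt <- spec$tail_omega
  rt <- helix_rise(s, at, omt)
  tdir <- c(-rdir[2], rdir[1])
  tail_centre <- P3 + spec$tail_axis_offset * rdir
  z_top <- s3[n3, 3]
  # first tail bead faces the core so the junction bond closes at ~spacing
  gap_xy <- spec$tail_axis_offset - at - a
  dz0 <- sqrt(max(s^2 - gap_xy^2, 0.01))
  tail <- helix_points(n_tail, at, -omt, -rt, phase = psi + pi,
                       z0 = z_top - dz0, centre = tail_centre)

  # converter: one linker bead bridging hinge -> compact ascending helix
  # displaced tangentially from the tail axis
  hinge <- tail[n_tail, ]
  conv_centre <- tail_centre + spec$conv_tangent_offset * tdir +
    spec$conv_radial_offset * rdir
  n_helix <- spec$n_conv - 1L
  to_hinge <- (hinge[1:2] - conv_centre) /
    sqrt(sum((hinge[1:2] - conv_centre)^2))
  phase0 <- atan2(to_hinge[2], to_hinge[1]) + conv_phase_nudge
  first <- conv_centre + at * c(cos(phase0), sin(phase0))
  gap <- sqrt(sum((first - hinge[1:2])^2))
  dzc <- sqrt(max(s^2 - min(gap, s - 0.05)^2, 0.01))
  helix <- helix_points(n_helix, at, omt, rt, phase = phase0,
                        z0 = hinge[3] + dzc + rt, centre = conv_centre)
  hv <- helix[1, ] - hinge
  mid <- hinge + hv / 2
  # kink direction: perpendicular to the hinge->helix vector, pointing away
  # from the nearest tail bead so the linker clears the flap
  dd <- sqrt(rowSums(sweep(tail[-n_tail, , drop = FALSE], 2, mid)^2))
  near_tail <- tail[which.min(dd), ]
  away <- mid - near_tail
  away <- away - hv * sum(away * hv) / sum(hv^2)
  if (sqrt(sum(away^2)) < 0.05) away <- c(-hv[2], hv[1], 0)
  perp <- away / sqrt(sum(away^2))
  # kink sized so both linker bonds stay near the bead spacing and the
  # hinge angle is well away from collinear
  kink <- sqrt(max(0.36^2 - sum(hv^2) / 4, 0.02))
  linker <- mid + kink * perp
  conv <- rbind(linker, helix)
  list(core = core, tail = tail, conv = conv, hinge = hinge,
       rdir = rdir, tdir = tdir, psi = psi)
}

.pose_converter <- function(geom, angle) {
  if (abs(angle) < 1e-12) return(geom$conv)
  # hinge rotation axis: the tangential horizontal direction, which swings
  # the converter off the tail flap and down against the core
  R <- rotation_about_axis(c(geom$tdir, 0), angle)
  sweep(sweep(geom$conv, 2, geom$hinge) %*% t(R), 2, geom$hinge, "+")
}

.as_calpha <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  calpha_structure(data.frame(
    bead = seq_len(nrow(xyz)), chain = chain, resno = resno, resid = "GLY",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

#' Generate the two-conformation toy motor
#'
#' Returns the pre and post conformations (identical motor-head coordinates,
#' converter rigidly rotated about the hinge bead by the respective angle)
#' and the matching domain partition (MH_big = core, MH_small = tail,
#' nucleotide-pocket motifs on the clamped flap). Both conformations are
#' checked to be self-avoiding (no non-bonded pair closer than 0.38 nm); on
#' a clash the converter phase is nudged in small documented steps before
#' giving up.
#'
#' @param spec A `toy_motor_spec`.
#' @return List with `pre`, `post` (`calpha` structures) and `partition`.
#' @export
make_toy_motor <- function(spec = toy_motor_spec()) {
  nudges <- c(0, 0.15, -0.15, 0.3, -0.3)
  for (nudge in nudges) {
    geom <- .toy_coords(spec, conv_phase_nudge = nudge)
    pre_xyz <- rbind(geom$core, geom$tail,
                     .pose_converter(geom, spec$hinge_angle_pre))
    post_xyz <- rbind(geom$core, geom$tail,
                      .pose_converter(geom, spec$hinge_angle_post))
    ok <- min_nonbonded_distance(pre_xyz) >= spec$min_clearance &&
      min_nonbonded_distance(post_xyz) >= spec$min_clearance
    if (ok) break
  }
  if (!ok) stop("toy motor spec produces unavoidable steric clashes")
  n_core <- spec$n_body - spec$n_tail
  core_idx <- seq_len(n_core)
  tail_idx <- n_core + seq_len(spec$n_tail)
  conv_idx <- spec$n_body + seq_len(spec$n_conv)
  partition <- domain_partition(
    MH = c(core_idx, tail_idx), converter = conv_idx,
    MH_big = core_idx, MH_small = tail_idx,
    P_loop = tail(core_idx, 3),
    switch_I = head(tail_idx, 2), switch_II = tail_idx[3:4],
    n = spec$n_body + spec$n_conv)
  list(pre = .as_calpha(pre_xyz), post = .as_calpha(post_xyz),
       partition = partition, spec = spec)
}

#' Linear filament surrogate
#'
#' Beads at exact spacing along a given axis; the principal filament axis of
#' the result equals `axis` exactly.
#'
#' @param n Number of beads, >= 4.
#' @param spacing Bead spacing, nm.
#' @param axis Direction (normalised internally).
#' @param origin Position of the first bead.
#' @param chain Chain label (default "F").
#' @return `calpha` structure.
#' @export
make_toy_filament <- function(n = 10L, spacing = 0.55, axis = c(1, 0, 0),
                              origin = c(0, 0, 0), chain = "F") {
  if (n < 4L) stop("filament needs at least 4 beads")
  axis <- axis / sqrt(sum(axis^2))
  k <- seq_len(n) - 1L
  xyz <- cbind(origin[1] + spacing * k * axis[1],
               origin[2] + spacing * k * axis[2],
               origin[3] + spacing * k * axis[3])
  suppressWarnings(.as_calpha(xyz, chain = chain))
}

#' Attach a pseudo-phosphate ligand at a pocket centroid
#'
#' Places a single pseudo-ligand atom (residue name "PO4") at the centroid
#' of the pocket beads. By construction every pocket bead lies within the
#' default coordination cutoff of the ligand, so `pi_mediated_contacts`
#' returns a coordinating set containing the pocket.
#'
#' @param pre `calpha` structure (the ligand-bound conformation).
#' @param pocket Bead indices forming the pocket; must be mutually within
#'   1.2 nm.
#' @return The structure with the ligand atom appended.
#' @export
make_toy_ligand <- function(pre, pocket) {
  if (length(pocket) == 0L) stop("pocket must be non-empty")
  xyz <- coords(pre)[pocket, , drop = FALSE]
  if (nrow(xyz) > 1L && max(dist(xyz)) > 1.2)
    stop("pocket too dispersed (beads must be mutually within 1.2 nm)")
  centroid <- colMeans(xyz)
  lig <- data.frame(ligand = "PO4", atom = "P",
                    x = centroid[1], y = centroid[2], z = centroid[3],
                    stringsAsFactors = FALSE)
  calpha_structure(pre$atoms, rbind(pre$ligands, lig))
}

#' Assemble the full toy system (motor + pocket ligand + filament)
#'
#' Convenience constructor used by the scenario pipeline and the test
#' suite: generates the toy motor, identifies the flap pocket (the beads
#' joined by tail-core contacts), attaches the pseudo-phosphate at its
#' centroid, and docks a frozen filament under the core, perpendicular to
#' the core axis.
#'
#' @param spec `toy_motor_spec`.
#' @param n_actin,actin_spacing Filament size/spacing.
#' @param cutoff Contact cutoff used for pocket identification, nm.
#' @return List with `pre`, `post` (`calpha`, motor + filament; `pre`
#'   carries the ligand), `partition` (including the actin group), `motor`
#'   (the bare generator output) and `pocket` bead indices.
#' @export
make_toy_system <- function(spec = toy_motor_spec(), n_actin = 10L,
                            actin_spacing = 0.55, cutoff = 0.8) {
  motor <- make_toy_motor(spec)
  part <- motor$partition
  # pocket: beads joined by clamp (tail-core) contacts
  clamp <- interface_contacts(motor$pre, part$MH_small, part$MH_big,
                              cutoff = cutoff, tag = "preConvMH")
  if (nrow(clamp) == 0L) stop("toy spec yields no tail-core clamp contacts")
  pocket <- sort(unique(c(clamp$i, clamp$j)))
  pre_lig <- make_toy_ligand(motor$pre, pocket)

  # filament under the core bottom, running along the direction in which
  # the pocket flap unclamps, so a forward strain on the converter biases
  # the clamp opening (the allosteric channel of the strain response)
  fil <- make_toy_filament(n_actin, actin_spacing, axis = c(0, 1, 0),
                           origin = c(0.475,
                                      0.55 - 0.5 * n_actin * actin_spacing,
                                      -0.55))
  pre_all <- bind_structures(pre_lig, fil)
  post_all <- bind_structures(motor$post, fil)
  n_motor <- n_beads(motor$pre)
  partition <- domain_partition(
    MH = part$MH, converter = part$converter,
    MH_big = part$MH_big, MH_small = part$MH_small,
    P_loop = part$P_loop, switch_I = part$switch_I,
    switch_II = part$switch_II,
    actin = pre_all$idx_b, n = n_motor + n_actin)
  list(pre = pre_all$structure, post = post_all$structure,
       partition = partition, motor = motor, pocket = pocket,
       spec = spec)
}

#' Write toy fixtures as PDB + JSON spec
#'
#' Writes pre/post conformations as single-model PDB files and the
#' generating spec as JSON alongside, for inspection with standard tools.
#'
#' @param motor Output of `make_toy_motor`.
#' @param dir Output directory (created if missing).
#' @export
write_toy_fixtures <- function(motor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calpha_pdb(motor$pre, file.path(dir, "toy_pre.pdb"))
  write_calpha_pdb(motor$post, file.path(dir, "toy_post.pdb"))
  jsonlite::write_json(motor$spec[!vapply(motor$spec, is.null, TRUE)],
                       file.path(dir, "toy_spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
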