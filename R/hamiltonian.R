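# Multi-basin structure-based Hamiltonian:
#   H = H_preMH + H_preConv + H_postConv + H_preConv-MH + H_postConv-MH
#       + H_MH-Actin
# Each domain term carries harmonic bonds/angles, 1-3 cosine dihedrals and
# 10-12 native contacts measured from its reference conformation; interface
# and actin terms are purely non-bonded. Non-native pairs repel as
# eps_l (sigma/r)^12. Energies are reduced by eps_h, lengths are nm.

.term_names <- c("preMH", "preConv", "postConv", "preConvMH", "postConvMH",
                 "MHActin", "repulsion", "external", "trap")

#' Force-field parameters
#'
#' Inputs are in physical units (kcal/mol based); values are stored reduced
#' by `eps_h`, so with the default eps_h = 1 kcal/mol reduced and physical
#' numbers coincide. Defaults: K_r = 20 kcal/(mol A^2) (= 2000 per nm^2),
#' K_theta = 20 kcal/(mol rad^2), K_phi1 = 1.0, K_phi3 = 0.5 kcal/mol,
#' eps_h = eps_l = 1.0 kcal/mol, sigma = 0.4 nm, unit bead mass.
#'
#' @param K_r Bond stiffness, kcal/(mol nm^2).
#' @param K_theta Angle stiffness, kcal/(mol rad^2).
#' @param K_phi1,K_phi3 Dihedral amplitudes (n = 1, 3), kcal/mol.
#' @param eps_h Native-contact depth, kcal/mol (energy unit).
#' @param eps_l Repulsion scale, kcal/mol.
#' @param sigma Repulsion length, nm.
#' @param mass Bead mass (reduced).
#' @return List of class `ff_params` in reduced units.
#' @export
ff_params <- function(K_r = 2000, K_theta = 20, K_phi1 = 1.0, K_phi3 = 0.5,
                      eps_h = 1.0, eps_l = 1.0, sigma = 0.4, mass = 1.0) {
  vals <- c(K_r = K_r, K_theta = K_theta, K_phi1 = K_phi1, K_phi3 = K_phi3,
            eps_h = eps_h, eps_l = eps_l, sigma = sigma, mass = mass)
  if (any(vals <= 0)) stop("all force-field parameters must be positive")
  structure(list(K_r = K_r / eps_h, K_theta = K_theta / eps_h,
                 K_phi1 = K_phi1 / eps_h, K_phi3 = K_phi3 / eps_h,
                 eps_h = 1.0, eps_l = eps_l / eps_h, sigma = sigma,
                 mass = mass, eps_h_kcal = eps_h),
            class = "ff_params")
}

geom_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

# Signed dihedral in (-pi, pi], same convention as the compiled engine.
geom_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  m <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  n <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
         b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(m * n)
  y <- sum((c(m[2] * n[3] - m[3] * n[2], m[3] * n[1] - m[1] * n[3],
              m[1] * n[2] - m[2] * n[1])) * b2) / sqrt(sum(b2^2))
  atan2(y, x)
}

#' Native bonded topology of a contiguous bead group
#'
#' For N consecutive beads: N-1 bonds, N-2 angles, N-3 dihedrals, with
#' native values (r0, theta0, phi0) measured from the supplied conformation.
#'
#' @param structure `calpha` structure (the reference conformation).
#' @param group Contiguous bead-index range.
#' @return List of data.frames `bonds` (i, j, r0), `angles` (i, j, k,
#'   theta0), `dihedrals` (i, j, k, l, phi0).
#' @export
build_bonded <- function(structure, group) {
  group <- as.integer(group)
  if (!identical(group, seq(min(group), max(group))))
    stop("group must be a contiguous index range")
  xyz <- coords(structure)
  n <- length(group)
  bonds <- if (n >= 2) {
    i <- group[1:(n - 1)]; j <- group[2:n]
    data.frame(i = i, j = j,
               r0 = sqrt(rowSums((xyz[j, , drop = FALSE] -
                                  xyz[i, , drop = FALSE])^2)))
  } else data.frame(i = integer(), j = integer(), r0 = numeric())
  angles <- if (n >= 3) {
    i <- group[1:(n - 2)]
    data.frame(i = i, j = i + 1L, k = i + 2L,
               theta0 = vapply(i, function(b)
                 geom_angle(xyz[b, ], xyz[b + 1L, ], xyz[b + 2L, ]), 0))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta0 = numeric())
  dihedrals <- if (n >= 4) {
    i <- group[1:(n - 3)]
    data.frame(i = i, j = i + 1L, k = i + 2L, l = i + 3L,
               phi0 = vapply(i, function(b)
                 geom_dihedral(xyz[b, ], xyz[b + 1L, ], xyz[b + 2L, ],
                               xyz[b + 3L, ]), 0))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), phi0 = numeric())
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

contiguous_runs <- function(idx) {
  idx <- sort(as.integer(idx))
  if (length(idx) == 0L) return(list())
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  lapply(seq_len(length(breaks) - 1L),
         function(k) idx[(breaks[k] + 1L):breaks[k + 1L]])
}

# Classify a bonded term by domain membership of its beads.
.term_class <- function(beads, mh, conv) {
  in_mh <- beads %in% mh; in_conv <- beads %in% conv
  if (all(in_mh)) "MH" else if (all(in_conv)) "Conv"
  else if (all(in_mh | in_conv)) "junction" else "other"
}

#' Assemble the multi-basin energy model
#'
#' Builds the switchable six-term Hamiltonian from two reference
#' conformations and the tagged contact maps. Toggles select which terms are
#' active; a toggled-on term with a missing map is an error. When
#' `pi_removed = TRUE`, the phosphate-mediated subset is removed from the
#' motor-head native-contact list (and its pairs become ordinary repulsive
#' pairs). The repulsive exclusion list covers every pair native in any
#' active map and bonded neighbours (intra-chain |i - j| <= 3); a pair
#' contributes at most one repulsive term. Filament (actin) beads are frozen
#' and carry no internal terms.
#'
#' Bonded bookkeeping: MH bonded terms come from the pre conformation;
#' converter-internal bonded terms come per basin from its conformation;
#' bonded terms spanning the MH-converter junction are assigned per
#' converter basin (native values from that basin's structure) except the
#' junction bond, taken once from the pre structure.
#'
#' @param structure_pre,structure_post `calpha` reference conformations.
#' @param partition `domain_partition` (actin group marks frozen beads).
#' @param maps Named list of `contact_map`s: preMH, preConv, postConv,
#'   preConvMH, postConvMH, actin (only toggled-on entries required).
#' @param params `ff_params`.
#' @param toggles Character vector of active terms, subset of
#'   c("preMH", "preConv", "postConv", "preConvMH", "postConvMH", "MHActin").
#' @param pi_subset Optional `contact_map` of phosphate-mediated contacts.
#' @param pi_removed Remove `pi_subset` from the motor-head contacts?
#' @param dedup_basins If TRUE, contacts listed by both converter basins (or
#'   both interface maps) contribute a single term (r0 from pre); default
#'   FALSE sums the basins literally, one term per basin.
#' @param actin_repulsion Include actin-motor non-native repulsion?
#' @return Object of class `energy_model`.
#' @export
assemble <- function(structure_pre, structure_post, partition, maps,
                     params = ff_params(),
                     toggles = c("preMH", "preConv", "preConvMH", "MHActin"),
                     pi_subset = NULL, pi_removed = FALSE,
                     dedup_basins = FALSE, actin_repulsion = TRUE) {
  stopifnot(inherits(partition, "domain_partition"))
  bad <- setdiff(toggles, .term_names[1:6])
  if (length(bad)) stop("unknown toggles: ", paste(bad, collapse = ", "))
  n <- n_beads(structure_pre)
  mh <- partition$MH; conv <- partition$converter; act <- partition$actin
  covered <- sort(c(mh, conv, act))
  if (!identical(covered, seq_len(n)))
    stop("partition must cover every bead exactly once (MH + converter + actin)")
  needed <- intersect(toggles, c("preMH", "preConv", "postConv",
                                 "preConvMH", "postConvMH"))
  needed <- c(needed, if ("MHActin" %in% toggles) "actin")
  needed <- sub("^MHActin$", "actin", needed)
  miss <- setdiff(needed, names(maps))
  if (length(miss))
    stop("toggled-on term(s) missing contact map(s): ",
         paste(miss, collapse = ", "))
  if (pi_removed && (is.null(pi_subset) || nrow(pi_subset) == 0L))
    stop("pi_removed = TRUE requires a non-empty pi_subset")

  term_id <- setNames(seq_along(.term_names) - 1L, .term_names)  # 0-based
  bonds <- angles <- dihedrals <- list()
  add_bonded <- function(df, type, term) {
    df$term <- term_id[[term]]
    if (type == "bond") bonds[[length(bonds) + 1L]] <<- df
    else if (type == "angle") angles[[length(angles) + 1L]] <<- df
    else dihedrals[[length(dihedrals) + 1L]] <<- df
  }

  chain <- structure_pre$atoms$chain
  motor_beads <- sort(c(mh, conv))
  nb <- length(motor_beads)
  run_id <- cumsum(c(TRUE, diff(motor_beads) != 1L |
                       chain[motor_beads[-1]] != chain[motor_beads[-nb]]))
  for (sub in split(motor_beads, run_id)) {
    {
      sub <- as.integer(sub)
      if (length(sub) < 2L) next
      top_pre <- build_bonded(structure_pre, sub)
      top_post <- build_bonded(structure_post, sub)
      classify <- function(df, cols) {
        apply(df[, cols, drop = FALSE], 1, function(b)
          .term_class(as.integer(b), mh, conv))
      }
      # bonds
      cls <- classify(top_pre$bonds, c("i", "j"))
      add_bonded(top_pre$bonds[cls == "MH", , drop = FALSE], "bond", "preMH")
      add_bonded(top_pre$bonds[cls == "junction", , drop = FALSE], "bond", "preMH")
      if ("preConv" %in% toggles)
        add_bonded(top_pre$bonds[cls == "Conv", , drop = FALSE], "bond", "preConv")
      if ("postConv" %in% toggles)
        add_bonded(top_post$bonds[cls == "Conv", , drop = FALSE], "bond", "postConv")
      # angles
      cls <- classify(top_pre$angles, c("i", "j", "k"))
      add_bonded(top_pre$angles[cls == "MH", , drop = FALSE], "angle", "preMH")
      if ("preConv" %in% toggles)
        add_bonded(top_pre$angles[cls %in% c("Conv", "junction"), , drop = FALSE],
                   "angle", "preConv")
      if ("postConv" %in% toggles)
        add_bonded(top_post$angles[cls %in% c("Conv", "junction"), , drop = FALSE],
                   "angle", "postConv")
      # dihedrals
      cls <- classify(top_pre$dihedrals, c("i", "j", "k", "l"))
      add_bonded(top_pre$dihedrals[cls == "MH", , drop = FALSE], "dih", "preMH")
      if ("preConv" %in% toggles)
        add_bonded(top_pre$dihedrals[cls %in% c("Conv", "junction"), , drop = FALSE],
                   "dih", "preConv")
      if ("postConv" %in% toggles)
        add_bonded(top_post$dihedrals[cls %in% c("Conv", "junction"), , drop = FALSE],
                   "dih", "postConv")
    }
  }
  bonds <- do.call(rbind, c(bonds, list(data.frame(i = integer(), j = integer(),
                                                   r0 = numeric(), term = integer()))))
  angles <- do.call(rbind, c(angles, list(data.frame(i = integer(), j = integer(),
                                                     k = integer(), theta0 = numeric(),
                                                     term = integer()))))
  dihedrals <- do.call(rbind, c(dihedrals, list(
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               phi0 = numeric(), term = integer()))))

  # native-contact term lists
  con <- list()
  add_contacts <- function(map, term) {
    if (is.null(map) || nrow(map) == 0L) return()
    con[[length(con) + 1L]] <<- data.frame(
      i = map$i, j = map$j, r0 = map$r0, eps = params$eps_h,
      term = term_id[[term]])
  }
  mh_map <- maps$preMH
  if (pi_removed) mh_map <- remove_contacts(mh_map, pi_subset)
  if ("preMH" %in% toggles) add_contacts(mh_map, "preMH")
  if ("preConv" %in% toggles) add_contacts(maps$preConv, "preConv")
  post_conv <- maps$postConv
  post_convmh <- maps$postConvMH
  if (dedup_basins) {
    if ("preConv" %in% toggles && !is.null(post_conv))
      post_conv <- exclusive_contacts(post_conv, maps$preConv)
    if ("preConvMH" %in% toggles && !is.null(post_convmh))
      post_convmh <- exclusive_contacts(post_convmh, maps$preConvMH)
  }
  if ("postConv" %in% toggles) add_contacts(post_conv, "postConv")
  if ("preConvMH" %in% toggles) add_contacts(maps$preConvMH, "preConvMH")
  if ("postConvMH" %in% toggles) add_contacts(post_convmh, "postConvMH")
  if ("MHActin" %in% toggles) add_contacts(maps$actin, "MHActin")
  con <- do.call(rbind, c(con, list(data.frame(i = integer(), j = integer(),
                                               r0 = numeric(), eps = numeric(),
                                               term = integer()))))

  # repulsive pairs: everything not native in an active map, not a bonded
  # neighbour, not frozen-frozen
  frozen <- rep(FALSE, n); frozen[act] <- TRUE
  native_key <- unique(paste(con$i, con$j))
  all_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  all_j <- sequence((n - 1L):1L) + all_i
  key <- paste(all_i, all_j)
  same_chain <- chain[all_i] == chain[all_j]
  excl <- (key %in% native_key) |
    (same_chain & (all_j - all_i) <= 3L) |
    (frozen[all_i] & frozen[all_j])
  if (!actin_repulsion) excl <- excl | xor(frozen[all_i], frozen[all_j])
  rep_i <- all_i[!excl]; rep_j <- all_j[!excl]

  model <- list(
    n = n,
    bond_i = as.integer(bonds$i), bond_j = as.integer(bonds$j),
    bond_r0 = bonds$r0, bond_term = as.integer(bonds$term),
    K_r = params$K_r,
    angle_i = as.integer(angles$i), angle_j = as.integer(angles$j),
    angle_k = as.integer(angles$k), angle_t0 = angles$theta0,
    angle_term = as.integer(angles$term), K_theta = params$K_theta,
    dih_i = as.integer(dihedrals$i), dih_j = as.integer(dihedrals$j),
    dih_k = as.integer(dihedrals$k), dih_l = as.integer(dihedrals$l),
    dih_phi0 = dihedrals$phi0, dih_term = as.integer(dihedrals$term),
    K_phi1 = params$K_phi1, K_phi3 = params$K_phi3,
    con_i = as.integer(con$i), con_j = as.integer(con$j),
    con_r0 = con$r0, con_eps = con$eps, con_term = as.integer(con$term),
    rep_i = as.integer(rep_i), rep_j = as.integer(rep_j),
    eps_l = params$eps_l, sigma = params$sigma,
    has_trap = FALSE, has_fext = FALSE,
    frozen = frozen, n_terms = length(.term_names),
    params = params, toggles = toggles, pi_removed = pi_removed,
    partition = partition, chain = chain,
    term_counts = table(factor(.term_names[con$term + 1L],
                               levels = .term_names[1:6])))
  class(model) <- "energy_model"
  model
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("energy_model: %d beads (%d frozen), toggles: %s%s\n",
              x$n, sum(x$frozen), paste(x$toggles, collapse = "+"),
              if (x$pi_removed) ", Pi removed" else ""))
  cat(sprintf("  bonds %d, angles %d, dihedrals %d, contacts %d, repulsive pairs %d\n",
              length(x$bond_i), length(x$angle_i), length(x$dih_i),
              length(x$con_i), length(x$rep_i)))
  print(x$term_counts)
  invisible(x)
}

#' Single-bead (or few-bead) harmonic-trap validation model
#'
#' A minimal `energy_model` with only per-bead harmonic restraints, used to
#' validate the thermostat (positional variance kT/k, equipartition) and
#' constant-force handling (mean displacement F/k).
#'
#' @param k Restraint stiffness (reduced energy / nm^2), recycled per bead.
#' @param x0 Restraint centre(s), n x 3 matrix.
#' @param params `ff_params`.
#' @export
harmonic_trap_model <- function(k, x0 = matrix(0, 1, 3),
                                params = ff_params()) {
  x0 <- matrix(x0, ncol = 3)
  n <- nrow(x0)
  model <- list(
    n = n,
    bond_i = integer(), bond_j = integer(), bond_r0 = numeric(),
    bond_term = integer(), K_r = params$K_r,
    angle_i = integer(), angle_j = integer(), angle_k = integer(),
    angle_t0 = numeric(), angle_term = integer(), K_theta = params$K_theta,
    dih_i = integer(), dih_j = integer(), dih_k = integer(),
    dih_l = integer(), dih_phi0 = numeric(), dih_term = integer(),
    K_phi1 = params$K_phi1, K_phi3 = params$K_phi3,
    con_i = integer(), con_j = integer(), con_r0 = numeric(),
    con_eps = numeric(), con_term = integer(),
    rep_i = integer(), rep_j = integer(),
    eps_l = params$eps_l, sigma = params$sigma,
    has_trap = TRUE, trap_k = rep_len(k, n), trap_x0 = x0,
    has_fext = FALSE, frozen = rep(FALSE, n),
    n_terms = length(.term_names), params = params,
    toggles = character(), pi_removed = FALSE, chain = rep("A", n),
    term_counts = NULL)
  class(model) <- "energy_model"
  model
}

#' Constant external force specification
#'
#' A total force of the given magnitude along `direction`, shared equally by
#' the beads of `target` (the per-bead force is magnitude/|target| unless
#' `per_bead = TRUE`). Magnitudes are accepted in kJ mol^-1 nm^-1 (the
#' conventional strain-force unit) and converted to reduced units (eps_h
#' nm^-1, i.e. kcal-based) internally: 1 kJ = 1/4.184 kcal.
#'
#' @param target Bead indices the force acts on.
#' @param direction Unit 3-vector (normalised internally; must be non-zero).
#' @param magnitude Total force, kJ mol^-1 nm^-1 unless `units = "reduced"`.
#' @param units "kJ/mol/nm" or "reduced".
#' @param per_bead Apply `magnitude` to every bead rather than in total.
#' @export
external_force <- function(target, direction, magnitude,
                           units = c("kJ/mol/nm", "reduced"),
                           per_bead = FALSE) {
  units <- match.arg(units)
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("direction must be non-zero")
  if (magnitude < 0) stop("magnitude must be >= 0")
  f_red <- if (units == "kJ/mol/nm") magnitude / 4.184 else magnitude
  structure(list(target = as.integer(target),
                 direction = direction / nd,
                 magnitude = magnitude, units = units,
                 f_reduced_total = if (per_bead) f_red * length(target) else f_red,
                 per_bead = per_bead),
            class = "external_force")
}

# Materialise an external_force into the model's per-bead force matrix.
set_external_force <- function(model, force) {
  if (is.null(force)) return(model)
  stopifnot(inherits(force, "external_force"))
  fext <- matrix(0, model$n, 3)
  per <- force$f_reduced_total / length(force$target)
  fext[force$target, ] <- rep(per * force$direction,
                              each = length(force$target))
  model$has_fext <- TRUE
  model$fext <- fext
  model$force_spec <- force
  model
}

#' Potential energy with per-term breakdown
#'
#' @param model `energy_model`.
#' @param coords N x 3 matrix (nm) or `calpha` structure.
#' @return List with `energy` (reduced, eps_h units) and named `breakdown`
#'   over the Hamiltonian terms plus repulsion/external/trap.
#' @export
potential_energy <- function(model, coords) {
  xyz <- coords(coords)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  res <- cpp_energy_forces(xyz, unclass(model))
  list(energy = res$energy,
       breakdown = setNames(res$breakdown, .term_names))
}

#' Forces (negative energy gradient)
#'
#' Analytic forces; frozen beads report zero force and any constant external
#' force is added to its target group.
#'
#' @inheritParams potential_energy
#' @return N x 3 matrix of reduced forces (eps_h / nm).
#' @export
forces <- function(model, coords) {
  xyz <- coords(coords)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  cpp_energy_forces(xyz, unclass(model))$forces
}

#' Serialize an energy model to a plain-text topology file
#'
#' A JSON header (parameters, toggles, counts) followed by sections atoms,
#' bonds, angles, dihedrals, pairs (native contacts) and exclusions
#' (repulsive pair list). Round-trippable via `read_topology`.
#'
#' @param model `energy_model`.
#' @param path Output file.
#' @export
write_topology <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(n = model$n,
              params = model$params[c("K_r", "K_theta", "K_phi1", "K_phi3",
                                      "eps_l", "sigma", "mass")],
              toggles = model$toggles, pi_removed = model$pi_removed)
  writeLines(paste0("#HEADER ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  writeLines("[atoms]", con)
  writeLines(sprintf("%d %s %d", seq_len(model$n), model$chain,
                     as.integer(model$frozen)), con)
  writeLines("[bonds]", con)
  writeLines(sprintf("%d %d %.17g %d", model$bond_i, model$bond_j,
                     model$bond_r0, model$bond_term), con)
  writeLines("[angles]", con)
  writeLines(sprintf("%d %d %d %.17g %d", model$angle_i, model$angle_j,
                     model$angle_k, model$angle_t0, model$angle_term), con)
  writeLines("[dihedrals]", con)
  writeLines(sprintf("%d %d %d %d %.17g %d", model$dih_i, model$dih_j,
                     model$dih_k, model$dih_l, model$dih_phi0,
                     model$dih_term), con)
  writeLines("[pairs]", con)
  writeLines(sprintf("%d %d %.17g %.17g %d", model$con_i, model$con_j,
                     model$con_r0, model$con_eps, model$con_term), con)
  writeLines("[exclusions]", con)
  writeLines(sprintf("%d %d", model$rep_i, model$rep_j), con)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#HEADER ", "", lines[1]))
  sec <- function(name) {
    start <- which(lines == paste0("[", name, "]"))
    ends <- c(grep("^\\[", lines), length(lines) + 1L)
    end <- min(ends[ends > start]) - 1L
    if (end < start + 1L) return(character())
    lines[(start + 1L):end]
  }
  num <- function(x, col) if (length(x)) as.numeric(vapply(strsplit(x, " "),
                                                           `[`, "", col)) else numeric()
  atoms <- sec("atoms"); b <- sec("bonds"); a <- sec("angles")
  d <- sec("dihedrals"); p <- sec("pairs"); e <- sec("exclusions")
  prm <- ff_params(K_r = hdr$params$K_r, K_theta = hdr$params$K_theta,
                   K_phi1 = hdr$params$K_phi1, K_phi3 = hdr$params$K_phi3,
                   eps_l = hdr$params$eps_l, sigma = hdr$params$sigma,
                   mass = hdr$params$mass)
  model <- list(
    n = hdr$n,
    bond_i = as.integer(num(b, 1)), bond_j = as.integer(num(b, 2)),
    bond_r0 = num(b, 3), bond_term = as.integer(num(b, 4)), K_r = prm$K_r,
    angle_i = as.integer(num(a, 1)), angle_j = as.integer(num(a, 2)),
    angle_k = as.integer(num(a, 3)), angle_t0 = num(a, 4),
    angle_term = as.integer(num(a, 5)), K_theta = prm$K_theta,
    dih_i = as.integer(num(d, 1)), dih_j = as.integer(num(d, 2)),
    dih_k = as.integer(num(d, 3)), dih_l = as.integer(num(d, 4)),
    dih_phi0 = num(d, 5), dih_term = as.integer(num(d, 6)),
    K_phi1 = prm$K_phi1, K_phi3 = prm$K_phi3,
    con_i = as.integer(num(p, 1)), con_j = as.integer(num(p, 2)),
    con_r0 = num(p, 3), con_eps = num(p, 4),
    con_term = as.integer(num(p, 5)),
    rep_i = as.integer(num(e, 1)), rep_j = as.integer(num(e, 2)),
    eps_l = prm$eps_l, sigma = prm$sigma,
    has_trap = FALSE, has_fext = FALSE,
    frozen = as.logical(as.integer(vapply(strsplit(atoms, " "), `[`, "", 3))),
    n_terms = length(.term_names), params = prm,
    toggles = hdr$toggles, pi_removed = isTRUE(hdr$pi_removed),
    chain = vapply(strsplit(atoms, " "), `[`, "", 2), term_counts = NULL)
  class(model) <- "energy_model"
  model
}
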