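# Langevin dynamics in reduced units.
#
# Time unit: tau_L = sqrt(m sigma^2 / eps_h); with m = 1, sigma = 0.4 nm and
# eps_h = 1 this is 0.4 internal time units (internal = sqrt(m nm^2/eps_h)).
# Friction and step size are specified in tau_L units and converted
# internally. kB = 0.0019872 kcal/(mol K), so T = 300 K corresponds to a
# reduced temperature of 0.5962 when eps_h = 1 kcal/mol.

.kB_kcal <- 0.0019872

#' Langevin run configuration
#'
#' @param T Temperature, K.
#' @param zeta Friction coefficient, units of 1/tau_L (low-friction default
#'   0.05 for efficient conformational sampling).
#' @param h Integration time step, units of tau_L (default 0.0025).
#' @param n_relax Steps discarded before sampling starts.
#' @param n_sample Sampled steps after relaxation.
#' @param save_every Frame stride (in steps).
#' @param seed RNG seed; the entire trajectory is a deterministic function
#'   of (model, init, config, seed).
#' @param e_guard Abort threshold on |potential energy| (divergence guard).
#' @export
langevin_config <- function(T = 300, zeta = 0.05, h = 0.0025,
                            n_relax = 20000L, n_sample = 200000L,
                            save_every = 200L, seed = 1L,
                            e_guard = 1e8) {
  stopifnot(zeta > 0, h > 0, T > 0, n_sample > 0, save_every > 0)
  structure(list(T = T, zeta = zeta, h = h,
                 n_relax = as.integer(n_relax),
                 n_sample = as.integer(n_sample),
                 save_every = as.integer(save_every),
                 seed = as.integer(seed), e_guard = e_guard),
            class = "langevin_config")
}

reduced_kT <- function(T, params) .kB_kcal * T / params$eps_h_kcal

tau_L <- function(params) sqrt(params$mass * params$sigma^2 / 1)

#' Integrate the Langevin equation of motion
#'
#' BBK (velocity-Verlet with friction) discretization of
#' m x'' = -zeta x' - dH/dx + Gamma(t), with random-force autocorrelation
#' 6 zeta kB T / h on the 3-vector (2 zeta kB T / h per component). Initial
#' velocities are drawn from the Maxwell distribution at the configured
#' temperature. Frozen beads (the filament) never move; an optional constant
#' external force is shared over its target group.
#'
#' @param model `energy_model`.
#' @param init N x 3 initial coordinates (nm) or `calpha` structure.
#' @param config `langevin_config`.
#' @param force Optional `external_force`.
#' @return Object of class `trajectory`: `frames` (N x 3 x n_frames array),
#'   `times` (reduced, tau_L units), `epot`, `ekin`, and provenance
#'   (`config`, toggles, force spec).
#' @export
langevin_run <- function(model, init, config = langevin_config(),
                         force = NULL) {
  xyz <- coords(init)
  stopifnot(nrow(xyz) == model$n)
  model <- set_external_force(model, force)
  prm <- model$params
  kT <- reduced_kT(config$T, prm)
  tl <- tau_L(prm)
  h <- config$h * tl
  zeta <- config$zeta / tl
  set.seed(config$seed)
  vel <- matrix(rnorm(3 * model$n, sd = sqrt(kT / prm$mass)), model$n, 3)
  vel[model$frozen, ] <- 0
  out <- cpp_langevin(xyz, vel, unclass(model),
                      n_steps = config$n_relax + config$n_sample,
                      n_relax = config$n_relax,
                      save_every = config$save_every,
                      h = h, zeta = zeta, kT = kT,
                      e_guard = config$e_guard)
  if (out$aborted)
    stop(sprintf(
      "energy divergence guard tripped (|E| = %.3g); diagnostic frame in attr",
      out$last_energy),
      call. = FALSE)
  n_saved <- out$n_saved
  frames <- out$frames
  traj <- structure(list(
    frames = frames,
    times = out$times / tl,    # report times in tau_L units
    epot = out$epot, ekin = out$ekin,
    config = config,
    toggles = model$toggles, pi_removed = model$pi_removed,
    force = model$force_spec %||% NULL,
    frozen = model$frozen,
    final = list(coords = out$coords, vel = out$vel)),
    class = "trajectory")
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames of %d beads, t in [%.1f, %.1f] tau_L\n",
              n_frames(x), dim(x$frames)[1], min(x$times), max(x$times)))
  invisible(x)
}

#' Number of saved frames
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as an N x 3 matrix
#' @param traj A `trajectory`.
#' @param k Frame index.
#' @export
frame_coords <- function(traj, k) traj$frames[, , k]

#' Validate constant-force handling on a tethered bead
#'
#' Runs a single bead in a harmonic trap of stiffness `k` with a constant
#' force `F` along x and reports the time-averaged displacement along the
#' axis, which must converge to F/k, together with the positional variance
#' (unchanged under the force, by the harmonic shift theorem).
#'
#' @param k Trap stiffness (reduced / nm^2).
#' @param F Constant force (reduced / nm).
#' @param config `langevin_config`.
#' @return List with `mean_displacement`, `expected` (F/k), `variance`.
#' @export
constant_force_check <- function(k, F, config = langevin_config(
  n_relax = 50000L, n_sample = 1000000L, save_every = 20L)) {
  model <- harmonic_trap_model(k)
  force <- if (F != 0)
    external_force(1L, c(1, 0, 0), F, units = "reduced") else NULL
  traj <- langevin_run(model, matrix(0, 1, 3), config, force)
  xs <- traj$frames[1, 1, ]
  list(mean_displacement = mean(xs), expected = F / k, variance = var(xs))
}

#' Principal axis of a filament bead cloud
#'
#' First principal component of the coordinates, with the sign chosen so the
#' axis points from the first-indexed bead toward the last (increasing
#' filament index).
#'
#' @param actin_coords M x 3 matrix (M >= 2) or `calpha` structure.
#' @return Unit 3-vector.
#' @export
actin_axis <- function(actin_coords) {
  xyz <- coords(actin_coords)
  if (nrow(xyz) < 2L) stop("need at least 2 filament beads")
  centred <- sweep(xyz, 2, colMeans(xyz))
  if (max(abs(centred)) < 1e-12) stop("degenerate filament (single point)")
  ax <- svd(centred, nu = 0, nv = 1)$v[, 1]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(ax * span) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Scan strain-force magnitudes
#'
#' Runs one trajectory per force magnitude, pulling the converter group
#' along the filament axis. Magnitudes are in kJ mol^-1 nm^-1 (total over
#' the group). All magnitudes share the same seed (common random numbers),
#' so the small systematic strain response is not swamped by independent
#' thermal noise between runs; the policy is recorded per trajectory.
#'
#' @param model `energy_model` (trailing-head assembly with actin present).
#' @param init Initial coordinates.
#' @param config `langevin_config`.
#' @param magnitudes Numeric vector of total forces, kJ mol^-1 nm^-1.
#' @param target Bead group pulled (default: converter of the model's
#'   partition).
#' @param direction Unit pulling direction (default: the actin axis of the
#'   frozen beads).
#' @return Named list of `trajectory` objects ("F0", "F3", ...), each with a
#'   `$strain` provenance entry.
#' @export
strain_scan <- function(model, init, config, magnitudes,
                        target = model$partition$converter,
                        direction = NULL) {
  if (is.null(direction)) {
    if (!any(model$frozen)) stop("no frozen filament beads to define an axis")
    direction <- actin_axis(coords(init)[model$frozen, , drop = FALSE])
  }
  out <- list()
  for (k in seq_along(magnitudes)) {
    mag <- magnitudes[k]
    f <- if (mag > 0) external_force(target, direction, mag) else NULL
    tr <- langevin_run(model, init, config, f)
    tr$strain <- list(magnitude_kJ = mag, direction = direction,
                      seed = config$seed, seed_policy = "common random numbers")
    out[[paste0("F", format(mag))]] <- tr
  }
  out
}
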