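# Scenario orchestration: wire the Hamiltonian toggles for each simulated
# state of the mechanochemical cycle, run the dynamics, and compute the
# scenario's observables.
#
# Toggle wiring (term names refer to the six-term multi-basin Hamiltonian):
#   leading               preMH + preConv + preConvMH + MHActin
#   trailing              preMH + postConv + postConvMH + MHActin
#   powerstroke_with_pi   all six, phosphate-mediated contacts retained
#   powerstroke_without_pi all six, phosphate-mediated subset removed
#   strain_scan           trailing toggles + constant pulling force on the
#                         converter along the filament axis
#   toy_demo              leading + trailing back-to-back comparison

.scenario_toggles <- list(
  leading = c("preMH", "preConv", "preConvMH", "MHActin"),
  trailing = c("preMH", "postConv", "postConvMH", "MHActin"),
  powerstroke_with_pi = c("preMH", "preConv", "postConv", "preConvMH",
                          "postConvMH", "MHActin"),
  powerstroke_without_pi = c("preMH", "preConv", "postConv", "preConvMH",
                             "postConvMH", "MHActin"))

#' Scenario configuration
#'
#' All numeric knobs for a scenario run live here. By default the scenario
#' runs on the synthetic toy system; supply `system` (the output of
#' `make_toy_system`, or an equivalently shaped list built from real
#' structures) to override.
#'
#' @param scenario One of "leading", "trailing", "powerstroke_with_pi",
#'   "powerstroke_without_pi", "strain_scan", "toy_demo".
#' @param spec `toy_motor_spec` used when no system is supplied.
#' @param system Optional pre-built system (list with `pre`, `post`,
#'   `partition`).
#' @param langevin `langevin_config`.
#' @param strain_magnitudes Total pulling forces for strain_scan,
#'   kJ mol^-1 nm^-1.
#' @param cutoff Native-contact cutoff, nm.
#' @param lig_cutoff Phosphate coordination cutoff, nm.
#' @param pi_mode "both" or "any" (endpoint coordination rule).
#' @param rmsd_bin,dist_bin Histogram bin widths, nm.
#' @param out_dir Optional output directory for trajectories, observable
#'   TSVs, summary + provenance JSON.
#' @export
scenario_config <- function(scenario = c("toy_demo", "leading", "trailing",
                                         "powerstroke_with_pi",
                                         "powerstroke_without_pi",
                                         "strain_scan"),
                            spec = toy_motor_spec(),
                            system = NULL,
                            langevin = langevin_config(),
                            strain_magnitudes = c(0, 3, 5),
                            cutoff = 0.8, lig_cutoff = 0.8,
                            pi_mode = "both",
                            rmsd_bin = 0.01, dist_bin = 0.05,
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, spec = spec, system = system,
                 langevin = langevin,
                 strain_magnitudes = strain_magnitudes,
                 cutoff = cutoff, lig_cutoff = lig_cutoff,
                 pi_mode = pi_mode, rmsd_bin = rmsd_bin,
                 dist_bin = dist_bin, out_dir = out_dir),
            class = "scenario_config")
}

#' Extract all six tagged contact maps of a system
#'
#' @param system List with `pre`, `post` (`calpha`) and `partition`.
#' @param cutoff Contact cutoff, nm.
#' @return Named list of `contact_map`s: preMH, preConv, postConv,
#'   preConvMH, postConvMH, actin.
#' @export
system_contact_maps <- function(system, cutoff = 0.8) {
  part <- system$partition
  maps <- list(
    preMH = native_contacts(system$pre, part$MH, cutoff, tag = "preMH"),
    preConv = native_contacts(system$pre, part$converter, cutoff,
                              tag = "preConv"),
    postConv = native_contacts(system$post, part$converter, cutoff,
                               tag = "postConv"),
    preConvMH = interface_contacts(system$pre, part$converter, part$MH,
                                   cutoff, tag = "preConvMH"),
    postConvMH = interface_contacts(system$post, part$converter, part$MH,
                                    cutoff, tag = "postConvMH"))
  if (length(part$actin) > 0L)
    maps$actin <- interface_contacts(system$pre, part$MH, part$actin,
                                     cutoff, tag = "actin")
  maps
}

#' Initial coordinates for a trailing-head run
#'
#' Composite structure: motor-head (and filament) coordinates from the pre
#' conformation, converter placed by superposing the post conformation onto
#' the pre motor head over the anchor group.
#'
#' @param system System list (`pre`, `post`, `partition`).
#' @param anchor Bead group for the superposition (default: the motor
#'   head).
#' @return N x 3 coordinate matrix.
#' @export
trailing_init <- function(system, anchor = system$partition$MH) {
  pre <- coords(system$pre); post <- coords(system$post)
  tf <- kabsch_superpose(post[anchor, , drop = FALSE],
                         pre[anchor, , drop = FALSE])
  conv <- system$partition$converter
  out <- pre
  out[conv, ] <- apply_transform(tf, post[conv, , drop = FALSE])
  out
}

# Reference RMSD of the post pose measured like the ensemble observable;
# the two-basin threshold is its midpoint (deterministic, structure-based).
.post_pose_rmsd <- function(system) {
  part <- system$partition
  fitted_rmsd(coords(system$post), system$pre, part$MH_big, part$converter)
}

#' Run one scenario end-to-end
#'
#' Builds the system (toy by default), extracts contact maps, assembles the
#' energy model with the scenario's toggle wiring, integrates the dynamics
#' and computes the scenario's distributional observables. With `out_dir`
#' set, writes trajectories (XYZ), per-frame observables (TSV), summaries
#' and provenance (JSON).
#'
#' @param config `scenario_config`.
#' @return List with `scenario`, `system`, `models` (term bookkeeping),
#'   `trajectories`, and `summaries` (named `distribution_summary`
#'   objects / mode tables appropriate to the scenario).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sys <- config$system %||% make_toy_system(config$spec, cutoff = config$cutoff)
  part <- sys$partition
  maps <- system_contact_maps(sys, config$cutoff)
  needs_pi <- config$scenario %in% c("powerstroke_with_pi",
                                     "powerstroke_without_pi")
  pi <- NULL
  if (needs_pi || nrow(sys$pre$ligands) > 0L)
    pi <- tryCatch(
      pi_mediated_contacts(sys$pre, maps$preMH, config$lig_cutoff,
                           mode = config$pi_mode),
      error = function(e) if (needs_pi) stop(
        "scenario '", config$scenario, "' requires a phosphate ligand: ",
        conditionMessage(e), call. = FALSE) else NULL)

  build <- function(toggles, pi_removed = FALSE)
    assemble(sys$pre, sys$post, part, maps,
             toggles = toggles,
             pi_subset = if (!is.null(pi)) pi$subset,
             pi_removed = pi_removed)

  run_one <- function(model, init, seed_offset = 0L) {
    cfg <- config$langevin
    cfg$seed <- cfg$seed + seed_offset
    langevin_run(model, init, cfg)
  }

  res <- list(scenario = config$scenario, system = sys, models = list(),
              trajectories = list(), summaries = list())
  conv_rmsd <- function(traj) estimate_modes(
    rmsd_distribution(traj, sys$pre, part$MH_big, part$converter,
                      config$rmsd_bin))
  small_rmsd <- function(traj) estimate_modes(
    rmsd_distribution(traj, sys$pre, part$MH_big, part$MH_small,
                      config$rmsd_bin))
  motif_dists <- function(traj) list(
    d_SWI_Ploop = estimate_modes(group_distance_series(
      traj, part$switch_I, part$P_loop, config$dist_bin)),
    d_SWII_Ploop = estimate_modes(group_distance_series(
      traj, part$switch_II, part$P_loop, config$dist_bin)),
    d_SWI_SWII = estimate_modes(group_distance_series(
      traj, part$switch_I, part$switch_II, config$dist_bin)))

  if (config$scenario %in% c("leading", "trailing")) {
    toggles <- .scenario_toggles[[config$scenario]]
    model <- build(toggles)
    init <- if (config$scenario == "leading") coords(sys$pre)
            else trailing_init(sys)
    traj <- run_one(model, init)
    res$models[[config$scenario]] <- model
    res$trajectories[[config$scenario]] <- traj
    res$summaries$conv_rmsd <- conv_rmsd(traj)
    res$summaries$small_rmsd <- small_rmsd(traj)
    res$summaries$motifs <- motif_dists(traj)
  } else if (config$scenario == "toy_demo") {
    for (sc in c("leading", "trailing")) {
      model <- build(.scenario_toggles[[sc]])
      init <- if (sc == "leading") coords(sys$pre) else trailing_init(sys)
      traj <- run_one(model, init)
      res$models[[sc]] <- model
      res$trajectories[[sc]] <- traj
      res$summaries[[paste0(sc, "_conv_rmsd")]] <- conv_rmsd(traj)
      res$summaries[[paste0(sc, "_small_rmsd")]] <- small_rmsd(traj)
      res$summaries[[paste0(sc, "_motifs")]] <- motif_dists(traj)
    }
    res$summaries$mode_leading <-
      res$summaries$leading_conv_rmsd$modes[1]
    res$summaries$mode_trailing <-
      res$summaries$trailing_conv_rmsd$modes[1]
  } else if (config$scenario %in% c("powerstroke_with_pi",
                                    "powerstroke_without_pi")) {
    pi_removed <- config$scenario == "powerstroke_without_pi"
    model <- build(.scenario_toggles[[config$scenario]],
                   pi_removed = pi_removed)
    traj <- run_one(model, coords(sys$pre))
    res$models[[config$scenario]] <- model
    res$trajectories[[config$scenario]] <- traj
    sm <- rmsd_distribution(traj, sys$pre, part$MH_big, part$converter,
                            config$rmsd_bin)
    sm <- estimate_modes(sm, expected_modes = 2)
    threshold <- .post_pose_rmsd(sys) / 2
    threshold <- min(max(threshold, min(sm$samples) + 1e-9),
                     max(sm$samples) - 1e-9)
    sm <- basin_populations(sm, threshold)
    res$summaries$conv_rmsd <- sm
    res$summaries$fraction_pre <- sm$population_split$fraction_below
    res$summaries$fraction_post <- sm$population_split$fraction_above
  } else if (config$scenario == "strain_scan") {
    model <- build(.scenario_toggles$trailing)
    init <- trailing_init(sys)
    trajs <- strain_scan(model, init, config$langevin,
                         config$strain_magnitudes,
                         target = part$converter)
    res$models$trailing <- model
    res$trajectories <- trajs
    res$summaries$small_big_distance <- lapply(trajs, function(tr)
      estimate_modes(group_distance_series(tr, part$MH_small, part$MH_big,
                                           config$dist_bin)))
    res$summaries$distance_modes <- vapply(
      res$summaries$small_big_distance, function(s) s$modes[1], 0)
    res$summaries$distance_means <- vapply(
      res$summaries$small_big_distance, function(s) mean(s$samples), 0)
    res$summaries$extension_means <- vapply(trajs, function(tr) {
      ext <- vapply(seq_len(n_frames(tr)), function(k) {
        fr <- frame_coords(tr, k)
        sqrt(sum((colMeans(fr[part$converter, , drop = FALSE]) -
                    colMeans(fr[part$MH, , drop = FALSE]))^2))
      }, 0)
      mean(ext)
    }, 0)
  }

  if (!is.null(config$out_dir)) .write_scenario(res, config)
  res
}

.write_scenario <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$trajectories)) {
    tr <- res$trajectories[[nm]]
    write_trajectory_xyz(tr, file.path(config$out_dir,
                                       paste0(nm, "_traj.xyz")))
    write_provenance(tr, file.path(config$out_dir,
                                   paste0(nm, "_provenance.json")),
                     extra = list(scenario = config$scenario))
  }
  summarise <- function(x) {
    if (inherits(x, "distribution_summary"))
      list(n = length(x$samples), modes = x$modes,
           population_split = x$population_split)
    else if (is.list(x)) lapply(x, summarise) else x
  }
  jsonlite::write_json(lapply(res$summaries, summarise),
                       file.path(config$out_dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
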