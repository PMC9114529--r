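# Ensemble helper shared by the experiment drivers: returns the ns_ensemble
# without the (large) final-state array unless asked.
arm_ensemble <- function(params, layout, settings, rule, keep_final = FALSE) {
  run_ensemble(params, layout, settings, rule, keep_final = keep_final)
}

#' Homogeneous-coating calibration of the line ligand content
#'
#' Simulates the ligand-induction experiment used to calibrate the line
#' contents: cells exposed to a homogeneously coated substrate (every cell
#' on-ligand, i.e. the on-line mask all `TRUE`) for 6 h, for the three arms
#' none/Fc (no ligand), Dll4 and Jag1, across a grid of coating densities.
#' The readout is the Jag1 expression response, operationalized as free
#' Jag1 averaged over cells and replicates at end time — the model quantity
#' up-regulated by NICD — reported raw and as fold-change over the
#' zero-density control to mirror qPCR normalization.
#'
#' @param params [model_parameters()].
#' @param densities Coating densities to simulate (molecules, `>= 0`).
#' @param settings [simulation_settings()]; the default end time for this
#'   experiment is 6 h.
#' @param M Number of cells in the simulated row.
#' @return Data frame with columns `ligand`, `density`, `jag1_mean`,
#'   `jag1_fold_change`; attribute `manifest` carries provenance.
#' @export
calibrate_coating <- function(params = model_parameters(),
                              densities = seq(0, 6000, by = 1500),
                              settings = simulation_settings(t_fin = 6,
                                                             n_replicates = 1000),
                              M = 12) {
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  arms <- c("none", "Dll4", "Jag1")
  rows <- list()
  for (arm in arms) {
    # the uncoated arm never applies ligand, so one density suffices
    for (dens in if (arm == "none") 0 else densities) {
      lay <- pattern_layout(M, on_line = rep(TRUE, M),
                            d_line = if (arm == "Dll4") dens else 0,
                            j_line = if (arm == "Jag1") dens else 0)
      ens <- run_ensemble(params, lay, settings, keep_final = TRUE)
      jmean <- mean(ens$final[3L, , ])   # free Jag1, species column 3
      rows[[length(rows) + 1L]] <-
        data.frame(ligand = arm, density = dens, jag1_mean = jmean)
    }
  }
  out <- do.call(rbind, rows)
  # uncoated control: the "none" arm (identical for every density since it
  # never applies ligand; the shared seed makes it one ensemble repeated)
  ctrl <- out$jag1_mean[out$ligand == "none"][1]
  out$jag1_fold_change <- out$jag1_mean / ctrl
  attr(out, "manifest") <- experiment_manifest("calibrate_coating", params,
                                               settings,
                                               grid = list(densities = densities,
                                                           M = M))
  out
}

#' Ensemble-mean Ef_cs across a ligand-density grid
#'
#' For each density, runs one ensemble with Dll4-only lines and one with
#' Jag1-only lines on the patterned layout (half the cells on lines by
#' default), with common random numbers across all conditions (same master
#' seed, hence shared initial conditions).
#'
#' @param densities Line ligand contents to sweep (molecules).
#' @param params [model_parameters()].
#' @param layout Baseline [pattern_layout()]; its `d_line`/`j_line` are
#'   overwritten per arm.
#' @param settings [simulation_settings()].
#' @return Data frame with columns `ligand`, `density`, `efcs_mean`,
#'   `efcs_median`, `n_undefined`; attribute `manifest`.
#' @export
ligand_density_sweep <- function(densities = seq(0, 6000, by = 500),
                                 params = model_parameters(),
                                 layout = pattern_layout(),
                                 settings = simulation_settings()) {
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  rows <- list()
  for (arm in c("Dll4", "Jag1")) {
    for (dens in densities) {
      lay <- pattern_layout(layout$M, on_line = layout$on_line,
                            d_line = if (arm == "Dll4") dens else 0,
                            j_line = if (arm == "Jag1") dens else 0)
      ens <- arm_ensemble(params, lay, settings, phenotype_rule())
      s <- ens$summary
      rows[[length(rows) + 1L]] <-
        data.frame(ligand = arm, density = dens, efcs_mean = s$efcs_mean,
                   efcs_median = s$efcs_median,
                   n_undefined = s$n_undefined)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- experiment_manifest("ligand_density_sweep",
                                               params, settings,
                                               grid = list(densities = densities,
                                                           M = layout$M))
  out
}

#' Ensemble-mean Ef_cs across an end-time grid
#'
#' Sweeps the simulation end time (default 6-24 h) for Dll4-only and
#' Jag1-only lines at a fixed line density. A single integration per
#' replicate to the largest end time provides every earlier end time as a
#' checkpoint, so the grid shares initial conditions and trajectories
#' exactly (common random numbers by construction).
#'
#' @param t_grid End times in hours, each a multiple of `settings$dt`.
#' @param density Line ligand content (molecules).
#' @param params,layout,settings As in [ligand_density_sweep()].
#' @return Data frame with columns `ligand`, `t_fin`, `efcs_mean`,
#'   `efcs_median`, `n_undefined`; attribute `manifest`.
#' @export
time_sweep <- function(t_grid = seq(6, 24, by = 3), density = 3000,
                       params = model_parameters(),
                       layout = pattern_layout(),
                       settings = simulation_settings()) {
  if (any(t_grid < 0) || any(t_grid > 24))
    stop("t_grid must lie within [0, 24] h", call. = FALSE)
  t_grid <- sort(t_grid)
  steps <- as.integer(round(t_grid / settings$dt))
  if (any(abs(steps * settings$dt - t_grid) > 1e-8))
    stop("every end time must be a multiple of dt", call. = FALSE)
  rows <- list()
  for (arm in c("Dll4", "Jag1")) {
    lay <- pattern_layout(layout$M, on_line = layout$on_line,
                          d_line = if (arm == "Dll4") density else 0,
                          j_line = if (arm == "Jag1") density else 0)
    set.seed(settings$seed)
    init <- sample_initial_state(lay$M, settings$n_replicates,
                                 settings$ic_bounds)
    res <- euler_ensemble(init, params, lay, settings$dt, max(steps),
                          checkpoint_steps = steps)
    for (k in seq_along(t_grid)) {
      v_final <- t(res$v_checkpoints[, , k])
      eff <- efcs_vector(v_final, lay$on_line)
      rows[[length(rows) + 1L]] <-
        data.frame(ligand = arm, t_fin = t_grid[k],
                   efcs_mean = mean(eff, na.rm = TRUE),
                   efcs_median = stats::median(eff, na.rm = TRUE),
                   n_undefined = sum(is.na(eff)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- experiment_manifest("time_sweep", params,
                                               settings,
                                               grid = list(t_grid = t_grid,
                                                           density = density,
                                                           M = layout$M))
  out
}

#' Ensemble-mean Ef_cs across an on-line cell-count grid
#'
#' Varies how many of the `M` cells sit on the patterned lines, keeping the
#' two-edge-block geometry (as symmetric as possible), at a fixed line
#' density, for both ligand arms with common random numbers. Because Ef_cs
#' is undefined when no tip/hybrid cell exists, the undefined-replicate
#' count is reported alongside the mean over defined replicates.
#'
#' @param counts On-line cell counts in `0..M`.
#' @param density Line ligand content (molecules).
#' @param params,settings As in [ligand_density_sweep()].
#' @param M Row size.
#' @return Data frame with columns `ligand`, `n_on`, `efcs_mean`,
#'   `efcs_median`, `n_undefined`, `frac_undefined`; attribute `manifest`.
#' @export
cell_count_sweep <- function(counts = 0:12, density = 3000,
                             params = model_parameters(),
                             settings = simulation_settings(), M = 12) {
  if (any(counts < 0) || any(counts > M))
    stop("counts must lie in 0..M", call. = FALSE)
  rows <- list()
  for (arm in c("Dll4", "Jag1")) {
    for (cnt in counts) {
      lay <- pattern_layout(M, n_on = cnt,
                            d_line = if (arm == "Dll4") density else 0,
                            j_line = if (arm == "Jag1") density else 0)
      ens <- arm_ensemble(params, lay, settings, phenotype_rule())
      s <- ens$summary
      rows[[length(rows) + 1L]] <-
        data.frame(ligand = arm, n_on = cnt, efcs_mean = s$efcs_mean,
                   efcs_median = s$efcs_median,
                   n_undefined = s$n_undefined,
                   frac_undefined = s$n_undefined / s$n_replicates)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- experiment_manifest("cell_count_sweep", params,
                                               settings,
                                               grid = list(counts = counts,
                                                           density = density,
                                                           M = M))
  out
}

#' One-at-a-time parameter sensitivity of mean Ef_cs
#'
#' Perturbs every kinetic/Hill parameter of the signaling model one at a
#' time by a multiplicative factor `1 + perturbation` and `1 - perturbation`
#' (default +/-10 percent), reruns the ensemble with common random numbers,
#' and reports the change of the ensemble-mean Ef_cs. The reference effect
#' is the ligand-type switch: rerunning the baseline with the line ligand
#' swapped (Dll4 to Jag1 or vice versa) at the same density.
#'
#' @param params [model_parameters()].
#' @param layout Patterned [pattern_layout()] with exactly one nonzero line
#'   ligand.
#' @param settings [simulation_settings()].
#' @param perturbation Relative perturbation (default 0.1).
#' @return An object of class `ns_sensitivity`: list with `table` (one row
#'   per parameter: baseline mean, means and deltas at the two
#'   perturbations, max absolute delta) and `ligand_switch_delta`.
#' @export
sensitivity_analysis <- function(params = model_parameters(),
                                 layout = pattern_layout(12, d_line = 3000),
                                 settings = simulation_settings(n_replicates = 1000),
                                 perturbation = 0.1) {
  if (perturbation <= 0)
    stop("perturbation must be positive", call. = FALSE)
  base <- arm_ensemble(params, layout, settings, phenotype_rule())
  base_mean <- base$summary$efcs_mean
  rows <- list()
  for (nm in .ns_param_names) {
    means <- vapply(c(1 + perturbation, 1 - perturbation), function(f) {
      p2 <- unclass(params)
      p2[[nm]] <- p2[[nm]] * f
      p2 <- structure(p2, class = "ns_params")
      if (p2[[nm]] <= 0 && nm %in% .ns_positive_params)
        return(NA_real_)
      validate_parameters(p2)
      arm_ensemble(p2, layout, settings,
                   phenotype_rule())$summary$efcs_mean
    }, numeric(1))
    rows[[nm]] <- data.frame(parameter = nm, baseline_mean = base_mean,
                             mean_up = means[1], mean_down = means[2],
                             delta_up = means[1] - base_mean,
                             delta_down = means[2] - base_mean)
  }
  tab <- do.call(rbind, rows)
  tab$max_abs_delta <- pmax(abs(tab$delta_up), abs(tab$delta_down),
                            na.rm = TRUE)
  switched <- pattern_layout(layout$M, on_line = layout$on_line,
                             d_line = layout$j_line,
                             j_line = layout$d_line)
  sw <- arm_ensemble(params, switched, settings, phenotype_rule())
  structure(list(table = tab,
                 ligand_switch_delta = sw$summary$efcs_mean - base_mean,
                 baseline_mean = base_mean,
                 perturbation = perturbation,
                 manifest = experiment_manifest("sensitivity_analysis",
                                                params, settings,
                                                grid = list(perturbation = perturbation))),
            class = "ns_sensitivity")
}

#' @export
print.ns_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity of mean Ef_cs (baseline %.1f%%, +/-%.0f%% perturbations)\n",
              x$baseline_mean, 100 * x$perturbation))
  cat(sprintf("  ligand-type switch delta: %+.1f percentage points\n",
              x$ligand_switch_delta))
  top <- x$table[order(-x$table$max_abs_delta), ][1:5, ]
  cat("  largest single-parameter effects:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s max |delta| = %.2f\n", top$parameter[i],
                top$max_abs_delta[i]))
  invisible(x)
}

# provenance block attached to every experiment table
experiment_manifest <- function(experiment, params, settings, grid) {
  list(experiment = experiment,
       package_version = as.character(utils::packageVersion("notchsprout")),
       params_hash = param_hash(params),
       seed = settings$seed,
       dt = settings$dt, t_fin = settings$t_fin,
       n_replicates = settings$n_replicates,
       grid = grid,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
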