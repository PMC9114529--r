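#' Run a seeded Monte-Carlo ensemble of row simulations
#'
#' Draws `settings$n_replicates` independent random initial rows (uniform
#' inside the initial-condition box, see [sample_initial_state()]) from the
#' master seed, integrates each with the explicit Euler scheme (compiled
#' kernel), classifies the final phenotypes and computes the per-replicate
#' efficiency of controlled sprouting. All initial conditions are drawn
#' up-front in a documented order, so results do not depend on replicate
#' execution order, and two arms run with the same master seed share
#' initial conditions (common random numbers).
#'
#' @param params [model_parameters()].
#' @param layout [pattern_layout()].
#' @param settings [simulation_settings()].
#' @param rule [phenotype_rule()].
#' @param keep_final Keep the full `6 x M x n_replicates` array of final
#'   states (default `TRUE`; disable for large sweeps).
#' @return An object of class `ns_ensemble`: list with
#'   \describe{
#'     \item{efcs}{numeric vector of per-replicate Ef_cs (percent; `NA`
#'       where undefined).}
#'     \item{phenotypes}{`n_replicates x M` matrix of phenotype labels.}
#'     \item{summary}{list with mean/median/quartiles/10th/90th percentiles
#'       of Ef_cs over defined replicates, the number of undefined
#'       replicates, and phenotype fractions on and off the lines.}
#'     \item{final}{final-state array (if `keep_final`).}
#'     \item{layout, settings, params_hash, seed}{provenance.}
#'   }
#' @examples
#' ens <- run_ensemble(model_parameters(),
#'                     pattern_layout(12, d_line = 3000),
#'                     simulation_settings(n_replicates = 50, seed = 7))
#' ens$summary$efcs_mean
#' @export
run_ensemble <- function(params, layout, settings = simulation_settings(),
                         rule = phenotype_rule(), keep_final = TRUE) {
  stopifnot(inherits(params, "ns_params"), inherits(layout, "ns_layout"),
            inherits(settings, "ns_settings"))
  set.seed(settings$seed)
  init <- sample_initial_state(layout$M, settings$n_replicates,
                               settings$ic_bounds)
  if (length(dim(init)) != 3L) init <- array(t(init), c(6L, layout$M, 1L))
  res <- euler_ensemble(init, params, layout, settings$dt, settings$n_steps)
  ens <- summarize_ensemble(res$final, layout, settings, params, rule,
                            keep_final)
  ens
}

# Shared post-processing: final (6 x M x nrep) -> ns_ensemble
summarize_ensemble <- function(final, layout, settings, params, rule,
                               keep_final = TRUE) {
  nrep <- dim(final)[3]
  v_final <- t(final[6L, , , drop = TRUE])          # nrep x M
  if (nrep == 1L) v_final <- matrix(v_final, 1L)
  eff <- efcs_vector(v_final, layout$on_line, rule)
  ph <- matrix(as.character(classify_phenotype(as.vector(v_final), rule)),
               nrep, layout$M)
  on <- layout$on_line
  frac <- function(m) {
    tab <- table(factor(m, levels = .ns_phenotypes))
    as.numeric(tab) / length(m)
  }
  summary <- list(
    efcs_mean = mean(eff, na.rm = TRUE),
    efcs_median = stats::median(eff, na.rm = TRUE),
    efcs_quartiles = stats::quantile(eff, c(0.25, 0.75), na.rm = TRUE,
                                     names = FALSE),
    efcs_p10_p90 = stats::quantile(eff, c(0.10, 0.90), na.rm = TRUE,
                                   names = FALSE),
    n_undefined = sum(is.na(eff)),
    n_replicates = nrep,
    phenotype_fraction_on = stats::setNames(frac(ph[, on, drop = FALSE]),
                                            .ns_phenotypes),
    phenotype_fraction_off = stats::setNames(frac(ph[, !on, drop = FALSE]),
                                             .ns_phenotypes))
  structure(list(efcs = eff, phenotypes = ph, summary = summary,
                 final = if (keep_final) final else NULL,
                 layout = layout, settings = settings,
                 params_hash = param_hash(params), seed = settings$seed),
            class = "ns_ensemble")
}

# vectorized Ef_cs over an nrep x M matrix of final activated VEGFR
efcs_vector <- function(v_final, on_line, rule = phenotype_rule()) {
  sprouting <- v_final >= rule$stalk_upper   # tip + hybrid
  c_on <- rowSums(sprouting[, on_line, drop = FALSE])
  c_off <- rowSums(sprouting[, !on_line, drop = FALSE])
  tot <- c_on + c_off
  ifelse(tot > 0, 100 * c_off / tot, NA_real_)
}

#' @export
print.ns_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Ensemble: %d replicates, M = %d (%d on lines), D_line = %g, J_line = %g\n",
              s$n_replicates, x$layout$M, sum(x$layout$on_line),
              x$layout$d_line, x$layout$j_line))
  cat(sprintf("  Ef_cs: mean %.1f%%, median %.1f%%, IQR [%.1f, %.1f], P10-P90 [%.1f, %.1f]\n",
              s$efcs_mean, s$efcs_median, s$efcs_quartiles[1],
              s$efcs_quartiles[2], s$efcs_p10_p90[1], s$efcs_p10_p90[2]))
  if (s$n_undefined > 0)
    cat(sprintf("  undefined Ef_cs in %d replicate(s) (excluded)\n",
                s$n_undefined))
  cat("  phenotype fractions on lines:  ",
      paste(sprintf("%s %.2f", .ns_phenotypes, s$phenotype_fraction_on),
            collapse = ", "), "\n", sep = "")
  cat("  phenotype fractions off lines: ",
      paste(sprintf("%s %.2f", .ns_phenotypes, s$phenotype_fraction_off),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
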