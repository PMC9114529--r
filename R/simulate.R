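#' Settings for Euler integration and Monte-Carlo ensembles
#'
#' @param dt Euler time step in hours (default 0.01).
#' @param t_fin End time in hours (default 12); must be a multiple of `dt`
#'   within tolerance.
#' @param n_replicates Ensemble size (default 10000).
#' @param seed Master RNG seed (integer). All randomness of an ensemble
#'   flows from this seed.
#' @param ic_bounds Named numeric vector of upper bounds of the random
#'   initial-condition box, one entry per species in the order
#'   `N, D, J, I, VR, V`. Default: 6000 molecules for the free species
#'   `N, D, J, VR` and 600 molecules for `I` and `V`.
#' @param record_every Trajectory recording interval in hours for
#'   [integrate_row()] (default 1); the final state is always recorded.
#' @return An object of class `ns_settings`.
#' @export
simulation_settings <- function(dt = 0.01, t_fin = 12, n_replicates = 10000,
                                seed = 1L, ic_bounds = .ns_ic_bounds,
                                record_every = 1) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (!is.numeric(t_fin) || length(t_fin) != 1L || t_fin < 0)
    stop("t_fin must be a single nonnegative number", call. = FALSE)
  n_steps <- round(t_fin / dt)
  if (abs(n_steps * dt - t_fin) > 1e-8 * max(1, t_fin))
    stop("t_fin must be an integer multiple of dt", call. = FALSE)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates))
    stop("n_replicates must be a positive integer", call. = FALSE)
  if (!is.numeric(ic_bounds) || length(ic_bounds) != 6L ||
      any(ic_bounds <= 0))
    stop("ic_bounds must be 6 positive numbers (N, D, J, I, VR, V)",
         call. = FALSE)
  if (!is.null(names(ic_bounds)) && setequal(names(ic_bounds), .ns_species))
    ic_bounds <- ic_bounds[.ns_species]
  ic_bounds <- stats::setNames(as.numeric(ic_bounds), .ns_species)
  structure(list(dt = dt, t_fin = t_fin, n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), ic_bounds = ic_bounds,
                 record_every = record_every),
            class = "ns_settings")
}

#' @export
print.ns_settings <- function(x, ...) {
  cat(sprintf(paste0("Simulation settings: dt = %g h, t_fin = %g h ",
                     "(%d steps), %d replicates, seed = %d\n"),
              x$dt, x$t_fin, x$n_steps, x$n_replicates, x$seed))
  invisible(x)
}

#' Draw random initial protein contents for a row of cells
#'
#' Each of the six species of each cell is drawn independently and
#' uniformly, strictly inside `(0, upper bound)`. Draw order is fixed and
#' documented for reproducibility: replicates outermost, then cells in
#' index order, then species in the order `N, D, J, I, VR, V` within each
#' cell. The caller controls the RNG via `set.seed()`; ensemble drivers do
#' this with the master seed.
#'
#' @param M Number of cells.
#' @param n_replicates Number of independent rows to draw.
#' @param ic_bounds Upper bounds per species (see
#'   [simulation_settings()]).
#' @return For `n_replicates = 1`, an `ns_state` matrix; otherwise a
#'   `6 x M x n_replicates` array (species x cell x replicate).
#' @export
sample_initial_state <- function(M, n_replicates = 1,
                                 ic_bounds = .ns_ic_bounds) {
  ic_bounds <- stats::setNames(as.numeric(ic_bounds), .ns_species)
  if (any(ic_bounds <= 0)) stop("ic_bounds must be positive", call. = FALSE)
  u <- stats::runif(6L * M * n_replicates)
  a <- array(u * ic_bounds, dim = c(6L, M, n_replicates))
  if (n_replicates == 1L) row_state(t(a[, , 1L])) else a
}

#' Integrate one row with the explicit Euler scheme
#'
#' Applies the forward-Euler update `state <- state + dt * row_rhs(state)`
#' for exactly `round(t_fin / dt)` steps, computing all derivatives
#' synchronously from the current full row state. Any species turning
#' negative or non-finite aborts with a diagnostic naming the step and
#' species: with the default parameters and `dt = 0.01` h the scheme is
#' stable, so such an event signals a misconfigured parameter set or step
#' size rather than something to clamp silently.
#'
#' @param initial Initial row state (see [row_state()],
#'   [sample_initial_state()]).
#' @param params [model_parameters()].
#' @param layout [pattern_layout()].
#' @param settings [simulation_settings()]; `n_replicates` is ignored here.
#' @param record Record the trajectory every `settings$record_every` hours
#'   (`TRUE`, default) or keep only the final state (`FALSE`).
#' @return An object of class `ns_trajectory`: list with `time` (hours),
#'   `states` (list of row states at the recorded times) and `final`.
#' @examples
#' set.seed(1)
#' tr <- integrate_row(sample_initial_state(4), model_parameters(),
#'                     pattern_layout(4), simulation_settings(t_fin = 1))
#' tr$final[, "V"]
#' @export
integrate_row <- function(initial, params, layout,
                          settings = simulation_settings(), record = TRUE) {
  state <- unclass(as.matrix(initial))
  M <- nrow(state)
  if (layout$M != M)
    stop("layout has M = ", layout$M, " but state has ", M, " cells",
         call. = FALSE)
  dt <- settings$dt
  n_steps <- settings$n_steps
  rec_steps <- if (record) {
    max(1L, as.integer(round(settings$record_every / dt)))
  } else n_steps + 1L
  times <- 0
  states <- list(row_state(state))
  for (s in seq_len(n_steps)) {
    state <- state + dt * row_rhs(state, params, layout)
    if (anyNA(state) || any(!is.finite(state)) || any(state < 0)) {
      bad <- which(is.na(state) | !is.finite(state) | state < 0,
                   arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("integration failure at step %d (t = %g h): ",
                          "species %s of cell %d became %s"),
                   s, s * dt, .ns_species[bad[2]], bad[1],
                   format(state[bad[1], bad[2]])),
           call. = FALSE)
    }
    if (s %% rec_steps == 0L || s == n_steps) {
      times <- c(times, s * dt)
      states[[length(states) + 1L]] <- row_state(state)
    }
  }
  if (n_steps == 0L) times <- 0  # final == initial
  structure(list(time = times, states = states,
                 final = states[[length(states)]]),
            class = "ns_trajectory")
}

#' @export
print.ns_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d cells, %d recorded times in [0, %g] h\n",
              nrow(x$final), length(x$time), max(x$time)))
  invisible(x)
}

# Integrate an ensemble with the compiled Euler kernel.
# init: 6 x M x nrep array; returns list(final = 6 x M x nrep array,
# v_checkpoints = M x nrep x n_checkpoint matrix of activated VEGFR).
euler_ensemble <- function(init, params, layout, dt, n_steps,
                           checkpoint_steps = integer(0)) {
  stopifnot(length(dim(init)) == 3L, dim(init)[1] == 6L,
            dim(init)[2] == layout$M)
  res <- euler_ensemble_cpp(init, params_vector(params),
                            as.integer(layout$on_line),
                            layout$d_line, layout$j_line,
                            dt, as.integer(n_steps),
                            as.integer(checkpoint_steps))
  res
}
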