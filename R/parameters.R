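#' Kinetic and regulatory parameters of the VEGF-Notch signaling network
#'
#' Builds the full parameter set for the per-cell signaling model: production
#' rates of Notch1, Dll4, Jag1 and VEGFR; degradation rates of free species
#' (`gamma`) and of activated species, i.e. NICD and activated VEGFR
#' (`gamma_S`); cis-inhibition (`k_C`) and trans-activation (`k_T`) rates;
#' the external VEGF content; and the shifted-Hill thresholds, exponents and
#' fold-changes that encode the regulatory logic:
#' NICD up-regulates Notch1 and Jag1, down-regulates Dll4 and VEGFR;
#' activated VEGFR up-regulates Dll4; Fringe (driven by NICD) strengthens
#' Dll4-Notch1 binding (`lambda_F_D > 1`) and weakens Jag1-Notch1 binding
#' (`lambda_F_J < 1`).
#'
#' The defaults follow the published Notch-Delta-Jagged-VEGF tip/stalk model
#' family; the full provenance of every value is annotated in the shipped
#' configuration file `system.file("extdata", "default_params.yaml",
#' package = "notchsprout")`, which encodes the same defaults.
#'
#' @param N0,D0,J0,VR0 Production rates of Notch1, Dll4, Jag1 and VEGFR
#'   (molecules/hour).
#' @param gamma Degradation rate of ligands and inactive receptors (1/hour).
#' @param gamma_S Degradation rate of NICD and activated VEGFR (1/hour).
#' @param k_C Cis-inhibition rate (1/(molecule x hour)).
#' @param k_T Trans-activation rate; also the VEGFR activation rate by
#'   external VEGF (1/(molecule x hour)).
#' @param V_ext External VEGF content (molecules), held constant.
#' @param I0 Hill threshold for all NICD-mediated regulation (molecules).
#' @param V0 Hill threshold for activated-VEGFR-mediated regulation of Dll4
#'   (molecules).
#' @param n_N,n_D,n_J,n_F,n_VR Hill exponents (dimensionless).
#' @param lambda_I_N,lambda_I_D,lambda_I_J,lambda_I_VR Fold-changes of the
#'   NICD-mediated regulation of Notch1, Dll4, Jag1 and VEGFR production.
#' @param lambda_V_D Fold-change of the activated-VEGFR-mediated regulation
#'   of Dll4 production.
#' @param lambda_F_D,lambda_F_J Fringe-mediated fold-changes of the
#'   Dll4-Notch1 and Jag1-Notch1 binding rates.
#' @return An object of class `ns_params`: a validated named list.
#' @examples
#' p <- model_parameters()
#' p$k_T
#' p2 <- model_parameters(V_ext = 10000)
#' @export
model_parameters <- function(N0 = 1200, D0 = 400, J0 = 800, VR0 = 200,
                             gamma = 0.1, gamma_S = 0.5,
                             k_C = 5e-4, k_T = 2.5e-5,
                             V_ext = 20000,
                             I0 = 200, V0 = 150,
                             n_N = 2, n_D = 2, n_J = 5, n_F = 2, n_VR = 2,
                             lambda_I_N = 2, lambda_I_D = 0,
                             lambda_I_J = 2, lambda_I_VR = 0,
                             lambda_V_D = 2,
                             lambda_F_D = 3, lambda_F_J = 0.1) {
  p <- list(N0 = N0, D0 = D0, J0 = J0, VR0 = VR0,
            gamma = gamma, gamma_S = gamma_S,
            k_C = k_C, k_T = k_T, V_ext = V_ext,
            I0 = I0, V0 = V0,
            n_N = n_N, n_D = n_D, n_J = n_J, n_F = n_F, n_VR = n_VR,
            lambda_I_N = lambda_I_N, lambda_I_D = lambda_I_D,
            lambda_I_J = lambda_I_J, lambda_I_VR = lambda_I_VR,
            lambda_V_D = lambda_V_D,
            lambda_F_D = lambda_F_D, lambda_F_J = lambda_F_J)
  validate_parameters(p)
  structure(p, class = "ns_params")
}

# names of strictly positive entries (rates, thresholds, exponents)
.ns_positive_params <- c("N0", "D0", "J0", "VR0", "gamma", "gamma_S",
                         "k_C", "k_T", "V_ext", "I0", "V0",
                         "n_N", "n_D", "n_J", "n_F", "n_VR")
.ns_lambda_params <- c("lambda_I_N", "lambda_I_D", "lambda_I_J",
                       "lambda_I_VR", "lambda_V_D",
                       "lambda_F_D", "lambda_F_J")
.ns_param_names <- c(.ns_positive_params, .ns_lambda_params)

validate_parameters <- function(p) {
  missing <- setdiff(.ns_param_names, names(p))
  if (length(missing))
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(p), .ns_param_names)
  if (length(unknown))
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in .ns_param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  bad <- .ns_positive_params[vapply(.ns_positive_params,
                                    function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  badl <- .ns_lambda_params[vapply(.ns_lambda_params,
                                   function(nm) p[[nm]] < 0, logical(1))]
  if (length(badl))
    stop("fold-change parameter(s) must be >= 0: ",
         paste(badl, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' @export
print.ns_params <- function(x, ...) {
  cat("VEGF-Notch signaling parameters (ns_params)\n")
  cat(sprintf("  production (molec/h): N0=%g D0=%g J0=%g VR0=%g\n",
              x$N0, x$D0, x$J0, x$VR0))
  cat(sprintf("  degradation (1/h): gamma=%g gamma_S=%g\n",
              x$gamma, x$gamma_S))
  cat(sprintf("  binding (1/(molec.h)): k_C=%g k_T=%g; V_ext=%g molec\n",
              x$k_C, x$k_T, x$V_ext))
  cat(sprintf("  Hill: I0=%g V0=%g; n = (N %g, D %g, J %g, F %g, VR %g)\n",
              x$I0, x$V0, x$n_N, x$n_D, x$n_J, x$n_F, x$n_VR))
  cat(sprintf(paste0("  folds: I->N %g, I->D %g, I->J %g, I->VR %g, ",
                     "V->D %g, F->D %g, F->J %g\n"),
              x$lambda_I_N, x$lambda_I_D, x$lambda_I_J, x$lambda_I_VR,
              x$lambda_V_D, x$lambda_F_D, x$lambda_F_J))
  invisible(x)
}

# fixed ordering used by the compiled integrator
params_vector <- function(p) {
  vapply(.ns_param_names, function(nm) as.numeric(p[[nm]]), numeric(1))
}

#' Stable hash of a parameter set (or any R object)
#'
#' Used in run manifests so that outputs carry the provenance needed to
#' regenerate them.
#'
#' @param x An R object, typically `ns_params`.
#' @return A character scalar.
#' @export
param_hash <- function(x) {
  rlang::hash(unclass(x))
}
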