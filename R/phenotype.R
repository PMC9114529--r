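#' Phenotype thresholds on final activated VEGFR
#'
#' Cells are phenotyped from their activated-VEGFR content at the end of the
#' simulation: stalk below `stalk_upper`, hybrid tip/stalk in
#' `[stalk_upper, hybrid_upper]` (both boundaries hybrid), tip above
#' `hybrid_upper`. A final value of exactly 0 is classified stalk.
#'
#' @param stalk_upper Upper bound of the stalk interval (molecules,
#'   default 100).
#' @param hybrid_upper Upper bound of the hybrid interval (molecules,
#'   default 300).
#' @return An object of class `ns_rule`.
#' @export
phenotype_rule <- function(stalk_upper = 100, hybrid_upper = 300) {
  if (!is.numeric(stalk_upper) || !is.numeric(hybrid_upper) ||
      length(stalk_upper) != 1L || length(hybrid_upper) != 1L ||
      stalk_upper <= 0 || hybrid_upper <= stalk_upper)
    stop("need 0 < stalk_upper < hybrid_upper", call. = FALSE)
  structure(list(stalk_upper = stalk_upper, hybrid_upper = hybrid_upper),
            class = "ns_rule")
}

.ns_phenotypes <- c("stalk", "hybrid", "tip")

#' Classify final activated-VEGFR values into phenotypes
#'
#' @param V_final Nonnegative numeric vector of activated-VEGFR contents at
#'   end time (molecules).
#' @param rule A [phenotype_rule()].
#' @return Factor with levels `stalk`, `hybrid`, `tip`.
#' @examples
#' classify_phenotype(c(50, 100, 300, 400))
#' @export
classify_phenotype <- function(V_final, rule = phenotype_rule()) {
  if (!is.numeric(V_final) || anyNA(V_final))
    stop("V_final must be numeric without NAs", call. = FALSE)
  if (any(V_final < 0))
    stop("V_final must be nonnegative", call. = FALSE)
  lab <- ifelse(V_final < rule$stalk_upper, "stalk",
                ifelse(V_final <= rule$hybrid_upper, "hybrid", "tip"))
  factor(lab, levels = .ns_phenotypes)
}

#' Efficiency of controlled sprouting from on/off-pattern counts
#'
#' `Ef_cs = 100 * C_off / (C_off + C_on)` percent, where `C_off` counts
#' sprouting (tip + hybrid) cells between the lines and `C_on` those on the
#' lines. When both counts are zero the statistic is undefined and returned
#' as `NA` (never coerced to 0 or 100); ensemble summaries exclude and
#' count such replicates.
#'
#' @param c_off,c_on Nonnegative integer counts.
#' @return An object of class `ns_efcs`: list with `value` (percent, or
#'   `NA` if undefined), `c_off`, `c_on`.
#' @examples
#' efcs_from_counts(10, 10)$value  # 50
#' @export
efcs_from_counts <- function(c_off, c_on) {
  for (v in list(c_off, c_on))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop("counts must be single nonnegative integers", call. = FALSE)
  value <- if (c_off + c_on > 0) 100 * c_off / (c_off + c_on) else NA_real_
  structure(list(value = value, c_off = as.integer(c_off),
                 c_on = as.integer(c_on)),
            class = "ns_efcs")
}

#' @export
print.ns_efcs <- function(x, ...) {
  cat(sprintf("Ef_cs = %s%% (C_off = %d, C_on = %d)\n",
              if (is.na(x$value)) "undefined" else format(x$value),
              x$c_off, x$c_on))
  invisible(x)
}

#' Efficiency of controlled sprouting from a simulated final state
#'
#' Classifies every cell of the final row state, counts tip and hybrid
#' cells on and off the patterned lines (stalk cells are excluded from both
#' counts) and applies [efcs_from_counts()].
#'
#' @param final Final row state (`M x 6` matrix).
#' @param layout The [pattern_layout()] used for the simulation.
#' @param rule A [phenotype_rule()].
#' @return An `ns_efcs` object.
#' @export
efcs_from_simulation <- function(final, layout, rule = phenotype_rule()) {
  final <- as.matrix(final)
  if (nrow(final) != layout$M)
    stop("layout has M = ", layout$M, " but state has ", nrow(final),
         " cells", call. = FALSE)
  ph <- classify_phenotype(final[, "V"], rule)
  sprouting <- ph != "stalk"
  efcs_from_counts(sum(sprouting & !layout$on_line),
                   sum(sprouting & layout$on_line))
}

#' Efficiency of controlled sprouting from a nuclei point pattern
#'
#' The imaging-analog of the statistic: each nucleus centroid is assigned
#' on-stripe or off-stripe from its coordinate along the stripe-normal axis
#' modulo the pattern pitch (see [point_on_stripe()]), and the on/off
#' counts feed [efcs_from_counts()]. With the default geometry (stripe
#' width = gap width) the two regions have equal area, as the statistic
#' requires.
#'
#' @param pattern A [point_pattern()] (or the result of
#'   [generate_point_pattern()] / [read_point_pattern()]).
#' @return An `ns_efcs` object.
#' @export
efcs_from_points <- function(pattern) {
  stopifnot(inherits(pattern, "ns_points"))
  on <- point_on_stripe(pattern$centroids$x_um, pattern$geometry)
  efcs_from_counts(sum(!on), sum(on))
}
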