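#' Stripe geometry of a micropatterned substrate
#'
#' Printed ligand lines of width `stripe_width` separated by gaps of width
#' `gap_width`, repeating along the x axis (the stripe-normal axis) with
#' pitch `stripe_width + gap_width`. `phase` shifts the left edge of the
#' first stripe. The default 100 um lines with 100 um spacing make the
#' on-stripe and off-stripe regions of any whole number of pitches equal in
#' area, which the efficiency-of-controlled-sprouting statistic assumes.
#'
#' @param stripe_width,gap_width Stripe and gap widths in um (positive).
#' @param phase Offset of the first stripe edge in um.
#' @param roi_width,roi_height Extent of the region of interest in um.
#' @return An object of class `ns_geometry`.
#' @export
stripe_geometry <- function(stripe_width = 100, gap_width = 100, phase = 0,
                            roi_width = 800, roi_height = 800) {
  if (stripe_width <= 0 || gap_width <= 0)
    stop("stripe_width and gap_width must be positive", call. = FALSE)
  if (roi_width <= 0 || roi_height <= 0)
    stop("ROI extent must be positive", call. = FALSE)
  structure(list(stripe_width = stripe_width, gap_width = gap_width,
                 pitch = stripe_width + gap_width, phase = phase,
                 roi_width = roi_width, roi_height = roi_height),
            class = "ns_geometry")
}

#' Assign points to stripes or gaps
#'
#' A coordinate is on-stripe when its position along the stripe-normal axis,
#' taken modulo the pitch relative to the phase, falls inside the stripe.
#' Stripes are closed and gaps half-open: a point exactly on a stripe edge
#' counts as on-line, a fixed tie-break that keeps counts reproducible.
#'
#' @param x Numeric vector of stripe-normal coordinates (um).
#' @param geometry A [stripe_geometry()].
#' @return Logical vector, `TRUE` for on-stripe.
#' @export
point_on_stripe <- function(x, geometry) {
  u <- (x - geometry$phase) %% geometry$pitch
  u <= geometry$stripe_width
}

#' Nuclei point pattern over a stripe geometry
#'
#' @param centroids Data frame with numeric columns `x_um`, `y_um`.
#' @param geometry A [stripe_geometry()]; all centroids must lie inside the
#'   ROI box `[0, roi_width] x [0, roi_height]`.
#' @param label Optional generating-regime label (free-form list, e.g.
#'   `list(mode = "random", strength = 0)`).
#' @return An object of class `ns_points`.
#' @export
point_pattern <- function(centroids, geometry = stripe_geometry(),
                          label = NULL) {
  stopifnot(is.data.frame(centroids),
            all(c("x_um", "y_um") %in% names(centroids)))
  x <- centroids$x_um; y <- centroids$y_um
  bad <- which(x < 0 | x > geometry$roi_width |
                 y < 0 | y > geometry$roi_height)
  if (length(bad))
    stop("centroid(s) outside the ROI bounding box: rows ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  structure(list(centroids = centroids[, c("x_um", "y_um"), drop = FALSE],
                 geometry = geometry, label = label),
            class = "ns_points")
}

#' @export
print.ns_points <- function(x, ...) {
  cat(sprintf("Point pattern: %d centroids, stripes %g um / gaps %g um, ROI %g x %g um\n",
              nrow(x$centroids), x$geometry$stripe_width,
              x$geometry$gap_width, x$geometry$roi_width,
              x$geometry$roi_height))
  if (!is.null(x$label))
    cat(sprintf("  regime: %s (strength %g)\n", x$label$mode,
                x$label$strength %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic nuclei point pattern
#'
#' Emulates the nuclei centroids counted on micropatterned substrates under
#' the three qualitative sprouting regimes, interpolated into a
#' quantitative family by `strength`: each point is first placed uniformly
#' in the ROI, then resampled to the gap (off-stripe) region with
#' probability `0.5 + 0.5 * strength` for negative patterning, to the
#' stripe region with the complementary probability for positive
#' patterning, and left at probability 0.5 for the random regime. Within
#' the chosen region the position is uniform. Points are independent (no
#' clustering).
#'
#' @param mode One of `"random"`, `"positive"`, `"negative"`.
#' @param strength Regime strength in `[0, 1]`; ignored for `"random"`.
#' @param n_points Number of centroids (`>= 0`).
#' @param geometry A [stripe_geometry()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the pattern is reproducible.
#' @return An `ns_points` object.
#' @examples
#' pp <- generate_point_pattern("negative", 1, 100, seed = 1)
#' efcs_from_points(pp)$value   # 100: all points in the gaps
#' @export
generate_point_pattern <- function(mode = c("random", "positive", "negative"),
                                   strength = 0, n_points = 1000,
                                   geometry = stripe_geometry(),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(strength) || length(strength) != 1L || strength < 0 ||
      strength > 1)
    stop("strength must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(n_points) || n_points < 0 || n_points != round(n_points))
    stop("n_points must be a nonnegative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_off <- switch(mode,
                  random = 0.5,
                  negative = 0.5 + 0.5 * strength,
                  positive = 0.5 - 0.5 * strength)
  x <- stats::runif(n_points, 0, geometry$roi_width)
  y <- stats::runif(n_points, 0, geometry$roi_height)
  to_off <- stats::runif(n_points) < p_off
  x <- resample_region(x, to_off, geometry)
  point_pattern(data.frame(x_um = x, y_um = y), geometry,
                label = list(mode = mode, strength = strength,
                             p_off = p_off))
}

# resample each x uniformly within the union of stripe (on) or gap (off)
# intervals clipped to [0, roi_width]; exact even when the ROI cuts a
# stripe or gap.
resample_region <- function(x, to_off, geometry) {
  g <- geometry
  # interval starts covering the ROI with one pitch of margin on the left
  k <- seq(floor((0 - g$phase) / g$pitch) - 1L,
           ceiling((g$roi_width - g$phase) / g$pitch))
  clip <- function(a, b) {
    a <- pmax(a, 0); b <- pmin(b, g$roi_width)
    keep <- b > a
    cbind(a[keep], b[keep])
  }
  stripes <- clip(g$phase + k * g$pitch,
                  g$phase + k * g$pitch + g$stripe_width)
  gaps <- clip(g$phase + k * g$pitch + g$stripe_width,
               g$phase + (k + 1) * g$pitch)
  draw <- function(n, iv) {
    len <- iv[, 2] - iv[, 1]
    pick <- sample.int(nrow(iv), n, replace = TRUE, prob = len)
    iv[pick, 1] + stats::runif(n) * len[pick]
  }
  out <- x
  n_off <- sum(to_off)
  if (n_off > 0) out[to_off] <- draw(n_off, gaps)
  if (n_off < length(x)) out[!to_off] <- draw(length(x) - n_off, stripes)
  out
}

#' Write / read a centroid table as CSV
#'
#' Plain CSV with columns `x_um`, `y_um`; geometry and regime metadata go
#' to a JSON sidecar (same path with extension `.json`) so a pattern
#' round-trips losslessly.
#'
#' @param pattern An `ns_points` object.
#' @param path CSV file path.
#' @return `write_point_pattern()` returns the path invisibly;
#'   `read_point_pattern()` returns an `ns_points` object.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "ns_points"))
  utils::write.csv(pattern$centroids, path, row.names = FALSE)
  meta <- list(geometry = unclass(pattern$geometry), label = pattern$label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  centroids <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  geometry <- stripe_geometry()
  label <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    g <- meta$geometry
    geometry <- stripe_geometry(g$stripe_width, g$gap_width, g$phase,
                                g$roi_width, g$roi_height)
    label <- meta$label
  }
  point_pattern(centroids, geometry, label)
}

#' Write the synthetic fixture suite
#'
#' Generates a deterministic set of small plain-text fixtures: centroid
#' CSVs for the three patterning regimes at several strengths and sizes,
#' the default parameter configuration, a small fixed row state, and a
#' manifest recording every seed used.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the suite.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(out_dir, seed = 20260101L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    list(mode = "random", strength = 0, n = 400),
    list(mode = "negative", strength = 0.4, n = 400),
    list(mode = "negative", strength = 1, n = 200),
    list(mode = "positive", strength = 0.4, n = 400),
    list(mode = "positive", strength = 1, n = 200))
  files <- character(0)
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    sk <- seed + k
    pp <- generate_point_pattern(s$mode, s$strength, s$n, seed = sk)
    f <- file.path(out_dir,
                   sprintf("points_%s_s%02d_n%d.csv", s$mode,
                           round(100 * s$strength), s$n))
    write_point_pattern(pp, f)
    files <- c(files, f)
    specs[[k]]$seed <- sk
    specs[[k]]$file <- basename(f)
  }
  cfgf <- file.path(out_dir, "default_params.yaml")
  save_config(model_parameters(), pattern_layout(),
              simulation_settings(), cfgf)
  set.seed(seed)
  st <- sample_initial_state(4)
  stf <- file.path(out_dir, "row_state_M4.csv")
  utils::write.csv(as.data.frame(unclass(st)), stf, row.names = FALSE)
  manifest <- list(seed = seed, patterns = specs,
                   config = basename(cfgf), row_state = basename(stf))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
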