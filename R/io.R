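#' Load a validated model configuration
#'
#' Reads a JSON or YAML configuration (decided by file extension) with up
#' to three top-level blocks: `parameters`, `layout` and `settings`.
#' Missing blocks and missing keys fall back to package defaults; unknown
#' keys are rejected with an error listing every offender, as are invalid
#' values (e.g. a negative degradation rate).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return List with elements `params` ([model_parameters()]), `layout`
#'   ([pattern_layout()]) and `settings` ([simulation_settings()]).
#' @examples
#' cfg <- load_config(system.file("extdata", "default_params.yaml",
#'                                package = "notchsprout"))
#' cfg$params$k_T
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known_blocks <- c("parameters", "layout", "settings", "metadata")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("unknown top-level config block(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  pkeys <- raw$parameters %||% list()
  bad <- setdiff(names(pkeys), .ns_param_names)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_parameters, pkeys)

  lkeys <- raw$layout %||% list()
  lallow <- c("M", "n_on", "d_line", "j_line", "on_line")
  bad <- setdiff(names(lkeys), lallow)
  if (length(bad))
    stop("unknown layout key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(lkeys$on_line)) lkeys$on_line <- as.logical(lkeys$on_line)
  layout <- do.call(pattern_layout, lkeys)

  skeys <- raw$settings %||% list()
  sallow <- c("dt", "t_fin", "n_replicates", "seed", "ic_bounds",
              "record_every")
  bad <- setdiff(names(skeys), sallow)
  if (length(bad))
    stop("unknown settings key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(skeys$ic_bounds)) skeys$ic_bounds <- unlist(skeys$ic_bounds)
  settings <- do.call(simulation_settings, skeys)

  list(params = params, layout = layout, settings = settings)
}

#' Save a model configuration
#'
#' Writes the three blocks read back by [load_config()]; YAML or JSON is
#' chosen from the file extension. The YAML form carries unit annotations
#' as comments.
#'
#' @param params,layout,settings The objects to serialize.
#' @param path Output path (`.yaml`, `.yml` or `.json`).
#' @return The path, invisibly.
#' @export
save_config <- function(params, layout, settings, path) {
  cfg <- list(
    metadata = list(
      package = "notchsprout",
      version = as.character(utils::packageVersion("notchsprout")),
      units = list(production = "molecules/hour",
                   degradation = "1/hour",
                   binding = "1/(molecule*hour)",
                   contents = "molecules",
                   time = "hours")),
    parameters = unclass(params),
    layout = list(M = layout$M, on_line = layout$on_line,
                  d_line = layout$d_line, j_line = layout$j_line),
    settings = list(dt = settings$dt, t_fin = settings$t_fin,
                    n_replicates = settings$n_replicates,
                    seed = settings$seed,
                    ic_bounds = as.list(settings$ic_bounds),
                    record_every = settings$record_every))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Bundles everything needed to regenerate an output bit-identically:
#' package version, parameter hash, settings echo, master seed, timestamp
#' and output file list.
#'
#' @param params,layout,settings The run inputs.
#' @param outputs Character vector of written files.
#' @return A list; write it with `jsonlite::write_json()`.
#' @export
run_manifest <- function(params, layout, settings, outputs = character(0)) {
  list(tool = "notchsprout",
       version = as.character(utils::packageVersion("notchsprout")),
       params_hash = param_hash(params),
       parameters = unclass(params),
       layout = list(M = layout$M, on_line = layout$on_line,
                     d_line = layout$d_line, j_line = layout$j_line),
       settings = list(dt = settings$dt, t_fin = settings$t_fin,
                       n_replicates = settings$n_replicates,
                       seed = settings$seed,
                       ic_bounds = as.list(settings$ic_bounds)),
       seed = settings$seed,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       outputs = outputs)
}

#' Write ensemble results as tidy CSV plus JSON manifest
#'
#' Writes (a) `efcs.csv`: one row per replicate with its Ef_cs (undefined
#' values as empty/NA fields, never 0 or 100); (b) `phenotypes.csv`: one
#' row per replicate and cell with the phenotype label and on-line flag;
#' (c) `summary.json`: the ensemble summary; (d) `manifest.json`. Re-running
#' the same ensemble with the manifest's seed reproduces the CSVs
#' byte-for-byte.
#'
#' @param ensemble An `ns_ensemble` from [run_ensemble()].
#' @param params The [model_parameters()] used (for the manifest).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_ensemble_results <- function(ensemble, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nrep <- ensemble$summary$n_replicates
  M <- ensemble$layout$M
  f_ef <- file.path(out_dir, "efcs.csv")
  utils::write.csv(data.frame(replicate = seq_len(nrep),
                              efcs = ensemble$efcs),
                   f_ef, row.names = FALSE, na = "NA")
  f_ph <- file.path(out_dir, "phenotypes.csv")
  utils::write.csv(data.frame(replicate = rep(seq_len(nrep), times = M),
                              cell = rep(seq_len(M), each = nrep),
                              on_line = rep(ensemble$layout$on_line,
                                            each = nrep),
                              phenotype = as.vector(ensemble$phenotypes)),
                   f_ph, row.names = FALSE)
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(ensemble$summary, f_sum, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  f_man <- file.path(out_dir, "manifest.json")
  man <- run_manifest(params, ensemble$layout, ensemble$settings,
                      outputs = basename(c(f_ef, f_ph, f_sum)))
  jsonlite::write_json(man, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(efcs = f_ef, phenotypes = f_ph, summary = f_sum,
              manifest = f_man))
}
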