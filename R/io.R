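## Run configuration (YAML) and result serialization.
##
## Config schema (YAML, version 1) — all keys optional except nothing:
##   profile: label of a shipped profile ("child-2yr", default) or an inline
##            mapping with the fields of read_parameters()'s `profile` block
##            plus full parameter blocks (then it is treated as a parameter
##            file body).
##   obstruction: {side: LVOT|RVOT|NONE, narrowing_ratio: (0,1], f_shape: >=1,
##                 D_cm: optional override}
##   solver: {rel_tol, abs_tol, max_beats, periodicity_tol, output_sampling}
##   experiment: {type: baseline|run|sweep|fshape|sensitivity,
##                ratios: [..], fshape_values: [..], fraction: (0,0.5]}
##   output_dir: path

.CONFIG_KEYS <- c("profile", "obstruction", "solver", "experiment",
                  "output_dir")

#' Build a validated run configuration
#'
#' @param profile profile label (see [default_parameters()]) or a
#'   `circulation_params` object.
#' @param side,narrowing_ratio,f_shape,D obstruction description
#'   (see [obstruction_geometry()]; `D = NULL` takes the profile's diameter
#'   for the chosen side).
#' @param solver a [solver_options()].
#' @param experiment experiment selector: `"baseline"`, `"run"`, `"sweep"`,
#'   `"fshape"` or `"sensitivity"`.
#' @param ratios,fshape_values,fraction experiment-specific settings.
#' @param output_dir where [write_outputs()] will put results.
#' @return a `vot_config` list with a fully resolved parameter set in
#'   `$params` and geometry in `$geom`.
#' @export
run_config <- function(profile = "child-2yr", side = "NONE",
                       narrowing_ratio = 1, f_shape = 1, D = NULL,
                       solver = solver_options(),
                       experiment = c("baseline", "run", "sweep", "fshape",
                                      "sensitivity"),
                       ratios = default_ratio_grid(),
                       fshape_values = c(1, 1.5, 2),
                       fraction = 0.1,
                       output_dir = ".") {
  experiment <- match.arg(experiment)
  params <- if (inherits(profile, "circulation_params")) profile else
    default_parameters(profile)
  if (is.null(D))
    D <- switch(side, LVOT = params$profile$D_LVOT,
                RVOT = params$profile$D_RVOT, NONE = params$profile$D_LVOT)
  geom <- obstruction_geometry(side, narrowing_ratio = narrowing_ratio,
                               D = D, f_shape = f_shape)
  stopifnot(inherits(solver, "solver_options"))
  cfg <- list(profile = if (is.character(profile)) profile else
                profile$profile$label,
              params = params, geom = geom, solver = solver,
              experiment = experiment, ratios = ratios,
              fshape_values = fshape_values, fraction = fraction,
              output_dir = output_dir)
  class(cfg) <- "vot_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Applies defaults for absent keys and rejects unknown keys and
#' out-of-range values with field-level messages.  A written config
#' ([save_config()]) loads back to an equivalent configuration.
#'
#' @param path YAML file.
#' @return a `vot_config` (see [run_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.CONFIG_KEYS, collapse = ", "), ")")
  ob <- y$obstruction
  if (!is.null(ob)) {
    bad <- setdiff(names(ob), c("side", "narrowing_ratio", "f_shape", "D_cm"))
    if (length(bad)) stop("unknown obstruction keys: ",
                          paste(bad, collapse = ", "))
    if (!is.null(ob$narrowing_ratio) &&
        (ob$narrowing_ratio <= 0 || ob$narrowing_ratio > 1))
      stop("obstruction.narrowing_ratio must lie in (0, 1], got ",
           ob$narrowing_ratio)
    if (!is.null(ob$f_shape) && ob$f_shape < 1)
      stop("obstruction.f_shape must be >= 1, got ", ob$f_shape)
  }
  sv <- y$solver
  if (!is.null(sv)) {
    bad <- setdiff(names(sv), c("rel_tol", "abs_tol", "max_beats",
                                "periodicity_tol", "output_sampling"))
    if (length(bad)) stop("unknown solver keys: ", paste(bad, collapse = ", "))
  }
  ex <- y$experiment
  if (!is.null(ex)) {
    bad <- setdiff(names(ex), c("type", "ratios", "fshape_values", "fraction"))
    if (length(bad)) stop("unknown experiment keys: ",
                          paste(bad, collapse = ", "))
  }
  solver <- do.call(solver_options, modifyList(
    list(), if (is.null(sv)) list() else sv))
  run_config(profile = if (is.null(y$profile)) "child-2yr" else y$profile,
             side = if (is.null(ob$side)) "NONE" else ob$side,
             narrowing_ratio = if (is.null(ob$narrowing_ratio)) 1 else
               ob$narrowing_ratio,
             f_shape = if (is.null(ob$f_shape)) 1 else ob$f_shape,
             D = ob$D_cm,
             solver = solver,
             experiment = if (is.null(ex$type)) "baseline" else ex$type,
             ratios = if (is.null(ex$ratios)) default_ratio_grid() else
               unlist(ex$ratios),
             fshape_values = if (is.null(ex$fshape_values)) c(1, 1.5, 2) else
               unlist(ex$fshape_values),
             fraction = if (is.null(ex$fraction)) 0.1 else ex$fraction,
             output_dir = if (is.null(y$output_dir)) "." else y$output_dir)
}

#' @rdname load_config
#' @param config a `vot_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "vot_config"))
  yaml::write_yaml(.config_as_list(config), path, precision = 15)
  invisible(path)
}

.config_as_list <- function(config) {
  list(profile = config$profile,
       obstruction = list(side = config$geom$side,
                          narrowing_ratio = config$geom$narrowing_ratio,
                          f_shape = config$geom$f_shape,
                          D_cm = config$geom$D),
       solver = unclass(config$solver),
       experiment = list(type = config$experiment,
                         ratios = config$ratios,
                         fshape_values = config$fshape_values,
                         fraction = config$fraction),
       output_dir = config$output_dir)
}

#' Hash of a configuration
#'
#' MD5 over the canonical YAML serialization; changes iff the configuration
#' changes.
#' @param config a `vot_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write simulation results to disk
#'
#' Serializes whatever the run produced — a `vot_beat` (long-format trace
#' CSV + one-row summary CSV), a `vot_summary`, a `vot_sweep` (wide CSV), or
#' a named list of such objects — together with a JSON manifest recording
#' the configuration hash, package version and file list.  Re-running an
#' identical configuration reproduces byte-identical CSVs.
#'
#' @param results object or named list of objects.
#' @param outdir output directory (created if needed).
#' @param config optional `vot_config` recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
write_outputs <- function(results, outdir, config = NULL) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("cannot create output directory ", outdir)
  if (!is.list(results) || inherits(results, c("vot_beat", "data.frame")))
    results <- list(result = results)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list")
  files <- character(0)
  wr <- function(df, name) {
    fp <- file.path(outdir, name)
    write.csv(df, fp, row.names = FALSE)
    files <<- c(files, name)
  }
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "vot_beat")) {
      wr(as.data.frame(x), paste0(nm, "_beat.csv"))
      wr(summarize_beat(x), paste0(nm, "_summary.csv"))
    } else if (inherits(x, "data.frame")) {
      wr(x, paste0(nm, ".csv"))
    } else stop("cannot serialize result '", nm, "' of class ",
                paste(class(x), collapse = "/"))
  }
  manifest <- list(
    package = "votsim",
    version = as.character(packageVersion("votsim")),
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
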