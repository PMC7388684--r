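#' @title Run configuration
#' @description Resolves a fully-specified, validated run from defaults, an
#'   optional YAML config file, and explicit arguments (precedence:
#'   arguments > file > defaults), and dispatches the scenario runners. The
#'   shell entry point `inst/exec/fructolyse` is a thin wrapper over these
#'   functions.
#' @name config
NULL

.config_defaults <- function() {
  list(
    params = NULL,              # NULL -> packaged default registry
    set = list(),               # named parameter overrides
    scenario = "diet",          # diet | oat | khk | single
    diet = "mixed-100g",        # preset name, or set grams/fru_frac
    grams = NULL,
    fru_frac = NULL,
    horizon_h = 12,
    report_dt_min = 1,
    rtol = 1e-8,
    atol = 1e-10,
    method = "lsoda",
    stoichiometry_mode = "paper-faithful",
    perturb = 0.1,
    inhibit = c(0, 0.5, 0.7, 1),
    out = NULL
  )
}

#' Parse and validate a run configuration
#'
#' @param path Optional YAML config file with any of the documented keys.
#' @param args Named list of explicit settings overriding the file.
#' @return A `run_config` list with every field resolved and validated.
#' @export
parse_config <- function(path = NULL, args = list()) {
  cfg <- .config_defaults()
  merge_in <- function(cfg, vals, src) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown) > 0)
      stop(sprintf("unknown config key(s) in %s: %s", src,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(cfg, vals)
  }
  if (!is.null(path)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc)) doc <- list()
    cfg <- merge_in(cfg, doc, path)
  }
  cfg <- merge_in(cfg, args, "arguments")
  if (!is.null(cfg$grams) && cfg$diet != .config_defaults()$diet &&
      !is.null(args$diet))
    stop("conflicting diet specification: give a preset or grams/fru_frac")
  if (!cfg$scenario %in% c("diet", "oat", "khk", "single"))
    stop("unknown scenario: ", cfg$scenario)
  if (!cfg$stoichiometry_mode %in% c("paper-faithful", "carbon-consistent"))
    stop("unknown stoichiometry_mode: ", cfg$stoichiometry_mode)
  structure(cfg, class = "run_config")
}

resolve_diet <- function(cfg) {
  if (!is.null(cfg$grams)) {
    diet_spec(cfg$grams,
              if (is.null(cfg$fru_frac)) 0.5 else cfg$fru_frac)
  } else {
    presets <- scenario_diets()
    if (!cfg$diet %in% names(presets))
      stop("unknown diet preset: ", cfg$diet, " (have: ",
           paste(names(presets), collapse = ", "), ")")
    presets[[cfg$diet]]
  }
}

#' Execute a resolved run configuration
#'
#' Loads parameters (with overrides), computes the shared baseline, runs the
#' configured scenario, and writes CSV reports when an output directory is
#' set.
#'
#' @param cfg A `run_config` from [parse_config()].
#' @param quiet Suppress the one-line-per-simulation log.
#' @return The scenario result object, invisibly when reports are written.
#' @export
run_scenario <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  params <- load_parameters(
    path = if (is.null(cfg$params)) default_parameter_path() else cfg$params,
    overrides = cfg$set)
  diet <- resolve_diet(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  opts <- list(rtol = cfg$rtol, atol = cfg$atol, method = cfg$method,
               mode = cfg$stoichiometry_mode,
               report_dt_min = cfg$report_dt_min)
  result <- switch(
    cfg$scenario,
    diet = {
      say("scenario diet: 3 arms, %g h horizon", cfg$horizon_h)
      do.call(run_diet_comparison,
              c(list(params = params, horizon_h = cfg$horizon_h), opts))
    },
    oat = {
      say("scenario oat: +/-%g%% over 11 reactions, diet %s",
          100 * cfg$perturb, diet$name)
      do.call(run_oat_sensitivity,
              c(list(params = params, diet = diet,
                     perturbation = cfg$perturb,
                     horizon_h = cfg$horizon_h), opts))
    },
    khk = {
      say("scenario khk: inhibition fractions %s",
          paste(cfg$inhibit, collapse = ", "))
      do.call(run_khk_inhibition,
              c(list(params = params, fractions = cfg$inhibit,
                     horizon_h = cfg$horizon_h), opts))
    },
    single = {
      say("single run: diet %s, %g h", diet$name, cfg$horizon_h)
      baseline <- do.call(run_to_baseline,
                          c(list(params = params, diet = diet), opts))
      do.call(run_simulation,
              c(list(initial = baseline, params = params, diet = diet,
                     horizon_h = cfg$horizon_h, fluxes = TRUE), opts))
    })
  if (!is.null(cfg$out)) {
    files <- write_report(result, cfg$out)
    say("wrote %d file(s) under %s", length(files), cfg$out)
    invisible(result)
  } else result
}
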