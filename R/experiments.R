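#' @title In-silico experiments
#' @description The three deterministic experiment runners: diet comparison
#'   (fructose vs mixed vs glucose, 100 g carbohydrate per meal),
#'   one-at-a-time (OAT) +/-10 percent sensitivity of the eleven hepatic rate
#'   constants, and graded fructokinase (KHK) inhibition under a 150 g/meal
#'   fructose diet, plus CSV report writers. All runners share the endpoint
#'   convention: state at t = 12 h of a simulation starting 08:00.
#' @name experiments
NULL

.endpoint_cols <- c(hepatic_FA = "FA", hepatic_TG = "TG",
                    plasma_FA = "FA_SBC", plasma_TG = "TG_SBC")

#' The eleven OAT sensitivity targets
#'
#' One entry per hepatocyte reaction, mapping the reaction label to the
#' maximal-rate parameter(s) scaled together for that reaction. Triose
#' phosphate isomerase is one enzyme with two directional maximal rates, so
#' both are scaled jointly.
#'
#' @return Named list of character vectors of parameter names.
#' @export
oat_targets <- function() {
  list(KHK = "V_KHK", aldB = "V_aldB",
       TPI = c("V_TPI_DHAP", "V_TPI_GA3P"),
       Tri = "V_Tri", PK = "V_PK", PEPCK = "V_PEPCK", PDC = "V_PDC",
       FAS = "V_FAS", boxi = "V_boxi", TGS = "V_TGS", Lply = "V_Lply")
}

endpoint_summary <- function(result, endpoint = c("final", "time-averaged")) {
  endpoint <- match.arg(endpoint)
  ep <- if (endpoint == "final") endpoint_state(result)
    else colMeans(result$trajectory)
  out <- ep[.endpoint_cols]
  names(out) <- names(.endpoint_cols)
  out
}

#' Compare diets from a shared baseline
#'
#' Runs each diet for `horizon_h` hours from the same initial state (by
#' default the converged daily baseline under the mixed 50/50 diet) and
#' summarises the lipid endpoints.
#'
#' @param diets List of `diet_spec` objects (default the three 100 g arms).
#' @param params A `parameter_set`.
#' @param baseline Optional shared initial 25-state vector; computed with
#'   [run_to_baseline()] under the mixed diet when omitted.
#' @param horizon_h Simulation horizon (default 12).
#' @param ... Passed to [run_simulation()].
#' @return List with `runs` (named list of `simulation_result`), `summary`
#'   (data frame of 12-h endpoints plus the plasma-TG maximum), and
#'   `baseline`.
#' @export
run_diet_comparison <- function(diets = scenario_diets()[1:3], params,
                                baseline = NULL, horizon_h = 12, ...) {
  stopifnot(length(diets) >= 1)
  if (is.null(names(diets)))
    names(diets) <- vapply(diets, function(d) d$name, character(1))
  if (is.null(baseline))
    baseline <- run_to_baseline(params, scenario_diets()[["mixed-100g"]], ...)
  runs <- lapply(diets, function(d)
    run_simulation(baseline, params, d, horizon_h = horizon_h, ...))
  summary <- do.call(rbind, lapply(names(runs), function(nm) {
    ep <- endpoint_summary(runs[[nm]])
    data.frame(diet = nm,
               hepatic_FA = ep[["hepatic_FA"]], hepatic_TG = ep[["hepatic_TG"]],
               plasma_FA = ep[["plasma_FA"]], plasma_TG = ep[["plasma_TG"]],
               plasma_TG_max = max(runs[[nm]]$trajectory[, "TG_SBC"]),
               blood_glucose_max = max(runs[[nm]]$trajectory[, "Glu_SBC"]))
  }))
  list(runs = runs, summary = summary, baseline = baseline)
}

#' One-at-a-time sensitivity of the hepatic rate constants
#'
#' For each target reaction and each direction, one full simulation is run
#' with only that reaction's maximal rate(s) scaled by `1 +/- perturbation`;
#' deltas are endpoint differences against the shared unperturbed run. All
#' runs share the initial state and solver settings.
#'
#' @param params A `parameter_set`.
#' @param diet A `diet_spec` (default mixed 50/50, 100 g/meal).
#' @param perturbation Fractional perturbation (default 0.1 for +/-10
#'   percent).
#' @param targets Named list as from [oat_targets()].
#' @param baseline Optional shared initial state (computed under `diet` when
#'   omitted).
#' @param horizon_h Simulation horizon (default 12).
#' @param endpoint `"final"` (state at the simulation end, the default
#'   reading of the endpoint convention) or `"time-averaged"`.
#' @param ... Passed to [run_simulation()].
#' @return A `sensitivity_report`: data frame with one row per target, and
#'   delta columns for each output x direction; the unperturbed endpoints
#'   are attached as attributes.
#' @export
run_oat_sensitivity <- function(params,
                                diet = scenario_diets()[["mixed-100g"]],
                                perturbation = 0.1,
                                targets = oat_targets(),
                                baseline = NULL, horizon_h = 12,
                                endpoint = "final", ...) {
  stopifnot(perturbation > -1)
  all_names <- unlist(targets)
  unknown <- setdiff(all_names, parameter_names())
  if (length(unknown) > 0)
    stop("unknown OAT target parameter(s): ", paste(unknown, collapse = ", "))
  if (is.null(baseline))
    baseline <- run_to_baseline(params, diet, ...)
  ref <- endpoint_summary(
    run_simulation(baseline, params, diet, horizon_h = horizon_h, ...),
    endpoint)
  rows <- lapply(names(targets), function(nm) {
    row <- list(reaction = nm)
    for (dir in c(1, -1)) {
      pp <- params
      for (pn in targets[[nm]])
        pp <- perturb_parameter(pp, pn, 1 + dir * perturbation)
      ep <- endpoint_summary(
        run_simulation(baseline, pp, diet, horizon_h = horizon_h, ...),
        endpoint)
      delta <- ep - ref
      tag <- if (dir > 0) "up" else "down"
      for (out in names(delta))
        row[[paste(out, tag, sep = "_")]] <- unname(delta[[out]])
    }
    as.data.frame(row)
  })
  report <- do.call(rbind, rows)
  attr(report, "reference_endpoints") <- ref
  attr(report, "perturbation") <- perturbation
  attr(report, "diet") <- diet$name
  class(report) <- c("sensitivity_report", "data.frame")
  report
}

#' Graded fructokinase inhibition under a very-high-fructose diet
#'
#' Scales `V_KHK` by `1 - fraction` for each inhibition fraction and runs
#' the 150 g/meal fructose diet from a shared baseline. Also computes the
#' steatosis-setup metric: the percent increase of the 12-h hepatic
#' triglyceride endpoint of the uninhibited 150 g diet over the 100 g
#' fructose diet.
#'
#' @param params A `parameter_set`.
#' @param fractions Inhibition fractions in \[0, 1\]
#'   (default 0, 0.5, 0.7, 1).
#' @param baseline Optional shared initial state (computed under the mixed
#'   diet when omitted, as for the diet comparison).
#' @param horizon_h Simulation horizon (default 12).
#' @param ... Passed to [run_simulation()].
#' @return List with `runs` (one `simulation_result` per fraction, names
#'   `inhib-<fraction>`), `endpoints` (data frame of 12-h lipid endpoints per
#'   fraction), `steatosis_increase_pct`, and `reference_100g` (the 100 g
#'   fructose run).
#' @export
run_khk_inhibition <- function(params, fractions = c(0, 0.5, 0.7, 1),
                               baseline = NULL, horizon_h = 12, ...) {
  if (any(fractions < 0 | fractions > 1))
    stop("inhibition fractions must lie in [0, 1]")
  presets <- scenario_diets()
  if (is.null(baseline))
    baseline <- run_to_baseline(params, presets[["mixed-100g"]], ...)
  diet150 <- presets[["fructose-150g"]]
  runs <- lapply(fractions, function(f) {
    pp <- params
    # full suppression means V_KHK = 0, which perturb_parameter (factor > 0)
    # deliberately cannot express; scale the entry directly
    pp$entries[["V_KHK"]]$value <- params$entries[["V_KHK"]]$value * (1 - f)
    run_simulation(baseline, pp, diet150, horizon_h = horizon_h, ...)
  })
  names(runs) <- sprintf("inhib-%g", fractions)
  endpoints <- do.call(rbind, lapply(seq_along(fractions), function(i) {
    ep <- endpoint_summary(runs[[i]])
    data.frame(fraction = fractions[i],
               hepatic_FA = ep[["hepatic_FA"]], hepatic_TG = ep[["hepatic_TG"]],
               plasma_FA = ep[["plasma_FA"]], plasma_TG = ep[["plasma_TG"]])
  }))
  ref100 <- run_simulation(baseline, params, presets[["fructose-100g"]],
                           horizon_h = horizon_h, ...)
  ref150 <- run_simulation(baseline, params, diet150,
                           horizon_h = horizon_h, ...)
  tg100 <- endpoint_state(ref100)[["TG"]]
  tg150 <- endpoint_state(ref150)[["TG"]]
  list(runs = runs, endpoints = endpoints,
       steatosis_increase_pct = 100 * (tg150 - tg100) / tg100,
       reference_100g = ref100)
}

#' Write experiment reports to CSV
#'
#' Writes trajectory tables (`time_h` plus the 25 state columns, and flux
#' columns when recorded), the sensitivity grid or inhibition endpoints as
#' applicable, and a plain-text run manifest echoing the configuration.
#'
#' @param result A `simulation_result`, `sensitivity_report`, or the list
#'   returned by [run_diet_comparison()] / [run_khk_inhibition()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, file) {
    path <- file.path(dir, file)
    # 17 significant digits so reading the CSV back reproduces the numbers
    # exactly
    out <- as.data.frame(lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.17g", col) else col),
      check.names = FALSE, optional = TRUE)
    names(out) <- names(df)
    tryCatch(
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
      error = function(e)
        stop(sprintf("failed writing %s: %s", path, conditionMessage(e))))
    written <<- c(written, path)
  }
  if (inherits(result, "simulation_result")) {
    put(as.data.frame(result), "trajectory.csv")
    manifest <- c(
      sprintf("diet: %s", result$diet$name),
      sprintf("stoichiometry_mode: %s", result$mode),
      sprintf("R_BS: %.17g", result$r_bs),
      sprintf("solver: %s rtol=%g atol=%g report_dt_min=%g",
              result$solver$method, result$solver$rtol, result$solver$atol,
              result$solver$report_dt_min),
      sprintf("params_version: %s", result$params_version),
      sprintf("horizon_h: %g", max(result$times_h)))
    writeLines(manifest, file.path(dir, "manifest.txt"))
    written <- c(written, file.path(dir, "manifest.txt"))
  } else if (inherits(result, "sensitivity_report")) {
    put(as.data.frame(result), "sensitivity.csv")
  } else if (is.list(result) && !is.null(result$runs)) {
    for (nm in names(result$runs))
      put(as.data.frame(result$runs[[nm]]),
          sprintf("trajectory-%s.csv", nm))
    if (!is.null(result$summary)) put(result$summary, "summary.csv")
    if (!is.null(result$endpoints)) put(result$endpoints, "endpoints.csv")
  } else stop("write_report: unrecognised result object")
  invisible(written)
}
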