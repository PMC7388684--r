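#' @title Whole-model assembly and integration
#' @description Assembles the 25-state right-hand side (11 hepatocyte
#'   metabolites; fructose, glucose, pyruvate/lactate, fatty acid,
#'   triglyceride, insulin and glucagon in each of the two blood
#'   compartments), integrates it with a stiff-capable adaptive solver, and
#'   provides the run-in-to-baseline, algebraic steady-state and
#'   carbon-balance audit utilities.
#' @name simulator
NULL

.shb_names <- paste0(c("Fru", "Glu", "Pyr", "FA", "TG", "Ins", "Gcg"), "_SHB")
.sbc_names <- paste0(c("Fru", "Glu", "Pyr", "FA", "TG", "Ins", "Gcg"), "_SBC")

#' Names of the 25 state variables, in fixed layout order
#'
#' Layout: the 11 hepatocyte species (`hepatic_species()`), then the 7
#' hepatic-blood species suffixed `_SHB`, then the 7 systemic-blood species
#' suffixed `_SBC`.
#' @return Character vector of length 25.
#' @export
state_names <- function() c(.hepatic_species, .shb_names, .sbc_names)

#' Assemble a full 25-component state vector
#'
#' @param hepatic Named numeric vector of the 11 hepatocyte species (uM).
#' @param shb Named numeric vector of the 7 hepatic-blood species (`Fru`,
#'   `Glu`, `Pyr`, `FA`, `TG`, `Ins`, `Gcg`).
#' @param sbc Same layout for the systemic blood.
#' @return Named numeric vector of length 25 in `state_names()` order.
#' @export
full_state <- function(hepatic, shb, sbc) {
  s <- c(hepatic[.hepatic_species], shb[.blood_species], sbc[.blood_species])
  names(s) <- state_names()
  if (any(is.na(s))) stop("full_state: missing species")
  s
}

#' Default (pre-run-in) initial state
#'
#' Physiologically plausible starting concentrations used to seed the
#' run-in; the experiments all start from [run_to_baseline()] output, so
#' these values only need to lie in the model's basin of attraction.
#' @return Named numeric vector of length 25 (uM; hormones basal-normalised).
#' @export
default_initial_state <- function() {
  hep <- c(Fru = 10, F1P = 100, DHAP = 50, GA = 10, GA3P = 50, Pyr = 800,
           ACoA = 100, FA = 300, TG = 15000, Glu = 5000, G6P = 200)
  blood <- c(Fru = 5, Glu = 1200, Pyr = 800, FA = 400, TG = 1500,
             Ins = 1, Gcg = 1)
  full_state(hep, blood, blood)
}

#' Full-model time derivative
#'
#' Composes the hepatocyte kinetics, cross-membrane transports, circulation,
#' hormone and periphery closures and the meal forcing into d/dt of the 25
#' states. The hepatic-blood metabolite balances are
#' `-T * R_HE + R_BS * (C_SBC - C_SHB)`; the systemic balances carry the meal
#' inputs, the volume-consistent circulation return and the periphery fluxes
#' with their original signs (fructose has no peripheral consumption).
#' Solver round-off slightly below zero is tolerated: rate laws see the state
#' floored at zero, the state itself is never modified.
#'
#' @param t_s Simulation time in seconds since 08:00.
#' @param state Named numeric vector of length 25 (`state_names()` order).
#' @param params A `parameter_set` or `param_values()` vector.
#' @param diet A `diet_spec`.
#' @param mode Stoichiometry mode, see [hepatic_derivatives()].
#' @return Named numeric vector of 25 derivatives (uM/s).
#' @export
assemble_derivatives <- function(t_s, state, params, diet,
                                 mode = "paper-faithful") {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  if (any(!is.finite(state))) {
    bad <- state_names()[!is.finite(state)]
    stop(sprintf("non-finite state (%s) at t = %.1f s",
                 paste(bad, collapse = ", "), t_s))
  }
  s <- pmax(state, 0)
  sh <- s[seq_len(11)]
  names(sh) <- .hepatic_species
  shb <- s[12:18]
  names(shb) <- .blood_species
  sbc <- s[19:25]
  names(sbc) <- .blood_species

  rates <- evaluate_hepatic_rates(sh, p)
  trans <- evaluate_transports(shb, sh, p)
  d_hep <- hepatic_derivatives(rates, trans, p, mode)

  metab <- c("Fru", "Glu", "Pyr", "FA", "TG")
  circ <- circulation_flux(sbc[metab], shb[metab], p)
  horm <- hormone_derivatives(sbc, shb, p)
  peri <- periphery_fluxes(sbc, p)
  meal <- meal_input_rate(diet, t_s / 3600)

  d_shb <- -trans * p[["R_HE"]] + circ$shb
  d_sbc <- c(
    meal[["Meal_Fru"]] + circ$sbc[["Fru"]],
    meal[["Meal_Glu"]] + circ$sbc[["Glu"]] - peri[["USE_Glu"]] -
      peri[["UP_FA"]] - peri[["UP_TG"]],
    circ$sbc[["Pyr"]],
    circ$sbc[["FA"]] - peri[["USE_FA"]] + peri[["UP_FA"]],
    circ$sbc[["TG"]] - peri[["USE_TG"]] + peri[["UP_TG"]]
  )
  d <- c(d_hep,
         d_shb, horm[["dIns_SHB"]], horm[["dGcg_SHB"]],
         d_sbc, horm[["dIns_SBC"]], horm[["dGcg_SBC"]])
  names(d) <- state_names()
  d
}

#' Integrate the model over a horizon
#'
#' Stiff-capable adaptive integration (deSolve, `lsoda` by default) with
#' dense output on a fixed reporting grid. Time zero is 08:00.
#'
#' @param initial Named 25-state vector (e.g. from [run_to_baseline()]).
#' @param params A `parameter_set`.
#' @param diet A `diet_spec`.
#' @param horizon_h Simulation horizon in hours (default 12).
#' @param report_dt_min Reporting grid step in minutes (default 1).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param method deSolve method name (default `"lsoda"`).
#' @param mode Stoichiometry mode.
#' @param fluxes If `TRUE`, also evaluate the 16 reaction rates and 5
#'   transports along the reported trajectory.
#' @return A `simulation_result`: list with `times_h`, `trajectory`
#'   (times x 25 matrix), optional `fluxes`, and a config echo.
#' @export
run_simulation <- function(initial, params, diet, horizon_h = 12,
                           report_dt_min = 1, rtol = 1e-8, atol = 1e-10,
                           method = "lsoda", mode = "paper-faithful",
                           fluxes = FALSE) {
  stopifnot(horizon_h > 0)
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  y0 <- initial[state_names()]
  if (any(is.na(y0))) stop("initial state is missing species")
  times <- seq(0, horizon_h * 3600, by = report_dt_min * 60)
  rhs <- function(t, y, parms) {
    list(assemble_derivatives(t, y, parms, diet, mode))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = p,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("solver failure at t = %.1f s; last state recorded",
                 sol[nrow(sol), 1]))
  traj <- unname(sol[, -1, drop = FALSE])
  colnames(traj) <- state_names()
  res <- structure(
    list(times_h = times / 3600,
         trajectory = traj,
         fluxes = NULL,
         diet = diet,
         mode = mode,
         solver = list(method = method, rtol = rtol, atol = atol,
                       report_dt_min = report_dt_min),
         r_bs = unname(p[["R_BS"]]),
         params_version = if (inherits(params, "parameter_set"))
           params$version else "raw-vector"),
    class = "simulation_result")
  if (fluxes) {
    fx <- t(apply(traj, 1, function(row) {
      sh <- pmax(row[seq_len(11)], 0)
      names(sh) <- .hepatic_species
      shb <- pmax(row[12:18], 0)
      names(shb) <- .blood_species
      c(evaluate_hepatic_rates(sh, p), evaluate_transports(shb, sh, p))
    }))
    res$fluxes <- fx
  }
  res
}

#' Final state of a simulation
#' @param result A `simulation_result`.
#' @return Named 25-state vector at the final reported time.
#' @export
endpoint_state <- function(result) {
  result$trajectory[nrow(result$trajectory), ]
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s, %.3g h horizon, %d reported steps (%s, mode %s)\n",
    x$diet$name, max(x$times_h), length(x$times_h), x$solver$method, x$mode))
  invisible(x)
}

#' Convert a simulation result to a data frame
#' @param x A `simulation_result`.
#' @param row.names,optional,... Standard `as.data.frame` arguments (unused).
#' @return Data frame with `time_h`, the 25 state columns, and flux columns
#'   when recorded.
#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  df <- data.frame(time_h = x$times_h, x$trajectory, check.names = FALSE)
  if (!is.null(x$fluxes)) df <- cbind(df, as.data.frame(x$fluxes))
  df
}

#' Run repeated identical days until the daily cycle converges
#'
#' Integrates 24-h days (meals per `diet`) starting from `init` and compares
#' successive 08:00 states; once the maximum relative cycle-to-cycle change
#' (with a 1-uM absolute floor) falls below `tol` the converged 08:00 state
#' is returned. Deterministic; errors if the cap is reached first.
#'
#' @param params A `parameter_set`.
#' @param diet A `diet_spec` (use `diet_spec(0)` for the zero-input
#'   baseline).
#' @param init Starting state (default [default_initial_state()]).
#' @param tol Convergence tolerance on the relative cycle change
#'   (default 1e-3, i.e. 0.1 percent).
#' @param max_days Day cap (default 30).
#' @param report_dt_min Reporting grid during the run-in (coarse by default;
#'   only the cycle endpoints matter).
#' @param ... Passed to [run_simulation()] (tolerances, mode, ...).
#' @return Named 25-state vector: the converged 08:00 state.
#' @export
run_to_baseline <- function(params, diet, init = default_initial_state(),
                            tol = 1e-3, max_days = 30, report_dt_min = 60,
                            ...) {
  state <- init
  rel <- Inf
  for (day in seq_len(max_days)) {
    res <- run_simulation(state, params, diet, horizon_h = 24,
                          report_dt_min = report_dt_min, ...)
    nxt <- endpoint_state(res)
    rel <- max(abs(nxt - state) / pmax(abs(state), 1))
    state <- nxt
    if (rel < tol) return(state)
  }
  stop(sprintf(
    "baseline did not converge within %d days (last cycle change %.3g)",
    max_days, rel))
}

#' Algebraic steady state of the zero-input model
#'
#' Damped Newton iteration on the autonomous right-hand side (zero diet)
#' with a finite-difference Jacobian, as an independent route to the
#' zero-input baseline found by [run_to_baseline()].
#'
#' @param params A `parameter_set`.
#' @param init Starting guess (default [default_initial_state()]).
#' @param tol Max-norm tolerance on the RHS at the root (uM/s).
#' @param max_iter Newton iteration cap.
#' @param mode Stoichiometry mode.
#' @return Named 25-state vector with `max(|RHS|) <= tol`.
#' @export
find_steady_state <- function(params, init = default_initial_state(),
                              tol = 1e-10, max_iter = 200,
                              mode = "paper-faithful") {
  p <- param_values(params)
  zero_diet <- diet_spec(0, 0.5, name = "zero")
  f <- function(x) assemble_derivatives(0, x, p, zero_diet, mode)
  x <- init
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) <= tol) return(x)
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-7 * abs(x[j]), 1e-9)
      xp <- x
      xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - fx) / h
    }
    step <- tryCatch(solve(J, -fx), error = function(e)
      solve(J + diag(1e-12, n), -fx))
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(fx)) || lambda < 1e-6)) break
      lambda <- lambda / 2
    }
    x <- xn
    fx <- fn
  }
  if (max(abs(fx)) > tol)
    stop(sprintf("steady state not found: max |RHS| = %.3g uM/s",
                 max(abs(fx))))
  x
}

#' Carbon balance audit of the fructose-pathway reactions
#'
#' Multiplies each reaction rate by its net carbon change using the species
#' weights {Fru 6, F1P 6, DHAP 3, GA 3, GA3P 3, Pyr 3, ACoA 2, FA 16, TG 51,
#' Glu 6, G6P 6}. All eleven fructolysis/lipid reactions conserve carbon
#' except pyruvate oxidation (one CO2 per event, residual `-R_PDC`) and, in
#' paper-faithful mode, lipolysis (the three-carbon glyceraldehyde backbone
#' is not returned, residual `-3 * R_Lply`); carbon-consistent mode returns
#' the backbone so lipolysis balances too.
#'
#' @param rates Named rate vector from [evaluate_hepatic_rates()].
#' @param mode Stoichiometry mode.
#' @return Named numeric vector of per-reaction carbon residuals (uM C/s)
#'   over the 12 fructose-pathway rate entries.
#' @export
carbon_audit <- function(rates, mode = c("paper-faithful",
                                         "carbon-consistent")) {
  mode <- match.arg(mode)
  w <- c(Fru = 6, F1P = 6, DHAP = 3, GA = 3, GA3P = 3, Pyr = 3, ACoA = 2,
         FA = 16, TG = 51, Glu = 6, G6P = 6)
  r <- rates
  res <- c(
    R_KHK = (w[["F1P"]] - w[["Fru"]]) * r[["R_KHK"]],
    R_aldB = (w[["DHAP"]] + w[["GA"]] - w[["F1P"]]) * r[["R_aldB"]],
    R_TPI_DHAP = (w[["GA3P"]] - w[["DHAP"]]) * r[["R_TPI_DHAP"]],
    R_TPI_GA3P = (w[["DHAP"]] - w[["GA3P"]]) * r[["R_TPI_GA3P"]],
    R_Tri = (w[["GA3P"]] - w[["GA"]]) * r[["R_Tri"]],
    R_PK = (w[["Pyr"]] - w[["GA3P"]]) * r[["R_PK"]],
    R_PEPCK = (w[["GA3P"]] - w[["Pyr"]]) * r[["R_PEPCK"]],
    R_PDC = (w[["ACoA"]] - w[["Pyr"]]) * r[["R_PDC"]],
    R_FAS = (w[["FA"]] - 8 * w[["ACoA"]]) * r[["R_FAS"]],
    R_boxi = (8 * w[["ACoA"]] - w[["FA"]]) * r[["R_boxi"]],
    R_TGS = (w[["TG"]] - 3 * w[["FA"]] - w[["GA3P"]]) * r[["R_TGS"]],
    R_Lply = ((3 * w[["FA"]] +
                 if (mode == "carbon-consistent") w[["GA"]] else 0) -
                w[["TG"]]) * r[["R_Lply"]]
  )
  res
}
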