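#' @title Dietary carbohydrate forcing
#' @description Compiles a meal schedule (grams of carbohydrate per meal and
#'   a fructose:glucose split) into smooth time-dependent input rates
#'   `Meal_Fru(t)` and `Meal_Glu(t)` entering the systemic-blood equations.
#'   Each meal is absorbed over a 4-h window shaped `sin^6(pi/4 * h)`, the
#'   classic spiked-meal forcing; the amplitude is normalised so the window
#'   integral equals the meal dose expressed as a concentration increment of
#'   the distribution volume (mean of `sin^6` over its half-period is 5/16).
#' @name diet
NULL

#' Construct a diet specification
#'
#' @param grams_per_meal Grams of carbohydrate per meal, >= 0.
#' @param fructose_fraction Fructose share of the carbohydrate, in \[0, 1\];
#'   the remainder is glucose.
#' @param meal_times Clock hours of meal starts (default 8:00, 12:00, 16:00).
#' @param window_h Absorption window per meal in hours (default 4); windows
#'   must not overlap.
#' @param molar_mass Hexose molar mass in g/mol (180.156 for both sugars).
#' @param distribution_volume Volume the dose is dissolved into, in L
#'   (default 4.2, the systemic blood volume `V_body - V_liver`).
#' @param name Optional label.
#' @return A `diet_spec` object.
#' @export
diet_spec <- function(grams_per_meal = 100, fructose_fraction = 0.5,
                      meal_times = c(8, 12, 16), window_h = 4,
                      molar_mass = 180.156, distribution_volume = 4.2,
                      name = NULL) {
  if (grams_per_meal < 0) stop("grams_per_meal must be >= 0")
  if (fructose_fraction < 0 || fructose_fraction > 1)
    stop("fructose_fraction must lie in [0, 1]")
  if (distribution_volume <= 0) stop("distribution_volume must be > 0")
  if (window_h <= 0) stop("window_h must be > 0")
  mt <- sort(meal_times)
  if (length(mt) > 1 && any(diff(mt) < window_h))
    stop("meal windows overlap")
  structure(list(grams_per_meal = grams_per_meal,
                 fructose_fraction = fructose_fraction,
                 meal_times = mt, window_h = window_h,
                 molar_mass = molar_mass,
                 distribution_volume = distribution_volume,
                 name = if (is.null(name))
                   sprintf("%gg-fru%.0f%%", grams_per_meal,
                           100 * fructose_fraction) else name),
            class = "diet_spec")
}

#' Peak absorption rate for one species of a meal
#'
#' Returns the amplitude `v_input` such that
#' `integral of v_input * sin^6(pi/window * t)` over one window equals the
#' per-meal dose as a concentration increment:
#' `grams * fraction / molar_mass * 1e6 / distribution_volume` uM. The window
#' integral of `sin^6` is `window * 5/16`.
#'
#' @param spec A `diet_spec`.
#' @param species `"fructose"` or `"glucose"`.
#' @return Amplitude in uM/s.
#' @export
meal_amplitude <- function(spec, species = c("fructose", "glucose")) {
  species <- match.arg(species)
  frac <- if (species == "fructose") spec$fructose_fraction else
    1 - spec$fructose_fraction
  dose_umol <- spec$grams_per_meal * frac / spec$molar_mass * 1e6
  dose_uM <- dose_umol / spec$distribution_volume
  window_s <- spec$window_h * 3600
  dose_uM / (window_s * 5 / 16)
}

#' Meal input rates at a simulation time
#'
#' Simulation time `t` is measured in hours since 08:00 of day one. Inside a
#' meal window starting at clock hour `m` the rate is
#' `amplitude * sin^6(pi/window * (t - m))`; outside all windows it is zero.
#' The schedule repeats every 24 h.
#'
#' @param spec A `diet_spec`.
#' @param t_h Simulation time in hours since 08:00 (vectorised).
#' @return Matrix with columns `Meal_Fru`, `Meal_Glu` (uM/s) and one row per
#'   time point (a named length-2 vector for scalar `t_h`).
#' @export
meal_input_rate <- function(spec, t_h) {
  clock <- (8 + t_h) %% 24
  shape <- numeric(length(t_h))
  for (m in spec$meal_times) {
    dt <- clock - m
    # window may wrap midnight
    dt <- ifelse(dt < 0, dt + 24, dt)
    inside <- dt >= 0 & dt < spec$window_h
    shape[inside] <- shape[inside] +
      sin(pi / spec$window_h * dt[inside])^6
  }
  out <- cbind(Meal_Fru = meal_amplitude(spec, "fructose") * shape,
               Meal_Glu = meal_amplitude(spec, "glucose") * shape)
  if (length(t_h) == 1) out[1, ] else out
}

#' Named diet presets for the in-silico experiments
#'
#' `fructose-100g`, `mixed-100g`, `glucose-100g` (the diet-comparison arms,
#' 100 g carbohydrate per meal with fructose fractions 1, 0.5, 0) and
#' `fructose-150g` (the very-high-fructose steatosis diet).
#'
#' @return Named list of `diet_spec` objects.
#' @export
scenario_diets <- function() {
  list(
    "fructose-100g" = diet_spec(100, 1.0, name = "fructose-100g"),
    "mixed-100g"    = diet_spec(100, 0.5, name = "mixed-100g"),
    "glucose-100g"  = diet_spec(100, 0.0, name = "glucose-100g"),
    "fructose-150g" = diet_spec(150, 1.0, name = "fructose-150g")
  )
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf(
    "<diet_spec> %s: %g g/meal, fructose fraction %.2f, meals at %s h, %g-h window\n",
    x$name, x$grams_per_meal, x$fructose_fraction,
    paste(x$meal_times, collapse = ", "), x$window_h))
  invisible(x)
}
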