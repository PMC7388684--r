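zero_diet <- function() diet_spec(0, 0.5, name = "zero")

test_that("state layout is the documented 25-variable order", {
  nm <- state_names()
  expect_length(nm, 25)
  expect_equal(nm[1:11], hepatic_species())
  expect_true(all(grepl("_SHB$", nm[12:18])))
  expect_true(all(grepl("_SBC$", nm[19:25])))
  h <- stats::setNames(rep(1, 11), hepatic_species())
  b <- stats::setNames(rep(2, 7), blood_species())
  s <- full_state(h, b, b)
  expect_equal(unname(s), c(rep(1, 11), rep(2, 14)))
  expect_error(full_state(h[-1], b, b), "missing")
})

test_that("the empty system is inert except for basal glucagon secretion", {
  p <- test_params()
  d <- assemble_derivatives(0, stats::setNames(rep(0, 25), state_names()),
                            p, zero_diet())
  gcg <- c("Gcg_SHB", "Gcg_SBC")
  expect_equal(unname(d[setdiff(state_names(), gcg)]), rep(0, 23))
  # glucagon is secreted maximally at zero glucose by construction
  expect_gt(d[["Gcg_SBC"]], 0)
})

test_that("assembled derivatives compose the module fluxes as tabulated", {
  p <- test_params()
  pv <- param_values(p)
  diet <- scenario_diets()[["mixed-100g"]]
  set.seed(31)
  for (i in 1:25) {
    sh <- random_hepatic_state()
    shb <- random_blood_state()
    sbc <- random_blood_state()
    s <- full_state(sh, shb, sbc)
    t_s <- stats::runif(1, 0, 43200)
    d <- assemble_derivatives(t_s, s, p, diet)

    rates <- evaluate_hepatic_rates(sh, pv)
    tr <- evaluate_transports(shb, sh, pv)
    expect_equal(d[1:11], hepatic_derivatives(rates, tr, pv),
                 tolerance = 1e-14, ignore_attr = TRUE)
    # hepatic blood: -T * R_HE + circulation (R_HE = 4 multiplier)
    metab <- c("Fru", "Glu", "Pyr", "FA", "TG")
    circ <- circulation_flux(sbc[metab], shb[metab], pv)
    expect_equal(unname(d[paste0(metab, "_SHB")]),
                 unname(-tr * pv[["R_HE"]] + circ$shb), tolerance = 1e-14)
    # systemic fructose: meal + circulation only, no periphery terms
    meal <- meal_input_rate(diet, t_s / 3600)
    expect_equal(d[["Fru_SBC"]],
                 unname(meal[["Meal_Fru"]] + circ$sbc[["Fru"]]),
                 tolerance = 1e-14)
    # systemic glucose carries the tabulated periphery signs
    per <- periphery_fluxes(sbc, pv)
    expect_equal(d[["Glu_SBC"]],
                 unname(meal[["Meal_Glu"]] + circ$sbc[["Glu"]] -
                          per[["USE_Glu"]] - per[["UP_FA"]] - per[["UP_TG"]]),
                 tolerance = 1e-14)
    expect_equal(d[["Pyr_SBC"]], unname(circ$sbc[["Pyr"]]),
                 tolerance = 1e-14)
    expect_equal(d[["FA_SBC"]],
                 unname(circ$sbc[["FA"]] - per[["USE_FA"]] + per[["UP_FA"]]),
                 tolerance = 1e-14)
  }
  expect_error(
    assemble_derivatives(0, replace(full_state(sh, shb, sbc), 3, NaN), p,
                         diet),
    "non-finite")
})

test_that("circulation alone conserves volume-weighted moles and equilibrates", {
  # disable reactions, transports, meals and hormones via a raw vector
  pv <- test_param_values()
  pv[grep("^V_", names(pv))] <- 0
  pv[c("V_body", "V_liver")] <- c(5, 0.8)  # keep volumes
  s0 <- stats::setNames(rep(0, 25), state_names())
  s0[c("Fru_SHB", "Fru_SBC")] <- c(100, 4000)
  s0[c("TG_SHB", "TG_SBC")] <- c(3000, 500)
  res <- run_simulation(s0, pv, zero_diet(), horizon_h = 2)
  vl <- 0.8; vr <- 4.2
  for (sp in c("Fru", "TG")) {
    tot <- vl * res$trajectory[, paste0(sp, "_SHB")] +
      vr * res$trajectory[, paste0(sp, "_SBC")]
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
    gap <- abs(res$trajectory[, paste0(sp, "_SHB")] -
                 res$trajectory[, paste0(sp, "_SBC")])
    # monotone equilibration, up to solver-tolerance wiggle near zero
    expect_true(all(diff(gap) <= 1e-6 * gap[1]))
    expect_lt(gap[length(gap)], gap[1] * 1e-3)
  }
})

test_that("zero-input steady state: integration and root-finding agree", {
  p <- test_params()
  eq_dyn <- run_to_baseline(p, zero_diet())
  eq_alg <- find_steady_state(p, init = eq_dyn, tol = 1e-9)
  expect_equal(eq_alg, eq_dyn, tolerance = 1e-3)
  # stationarity over 12 h (0.1% with a 1-uM absolute floor)
  res <- run_simulation(eq_alg, p, zero_diet(), horizon_h = 12)
  drift <- abs(sweep(res$trajectory, 2, eq_alg)) /
    pmax(abs(rep(eq_alg, each = nrow(res$trajectory))), 1)
  expect_lt(max(drift), 1e-3)
  # hormones stay constant at their basal fixed point
  for (hcol in c("Ins_SBC", "Gcg_SBC"))
    expect_lt(diff(range(res$trajectory[, hcol])) /
                max(res$trajectory[, hcol], 1e-9), 1e-3)
  # deterministic: repeated run-in is bit-identical
  expect_identical(eq_dyn, run_to_baseline(p, zero_diet()))
  # converged result is invariant to a larger day cap
  expect_identical(eq_dyn, run_to_baseline(p, zero_diet(), max_days = 40))
})

test_that("simulation results are well-formed and non-negative", {
  p <- test_params()
  res <- run_simulation(default_initial_state(), p,
                        scenario_diets()[["mixed-100g"]], horizon_h = 3,
                        fluxes = TRUE)
  expect_s3_class(res, "simulation_result")
  expect_true(all(diff(res$times_h) > 0))
  expect_equal(dim(res$trajectory), c(181, 25))
  expect_equal(ncol(res$fluxes), 21)
  colmax <- apply(abs(res$trajectory), 2, max)
  expect_true(all(res$trajectory >= -1e-6 * rep(colmax,
                                                each = nrow(res$trajectory))))
  df <- as.data.frame(res)
  expect_equal(names(df)[1], "time_h")
  expect_equal(ncol(df), 1 + 25 + 21)
})

test_that("reported trajectory is consistent with the vector field", {
  p <- test_params()
  diet <- scenario_diets()[["mixed-100g"]]
  res <- run_simulation(default_initial_state(), p, diet, horizon_h = 2)
  tr <- res$trajectory
  t_s <- res$times_h * 3600
  # central differences vs RHS at interior reporting points
  i <- seq(31, 91, by = 10)
  for (k in i) {
    fd <- (tr[k + 1, ] - tr[k - 1, ]) / (t_s[k + 1] - t_s[k - 1])
    rhs <- assemble_derivatives(t_s[k], tr[k, ], p, diet)
    scale <- max(abs(rhs), 1e-3)
    expect_lt(max(abs(fd - rhs)) / scale, 0.05)
  }
})

test_that("carbon audit flags only the known boundary reactions", {
  set.seed(41)
  r <- stats::setNames(stats::runif(16, 0, 10), rate_names())
  audit <- carbon_audit(r, "paper-faithful")
  expect_equal(audit[["R_aldB"]], 0)          # 6 -> 3 + 3
  expect_equal(audit[["R_FAS"]], 0)           # 8 x 2 -> 16
  expect_equal(audit[["R_TGS"]], 0)           # 3 x 16 + 3 -> 51
  expect_equal(audit[["R_PDC"]], -r[["R_PDC"]])     # one CO2 per event
  expect_equal(audit[["R_Lply"]], -3 * r[["R_Lply"]])  # backbone dropped
  expect_equal(unname(audit[setdiff(names(audit),
                                    c("R_PDC", "R_Lply"))]),
               rep(0, 10))
  audit_cc <- carbon_audit(r, "carbon-consistent")
  expect_equal(audit_cc[["R_Lply"]], 0)       # backbone returned
  expect_equal(audit_cc[["R_PDC"]], -r[["R_PDC"]])
})
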