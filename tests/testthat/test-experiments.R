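# Runner mechanics are tested on short horizons from a fixed shared state;
# the full 12-h scientific properties live in test-acceptance.R.

shared_state <- function() default_initial_state()

test_that("the sensitivity target list covers the eleven tabulated reactions", {
  tg <- oat_targets()
  expect_length(tg, 11)
  expect_setequal(names(tg), c("KHK", "aldB", "TPI", "Tri", "PK", "PEPCK",
                               "PDC", "FAS", "boxi", "TGS", "Lply"))
  expect_equal(tg$TPI, c("V_TPI_DHAP", "V_TPI_GA3P"))  # one enzyme, two Vmax
  expect_true(all(unlist(tg) %in% parameter_names()))
})

test_that("zero perturbation yields exactly zero deltas", {
  p <- test_params()
  rep0 <- run_oat_sensitivity(p, perturbation = 0,
                              targets = oat_targets()[c("KHK", "TGS")],
                              baseline = shared_state(), horizon_h = 2)
  deltas <- as.matrix(rep0[, setdiff(names(rep0), "reaction")])
  expect_identical(unname(deltas), matrix(0, 2, 8))
})

test_that("sensitivity report is invariant to target ordering", {
  p <- test_params()
  t1 <- oat_targets()[c("PK", "Lply")]
  t2 <- rev(t1)
  r1 <- run_oat_sensitivity(p, targets = t1, baseline = shared_state(),
                            horizon_h = 2)
  r2 <- run_oat_sensitivity(p, targets = t2, baseline = shared_state(),
                            horizon_h = 2)
  r2 <- r2[match(r1$reaction, r2$reaction), ]
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("each delta equals the difference of two standalone simulations", {
  p <- test_params()
  d <- scenario_diets()[["mixed-100g"]]
  rep1 <- run_oat_sensitivity(p, targets = oat_targets()["PK"],
                              baseline = shared_state(), horizon_h = 2)
  ref <- run_simulation(shared_state(), p, d, horizon_h = 2)
  per <- run_simulation(shared_state(), perturb_parameter(p, "V_PK", 1.1),
                        d, horizon_h = 2)
  want <- endpoint_state(per)[["TG"]] - endpoint_state(ref)[["TG"]]
  expect_equal(rep1$hepatic_TG_up[1], want, tolerance = 1e-9)
})

test_that("identical diets give identical trajectories; runs are deterministic", {
  p <- test_params()
  d <- scenario_diets()[["mixed-100g"]]
  dc <- run_diet_comparison(list(a = d, b = d), p, baseline = shared_state(),
                            horizon_h = 2)
  expect_identical(dc$runs$a$trajectory, dc$runs$b$trajectory)
  again <- run_diet_comparison(list(a = d), p, baseline = shared_state(),
                               horizon_h = 2)
  expect_identical(again$runs$a$trajectory, dc$runs$a$trajectory)
  expect_equal(nrow(dc$summary), 2)
  expect_true(all(c("hepatic_TG", "plasma_TG", "plasma_TG_max") %in%
                    names(dc$summary)))
})

test_that("zero inhibition reproduces the uninhibited run bit-for-bit", {
  p <- test_params()
  kh <- run_khk_inhibition(p, fractions = 0, baseline = shared_state(),
                           horizon_h = 2)
  direct <- run_simulation(shared_state(), p,
                           scenario_diets()[["fructose-150g"]], horizon_h = 2)
  expect_identical(kh$runs[["inhib-0"]]$trajectory, direct$trajectory)
  expect_error(run_khk_inhibition(p, fractions = 1.2), "fractions")
})

test_that("full KHK suppression silences fructokinase and drains F1P", {
  p <- test_params()
  pp <- p
  pp$entries[["V_KHK"]]$value <- 0
  # start from a fructose-loaded state so F1P has something to drain
  s <- shared_state()
  s[["F1P"]] <- 2000
  res <- run_simulation(s, pp, scenario_diets()[["fructose-150g"]],
                        horizon_h = 2, fluxes = TRUE)
  expect_true(all(res$fluxes[, "R_KHK"] == 0))
  expect_true(all(diff(res$trajectory[, "F1P"]) <= 1e-9))
})

test_that("reports round-trip through CSV and echo the configuration", {
  p <- test_params()
  dir <- withr::local_tempdir()
  res <- run_simulation(shared_state(), p, scenario_diets()[["mixed-100g"]],
                        horizon_h = 1, fluxes = TRUE)
  files <- write_report(res, dir)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  back <- utils::read.csv(file.path(dir, "trajectory.csv"),
                          check.names = FALSE)
  expect_identical(unname(as.matrix(back[, state_names()])),
                   unname(res$trajectory))
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("stoichiometry_mode: paper-faithful", manifest)))
  expect_true(any(grepl("^R_BS: 0.0166", manifest)))

  rep1 <- run_oat_sensitivity(p, targets = oat_targets(),
                              perturbation = 0,
                              baseline = shared_state(), horizon_h = 1)
  write_report(rep1, dir)
  grid <- utils::read.csv(file.path(dir, "sensitivity.csv"))
  expect_equal(dim(grid), c(11, 9))  # 11 reactions x (label + 8 deltas)
})
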