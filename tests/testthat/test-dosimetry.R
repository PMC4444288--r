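# TAC quadrature, therapy prediction, relative deviation, cohort roll-up

test_that("TAC of a constant retention curve matches the closed form", {
  tg <- cd66pbpk:::.tac_grid(0, 20000)
  traj <- constant_retention_traj(tg)
  y90 <- nuclide("Y90")
  a_20000 <- tac(traj, "total_body", y90, horizon = 20000)
  lam_h <- y90$lambda_phys * 60
  oracle <- (1 / lam_h) * (1 - exp(-lam_h * 20000 / 60))
  expect_equal(as.numeric(a_20000), oracle, tolerance = 1e-4)
  expect_equal(oracle, 89.95, tolerance = 1e-3)
  expect_equal(1 / lam_h, 92.47, tolerance = 1e-4)
  # quadrature error estimate is small
  expect_lt(attr(a_20000, "quad_error") / oracle, 1e-4)

  # zero curve -> 0 (use the unlabeled-only trajectory: serum region of a
  # zero-labeled state is still defined through n_lab)
  traj0 <- traj
  traj0$y[] <- 0; traj0$f[] <- 0
  expect_equal(as.numeric(tac(traj0, "liver", y90, n_lab = 1)), 0)

  # grid refinement changes the TAC by < 0.01%
  tg2 <- cd66pbpk:::.tac_grid(0, 20000, n = 800)
  traj2 <- constant_retention_traj(tg2)
  a2 <- tac(traj2, "total_body", y90, horizon = 20000)
  expect_lt(abs(a2 - a_20000) / a_20000, 1e-4)

  expect_error(tac(traj, "total_body", y90, horizon = 30000), "horizon")
})

test_that("total-body TAC never exceeds the physical bound 1/lambda", {
  th <- ref_theta()
  traj <- simulate_phase(th, 1, ref_injection_pre(),
                         cd66pbpk:::.tac_grid(0, 20000), rtol = 1e-7)
  for (nuc in list(nuclide("In111"), nuclide("Y90"))) {
    a_tb <- as.numeric(tac(traj, "total_body", nuc, c_RM = th[["c_RM"]]))
    expect_lt(a_tb, 1 / (nuc$lambda_phys * 60))
  }
})

test_that("relative deviation is the plain ratio formula", {
  expect_equal(relative_deviation(4.9, 4.9), 0)
  expect_equal(relative_deviation(3.8, 4.9), -1.1 / 4.9)
  expect_equal(round(relative_deviation(3.8, 4.9), 4), -0.2245)
  expect_equal(relative_deviation(5, 4), 0.25)
  expect_error(relative_deviation(1, 0), "positive")
})

test_that("zero-residual prediction with identical phases is idempotent", {
  # same nuclide, same amount, carryover disabled: the 'therapy' phase is an
  # exact replay of the pre-therapy phase
  ds <- tiny_dataset(seed = 51, noise = FALSE)
  ds$injections[2, c("amount_mg", "activity_MBq", "nuclide")] <-
    ds$injections[1, c("amount_mg", "activity_MBq", "nuclide")]
  pop <- population_spec()
  th <- sample_patient(pop, 51)$theta

  pre <- cd66pbpk:::.simulate_pre_dense(th, 1, ds)
  pre_tacs <- cd66pbpk:::.tacs_of(pre, 0, nuclide("In111"), th[["c_RM"]])
  ther <- cd66pbpk:::.simulate_therapy_dense(th, 1, ds, carryover = FALSE)
  ther_tacs <- cd66pbpk:::.tacs_of(ther$traj, ther$t_start,
                                   nuclide("In111"), th[["c_RM"]])
  expect_equal(ther_tacs, pre_tacs, tolerance = 1e-4)
})

test_that("linear regime: predicted serum TAC equals pre-therapy TAC with
          the therapy nuclide's decay", {
  # huge antigen pools remove saturation; amounts cancel in fractions
  ds <- tiny_dataset(seed = 61, noise = FALSE)
  th <- sample_patient(population_spec(), 61)$theta
  th[["Ag_L"]] <- 1e6; th[["Ag_S"]] <- 1e6

  pre <- cd66pbpk:::.simulate_pre_dense(th, 1, ds)
  a_pre_y90 <- as.numeric(tac(pre, "serum", nuclide("Y90"),
                              c_RM = th[["c_RM"]]))
  ther <- cd66pbpk:::.simulate_therapy_dense(th, 1, ds, carryover = TRUE)
  a_pred <- as.numeric(tac(ther$traj, "serum", ther$nuclide,
                           t_start = ther$t_start, c_RM = th[["c_RM"]]))
  expect_equal(a_pred, a_pre_y90, tolerance = 5e-3)
})

test_that("saturating regime: therapy lowers red marrow and raises serum", {
  # low antigen pool, therapy amount well above the pre-therapy amount
  th <- ref_theta()
  th[["Ag_L"]] <- 0.1; th[["Ag_S"]] <- 0.05
  ds <- tiny_dataset(seed = 71, noise = FALSE)
  ds$injections$amount_mg <- c(0.5, 2.5)

  pre <- cd66pbpk:::.simulate_pre_dense(th, 1, ds)
  ther <- cd66pbpk:::.simulate_therapy_dense(th, 1, ds)
  y90 <- nuclide("Y90")
  a_rm_pre <- as.numeric(tac(pre, "red_marrow", y90, c_RM = th[["c_RM"]]))
  a_rm_ther <- as.numeric(tac(ther$traj, "red_marrow", y90,
                              t_start = ther$t_start, c_RM = th[["c_RM"]]))
  a_se_pre <- as.numeric(tac(pre, "serum", y90, c_RM = th[["c_RM"]]))
  a_se_ther <- as.numeric(tac(ther$traj, "serum", y90,
                              t_start = ther$t_start, c_RM = th[["c_RM"]]))
  expect_lt(a_rm_ther, a_rm_pre)
  expect_gt(a_se_ther, a_se_pre)
})

test_that("cohort summary equals a naive per-patient recomputation", {
  tabs <- expand.grid(patient_id = c("A", "B", "C"),
                      region = c("serum", "red_marrow"),
                      tag = c("pre_therapy", "prediction", "therapy"),
                      stringsAsFactors = FALSE)
  set.seed(5)
  tabs$a_h <- runif(nrow(tabs), 2, 50)
  cs <- cohort_summary(tabs)
  for (rg in c("serum", "red_marrow")) {
    sel <- tabs$region == rg
    ratios <- vapply(c("A", "B", "C"), function(p) {
      pre <- tabs$a_h[sel & tabs$patient_id == p & tabs$tag == "pre_therapy"]
      ther <- tabs$a_h[sel & tabs$patient_id == p & tabs$tag == "therapy"]
      pre / ther
    }, numeric(1))
    expect_equal(cs$ratio_pre_ther_mean[cs$region == rg], mean(ratios))
    expect_equal(cs$ratio_pre_ther_sd[cs$region == rg], sd(ratios))
    expect_equal(cs$therapy_mean[cs$region == rg],
                 mean(tabs$a_h[sel & tabs$tag == "therapy"]))
  }
  # single patient: means equal the values, SDs zero
  one <- tabs[tabs$patient_id == "A", ]
  cs1 <- cohort_summary(one)
  expect_equal(cs1$prediction_sd, c(0, 0))
  expect_equal(cs1$ratio_pred_ther_sd, c(0, 0))
})

test_that("Akaike-averaged TACs lie between the per-model TACs", {
  v1 <- c(10, 20); v2 <- c(14, 18)
  for (w1 in c(0.2, 0.5, 0.9)) {
    m <- mapply(function(a, b) model_average(c(a, b), c(0, 0),
                                             c(w1, 1 - w1))$value, v1, v2)
    expect_true(all(m >= pmin(v1, v2) & m <= pmax(v1, v2)))
  }
})
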