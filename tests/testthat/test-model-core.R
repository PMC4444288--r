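# model core: conversions, injection partition, binding, ODE invariants

test_that("mass and activity conversions follow the molar conventions", {
  expect_equal(mg_to_nmol(1), 6.7)
  expect_equal(mg_to_nmol(0), 0)
  expect_equal(mg_to_nmol(1.3), 8.71)
  expect_error(mg_to_nmol(-1), "non-negative")

  nuc <- nuclide_spec("In111", 4042)
  expect_equal(nuc$lambda_phys, log(2) / 4042, tolerance = 1e-12)
  # independent oracle: N = A / lambda atoms, Avogadro 6.02214076e23 / mol
  lambda <- log(2) / 4042
  atoms <- 130e6 * 60 / lambda
  n_lab_oracle <- atoms / 6.02214076e14
  expect_equal(activity_to_nmol(130, nuc), n_lab_oracle, tolerance = 1e-12)
  expect_equal(n_lab_oracle, 0.0755, tolerance = 2e-3)
})

test_that("injection partition is binomial in r_im and conserves total", {
  part <- immunoreactivity_partition(0.8)
  expect_equal(part$f_full + part$f_half + part$f_non, 1)
  expect_equal(part$f_full, 0.64)
  expect_equal(part$f_half, 0.32)

  inj <- ref_injection_pre()
  amt <- partition_injection(inj, 0.8)
  expect_equal(sum(amt), mg_to_nmol(0.5))
  expect_equal(attr(amt, "n_lab"), activity_to_nmol(130, inj$nuclide))
  # unlabeled row is (n_tot - n_lab) * (0.64, 0.32, 0.04)
  n_unl <- attr(amt, "n_tot") - attr(amt, "n_lab")
  expect_equal(unname(amt["unlabeled", ]),
               n_unl * c(0.64, 0.32, 0.04))

  # degenerate partitions
  amt1 <- partition_injection(inj, 1)
  expect_equal(unname(amt1[, c("half", "non")]), matrix(0, 2, 2))

  # specific activity above one label per molecule is rejected
  tiny <- injection(0, 1e-4, 130, nuclide("In111"))
  expect_error(partition_injection(tiny, 0.8), "specific activity")
})

test_that("binding fluxes obey conservation, saturation and equilibrium", {
  spec <- antibody_spec()
  expect_equal(binding_fluxes(1, 1, 1, 1, "non", spec),
               c(dF = 0, dM = 0, dB = 0))
  # every class conserves antibody within the binding step
  for (cl in c("full", "half", "non")) {
    fl <- binding_fluxes(0.7, 0.3, 0.2, 5, cl, spec, vol = 0.4)
    expect_equal(sum(fl), 0, tolerance = 1e-14)
  }
  # half-reactive equilibrium: M / (C * Ag_free) = k_on / k_off = 0.1 l/nmol
  Ka <- spec$k_on / spec$k_off
  expect_equal(Ka, 0.1)
  C <- 0.5; Agf <- 2; M_eq <- Ka * C * Agf
  fl <- binding_fluxes(C, M_eq, 0, Agf, "half", spec)
  expect_equal(fl[["dM"]], 0, tolerance = 1e-14)
  # saturation boundary: no free antigen, association off
  fl <- binding_fluxes(1, 0.5, 0.2, 0, "full", spec, vol = 0.4)
  expect_equal(fl[["dF"]], spec$k_off * 0.5)
  expect_equal(fl[["dB"]], -2 * spec$k_off * 0.2)
})

test_that("lossless system conserves antibody and the antigen ledger", {
  sys <- conservative_system()
  y0 <- initial_state(sys, ref_injection_pre(), r_im = 0.8)
  traj <- simulate_pbpk(sys, y0, c(0, 10, 100, 1000, 5000, 20000))
  tot <- rowSums(traj$y)
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-8)
  # antigen ledger: occupancy never exceeds the pool
  agf <- cd66pbpk:::.ag_free(sys, traj$y)
  expect_true(all(agf > -1e-8 * max(sys$Ag)))
})

test_that("physical decay only relabels: label sums match decay-free run", {
  th <- ref_theta()
  pool <- antigen_pool_model1(th[["Ag_L"]], th[["Ag_S"]])
  tg <- c(0, 60, 1440, 8640)
  inj <- ref_injection_pre()
  sys0 <- build_rhs(th, pool)                       # lambda_phys = 0
  sys1 <- build_rhs(th, pool, nuclide = inj$nuclide)
  y0 <- initial_state(sys0, inj, th[["r_im"]])
  tr0 <- simulate_pbpk(sys0, y0, tg)
  tr1 <- simulate_pbpk(sys1, y0, tg)
  si <- sys0$si
  for (nm_l in grep("\\.L(\\.|$)", si$names, value = TRUE)) {
    nm_u <- sub("\\.L", ".U", nm_l)
    expect_equal(tr1$y[, nm_l] + tr1$y[, nm_u],
                 tr0$y[, nm_l] + tr0$y[, nm_u],
                 tolerance = 1e-6)
  }
  # and labeled amounts are the decay-free ones times exp(-lambda t)
  decay <- exp(-inj$nuclide$lambda_phys * tg)
  expect_equal(tr1$y[, "P.L.full"], tr0$y[, "P.L.full"] * decay,
               tolerance = 1e-5)
})

test_that("r_im = 1 reduces to the single-species legacy model", {
  th <- ref_theta(); th[["r_im"]] <- 1
  pool <- antigen_pool_model1(th[["Ag_L"]], th[["Ag_S"]])
  sys <- build_rhs(th, pool)
  y0 <- initial_state(sys, ref_injection_pre(), 1)
  traj <- simulate_pbpk(sys, y0, c(0, 100, 2000, 20000))
  off <- grep("\\.(half|non)$", sys$si$names, value = TRUE)
  expect_true(all(abs(traj$y[, off]) < 1e-12))
})

test_that("linear limit matches the matrix-exponential closed form", {
  # Ag -> infinity with k_on * Ag / V fixed: scale antigen up, k_on down
  S <- 1e6
  th <- ref_theta()
  spec <- antibody_spec(k_on = 0.006 / S, k_off = 0.06)
  pool <- antigen_pool_model1(0.31 * S, 0.22 * S)
  sys <- build_rhs(th, pool, spec = spec)
  y0 <- initial_state(sys, ref_injection_pre(), th[["r_im"]])
  tg <- c(0, 30, 240, 1440, 8640)
  traj <- simulate_pbpk(sys, y0, tg, rtol = 1e-10, atol = 1e-14)

  A_lin <- sys$A
  for (r in seq_len(nrow(sys$assoc))) {
    i <- sys$assoc$i[r]; j <- sys$assoc$j[r]
    cAg <- sys$assoc$coef[r] * sys$Ag[sys$assoc$o[r]]
    A_lin[j, i] <- A_lin[j, i] + cAg
    A_lin[i, i] <- A_lin[i, i] - cAg
  }
  for (k in seq_along(tg)) {
    y_ref <- as.numeric(Matrix::expm(Matrix::Matrix(A_lin * tg[k])) %*% y0)
    sel <- abs(y_ref) > 1e-9 * sum(y0)
    expect_lt(max(abs(traj$y[k, sel] - y_ref[sel]) / abs(y_ref[sel])),
              5e-3)
  }
})

test_that("observables satisfy their boundary conventions", {
  th <- ref_theta()
  traj <- simulate_phase(th, 1, ref_injection_pre(), c(0, 5, 1440))
  obs <- observables(traj, c_RM = th[["c_RM"]])
  tb0 <- obs$value[obs$region == "total_body" & obs$time_min == 0]
  expect_equal(tb0, 1)
  ser0 <- obs$value[obs$region == "serum" & obs$time_min == 0]
  expect_equal(ser0, 1 / th[["V_serum"]])
  # c_RM = 1 gives the raw content fraction
  obs1 <- observables(traj, c_RM = 1, regions = "red_marrow")
  obs2 <- observables(traj, c_RM = 2, regions = "red_marrow")
  expect_equal(obs2$value, 2 * obs1$value)
  expect_error(observables(traj, regions = "kidney"), "unknown region")
})

test_that("saturation: organ bound fraction is non-increasing in amount", {
  th <- ref_theta()
  bound_frac <- function(mass_mg) {
    inj <- injection(0, mass_mg, 10, nuclide("In111"))
    traj <- simulate_phase(th, 1, inj, c(0, 1440), rtol = 1e-7)
    cols <- grep("^(M|B)_RM\\.", colnames(traj$y), value = TRUE)
    sum(traj$y[2, cols]) / mg_to_nmol(mass_mg)
  }
  fr <- vapply(c(0.5, 2, 8, 32, 128), bound_frac, numeric(1))
  expect_true(all(diff(fr) < 1e-10))
})

test_that("simulate contract: zero state, monotone grid, refinement", {
  sys <- conservative_system()
  y0 <- setNames(numeric(sys$si$n), sys$si$names)
  tr <- simulate_pbpk(sys, y0, c(0, 10, 100))
  expect_true(all(tr$y == 0))
  expect_error(simulate_pbpk(sys, y0, c(0, 10, 10)), "increasing")

  th <- ref_theta()
  tg <- c(0, 30, 240, 2880, 20000)
  t1 <- simulate_phase(th, 1, ref_injection_pre(), tg, rtol = 1e-6,
                       atol = 1e-10)
  t2 <- simulate_phase(th, 1, ref_injection_pre(), tg, rtol = 5e-7,
                       atol = 5e-11)
  o1 <- observables(t1, c_RM = 1); o2 <- observables(t2, c_RM = 1)
  sel <- o2$value > 1e-6
  expect_lt(max(abs(o1$value[sel] - o2$value[sel]) / o2$value[sel]), 1e-3)
})
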