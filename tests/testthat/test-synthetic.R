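# virtual-patient generator: determinism, distributions, schedules

test_that("sampling is deterministic and respects truncation bounds", {
  pop <- population_spec()
  a <- sample_patient(pop, 7)
  b <- sample_patient(pop, 7)
  expect_identical(a$theta, b$theta)
  expect_identical(a$injections, b$injections)

  for (k in 1:15) {
    vp <- sample_patient(pop, 100 + k)
    pr <- pop$params
    expect_true(all(vp$theta >= pr$lo & vp$theta <= pr$hi))
    # pool is derived, never sampled: bit-exact constraint identity
    expect_identical(vp$pool$Ag_B,
                     (vp$theta[["Ag_L"]] + vp$theta[["Ag_S"]]) / 0.9)
    expect_identical(vp$pool$Ag_RM, 38 * vp$pool$Ag_B)
  }

  # zero dispersion collapses to the population means
  pop0 <- population_spec()
  pop0$params$sd[] <- 0
  p0 <- pop0$physiology
  p0$bsa_sd <- 0; p0$hct_sd <- 0; p0$vol_ratio_cv <- 0
  pop0$physiology <- p0
  vp0 <- sample_patient(pop0, 3)
  expect_equal(unname(vp0$theta), pop0$params$mean)

  # infeasible truncation errors out
  bad <- population_spec()
  bad$params$mean[1] <- 50
  expect_error(sample_patient(bad, 1), "infeasible truncation")
})

test_that("r_im draws match the truncated-normal mean oracle", {
  pop <- population_spec()
  pr <- pop$params[pop$params$name == "r_im", ]
  set.seed(123)
  draws <- cd66pbpk:::.rtruncnorm(1000, pr$mean, pr$sd, pr$lo, pr$hi)
  m_oracle <- cd66pbpk:::.truncnorm_mean(pr$mean, pr$sd, pr$lo, pr$hi)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_oracle), 3 * se)
  expect_true(all(draws >= pr$lo & draws <= pr$hi))
})

test_that("multiplicative lognormal noise has the configured CV", {
  sdlog <- sqrt(log(1 + 0.10^2))
  set.seed(99)
  mult <- exp(rnorm(10000, -sdlog^2 / 2, sdlog))
  expect_lt(abs(sd(mult) / mean(mult) - 0.10) / 0.10, 0.05)
  expect_lt(abs(mean(mult) - 1), 0.01) # mean-preserving
})

test_that("generated datasets honour schedules, noise flag and schema", {
  pop <- population_spec()
  vp <- sample_patient(pop, 55)
  ds0 <- generate_dataset(vp, pop, seed = 56, noise = FALSE,
                          therapy_template = "C")
  ds1 <- generate_dataset(vp, pop, seed = 56, noise = TRUE,
                          therapy_template = "C")
  expect_length(validate_dataset(ds0), 0)
  m0 <- ds0$measurements; m1 <- ds1$measurements
  expect_identical(m0[c("phase", "region", "time_min")],
                   m1[c("phase", "region", "time_min")])
  expect_false(any(m0$value == m1$value))
  expect_true(all(m1$value > 0))

  img <- m0[m0$phase == "pre" & m0$region == "liver", "time_min"]
  expect_equal(img, c(2, 4, 24, 48, 72, 144) * 60)
  ser <- m0[m0$phase == "pre" & m0$region == "serum", "time_min"]
  expect_equal(ser, c(5, 30, 60, 120, 240, 1440, 2880, 4320, 8640))
  ther <- m0[m0$phase == "therapy", "time_min"]
  expect_equal(ther, pop$therapy_time_min +
                 c(5, 15, 30, 60, 120, 240, 1440, 2880))

  # bolus limit: noise-free 5-min serum close to 1 / V_serum
  s5 <- m0$value[m0$phase == "pre" & m0$region == "serum" &
                   m0$time_min == 5]
  expect_equal(s5, 1 / vp$theta[["V_serum"]], tolerance = 0.15)
})

test_that("cohort seed streams are disjoint from cohort size", {
  pop <- population_spec()
  c3 <- make_cohort(3, pop, seed = 5)
  c5 <- make_cohort(5, pop, seed = 5)
  for (k in 1:3) {
    expect_identical(c3$patients[[k]]$theta, c5$patients[[k]]$theta)
    expect_identical(c3$datasets[[k]]$measurements,
                     c5$datasets[[k]]$measurements)
  }
  expect_equal(nrow(c5$truth), 5)
  pr <- pop$params
  for (p in pr$name)
    expect_true(all(c5$truth[[p]] >= pr$lo[pr$name == p] &
                      c5$truth[[p]] <= pr$hi[pr$name == p]))
})
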