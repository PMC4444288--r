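# Virtual-patient generation.
#
# The generating population reproduces the statistical structure the
# analysis assumes: cohort dispersion of the adjustable parameters
# (independent truncated normals within the fitting bounds), the
# administered amounts of the two phases, the standard sampling schedules,
# and multiplicative lognormal measurement noise.

# exact truncated-normal sampling by inverse CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12)
    stop(sprintf("infeasible truncation: N(%g, %g) on [%g, %g]",
                 mean, sd, lo, hi))
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# closed-form mean of the truncated normal (oracle for tests)
.truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Population specification for virtual patients
#'
#' Defaults encode the cohort this model is calibrated for: parameter means
#' and SDs at the scale reported for 27 leukemia patients, administered
#' amounts of (0.5 +/- 0.1) mg with (130 +/- 16) MBq In-111 pre-therapy and
#' (1.3 +/- 0.5) mg with (3.2 +/- 0.9) GBq Y-90 for therapy, the standard
#' imaging/serum schedules, and 10% imaging / 5% serum fractional noise.
#' Physiology distributions (body surface area, hematocrit, organ-volume
#' enlargement) are package choices documented in the methods vignette.
#'
#' @param overrides named list replacing any top-level element.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(overrides = list()) {
  params <- data.frame(
    name = .PARAM_NAMES,
    mean = c(0.31, 0.22, 0.235, 0.107, 0.0067, 1.22, 6.8e-5, 0.801, 2.99),
    sd   = c(0.26, 0.19, 0.089, 0.048, 0.0021, 0.33, 1.7e-5, 0.090, 0.62),
    lo   = c(0.001, 0.001, 0, 0, 1e-4, 0.5, 1e-5, 0.5, 1),
    hi   = c(2, 2, 1, 1, 0.1, 3, 1e-4, 1.0, 10),
    stringsAsFactors = FALSE
  )
  spec <- list(
    params = params,
    constraint_model = 1L,
    injections = list(
      pre = list(mass_mean = 0.5, mass_sd = 0.1, mass_lo = 0.2, mass_hi = 1,
                 act_mean = 130, act_sd = 16, act_lo = 60, act_hi = 250,
                 nuclide = "In111"),
      therapy = list(mass_mean = 1.3, mass_sd = 0.5, mass_lo = 0.4,
                     mass_hi = 3.5, act_mean = 3200, act_sd = 900,
                     act_lo = 1000, act_hi = 6000, nuclide = "Y90")
    ),
    therapy_time_min = 11520, # 192 h after the pre-therapeutic injection
    physiology = list(bsa_mean = 1.9, bsa_sd = 0.2, bsa_lo = 1.4,
                      bsa_hi = 2.6, hct_mean = 0.38, hct_sd = 0.05,
                      hct_lo = 0.20, hct_hi = 0.55, p_male = 0.5,
                      V_calc_L = 1.8, V_calc_S = 0.2,
                      vol_ratio_cv = 0.25),
    noise = list(fsd_imaging = 0.10, fsd_serum = 0.05),
    schedules = list(
      pre_imaging = c(2, 4, 24, 48, 72, 144) * 60,
      pre_serum = c(5, 30, 60, 120, 240, 1440, 2880, 4320, 8640),
      therapy_serum = list(
        A = c(5, 30, 60, 120, 240, 1440, 2880),
        B = c(5, 30, 120, 240, 1440),
        C = c(5, 15, 30, 60, 120, 240, 1440, 2880),
        D = c(5, 60, 1440, 2880)
      )
    )
  )
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(spec))
    if (length(unknown))
      stop("unknown population_spec element(s): ",
           paste(unknown, collapse = ", "))
    spec <- modifyList(spec, overrides)
  }
  structure(spec, class = "population_spec")
}

#' Sample one virtual patient's ground truth
#'
#' Draws the nine adjustable parameters from truncated normals within their
#' bounds, the physiology block, and both injections; the blood and red
#' marrow antigen amounts are derived through the chosen constraint model,
#' never sampled independently.
#'
#' @param pop a [population_spec()].
#' @param seed integer seed (same seed, same patient).
#' @param patient_id identifier for the generated records.
#' @return Object of class `virtual_patient` with `theta` (truth parameters),
#'   `pool`, `physiology`, `injections`, `constraint_model`, `seed`.
#' @export
sample_patient <- function(pop, seed, patient_id = sprintf("VP%04d", seed)) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(as.integer(seed))
  pr <- pop$params
  theta <- setNames(vapply(seq_len(nrow(pr)), function(i)
    .rtruncnorm(1, pr$mean[i], pr$sd[i], pr$lo[i], pr$hi[i]), numeric(1)),
    pr$name)

  ph <- pop$physiology
  sdlog <- sqrt(log(1 + ph$vol_ratio_cv^2))
  ratio_L <- exp(rnorm(1, -sdlog^2 / 2, sdlog))
  ratio_S <- exp(rnorm(1, -sdlog^2 / 2, sdlog))
  phys <- patient_physiology(
    sex = if (rbinom(1, 1, ph$p_male) == 1) "male" else "female",
    body_surface_area = .rtruncnorm(1, ph$bsa_mean, ph$bsa_sd, ph$bsa_lo,
                                    ph$bsa_hi),
    hematocrit = .rtruncnorm(1, ph$hct_mean, ph$hct_sd, ph$hct_lo,
                             ph$hct_hi),
    V_MRI_L = ratio_L * ph$V_calc_L, V_MRI_S = ratio_S * ph$V_calc_S,
    V_calc_L = ph$V_calc_L, V_calc_S = ph$V_calc_S)

  draw_inj <- function(spec, time_min) {
    mass <- .rtruncnorm(1, spec$mass_mean, spec$mass_sd, spec$mass_lo,
                        spec$mass_hi)
    act <- .rtruncnorm(1, spec$act_mean, spec$act_sd, spec$act_lo,
                       spec$act_hi)
    # keep specific activity below one label per molecule
    n_tot <- mg_to_nmol(mass)
    n_lab <- activity_to_nmol(act, nuclide(spec$nuclide))
    if (n_lab > 0.95 * n_tot) act <- act * 0.95 * n_tot / n_lab
    data.frame(time_min = time_min, amount_mg = mass, activity_MBq = act,
               nuclide = spec$nuclide)
  }
  inj <- rbind(cbind(phase = "pre", draw_inj(pop$injections$pre, 0)),
               cbind(phase = "therapy",
                     draw_inj(pop$injections$therapy, pop$therapy_time_min)))

  pool <- if (pop$constraint_model == 1) {
    antigen_pool_model1(theta[["Ag_L"]], theta[["Ag_S"]])
  } else {
    antigen_pool_model2(theta[["Ag_L"]], theta[["Ag_S"]], phys)
  }
  structure(list(patient_id = patient_id, theta = theta, pool = pool,
                 physiology = phys, injections = inj,
                 constraint_model = pop$constraint_model, seed = seed),
            class = "virtual_patient")
}

#' Generate a noisy measurement dataset from a virtual patient
#'
#' Simulates the truth trajectories at the schedule times and applies
#' independent multiplicative lognormal noise with the configured fractional
#' SD per measurement type (mean-preserving: `E[noisy] = truth`).
#'
#' @param patient a [sample_patient()] result.
#' @param pop the [population_spec()] (schedules and noise levels).
#' @param seed integer seed for the noise stream.
#' @param therapy_template which therapy serum schedule template to use
#'   (`"A"`, `"B"`, `"C"`, `"D"`), or `NULL` to pick by patient seed.
#' @param noise logical; `FALSE` returns noise-free observables.
#' @param include_therapy include the therapy-phase serum series.
#' @param rtol,atol solver tolerances.
#' @return A validated `patient_dataset` with provenance recording the seeds
#'   and the truth parameters.
#' @export
generate_dataset <- function(patient, pop = population_spec(), seed,
                             therapy_template = NULL, noise = TRUE,
                             include_therapy = TRUE, rtol = 1e-8,
                             atol = 1e-12) {
  stopifnot(inherits(patient, "virtual_patient"))
  ds_inj <- patient$injections
  th <- patient$theta
  fsd_i <- pop$noise$fsd_imaging
  fsd_s <- pop$noise$fsd_serum

  sched_img <- pop$schedules$pre_imaging
  sched_ser <- pop$schedules$pre_serum
  t_ther <- ds_inj$time_min[ds_inj$phase == "therapy"]

  inj_pre <- injection(0, ds_inj$amount_mg[1], ds_inj$activity_MBq[1],
                       nuclide(ds_inj$nuclide[1]))
  tgrid <- sort(unique(c(0, sched_img, sched_ser, t_ther)))
  traj <- simulate_phase(th, patient$constraint_model, inj_pre, tgrid,
                         physiology = patient$physiology, rtol = rtol,
                         atol = atol)
  obs <- observables(traj, c_RM = th[["c_RM"]])
  val_at <- function(region, times)
    obs$value[match(paste(region, times), paste(obs$region, obs$time_min))]

  rows <- list()
  for (rg in c("red_marrow", "liver", "spleen", "total_body"))
    rows[[rg]] <- data.frame(phase = "pre", region = rg,
                             time_min = sched_img,
                             value = val_at(rg, sched_img),
                             fractional_sd = fsd_i)
  rows$serum <- data.frame(phase = "pre", region = "serum",
                           time_min = sched_ser,
                           value = val_at("serum", sched_ser),
                           fractional_sd = fsd_s)

  if (include_therapy) {
    set.seed(as.integer(seed) + 1L)
    if (is.null(therapy_template))
      therapy_template <- sample(names(pop$schedules$therapy_serum), 1)
    sched_t <- pop$schedules$therapy_serum[[therapy_template]]
    inj_ther <- injection(t_ther, ds_inj$amount_mg[2],
                          ds_inj$activity_MBq[2], nuclide(ds_inj$nuclide[2]))
    carry <- .carryover_state(traj$y[match(t_ther, traj$times), ])
    traj2 <- simulate_phase(th, patient$constraint_model, inj_ther,
                            t_ther + sort(unique(c(0, sched_t))),
                            physiology = patient$physiology,
                            carry_state = carry, rtol = rtol, atol = atol)
    obs2 <- observables(traj2, c_RM = th[["c_RM"]], regions = "serum")
    sel <- match(t_ther + sched_t, obs2$time_min)
    rows$therapy <- data.frame(phase = "therapy", region = "serum",
                               time_min = t_ther + sched_t,
                               value = obs2$value[sel],
                               fractional_sd = fsd_s)
  }
  meas <- do.call(rbind, c(rows, make.row.names = FALSE))

  if (noise) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + meas$fractional_sd^2))
    meas$value <- meas$value *
      exp(rnorm(nrow(meas), -sdlog^2 / 2, sdlog))
  }

  patient_dataset(patient$patient_id, patient$physiology, ds_inj, meas,
                  provenance = list(
                    generator = "cd66pbpk::generate_dataset",
                    synthetic = TRUE, seed = seed,
                    patient_seed = patient$seed,
                    therapy_template = if (include_therapy)
                      therapy_template else NA,
                    truth = as.list(patient$theta),
                    rng = "Mersenne-Twister"))
}

# per-patient seed derivation: disjoint, independent of cohort size
.patient_seed <- function(master_seed, k) {
  (as.integer(master_seed) %% 1000003L) * 2000L + 2L * as.integer(k)
}

#' Generate a cohort of virtual patients
#'
#' @param n number of patients (>= 1).
#' @param pop a [population_spec()].
#' @param seed master seed; patient `k`'s seeds are derived from it and do
#'   not depend on `n`.
#' @param ... passed to [generate_dataset()].
#' @return list with `datasets` (list of `patient_dataset`), `patients`
#'   (the truth objects) and `truth` (data.frame ledger of generating
#'   parameters, one row per patient).
#' @export
make_cohort <- function(n, pop = population_spec(), seed = 1L, ...) {
  stopifnot(n >= 1)
  patients <- list(); datasets <- list(); truth <- list()
  for (k in seq_len(n)) {
    ps <- .patient_seed(seed, k)
    vp <- sample_patient(pop, ps, patient_id = sprintf("VP%03d", k))
    ds <- generate_dataset(vp, pop, seed = ps + 1L, ...)
    patients[[k]] <- vp
    datasets[[k]] <- ds
    truth[[k]] <- data.frame(patient_id = vp$patient_id, seed = ps,
                             t(vp$theta), Ag_B = vp$pool$Ag_B,
                             Ag_RM = vp$pool$Ag_RM,
                             constraint_model = vp$constraint_model)
  }
  list(datasets = datasets, patients = patients,
       truth = do.call(rbind, truth))
}
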