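# Time-integrated activity coefficients (TACs) and therapy prediction.
#
# Measured series are decay-corrected, so simulations run the decay-free
# system and the physical decay of the relevant nuclide is applied
# analytically inside the time integral:
#   a~ = Int_0^T obs(t) exp(-lambda_phys (t - t0)) dt   (reported in hours).

# dense output grid for quadrature: geometric early refinement + linear tail
.tac_grid <- function(t0, horizon, n = 400) {
  g <- unique(c(0, exp(seq(log(0.5), log(horizon), length.out = n - 60)),
                seq(0, horizon, length.out = 60)))
  t0 + sort(unique(round(g, 6)))
}

# integral of obs * exp(-lambda (t - t0)) via corrected trapezoid on the
# trajectory's value/derivative columns (exact for cubic Hermite data)
.hermite_decay_integral <- function(times, value, deriv, lambda, t0) {
  g <- value * exp(-lambda * (times - t0))
  gp <- (deriv - lambda * value) * exp(-lambda * (times - t0))
  h <- diff(times)
  n <- length(times)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  sum(h / 2 * (g[i1] + g[i2]) + h^2 / 12 * (gp[i1] - gp[i2]))
}

#' Time-integrated activity coefficient for one region
#'
#' Integrates the decay-corrected observable times the physical-decay factor
#' of `nuclide` from `t_start` over `horizon` minutes, on the trajectory's
#' dense (value + derivative) output; a grid-coarsening Richardson estimate
#' of the quadrature error is attached as attribute `"quad_error"`.
#'
#' @param traj a `pbpk_trajectory` covering `[t_start, t_start + horizon]`
#'   densely (use [.tac_grid] times when simulating).
#' @param region one of `red_marrow`, `liver`, `spleen`, `total_body`,
#'   `serum`.
#' @param nuclide a [nuclide_spec()] supplying the decay constant.
#' @param t_start integration start (min); defaults to the trajectory start.
#' @param horizon integration span (min), default 20000.
#' @param c_RM red-marrow scaling correction for the observable.
#' @param n_lab labeled amount basis; defaults to the trajectory's.
#' @return a~ in hours.
#' @export
tac <- function(traj, region, nuclide, t_start = traj$times[1],
                horizon = 20000, c_RM = 1, n_lab = traj$n_lab) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  if (t_start + horizon > max(traj$times) + 1e-6 || t_start < traj$times[1])
    stop("trajectory does not cover the integration horizon")
  obs <- observables(traj, c_RM = c_RM, n_lab = n_lab, regions = region)
  sel <- obs$time_min >= t_start - 1e-9 &
    obs$time_min <= t_start + horizon + 1e-9
  tt <- obs$time_min[sel]; v <- obs$value[sel]; d <- obs$deriv[sel]
  lam <- nuclide$lambda_phys
  I <- .hermite_decay_integral(tt, v, d, lam, t_start)
  coarse <- seq(1, length(tt), by = 2)
  if (length(tt) %% 2 == 0) coarse <- c(coarse, length(tt))
  I2 <- .hermite_decay_integral(tt[coarse], v[coarse], d[coarse], lam,
                                t_start)
  out <- I / 60
  attr(out, "quad_error") <- abs(I - I2) / 15 / 60
  out
}

# simulate the pre-therapy phase densely for TAC integration
.simulate_pre_dense <- function(theta, model_id, dataset, horizon = 20000,
                                spec = antibody_spec(),
                                fixed = fixed_defaults(), rtol = 1e-6,
                                atol = 1e-10, n_grid = 400) {
  inj <- .get_injection(dataset, "pre")
  simulate_phase(theta, model_id, inj, .tac_grid(0, horizon, n_grid),
                 physiology = dataset$physiology, spec = spec, fixed = fixed,
                 rtol = rtol, atol = atol)
}

# simulate the therapy phase: pre-phase to the therapy time, carry the
# surviving antibody forward as unlabeled, inject the therapeutic amount
.simulate_therapy_dense <- function(theta, model_id, dataset,
                                    horizon = 20000, carryover = TRUE,
                                    spec = antibody_spec(),
                                    fixed = fixed_defaults(), rtol = 1e-6,
                                    atol = 1e-10, n_grid = 400) {
  th <- setNames(as.numeric(theta), .PARAM_NAMES)
  inj_pre <- .get_injection(dataset, "pre")
  inj_ther <- .get_injection(dataset, "therapy")
  t_ther <- inj_ther$time_min
  carry <- NULL
  if (carryover) {
    pre <- simulate_phase(th, model_id, inj_pre, c(0, t_ther),
                          physiology = dataset$physiology, spec = spec,
                          fixed = fixed, rtol = rtol, atol = atol)
    carry <- .carryover_state(pre$y[nrow(pre$y), ])
  }
  traj <- simulate_phase(th, model_id, inj_ther,
                         .tac_grid(t_ther, horizon, n_grid),
                         physiology = dataset$physiology,
                         carry_state = carry, spec = spec, fixed = fixed,
                         rtol = rtol, atol = atol)
  list(traj = traj, t_start = t_ther, nuclide = inj_ther$nuclide)
}

# TACs for all regions of a dense phase simulation
.tacs_of <- function(traj, t_start, nuclide, c_RM, horizon = 20000) {
  vapply(.REGIONS, function(r)
    as.numeric(tac(traj, r, nuclide, t_start = t_start, horizon = horizon,
                   c_RM = c_RM)), numeric(1))
}

# delta-method SEs of the per-region TACs given the fit covariance
.tac_se <- function(theta, cov, simulate_fn, horizon) {
  base <- simulate_fn(theta)
  tac0 <- .tacs_of(base$traj, base$t_start, base$nuclide,
                   theta[["c_RM"]], horizon)
  G <- matrix(0, length(.REGIONS), length(theta),
              dimnames = list(.REGIONS, names(theta)))
  for (k in seq_along(theta)) {
    h <- max(1e-4 * abs(theta[k]), 1e-8)
    th2 <- theta; th2[k] <- th2[k] + h
    s2 <- simulate_fn(th2)
    G[, k] <- (.tacs_of(s2$traj, s2$t_start, s2$nuclide, th2[["c_RM"]],
                        horizon) - tac0) / h
  }
  se <- sqrt(pmax(rowSums((G %*% cov) * G), 0))
  list(tac = tac0, se = se)
}

#' Pre-therapy TAC table from a fit
#'
#' Simulates the pre-therapeutic injection with the fitted parameters and
#' integrates every region over the horizon with the chosen nuclide's decay.
#' By default the pre-therapy nuclide (In-111) is used; passing the therapy
#' nuclide gives the "equal biodistribution" re-decayed convention.
#'
#' @param fit a `pbpk_fit` from pre-therapy data.
#' @param dataset the patient dataset.
#' @param nuclide decay to apply (default: the pre-therapy injection's).
#' @param horizon integration span (min).
#' @param compute_se propagate the parameter covariance (delta method).
#' @param tag tag stored in the table.
#' @return data.frame `region`, `a_h`, `se_h`, `tag`, `model_id`.
#' @export
tac_table_pre <- function(fit, dataset, nuclide = NULL, horizon = 20000,
                          compute_se = TRUE, tag = "pre_therapy") {
  stopifnot(inherits(fit, "pbpk_fit"))
  if (is.null(nuclide)) nuclide <- .get_injection(dataset, "pre")$nuclide
  theta <- fit$estimates
  simfn <- function(th) list(
    traj = .simulate_pre_dense(th, fit$model_id, dataset, horizon,
                               spec = fit$problem$spec,
                               fixed = fit$problem$fixed),
    t_start = 0, nuclide = nuclide)
  if (compute_se) {
    res <- .tac_se(theta, fit$covariance, simfn, horizon)
    a <- res$tac; se <- res$se
  } else {
    s <- simfn(theta)
    a <- .tacs_of(s$traj, 0, nuclide, theta[["c_RM"]], horizon)
    se <- rep(NA_real_, length(a))
  }
  data.frame(region = .REGIONS, a_h = as.numeric(a), se_h = as.numeric(se),
             tag = tag, model_id = fit$model_id, row.names = NULL)
}

#' Predict the therapeutic biodistribution from pre-therapy fits
#'
#' For each constraint-model fit: simulates the pre-therapeutic injection up
#' to the therapy time, carries all surviving antibody forward as unlabeled
#' (the pre-therapy label contributes no therapeutic activity but keeps
#' occupying antigen), injects the recorded therapeutic amount partitioned by
#' the fitted immunoreactivity with the therapy label, and integrates the
#' TACs from the therapy time. Per-model tables are combined with Akaike
#' weights.
#'
#' @param fits list of `pbpk_fit` objects (pre-therapy fits; one per model).
#' @param dataset patient dataset with a therapy injection record.
#' @param horizon integration span (min).
#' @param carryover include residual pre-therapy antibody (default TRUE).
#' @param compute_se propagate parameter covariance per model.
#' @return list with `tac_table` (Akaike-averaged, tag `"prediction"`),
#'   `per_model` tables, `weights`, and `serum` (the predicted therapeutic
#'   serum observable series per model).
#' @export
predict_therapy <- function(fits, dataset, horizon = 20000, carryover = TRUE,
                            compute_se = TRUE) {
  if (inherits(fits, "pbpk_fit")) fits <- list(fits)
  if (!"therapy" %in% dataset$injections$phase)
    stop("missing therapy injection record")
  w <- akaike_weights(vapply(fits, function(f) f$aic, numeric(1)))
  per_model <- list(); serum <- list()
  for (f in fits) {
    simfn <- function(th) .simulate_therapy_dense(
      th, f$model_id, dataset, horizon, carryover = carryover,
      spec = f$problem$spec, fixed = f$problem$fixed)
    theta <- f$estimates
    if (compute_se) {
      res <- .tac_se(theta, f$covariance, simfn, horizon)
      a <- res$tac; se <- res$se
      s <- simfn(theta)
    } else {
      s <- simfn(theta)
      a <- .tacs_of(s$traj, s$t_start, s$nuclide, theta[["c_RM"]], horizon)
      se <- rep(NA_real_, length(a))
    }
    per_model[[as.character(f$model_id)]] <-
      data.frame(region = .REGIONS, a_h = as.numeric(a),
                 se_h = as.numeric(se), tag = "prediction",
                 model_id = f$model_id, row.names = NULL)
    serum[[as.character(f$model_id)]] <-
      observables(s$traj, c_RM = theta[["c_RM"]], regions = "serum")
  }
  avg <- per_model[[1]][c("region", "tag")]
  comb <- lapply(seq_along(.REGIONS), function(i) model_average(
    vapply(per_model, function(t) t$a_h[i], numeric(1)),
    vapply(per_model, function(t) if (all(is.finite(t$se_h))) t$se_h[i]
           else 0, numeric(1)),
    w))
  avg$a_h <- vapply(comb, `[[`, numeric(1), "value")
  avg$se_h <- vapply(comb, `[[`, numeric(1), "se")
  avg$averaged <- TRUE
  list(tac_table = avg, per_model = per_model, weights = w, serum = serum)
}

#' Reference therapy TACs from a joint fit
#'
#' Fits the model (model 2 by convention) simultaneously to the pre-therapy
#' and therapy data, then integrates the fitted therapeutic curves.
#'
#' @param dataset patient dataset with therapy serum measurements.
#' @param model_id constraint model used for the joint fit (default 2).
#' @param horizon integration span (min).
#' @param n_starts,seed,maxit passed to [fit_pbpk()].
#' @param compute_se propagate the joint-fit covariance.
#' @param ... further arguments to [fit_problem()].
#' @return list with `fit` (the joint `pbpk_fit`) and `tac_table`
#'   (tag `"therapy"`).
#' @export
fit_therapy_reference <- function(dataset, model_id = 2, horizon = 20000,
                                  n_starts = 3, seed = 1L, maxit = 60,
                                  compute_se = TRUE, ...) {
  if (!any(dataset$measurements$phase == "therapy"))
    stop("dataset has no therapy measurements")
  prob <- fit_problem(dataset, model_id = model_id,
                      include_therapy_data = TRUE, ...)
  fit <- fit_pbpk(prob, n_starts = n_starts, seed = seed, maxit = maxit)
  theta <- fit$estimates
  simfn <- function(th) .simulate_therapy_dense(
    th, model_id, dataset, horizon, spec = prob$spec, fixed = prob$fixed)
  if (compute_se) {
    res <- .tac_se(theta, fit$covariance, simfn, horizon)
    a <- res$tac; se <- res$se
  } else {
    s <- simfn(theta)
    a <- .tacs_of(s$traj, s$t_start, s$nuclide, theta[["c_RM"]], horizon)
    se <- rep(NA_real_, length(a))
  }
  list(fit = fit,
       tac_table = data.frame(region = .REGIONS, a_h = as.numeric(a),
                              se_h = as.numeric(se), tag = "therapy",
                              model_id = model_id, row.names = NULL))
}

#' Relative deviation of predicted vs reference TAC
#'
#' `RD = (a_pred - a_ther) / a_ther`.
#'
#' @param a_pred predicted TAC (h).
#' @param a_ther reference (therapy-fitted) TAC (h), > 0.
#' @return fractional relative deviation.
#' @export
relative_deviation <- function(a_pred, a_ther) {
  if (any(!is.finite(a_ther)) || any(a_ther <= 0))
    stop("a_ther must be positive")
  (a_pred - a_ther) / a_ther
}

#' Cohort roll-up of per-patient TAC tables
#'
#' @param tables data.frame with columns `patient_id`, `region`, `tag`
#'   (`pre_therapy` / `prediction` / `therapy`), `a_h`.
#' @return data.frame per region with mean and SD of each tag's TAC and of
#'   the per-patient ratios `pre/therapy` and `prediction/therapy` (ratios
#'   averaged per patient, not ratios of means).
#' @export
cohort_summary <- function(tables) {
  stopifnot(all(c("patient_id", "region", "tag", "a_h") %in% names(tables)))
  out <- list()
  for (rg in unique(tables$region)) {
    t_r <- tables[tables$region == rg, ]
    row <- list(region = rg)
    for (tg in c("pre_therapy", "prediction", "therapy")) {
      v <- t_r$a_h[t_r$tag == tg]
      row[[paste0(tg, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(tg, "_sd")]] <- if (length(v) > 1) sd(v) else 0
    }
    wide <- Reduce(function(a, b) merge(a, b, by = "patient_id"), list(
      setNames(t_r[t_r$tag == "pre_therapy", c("patient_id", "a_h")],
               c("patient_id", "pre")),
      setNames(t_r[t_r$tag == "prediction", c("patient_id", "a_h")],
               c("patient_id", "pred")),
      setNames(t_r[t_r$tag == "therapy", c("patient_id", "a_h")],
               c("patient_id", "ther"))))
    if (nrow(wide)) {
      row$ratio_pre_ther_mean <- mean(wide$pre / wide$ther)
      row$ratio_pre_ther_sd <- if (nrow(wide) > 1)
        sd(wide$pre / wide$ther) else 0
      row$ratio_pred_ther_mean <- mean(wide$pred / wide$ther)
      row$ratio_pred_ther_sd <- if (nrow(wide) > 1)
        sd(wide$pred / wide$ther) else 0
    }
    out[[rg]] <- as.data.frame(row)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
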