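# Weighted least-squares estimation of the nine adjustable parameters.

.PARAM_NAMES <- c("Ag_L", "Ag_S", "ex_l", "ex_s", "f_RM", "c_RM",
                  "lambda_db", "r_im", "V_serum")

#' Default initial values and bounds for the adjustable parameters
#'
#' `f_RM` is handled as a fraction internally (the conventional tabulation is
#' in percent); `V_serum` defaults to the patient's dilution-volume estimate
#' `V_m1` ("individual" initial value) at fit time.
#'
#' @param r_im_upper individual upper limit for the immunoreactivity
#'   (default 1).
#' @return list with numeric vectors `init`, `lower`, `upper`.
#' @export
default_fit_setup <- function(r_im_upper = 1.0) {
  init <- c(Ag_L = 0.15, Ag_S = 0.15, ex_l = 0.19, ex_s = 0.04,
            f_RM = 0.03, c_RM = 1.0, lambda_db = 7e-5, r_im = 0.9,
            V_serum = NA_real_)
  lower <- c(Ag_L = 0.001, Ag_S = 0.001, ex_l = 0, ex_s = 0, f_RM = 1e-4,
             c_RM = 0.5, lambda_db = 1e-5, r_im = 0.5, V_serum = 1)
  upper <- c(Ag_L = 2, Ag_S = 2, ex_l = 1, ex_s = 1, f_RM = 0.1,
             c_RM = 3, lambda_db = 1e-4, r_im = r_im_upper, V_serum = 10)
  list(init = init, lower = lower, upper = upper)
}

#' Define a fit problem
#'
#' Packages a patient dataset with the constraint model, weighting scheme,
#' initial values and bounds into the object consumed by [fit_pbpk()].
#'
#' @param dataset a `patient_dataset` (see [patient_dataset()]).
#' @param model_id antigen constraint model, 1 or 2.
#' @param include_therapy_data if `TRUE`, the therapy-phase serum
#'   measurements enter the objective (joint fit).
#' @param fsd fractional standard deviations by measurement type; imaging
#'   applies to the gamma-camera regions, serum to serum samples.
#' @param init,lower,upper optional overrides of [default_fit_setup()]
#'   (named, any subset).
#' @param r_im_upper individual upper immunoreactivity limit.
#' @param prior_weight multiplier on the squared serum-volume prior penalty
#'   (1 = standard Bayesian term, 0 = no prior).
#' @param fixed fixed constants, see [fixed_defaults()].
#' @param spec an [antibody_spec()].
#' @param rtol,atol solver tolerances used inside the objective.
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(dataset, model_id = 1, include_therapy_data = FALSE,
                        fsd = c(imaging = 0.10, serum = 0.05),
                        init = NULL, lower = NULL, upper = NULL,
                        r_im_upper = 1.0, prior_weight = 1,
                        fixed = fixed_defaults(),
                        spec = antibody_spec(), rtol = 1e-5, atol = 1e-9) {
  stopifnot(inherits(dataset, "patient_dataset"), model_id %in% c(1, 2))
  setup <- default_fit_setup(r_im_upper)
  override <- function(base, x) {
    if (!is.null(x)) base[names(x)] <- x
    base
  }
  setup$init <- override(setup$init, init)
  setup$lower <- override(setup$lower, lower)
  setup$upper <- override(setup$upper, upper)

  pre <- dataset$measurements[dataset$measurements$phase == "pre", ]
  if (!nrow(pre)) stop("dataset has no pre-therapy measurements")
  ther <- dataset$measurements[dataset$measurements$phase == "therapy", ]
  if (include_therapy_data && !nrow(ther))
    stop("joint fit requested but dataset has no therapy measurements")

  # serum-volume prior from the first pre-therapy serum sample
  ser <- pre[pre$region == "serum", ]
  if (!nrow(ser)) stop("dataset has no pre-therapy serum measurements")
  first <- ser[which.min(ser$time_min), ]
  prior <- serum_volume_prior(1, first$value, dataset$physiology)
  if (is.na(setup$init[["V_serum"]]))
    setup$init[["V_serum"]] <- min(max(prior$V_m1, setup$lower[["V_serum"]]),
                                   setup$upper[["V_serum"]])

  structure(
    list(dataset = dataset, model_id = model_id,
         include_therapy_data = include_therapy_data, fsd = fsd,
         init = setup$init, lower = setup$lower, upper = setup$upper,
         prior = prior, prior_weight = prior_weight, fixed = fixed,
         spec = spec, rtol = rtol, atol = atol),
    class = "fit_problem"
  )
}

# weighted residual vector (data residuals, then the prior residual)
.fit_residuals <- function(theta, problem, with_prior = TRUE) {
  ds <- problem$dataset
  th <- setNames(as.numeric(theta), .PARAM_NAMES)
  pre <- ds$measurements[ds$measurements$phase == "pre", ]
  pre_inj <- .get_injection(ds, "pre")
  t_ther <- if (problem$include_therapy_data)
    .get_injection(ds, "therapy")$time_min else NULL

  tgrid <- sort(unique(c(0, pre$time_min, t_ther)))
  traj <- simulate_phase(th, problem$model_id, pre_inj, tgrid,
                         physiology = ds$physiology, spec = problem$spec,
                         fixed = problem$fixed, rtol = problem$rtol,
                         atol = problem$atol)
  obs <- observables(traj, c_RM = th[["c_RM"]])
  pred <- obs$value[match(paste(pre$region, pre$time_min),
                          paste(obs$region, obs$time_min))]
  sigma <- ifelse(pre$region == "serum", problem$fsd[["serum"]],
                  problem$fsd[["imaging"]]) * pre$value
  r <- (pred - pre$value) / sigma

  if (problem$include_therapy_data) {
    ther <- ds$measurements[ds$measurements$phase == "therapy", ]
    ther_inj <- .get_injection(ds, "therapy")
    carry <- .carryover_state(traj$y[match(t_ther, traj$times), ])
    tg2 <- sort(unique(c(t_ther, ther$time_min)))
    traj2 <- simulate_phase(th, problem$model_id, ther_inj, tg2,
                            physiology = ds$physiology, carry_state = carry,
                            spec = problem$spec, fixed = problem$fixed,
                            rtol = problem$rtol, atol = problem$atol)
    obs2 <- observables(traj2, c_RM = th[["c_RM"]])
    pred2 <- obs2$value[match(paste(ther$region, ther$time_min),
                              paste(obs2$region, obs2$time_min))]
    sigma2 <- ifelse(ther$region == "serum", problem$fsd[["serum"]],
                     problem$fsd[["imaging"]]) * ther$value
    r <- c(r, (pred2 - ther$value) / sigma2)
  }
  if (with_prior)
    r <- c(r, sqrt(problem$prior_weight) *
             (th[["V_serum"]] - problem$prior$prior_mean) /
             problem$prior$prior_sd)
  r
}

#' Weighted least-squares objective
#'
#' Sum of squared weighted residuals over all measurements, with per-datum
#' standard deviation `fsd * value`, plus the squared Bayesian serum-volume
#' penalty `((V_serum - prior_mean) / prior_sd)^2`. Integrator failures are
#' converted into a large finite penalty so the optimizer can recover.
#'
#' @param theta parameter vector in the order
#'   `Ag_L, Ag_S, ex_l, ex_s, f_RM, c_RM, lambda_db, r_im, V_serum`.
#' @param problem a [fit_problem()].
#' @return scalar objective value.
#' @export
pbpk_objective <- function(theta, problem) {
  r <- tryCatch(.fit_residuals(theta, problem), error = function(e) {
    warning("objective: integrator failure (", conditionMessage(e),
            "); returning penalty", call. = FALSE)
    NULL
  })
  if (is.null(r)) return(1e12)
  sum(r^2)
}

# -- bounded Levenberg-Marquardt on a logistic transform ---------------------

.to_unconstrained <- function(theta, lo, hi) {
  z <- (theta - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
  log(z / (1 - z))
}

.from_unconstrained <- function(u, lo, hi) lo + (hi - lo) / (1 + exp(-u))

.lm_minimize <- function(rfun, u0, maxit = 60, ftol = 1e-10, ptol = 1e-9) {
  u <- u0
  r <- rfun(u)
  obj <- sum(r^2)
  lambda <- 1e-3
  npar <- length(u)
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(r), npar)
    for (k in seq_len(npar)) {
      du <- 1e-4 * max(1, abs(u[k]))
      u2 <- u; u2[k] <- u2[k] + du
      J[, k] <- (rfun(u2) - r) / du
    }
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    d <- pmax(diag(JtJ), 1e-12)
    improved <- FALSE
    for (try in 1:12) {
      step <- tryCatch(solve(JtJ + lambda * diag(d, npar), -g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      u_try <- u + as.numeric(step)
      r_try <- rfun(u_try)
      obj_try <- sum(r_try^2)
      if (is.finite(obj_try) && obj_try < obj) {
        moved <- max(abs(u_try - u))
        rel <- (obj - obj_try) / max(obj, .Machine$double.eps)
        u <- u_try; r <- r_try; obj <- obj_try
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (rel < ftol || moved < ptol) return(list(u = u, obj = obj,
                                                    iters = it,
                                                    converged = TRUE))
        break
      }
      lambda <- lambda * 8
    }
    if (!improved) return(list(u = u, obj = obj, iters = it,
                               converged = TRUE))
  }
  list(u = u, obj = obj, iters = maxit, converged = FALSE)
}

# seeded latin-hypercube starting points within the bounds
.lhs_starts <- function(n, lower, upper, seed) {
  set.seed(seed)
  npar <- length(lower)
  out <- matrix(NA_real_, n, npar, dimnames = list(NULL, names(lower)))
  for (k in seq_len(npar)) {
    strata <- (sample(n) - runif(n)) / n
    out[, k] <- lower[k] + strata * (upper[k] - lower[k])
  }
  out
}

#' Fit the PBPK model to one patient
#'
#' Bounded Levenberg-Marquardt minimisation of [pbpk_objective()] on a
#' logistic reparameterisation of the Table-style bounds, with a seeded
#' Latin-hypercube multi-start (the first start is always the conventional
#' initial-value vector). Standard errors and correlations come from the
#' linearised covariance `(J'J)^-1` of the weighted residual Jacobian at the
#' optimum.
#'
#' @param problem a [fit_problem()].
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed for the multi-start sampling.
#' @param maxit LM iteration cap per start.
#' @return Object of class `pbpk_fit` with fields `model_id`, `estimates`,
#'   `se`, `cv`, `correlation`, `objective`, `N`, `K`, `aic` (corrected AIC),
#'   `converged`, plus bookkeeping.
#' @export
fit_pbpk <- function(problem, n_starts = 5, seed = 1L, maxit = 60) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1)
  lo <- problem$lower; hi <- problem$upper
  rfun <- function(u) {
    th <- .from_unconstrained(u, lo, hi)
    r <- tryCatch(.fit_residuals(th, problem), error = function(e) NULL)
    if (is.null(r)) rep(1e6, .n_residuals(problem)) else r
  }

  starts <- rbind(problem$init,
                  if (n_starts > 1)
                    .lhs_starts(n_starts - 1L, lo, hi, seed))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    u0 <- .to_unconstrained(starts[s, ], lo, hi)
    res <- .lm_minimize(rfun, u0, maxit = maxit)
    if (is.null(best) || res$obj < best$obj) best <- res
  }
  theta <- setNames(.from_unconstrained(best$u, lo, hi), .PARAM_NAMES)

  # linearised covariance at the optimum, finite differences in theta space
  r0 <- .fit_residuals(theta, problem)
  J <- matrix(0, length(r0), length(theta),
              dimnames = list(NULL, .PARAM_NAMES))
  for (k in seq_along(theta)) {
    h <- 1e-4 * (hi[k] - lo[k])
    up <- min(theta[k] + h, hi[k]); dn <- max(theta[k] - h, lo[k])
    t_up <- theta; t_up[k] <- up
    t_dn <- theta; t_dn[k] <- dn
    J[, k] <- (.fit_residuals(t_up, problem) -
               .fit_residuals(t_dn, problem)) / (up - dn)
  }
  JtJ <- crossprod(J)
  sv <- svd(JtJ)
  pos <- sv$d > max(sv$d) * 1e-12
  cov <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  se <- sqrt(pmax(diag(cov), 0))
  corr <- cov / outer(se, se)
  diag(corr) <- 1
  dimnames(corr) <- list(.PARAM_NAMES, .PARAM_NAMES)

  N <- .n_residuals(problem) - 1L # data points (prior excluded)
  K <- length(theta)
  structure(
    list(model_id = problem$model_id, estimates = theta,
         se = setNames(se, .PARAM_NAMES),
         cv = setNames(se / abs(theta), .PARAM_NAMES),
         correlation = corr, covariance = cov, objective = best$obj,
         N = N, K = K, aic = pbpk_aic(best$obj, N, K),
         converged = best$converged, n_starts = n_starts, seed = seed,
         problem = problem),
    class = "pbpk_fit"
  )
}

.n_residuals <- function(problem) {
  ds <- problem$dataset
  n <- sum(ds$measurements$phase == "pre")
  if (problem$include_therapy_data)
    n <- n + sum(ds$measurements$phase == "therapy")
  n + 1L # + prior
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("PBPK fit (constraint model %d): objective %.4g, AICc %.2f\n",
              x$model_id, x$objective, x$aic))
  est <- x$estimates
  est[["f_RM"]] <- est[["f_RM"]] * 100 # report as percent
  tab <- data.frame(estimate = signif(est, 4),
                    se = signif(x$se, 3), cv = signif(x$cv, 3))
  rownames(tab)[rownames(tab) == "f_RM"] <- "f_RM [%]"
  tab["f_RM [%]", "se"] <- signif(x$se[["f_RM"]] * 100, 3)
  print(tab)
  invisible(x)
}

#' Akaike information criterion (small-sample corrected)
#'
#' `AICc = N log(obj / N) + 2K + 2K(K+1)/(N - K - 1)`; the last term is the
#' small-sample correction (dropped when `corrected = FALSE`).
#'
#' @param objective weighted sum of squared residuals at the optimum (or a
#'   `pbpk_fit` object, in which case `N` and `K` are taken from it).
#' @param N number of data points; must exceed `K + 1`.
#' @param K number of adjustable parameters.
#' @param corrected use the small-sample correction (default).
#' @return scalar AIC value.
#' @export
pbpk_aic <- function(objective, N = NULL, K = NULL, corrected = TRUE) {
  if (inherits(objective, "pbpk_fit")) {
    N <- objective$N; K <- objective$K; objective <- objective$objective
  }
  if (corrected && N <= K + 1)
    stop("AICc requires N > K + 1")
  out <- N * log(objective / N) + 2 * K
  if (corrected) out <- out + 2 * K * (K + 1) / (N - K - 1)
  out
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; invariant to adding a constant to all AICs.
#'
#' @param aics numeric vector of AIC values (at least one finite).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (!any(is.finite(aics))) stop("need at least one finite AIC")
  d <- aics - min(aics, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Akaike-weight model averaging
#'
#' Weighted mean of the per-model estimates; the averaged standard error uses
#' the multimodel combination rule
#' `sqrt(sum w_i (se_i^2 + (v_i - vbar)^2))`, inflating the within-model
#' uncertainty by the between-model spread.
#'
#' @param values per-model point estimates.
#' @param ses per-model standard errors (same length).
#' @param weights Akaike weights (same length, summing to 1).
#' @return list with `value` and `se`.
#' @export
model_average <- function(values, ses, weights) {
  if (length(values) != length(ses) || length(values) != length(weights))
    stop("values, ses and weights must have equal length")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  vbar <- sum(weights * values)
  se <- sqrt(sum(weights * (ses^2 + (values - vbar)^2)))
  list(value = vbar, se = se)
}
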