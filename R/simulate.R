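# Trajectory simulation and mapping to measurable observables.

#' Simulate a PBPK trajectory
#'
#' Integrates the system with the package's stiff Rosenbrock solver,
#' returning states and derivatives at the requested output times (the
#' derivatives support cubic-Hermite dense evaluation and quadrature).
#'
#' @param sys a `pbpk_system` from [build_rhs()].
#' @param state0 initial state (named as `sys$si$names`), non-negative.
#' @param t_grid strictly increasing output times (min); integration starts
#'   at `t_grid[1]`.
#' @param rtol,atol relative / absolute (nmol) solver tolerances.
#' @param max_steps step budget before the solver aborts.
#' @return Object of class `pbpk_trajectory`: `times`, state matrix `y`,
#'   derivative matrix `f`, the system, and solver statistics.
#' @export
simulate_pbpk <- function(sys, state0, t_grid, rtol = 1e-8, atol = 1e-12,
                          max_steps = 500000L) {
  stopifnot(inherits(sys, "pbpk_system"))
  if (length(t_grid) < 1 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (any(state0 < 0)) stop("state0 must be non-negative")
  if (length(state0) != sys$si$n) stop("state0 has wrong length")

  res <- .pbpk_integrate(sys$A, sys$assoc$i - 1L, sys$assoc$j - 1L,
                         sys$assoc$o - 1L, sys$assoc$coef, sys$occw, sys$Ag,
                         as.numeric(state0), as.numeric(t_grid),
                         rtol, atol, as.integer(max_steps))
  y <- res$y; f <- res$f
  colnames(y) <- colnames(f) <- sys$si$names
  structure(list(times = as.numeric(t_grid), y = y, f = f, sys = sys,
                 n_lab = attr(state0, "n_lab"),
                 nstep = res$nstep, nreject = res$nreject),
            class = "pbpk_trajectory")
}

#' Observable projection matrix
#'
#' Every measurable region is an affine function of the state:
#' `obs = const + (W %*% y) / n_lab`. With the decay-free system the labeled
#' columns carry the decay-corrected labeled amounts, so these observables
#' match decay-corrected gamma-camera / serum data directly.
#'
#' @param sys a `pbpk_system`.
#' @param c_RM red-marrow scaling correction applied to the model's total RM
#'   content to map it onto the height-scaled measurement convention.
#' @return list with matrix `W` (regions x states) and vector `const`.
#' @keywords internal
.observable_matrix <- function(sys, c_RM) {
  si <- sys$si
  oc <- .obs_columns(si)
  W <- matrix(0, length(.REGIONS), si$n, dimnames = list(.REGIONS, si$names))
  const <- setNames(numeric(length(.REGIONS)), .REGIONS)
  W["serum", oc$serum_free] <- 1 / sys$params$V_serum
  if (sys$serum_includes_metabolites)
    W["serum", oc$serum_meta] <- 1 / sys$params$V_serum
  W["red_marrow", oc$red_marrow] <- c_RM
  W["liver", oc$liver] <- 1
  W["spleen", oc$spleen] <- 1
  W["total_body", oc$excreted] <- -1
  const["total_body"] <- 1
  list(W = W, const = const)
}

#' Map a trajectory to observable series
#'
#' @param traj a `pbpk_trajectory`.
#' @param c_RM red-marrow scaling correction factor.
#' @param n_lab labeled amount injected (nmol); defaults to the value stored
#'   on the trajectory by [initial_state()].
#' @param regions which regions to report.
#' @return A data.frame with columns `region`, `time_min`, `value`
#'   (fraction of injected labeled amount; for `serum`, fraction per litre)
#'   and `deriv` (d value / d min). Values from a decay-free system are
#'   decay-corrected fractions.
#' @export
observables <- function(traj, c_RM = 1, n_lab = traj$n_lab,
                        regions = .REGIONS) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  if (is.null(n_lab) || !is.finite(n_lab) || n_lab <= 0)
    stop("n_lab (injected labeled amount) must be positive")
  unknown <- setdiff(regions, .REGIONS)
  if (length(unknown)) stop("unknown region(s): ",
                            paste(unknown, collapse = ", "))
  om <- .observable_matrix(traj$sys, c_RM)
  vals <- sweep(traj$y %*% t(om$W) / n_lab, 2, om$const, `+`)
  dervs <- traj$f %*% t(om$W) / n_lab
  do.call(rbind, lapply(regions, function(r) {
    data.frame(region = r, time_min = traj$times, value = vals[, r],
               deriv = dervs[, r], row.names = NULL)
  }))
}

#' Simulate one measurement phase for a parameter vector
#'
#' Convenience wrapper used by the fitting and dosimetry layers: builds the
#' system for a full adjustable-parameter vector, forms the bolus initial
#' state (optionally on top of a carryover state) and simulates.
#'
#' @param theta named vector with `Ag_L`, `Ag_S`, `ex_l`, `ex_s`, `f_RM`
#'   (fraction), `c_RM`, `lambda_db`, `r_im`, `V_serum`.
#' @param model_id antigen-constraint model, 1 or 2.
#' @param inj an [injection()].
#' @param t_grid output times (min), starting at the injection time.
#' @param physiology patient physiology (required for model 2).
#' @param carry_state optional pre-existing state (residual antibody).
#' @param spec,fixed,rtol,atol passed through.
#' @return `pbpk_trajectory` (decay-free system; decay-corrected basis).
#' @export
simulate_phase <- function(theta, model_id, inj, t_grid, physiology = NULL,
                           carry_state = NULL, spec = antibody_spec(),
                           fixed = fixed_defaults(), rtol = 1e-8,
                           atol = 1e-12) {
  theta <- as.list(theta)
  pool <- if (model_id == 1) {
    antigen_pool_model1(theta$Ag_L, theta$Ag_S)
  } else {
    antigen_pool_model2(theta$Ag_L, theta$Ag_S, physiology)
  }
  sys <- build_rhs(theta, pool, spec = spec, nuclide = NULL, fixed = fixed)
  y0 <- initial_state(sys, inj, theta$r_im, state = carry_state)
  simulate_pbpk(sys, y0, t_grid, rtol = rtol, atol = atol)
}

# Carry residual antibody forward into a fresh (therapy) system: the old
# label is a different nuclide contributing no activity in the new phase,
# so all surviving antibody of both labels moves to the unlabeled pool of
# the congruent compartment; metabolites likewise.
.carryover_state <- function(state_at_switch) {
  si <- state_index()
  y <- setNames(numeric(si$n), si$names)
  lnames <- grep("\\.L(\\.|$)", si$names, value = TRUE)
  for (nm_l in lnames) {
    nm_u <- sub("\\.L", ".U", nm_l)
    y[nm_u] <- state_at_switch[nm_l] + state_at_switch[nm_u]
  }
  y
}
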