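#' @useDynLib cd66pbpk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx dnorm integrate median optim pnorm qnorm rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils modifyList read.csv write.csv
NULL

# Avogadro's number per nmol of substance
.AVOGADRO_NMOL <- 6.02214076e14

#' Radionuclide specification
#'
#' Describes the physical decay of the label. The pre-therapeutic tracer is
#' In-111, the therapeutic label is Y-90; both are available as built-ins via
#' [nuclide()].
#'
#' @param name label, e.g. `"In111"`.
#' @param half_life_min physical half-life in minutes (> 0).
#' @return An object of class `nuclide_spec` with fields `name`,
#'   `half_life_min` and `lambda_phys` (1/min), where
#'   `lambda_phys = log(2) / half_life_min`.
#' @export
nuclide_spec <- function(name, half_life_min) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("half_life_min must be a positive number")
  structure(
    list(name = name, half_life_min = half_life_min,
         lambda_phys = log(2) / half_life_min),
    class = "nuclide_spec"
  )
}

#' Built-in nuclides
#'
#' @param name `"In111"` (pre-therapy imaging label, half-life 4042 min) or
#'   `"Y90"` (therapy label, half-life 64.1 h = 3846 min).
#' @return A [nuclide_spec()].
#' @export
nuclide <- function(name = c("In111", "Y90")) {
  name <- match.arg(name)
  switch(name,
    In111 = nuclide_spec("In111", 4042),
    Y90   = nuclide_spec("Y90", 64.1 * 60)
  )
}

#' Antibody specification
#'
#' Molar conversion and intrinsic binding rates of the anti-CD66 antibody
#' (BW250/183). The association/dissociation rates are fixed to typical
#' values for this antibody class; fits are insensitive to their exact
#' magnitude because binding is transport- and antigen-limited.
#'
#' @param molar_conversion nmol of antibody per mg (default 6.7).
#' @param k_on association rate constant, l/nmol/min (default 0.006).
#' @param k_off dissociation rate constant, 1/min (default 0.06).
#' @return An object of class `antibody_spec`.
#' @export
antibody_spec <- function(molar_conversion = 6.7, k_on = 0.006, k_off = 0.06) {
  vals <- c(molar_conversion = molar_conversion, k_on = k_on, k_off = k_off)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("antibody_spec fields must all be positive")
  structure(as.list(vals), class = "antibody_spec")
}

#' Convert antibody mass to amount of substance
#'
#' @param mass_mg mass in mg (>= 0), vectorised.
#' @param spec an [antibody_spec()].
#' @return amount in nmol.
#' @export
#' @examples
#' mg_to_nmol(1)    # 6.7 nmol
#' mg_to_nmol(1.3)  # 8.71 nmol, a typical therapeutic amount
mg_to_nmol <- function(mass_mg, spec = antibody_spec()) {
  if (any(!is.finite(mass_mg)) || any(mass_mg < 0))
    stop("mass_mg must be non-negative")
  mass_mg * spec$molar_conversion
}

#' Amount of labeled antibody corresponding to an activity
#'
#' Assumes one radiolabel per antibody molecule: the number of labeled
#' molecules equals the number of radioactive atoms N = A / lambda.
#'
#' @param activity_MBq activity in MBq (>= 0).
#' @param nuclide a [nuclide_spec()].
#' @return labeled antibody amount in nmol.
#' @export
activity_to_nmol <- function(activity_MBq, nuclide) {
  if (any(!is.finite(activity_MBq)) || any(activity_MBq < 0))
    stop("activity_MBq must be non-negative")
  decays_per_min <- activity_MBq * 1e6 * 60
  atoms <- decays_per_min / nuclide$lambda_phys
  atoms / .AVOGADRO_NMOL
}

#' Immunoreactivity partition
#'
#' With probability `r_im` that one antibody binding arm is immunoreactive,
#' the injected antibody splits binomially into fully (`r_im^2`), half
#' (`2 r_im (1 - r_im)`) and non-immunoreactive (`(1 - r_im)^2`) fractions.
#'
#' @param r_im probability in \[0, 1\] that one binding arm is reactive.
#' @return Object of class `immunoreactivity_partition` with fields `r_im`,
#'   `f_full`, `f_half`, `f_non` (summing to 1 exactly).
#' @export
immunoreactivity_partition <- function(r_im) {
  if (!is.finite(r_im) || r_im < 0 || r_im > 1)
    stop("r_im must lie in [0, 1]")
  f_full <- r_im^2
  f_half <- 2 * r_im * (1 - r_im)
  structure(
    list(r_im = r_im, f_full = f_full, f_half = f_half,
         f_non = 1 - f_full - f_half),
    class = "immunoreactivity_partition"
  )
}

#' Injection record
#'
#' @param time_min time of administration in minutes since the
#'   pre-therapeutic injection.
#' @param amount_mg antibody mass administered (mg, > 0).
#' @param activity_MBq labeled activity administered (MBq, >= 0).
#' @param nuclide a [nuclide_spec()].
#' @return Object of class `injection`.
#' @export
injection <- function(time_min, amount_mg, activity_MBq, nuclide) {
  if (!is.finite(amount_mg) || amount_mg <= 0) stop("amount_mg must be > 0")
  if (!is.finite(activity_MBq) || activity_MBq < 0)
    stop("activity_MBq must be >= 0")
  stopifnot(inherits(nuclide, "nuclide_spec"))
  structure(list(time_min = time_min, amount_mg = amount_mg,
                 activity_MBq = activity_MBq, nuclide = nuclide),
            class = "injection")
}

#' Partition an injection into the six antibody species
#'
#' Splits the administered antibody into labeled/unlabeled amounts (from the
#' administered activity, one label per molecule) and each of those into
#' fully, half and non-immunoreactive fractions.
#'
#' @param inj an [injection()].
#' @param r_im arm-level immunoreactivity probability.
#' @param spec an [antibody_spec()].
#' @return A 2 x 3 matrix (rows `labeled`, `unlabeled`; columns `full`,
#'   `half`, `non`) of amounts in nmol, with attributes `n_tot` and `n_lab`.
#' @export
partition_injection <- function(inj, r_im, spec = antibody_spec()) {
  part <- immunoreactivity_partition(r_im)
  n_tot <- mg_to_nmol(inj$amount_mg, spec)
  n_lab <- activity_to_nmol(inj$activity_MBq, inj$nuclide)
  if (n_lab > n_tot * (1 + 1e-9))
    stop(sprintf(paste0("specific activity too high: labeled amount ",
                        "%.4g nmol exceeds total %.4g nmol"), n_lab, n_tot))
  n_unl <- n_tot - n_lab
  frac <- c(full = part$f_full, half = part$f_half, non = part$f_non)
  out <- rbind(labeled = n_lab * frac, unlabeled = n_unl * frac)
  attr(out, "n_tot") <- n_tot
  attr(out, "n_lab") <- n_lab
  out
}
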