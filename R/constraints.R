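# Antigen-number constraint models and the serum-volume prior.
#
# The amounts of CD66 antigen in blood and red marrow are not freely
# estimable from pre-therapy data alone; they are tied to the liver and
# spleen antigen amounts through granulocyte distribution ratios measured in
# healthy subjects: red marrow holds 38 times the blood granulocyte pool,
# and liver + spleen marginated granulocytes account for 90% of a pool
# equal in size to the circulating one.

#' Marrow-to-blood granulocyte pool ratio (healthy subjects)
#' @export
AG_RM_TO_BLOOD <- 38

#' Fraction of the marginated granulocyte pool residing in liver + spleen
#' @export
AG_LIVER_SPLEEN_FRACTION <- 0.9

.new_pool <- function(Ag_L, Ag_S, Ag_B, model) {
  structure(list(Ag_L = Ag_L, Ag_S = Ag_S, Ag_B = Ag_B,
                 Ag_RM = AG_RM_TO_BLOOD * Ag_B, constraint_model = model),
            class = "antigen_pool")
}

#' Antigen pool under constraint model 1
#'
#' `Ag_B = (Ag_L + Ag_S) / 0.9` and `Ag_RM = 38 Ag_B`.
#'
#' @param Ag_L,Ag_S antigen amounts in liver and spleen (nmol, >= 0).
#' @return Object of class `antigen_pool` with fields `Ag_L`, `Ag_S`,
#'   `Ag_B`, `Ag_RM`, `constraint_model`.
#' @export
antigen_pool_model1 <- function(Ag_L, Ag_S) {
  if (any(!is.finite(c(Ag_L, Ag_S))) || Ag_L < 0 || Ag_S < 0)
    stop("Ag_L and Ag_S must be non-negative")
  .new_pool(Ag_L, Ag_S, (Ag_L + Ag_S) / AG_LIVER_SPLEEN_FRACTION, 1L)
}

#' Antigen pool under constraint model 2
#'
#' As model 1, but each organ term is weighted by the ratio of the
#' MRI-measured to the calculated average organ volume, compensating for the
#' organomegaly common in acute leukemia:
#' `Ag_B = (Ag_L V_MRI_L / V_calc_L + Ag_S V_MRI_S / V_calc_S) / 0.9`.
#'
#' @inheritParams antigen_pool_model1
#' @param phys a [patient_physiology()] carrying `V_MRI_L`, `V_MRI_S`,
#'   `V_calc_L`, `V_calc_S`.
#' @export
antigen_pool_model2 <- function(Ag_L, Ag_S, phys) {
  if (any(!is.finite(c(Ag_L, Ag_S))) || Ag_L < 0 || Ag_S < 0)
    stop("Ag_L and Ag_S must be non-negative")
  v <- c(phys$V_MRI_L, phys$V_MRI_S, phys$V_calc_L, phys$V_calc_S)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("model 2 requires positive MRI and calculated organ volumes")
  Ag_B <- (Ag_L * phys$V_MRI_L / phys$V_calc_L +
           Ag_S * phys$V_MRI_S / phys$V_calc_S) / AG_LIVER_SPLEEN_FRACTION
  .new_pool(Ag_L, Ag_S, Ag_B, 2L)
}

#' Patient physiology block
#'
#' @param sex `"male"` or `"female"`.
#' @param body_surface_area m^2.
#' @param hematocrit fraction in (0, 1).
#' @param V_MRI_L,V_MRI_S individually measured (MRI) liver/spleen volumes, l.
#' @param V_calc_L,V_calc_S calculated average organ volumes, l.
#' @return Object of class `patient_physiology`.
#' @export
patient_physiology <- function(sex = c("male", "female"), body_surface_area,
                               hematocrit, V_MRI_L, V_MRI_S, V_calc_L,
                               V_calc_S) {
  sex <- match.arg(sex)
  if (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie strictly between 0 and 1")
  vols <- c(body_surface_area, V_MRI_L, V_MRI_S, V_calc_L, V_calc_S)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("body surface area and organ volumes must be positive")
  structure(list(sex = sex, body_surface_area = body_surface_area,
                 hematocrit = hematocrit, V_MRI_L = V_MRI_L,
                 V_MRI_S = V_MRI_S, V_calc_L = V_calc_L,
                 V_calc_S = V_calc_S),
            class = "patient_physiology")
}

#' Anthropometric serum volume
#'
#' `V_BSA = BSA x 2.8 (male) or 2.4 (female) x (1 - hematocrit)` litres.
#'
#' @param phys a [patient_physiology()].
#' @return serum volume in l.
#' @export
v_bsa <- function(phys) {
  f <- if (phys$sex == "male") 2.8 else 2.4
  phys$body_surface_area * f * (1 - phys$hematocrit)
}

#' Bayesian prior for the total serum volume
#'
#' The prior mean is the dilution volume of the first (~5 min) serum sample,
#' `V_m1 = injected activity / first measured serum activity concentration`
#' (at 5 min essentially all labeled antibody is still in serum). The prior
#' SD is `|V_m1 - V_BSA|`, the disagreement between the dilution estimate and
#' the anthropometric serum volume. A degenerate prior (`V_m1 == V_BSA`)
#' would have zero width; it is replaced by `0.1 V_m1` and flagged.
#'
#' @param injected_activity activity administered (any unit).
#' @param first_serum_concentration measured serum activity concentration of
#'   the first sample, same activity unit per litre (> 0).
#' @param phys a [patient_physiology()].
#' @param fallback_rel_sd relative SD substituted when the prior degenerates.
#' @return Object of class `serum_volume_prior` with `V_m1`, `V_BSA`,
#'   `prior_mean`, `prior_sd`, `degenerate`.
#' @export
serum_volume_prior <- function(injected_activity, first_serum_concentration,
                               phys, fallback_rel_sd = 0.1) {
  if (!is.finite(first_serum_concentration) || first_serum_concentration <= 0)
    stop("first_serum_concentration must be positive")
  V_m1 <- injected_activity / first_serum_concentration
  V_BSA <- v_bsa(phys)
  prior_sd <- abs(V_m1 - V_BSA)
  degenerate <- prior_sd <= .Machine$double.eps * max(1, V_m1)
  if (degenerate) prior_sd <- fallback_rel_sd * V_m1
  if (V_m1 < 1 || V_m1 > 10)
    warning(sprintf("V_m1 = %.3g l outside the [1, 10] l serum-volume bounds;
 it will be clipped at fit time", V_m1))
  structure(list(V_m1 = V_m1, V_BSA = V_BSA, prior_mean = V_m1,
                 prior_sd = prior_sd, degenerate = degenerate),
            class = "serum_volume_prior")
}
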