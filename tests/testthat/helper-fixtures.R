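# Shared fixtures for the test suite. Everything is generated in code.

# a mid-cohort parameter vector (population means)
ref_theta <- function() {
  c(Ag_L = 0.31, Ag_S = 0.22, ex_l = 0.235, ex_s = 0.107, f_RM = 0.0067,
    c_RM = 1.22, lambda_db = 6.8e-5, r_im = 0.8, V_serum = 3.0)
}

ref_injection_pre <- function() injection(0, 0.5, 130, nuclide("In111"))

ref_physiology <- function() {
  patient_physiology(sex = "male", body_surface_area = 1.9,
                     hematocrit = 0.40, V_MRI_L = 1.8, V_MRI_S = 0.2,
                     V_calc_L = 1.8, V_calc_S = 0.2)
}

# lossless system: no decay, no degradation (for conservation checks)
conservative_system <- function(theta = ref_theta(), pool = NULL) {
  theta[["lambda_db"]] <- 0
  if (is.null(pool)) pool <- antigen_pool_model1(theta[["Ag_L"]],
                                                 theta[["Ag_S"]])
  build_rhs(theta, pool, fixed = fixed_defaults(list(lambda_df = 0)))
}

# a static trajectory with constant total-body retention 1 (all transport
# and loss switched off) for TAC closed-form checks
constant_retention_traj <- function(t_grid) {
  fx <- fixed_defaults(list(Q_co = 0, Q_liver = 0, Q_spleen = 0, Q_GI = 0,
                            lambda_df = 0, k_ret = 0, k_unspec = 0,
                            k_meta_ex1 = 0, k_meta_ex2 = 0, k_urine = 0))
  th <- ref_theta()
  th[["lambda_db"]] <- 0
  sys <- build_rhs(th, antigen_pool_model1(0, 0), fixed = fx)
  y0 <- initial_state(sys, ref_injection_pre(), r_im = 0)
  simulate_pbpk(sys, y0, t_grid)
}

# small deterministic synthetic dataset (noise-free unless stated)
tiny_dataset <- function(seed = 11, noise = FALSE, include_therapy = TRUE) {
  pop <- population_spec()
  vp <- sample_patient(pop, seed)
  generate_dataset(vp, pop, seed = seed + 1, noise = noise,
                   include_therapy = include_therapy,
                   therapy_template = "A", rtol = 1e-7, atol = 1e-11)
}
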