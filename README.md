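# cd66pbpk

Physiologically based pharmacokinetic (PBPK) modelling of radiolabeled
anti-CD66 monoclonal antibodies for red marrow dosimetry in
radioimmunotherapy conditioning of acute leukemia patients.

## The problem

Before stem-cell transplantation, the red marrow is irradiated selectively
with Y-90-labeled anti-CD66 antibody. Treatment planning needs the
time-integrated activity coefficients (TACs, `ã` in hours) of red marrow,
liver, spleen, serum and total body during *therapy*, but only
pre-therapeutic tracer measurements (In-111, ~0.5 mg antibody) are available
in advance. Because the therapeutic antibody amount (~1.3 mg ≈ 9 nmol) is of
the same order as the total CD66 antigen amount (tens of nmol), binding
saturates and the therapeutic biodistribution differs from the
pre-therapeutic one — assuming they are equal systematically underestimates
circulating activity and overestimates marrow retention.

This package implements the full pipeline:

* a whole-body PBPK model with six antibody species — label
  {labeled, unlabeled} × immunoreactivity class {fully (`r_im²`), half
  (`2 r_im (1 − r_im)`), non (`(1 − r_im)²`)} — competing for shared antigen
  via saturable mono- and bivalent binding in red marrow, liver, spleen and
  blood, with flow transport, unspecific-uptake delay pools, degradation, a
  metabolite/excretion submodel and physical decay (own stiff Rosenbrock
  integrator, analytic Jacobian);
* two antigen-number constraint models (`Ag_RM = 38 Ag_B`,
  `Ag_B = (Ag_L + Ag_S)/0.9`, optionally MRI-volume-weighted), weighted
  least-squares fitting of nine parameters per patient with a Bayesian
  serum-volume prior, AICc + Akaike-weight model averaging;
* therapy prediction with nuclide switch, saturation and residual-antibody
  carryover; joint (pre + therapy) reference fits; relative-deviation
  statistics `RD = (ã_pred − ã_ther)/ã_ther`;
* a virtual-patient generator (calibrated parameter dispersion, standard
  schedules, lognormal noise) so every stage is testable offline.

See `vignettes/cd66-pbpk-methods.Rmd` for the model, assumptions and design
choices.

## Worked example

```r
library(cd66pbpk)
pop <- population_spec()
vp  <- sample_patient(pop, 42)                 # truth: r_im 0.701, Ag_RM 51 nmol
ds  <- generate_dataset(vp, pop, seed = 43, therapy_template = "A")

fits <- lapply(1:2, function(m)
  fit_pbpk(fit_problem(ds, model_id = m), n_starts = 2, seed = 1))
akaike_weights(sapply(fits, `[[`, "aic"))      # 0.554 0.446
fits[[1]]
#> PBPK fit (constraint model 1): objective 26.63, AICc 18.74
#>            estimate       se     cv
#> Ag_L      9.246e-01 3.87e-01 0.4190
#> ...
#> r_im      6.506e-01 4.80e-02 0.0737
#> V_serum   3.342e+00 1.23e-01 0.0368

pred  <- predict_therapy(fits, ds, compute_se = FALSE)
joint <- fit_therapy_reference(ds, n_starts = 1, compute_se = FALSE)
pred$tac_table                                  # Akaike-averaged prediction
#>       region        tag        a_h ...
#> 1 red_marrow prediction 50.96
#> 5      serum prediction  5.64
joint$tac_table                                 # joint-fit reference
#> 1 red_marrow therapy    50.85
#> 5      serum therapy     5.76

relative_deviation(
  pred$tac_table$a_h[pred$tac_table$region == "serum"],
  joint$tac_table$a_h[joint$tac_table$region == "serum"])
#> -0.02
```

The fitted immunoreactivity (0.65 ± 0.05 vs truth 0.701) and the −2%
serum-TAC prediction error illustrate the pipeline's point: the PBPK
prediction tracks the therapeutic biodistribution even though the
therapeutic amount saturates differently than the tracer amount. The whole
cohort analysis (both models, weights, TAC tables, RD statistics under both
the PBPK and the equal-biodistribution conventions) runs via

```r
out <- run_pipeline(list(seed = 1, cohort = list(n = 5),
                         out_dir = "results"))
out$rd_stats
```

or from the command line with
`Rscript inst/cli/cd66pbpk.R report --n 5 --seed 1 --out results`.

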