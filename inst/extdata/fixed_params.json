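{
  "version": "1.0",
  "note": "Fixed (non-adjustable) physiological and kinetic constants of the anti-CD66 PBPK model. Reference-man style stand-in values; every entry is overridable via fixed_defaults(overrides = ...).",
  "parameters": {
    "Q_co": {
      "value": 3.0,
      "unit": "l/min",
      "source": "cardiac plasma flow: reference-man cardiac output ~5.0-6.5 l/min blood times (1 - hematocrit ~0.40), rounded"
    },
    "Q_liver": {
      "value": 0.80,
      "unit": "l/min",
      "source": "total hepatic plasma flow, ~25-27% of cardiac plasma flow (reference man)"
    },
    "Q_spleen": {
      "value": 0.09,
      "unit": "l/min",
      "source": "splenic plasma flow, ~3% of cardiac plasma flow (reference man)"
    },
    "Q_GI": {
      "value": 0.50,
      "unit": "l/min",
      "source": "gastrointestinal (non-splenic splanchnic) plasma flow, ~15-17% of cardiac plasma flow"
    },
    "perm_liver": {
      "value": 0.05,
      "unit": "unity",
      "source": "vascular transmission factor for antibody exchange with the liver space (transcapillary antibody transport is slow relative to plasma flow even in sinusoidal organs); keeps the 5-min serum sample an essentially pure serum dilution"
    },
    "perm_spleen": {
      "value": 0.05,
      "unit": "unity",
      "source": "vascular transmission factor, spleen"
    },
    "perm_GI": {
      "value": 0.01,
      "unit": "unity",
      "source": "vascular transmission factor, gastrointestinal tract (continuous capillaries, low macromolecule permeability)"
    },
    "V_RM": {
      "value": 0.35,
      "unit": "l",
      "source": "antibody-accessible (vascular + interstitial) distribution volume of red marrow, ~30% of ~1.2 l marrow"
    },
    "V_liver": {
      "value": 0.35,
      "unit": "l",
      "source": "antibody-accessible distribution volume of liver, ~20% of ~1.8 l organ volume"
    },
    "V_spleen": {
      "value": 0.06,
      "unit": "l",
      "source": "antibody-accessible distribution volume of spleen, ~30% of ~0.2 l organ volume"
    },
    "V_GI": {
      "value": 0.45,
      "unit": "l",
      "source": "antibody-accessible distribution volume of gastrointestinal tract"
    },
    "lambda_df": {
      "value": 3e-05,
      "unit": "1/min",
      "source": "degradation rate of free antibody; IgG catabolic half-life of ~2-3 weeks"
    },
    "k_unspec": {
      "value": 5e-03,
      "unit": "1/min",
      "source": "scale of unspecific (delay-compartment) uptake from the organ free space; the fitted fractions ex_l, ex_s multiply this rate. Chosen so that ex ~ 0.1-0.25 yields the few-percent late liver/spleen unspecific retention seen for intact IgG"
    },
    "k_ret": {
      "value": 1e-03,
      "unit": "1/min",
      "source": "return rate from the extravascular delay (unspecific uptake) compartment; ~17 h mean residence"
    },
    "k_meta_ex1": {
      "value": 3e-03,
      "unit": "1/min",
      "source": "plasma metabolites to extravascular metabolite pool 1 (Houston-type degradation submodel)"
    },
    "k_ex1_meta": {
      "value": 1e-03,
      "unit": "1/min",
      "source": "extravascular metabolite pool 1 back to plasma metabolites"
    },
    "k_meta_ex2": {
      "value": 1e-03,
      "unit": "1/min",
      "source": "plasma metabolites to extravascular metabolite pool 2"
    },
    "k_ex2_meta": {
      "value": 5e-04,
      "unit": "1/min",
      "source": "extravascular metabolite pool 2 back to plasma metabolites"
    },
    "k_urine": {
      "value": 1e-02,
      "unit": "1/min",
      "source": "urinary excretion of small labeled metabolites from plasma (DTPA-chelate clearance scale)"
    }
  }
}
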