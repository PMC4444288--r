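# Construction of the coupled ODE system (linear matrix + association terms).

#' Saturable mono-/bivalent binding fluxes for one species and organ
#'
#' Implements the bivalent binding scheme: a fully immunoreactive antibody
#' associates with statistical factor 2 (two reactive arms), the bound
#' monovalent complex can cross-link a second antigen at `k_on_x = k_on`
#' acting on the local complex concentration `M / vol`, and the bivalent
#' complex releases one arm with statistical factor `2 k_off`. Half-reactive
#' antibody has a single association arm; non-reactive antibody does not
#' bind.
#'
#' @param free_conc free antibody concentration at the binding site (nmol/l).
#' @param M monovalently bound amount (nmol).
#' @param B bivalently bound amount (nmol).
#' @param Ag_free free antigen amount (nmol).
#' @param class one of `"full"`, `"half"`, `"non"`.
#' @param spec an [antibody_spec()].
#' @param vol distribution volume of the binding site (l), used for the
#'   cross-linking concentration.
#' @return Named vector `c(dF, dM, dB)` in nmol/min; `dF + dM + dB == 0`.
#' @export
binding_fluxes <- function(free_conc, M, B, Ag_free,
                           class = c("full", "half", "non"),
                           spec = antibody_spec(), vol = 1) {
  class <- match.arg(class)
  stopifnot(free_conc >= 0, M >= 0, B >= 0, Ag_free >= 0, vol > 0)
  k_on <- spec$k_on; k_off <- spec$k_off
  if (class == "non") return(c(dF = 0, dM = 0, dB = 0))
  if (class == "half") {
    assoc <- k_on * free_conc * Ag_free
    dM <- assoc - k_off * M
    return(c(dF = -assoc + k_off * M, dM = dM, dB = 0))
  }
  assoc1 <- 2 * k_on * free_conc * Ag_free
  xlink <- k_on * (M / vol) * Ag_free
  dM <- assoc1 - k_off * M - xlink + 2 * k_off * B
  dB <- xlink - 2 * k_off * B
  dF <- -assoc1 + k_off * M
  c(dF = dF, dM = dM, dB = dB)
}

#' Build the PBPK right-hand side
#'
#' Assembles the full ODE system for all six antibody species: blood-flow
#' transport between plasma and the organ spaces, saturable binding with
#' shared free antigen per site, unspecific uptake into extravascular delay
#' compartments for liver and spleen, degradation of bound (`lambda_db`) and
#' free (`lambda_df`) antibody into the label-matched metabolite submodel,
#' urinary excretion, and (optionally) physical decay moving every labeled
#' state into its unlabeled counterpart.
#'
#' @param params named list/vector of adjustable kinetic parameters:
#'   `ex_l`, `ex_s` (unspecific uptake fractions), `f_RM` (fraction of
#'   cardiac plasma flow to red marrow, as a fraction not percent),
#'   `lambda_db` (1/min), `V_serum` (l). (`c_RM` and `r_im` do not enter the
#'   ODE; they act on observables and initial conditions.)
#' @param pool an antigen pool as returned by [antigen_pool_model1()] or
#'   [antigen_pool_model2()].
#' @param spec an [antibody_spec()].
#' @param nuclide a [nuclide_spec()] supplying `lambda_phys`, or `NULL` for
#'   the decay-free system (used for decay-corrected observables; see the
#'   methods vignette).
#' @param fixed fixed constants from [fixed_defaults()].
#' @param serum_includes_metabolites logical; whether plasma metabolites
#'   count towards the serum observable.
#' @return Object of class `pbpk_system`: the linear matrix `A`, the
#'   association term table, occupancy weights, antigen vector, and an
#'   `rhs(y)` closure evaluating the derivative.
#' @export
build_rhs <- function(params, pool, spec = antibody_spec(), nuclide = NULL,
                      fixed = fixed_defaults(),
                      serum_includes_metabolites = TRUE) {
  si <- state_index()
  p <- as.list(params)
  req <- c("ex_l", "ex_s", "f_RM", "lambda_db", "V_serum")
  miss <- setdiff(req, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  stopifnot(p$ex_l >= 0, p$ex_l <= 1, p$ex_s >= 0, p$ex_s <= 1,
            p$f_RM >= 0, p$lambda_db >= 0, p$V_serum > 0)
  if (!inherits(pool, "antigen_pool")) stop("pool must be an antigen_pool")
  lambda_phys <- if (is.null(nuclide)) 0 else nuclide$lambda_phys

  n <- si$n
  A <- matrix(0, n, n, dimnames = list(si$names, si$names))
  add <- function(to, from, rate) {
    A[to, from] <<- A[to, from] + rate
    A[from, from] <<- A[from, from] - rate
  }

  # effective antibody exchange flow: organ plasma flow times the vascular
  # transmission factor (antibody extravasation is far slower than plasma
  # flow; red marrow's effective flow is the fitted f_RM itself)
  Q <- c(RM = p$f_RM * fixed$Q_co,
         Li = fixed$Q_liver * fixed$perm_liver,
         Sp = fixed$Q_spleen * fixed$perm_spleen,
         GI = fixed$Q_GI * fixed$perm_GI)
  V <- c(RM = fixed$V_RM, Li = fixed$V_liver, Sp = fixed$V_spleen,
         GI = fixed$V_GI, Bl = p$V_serum)
  ex <- c(RM = 0, Li = p$ex_l, Sp = p$ex_s, GI = 0)

  a_o <- integer(0); a_i <- integer(0); a_j <- integer(0); a_c <- numeric(0)
  aterm <- function(o, i, j, coef) {
    a_o[[length(a_o) + 1L]] <<- match(o, si$organs)
    a_i[[length(a_i) + 1L]] <<- si$idx[[i]]
    a_j[[length(a_j) + 1L]] <<- si$idx[[j]]
    a_c[[length(a_c) + 1L]] <<- coef
  }

  for (l in .LABELS) {
    for (cl in .CLASSES) {
      nm <- function(comp) paste(comp, l, cl, sep = ".")
      meta <- paste("Meta", l, sep = ".")

      # flow transport plasma <-> organ spaces
      for (o in c("RM", "Li", "Sp", "GI")) {
        tgt <- if (o == "GI") "GI" else paste0("F_", o)
        add(nm(tgt), nm("P"), Q[[o]] / p$V_serum)
        add(nm("P"), nm(tgt), Q[[o]] / V[[o]])
      }
      # unspecific uptake: slow first-order transfer from the organ free
      # space into the extravascular delay pool, scaled by the fitted
      # fraction ex_o; first-order return at k_ret
      add(nm("D_Li"), nm("F_Li"), ex[["Li"]] * fixed$k_unspec)
      add(nm("D_Sp"), nm("F_Sp"), ex[["Sp"]] * fixed$k_unspec)
      add(nm("F_Li"), nm("D_Li"), fixed$k_ret)
      add(nm("F_Sp"), nm("D_Sp"), fixed$k_ret)

      # free-antibody degradation (plasma, organ spaces, GI)
      for (comp in c("P", "F_RM", "F_Li", "F_Sp", "GI"))
        add(meta, nm(comp), fixed$lambda_df)

      if (cl != "non") {
        for (o in .ORGANS) {
          fcomp <- nm(.ORGAN_FREE[[o]])
          mcomp <- nm(paste0("M_", o))
          vol <- if (o == "Bl") p$V_serum else V[[o]]
          # association (nonlinear, shared free antigen); statistical factor
          # 2 for the fully reactive species, 1 for half-reactive
          k1 <- if (cl == "full") 2 * spec$k_on else spec$k_on
          aterm(o, fcomp, mcomp, k1 / vol)
          add(fcomp, mcomp, spec$k_off)          # dissociation
          add(meta, mcomp, p$lambda_db)          # degradation of bound
          if (cl == "full") {
            bcomp <- nm(paste0("B_", o))
            aterm(o, mcomp, bcomp, spec$k_on / vol)  # cross-linking
            add(mcomp, bcomp, 2 * spec$k_off)
            add(meta, bcomp, p$lambda_db)
          }
        }
      }
    }
    # metabolite submodel per label
    m <- function(comp) paste(comp, l, sep = ".")
    add(m("ex1"), m("Meta"), fixed$k_meta_ex1)
    add(m("Meta"), m("ex1"), fixed$k_ex1_meta)
    add(m("ex2"), m("Meta"), fixed$k_meta_ex2)
    add(m("Meta"), m("ex2"), fixed$k_ex2_meta)
    add(m("Excr"), m("Meta"), fixed$k_urine)
  }

  # physical decay relabels: labeled state -> congruent unlabeled state
  if (lambda_phys > 0) {
    for (nm_l in grep("\\.L(\\.|$)", si$names, value = TRUE)) {
      nm_u <- sub("\\.L", ".U", nm_l)
      add(nm_u, nm_l, lambda_phys)
    }
  }

  assoc <- data.frame(o = a_o, i = a_i, j = a_j, coef = a_c)
  Ag <- c(RM = pool$Ag_RM, Li = pool$Ag_L, Sp = pool$Ag_S, Bl = pool$Ag_B)

  sys <- structure(
    list(A = A, assoc = assoc, occw = si$occw, Ag = Ag, si = si,
         params = p, pool = pool, spec = spec, nuclide = nuclide,
         fixed = fixed, lambda_phys = lambda_phys,
         serum_includes_metabolites = serum_includes_metabolites),
    class = "pbpk_system"
  )
  sys$rhs <- function(y) {
    stopifnot(length(y) == n)
    as.numeric(.pbpk_rhs_eval(sys$A, sys$assoc$i - 1L, sys$assoc$j - 1L,
                              sys$assoc$o - 1L, sys$assoc$coef, sys$occw,
                              sys$Ag, y))
  }
  sys
}

#' Initial state for an injection
#'
#' Places the partitioned injection amounts as an instantaneous bolus into
#' the plasma compartments of the six species.
#'
#' @param sys a `pbpk_system` from [build_rhs()].
#' @param inj an [injection()].
#' @param r_im arm-level immunoreactivity used to partition the bolus.
#' @param state optional existing state to add the bolus to (carryover).
#' @return Named state vector (nmol) with attribute `n_lab`, the labeled
#'   amount injected (the normalisation basis for observables).
#' @export
initial_state <- function(sys, inj, r_im, state = NULL) {
  si <- sys$si
  y <- if (is.null(state)) setNames(numeric(si$n), si$names) else state
  amt <- partition_injection(inj, r_im, sys$spec)
  for (l in c(labeled = "L", unlabeled = "U")) {
    row <- if (l == "L") "labeled" else "unlabeled"
    for (cl in .CLASSES)
      y[paste("P", l, cl, sep = ".")] <-
        y[paste("P", l, cl, sep = ".")] + amt[row, cl]
  }
  attr(y, "n_lab") <- attr(amt, "n_lab")
  y
}

# free antigen per organ for a state matrix (rows = times)
.ag_free <- function(sys, ymat) {
  occ <- ymat %*% sys$occw
  sweep(-occ, 2, sys$Ag, `+`)
}
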