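# State-space layout.
#
# Six antibody species (label {L, U} x immunoreactivity class
# {full, half, non}), each with free compartments
#   P (main vascular/plasma), F_RM, F_Li, F_Sp (organ vascular+interstitial,
#   one lumped space per organ), GI, D_Li, D_Sp (extravascular delay),
# plus bound compartments per antigen-expressing site {RM, Li, Sp, Bl}:
# monovalent M (classes full, half) and bivalent B (class full only; blood
# binding takes place in the plasma compartment itself). Per label there are
# four metabolite states (Meta, ex1, ex2, Excr) fed by degradation.

.LABELS <- c("L", "U")
.CLASSES <- c("full", "half", "non")
.ORGANS <- c("RM", "Li", "Sp", "Bl")
.FREE_COMPS <- c("P", "F_RM", "F_Li", "F_Sp", "GI", "D_Li", "D_Sp")
.META_COMPS <- c("Meta", "ex1", "ex2", "Excr")

# free compartment in which each organ's antigen binds
.ORGAN_FREE <- c(RM = "F_RM", Li = "F_Li", Sp = "F_Sp", Bl = "P")

#' State index of the PBPK model
#'
#' @return A list with the state names, their count `n`, the organ order used
#'   for antigen pools, and the occupancy-weight matrix `occw`
#'   (states x organs; 1 per monovalently, 2 per bivalently bound antibody)
#'   used to form free-antigen amounts `Ag_free = Ag - t(occw) %*% y`.
#' @export
state_index <- function() {
  if (!is.null(.pkg_env$state_index)) return(.pkg_env$state_index)
  nm <- character(0)
  for (l in .LABELS) {
    for (cl in .CLASSES) {
      nm <- c(nm, paste(.FREE_COMPS, l, cl, sep = "."))
      if (cl != "non")
        nm <- c(nm, paste(paste0("M_", .ORGANS), l, cl, sep = "."))
      if (cl == "full")
        nm <- c(nm, paste(paste0("B_", .ORGANS), l, cl, sep = "."))
    }
    nm <- c(nm, paste(.META_COMPS, l, sep = "."))
  }
  n <- length(nm)
  occw <- matrix(0, n, length(.ORGANS), dimnames = list(nm, .ORGANS))
  for (o in .ORGANS) {
    occw[grep(paste0("^M_", o, "\\."), nm), o] <- 1
    occw[grep(paste0("^B_", o, "\\."), nm), o] <- 2
  }
  idx <- setNames(seq_len(n), nm)
  ab_states <- nm[!grepl(paste0("^(", paste(.META_COMPS, collapse = "|"),
                                ")\\."), nm)]
  out <- list(names = nm, n = n, idx = idx, organs = .ORGANS, occw = occw,
              antibody_states = ab_states)
  .pkg_env$state_index <- out
  out
}

# indices of the labeled-species columns entering each observable region
.obs_columns <- function(si) {
  nm <- si$names
  lab <- function(p) grep(p, nm, value = TRUE)
  list(
    serum_free = lab("^P\\.L\\."),
    serum_meta = "Meta.L",
    red_marrow = c(lab("^F_RM\\.L\\."), lab("^M_RM\\.L\\."),
                   lab("^B_RM\\.L\\.")),
    liver = c(lab("^F_Li\\.L\\."), lab("^D_Li\\.L\\."), lab("^M_Li\\.L\\."),
              lab("^B_Li\\.L\\.")),
    spleen = c(lab("^F_Sp\\.L\\."), lab("^D_Sp\\.L\\."), lab("^M_Sp\\.L\\."),
               lab("^B_Sp\\.L\\.")),
    excreted = "Excr.L"
  )
}

.REGIONS <- c("red_marrow", "liver", "spleen", "total_body", "serum")
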