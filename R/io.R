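# Patient-dataset schema and file round trip.
#
# On disk a dataset is a pair of sibling files sharing a basename:
#   <base>_measurements.csv  (phase, region, time_min, value, fractional_sd)
#   <base>_meta.json         (patient id, physiology, injections, provenance)

.PHASES <- c("pre", "therapy")

#' Construct and validate a patient dataset
#'
#' @param patient_id identifier string.
#' @param physiology a [patient_physiology()].
#' @param injections data.frame with columns `phase` (`"pre"`/`"therapy"`),
#'   `time_min`, `amount_mg`, `activity_MBq`, `nuclide` (`"In111"`/`"Y90"`).
#' @param measurements data.frame with columns `phase`, `region`, `time_min`,
#'   `value` (fraction of injected activity; for serum, fraction per litre),
#'   `fractional_sd`.
#' @param provenance free-form metadata list.
#' @return Object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, physiology, injections, measurements,
                            provenance = list()) {
  ds <- structure(
    list(patient_id = as.character(patient_id), physiology = physiology,
         injections = as.data.frame(injections),
         measurements = as.data.frame(measurements),
         provenance = provenance),
    class = "patient_dataset"
  )
  problems <- validate_dataset(ds)
  if (length(problems))
    stop("invalid patient dataset:\n  ", paste(problems, collapse = "\n  "))
  ds
}

#' Validate a patient dataset against the schema
#'
#' @param ds a candidate `patient_dataset`.
#' @return character vector of violations (empty when valid), each naming the
#'   offending row where applicable.
#' @export
validate_dataset <- function(ds) {
  p <- character(0)
  m <- ds$measurements
  need <- c("phase", "region", "time_min", "value", "fractional_sd")
  if (!all(need %in% names(m)))
    return(paste("measurements missing column(s):",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (!nrow(m)) return("no data: measurement table is empty")
  bad <- which(!m$phase %in% .PHASES)
  if (length(bad)) p <- c(p, paste0("row ", bad, ": unknown phase '",
                                    m$phase[bad], "'"))
  bad <- which(!m$region %in% .REGIONS)
  if (length(bad)) p <- c(p, paste0("row ", bad, ": unknown region '",
                                    m$region[bad], "'"))
  bad <- which(!is.finite(m$time_min) | m$time_min < 0)
  if (length(bad)) p <- c(p, paste0("row ", bad, ": negative or missing time"))
  bad <- which(!is.finite(m$value) | m$value <= 0)
  if (length(bad)) p <- c(p, paste0("row ", bad, ": non-positive value"))
  bad <- which(m$region != "serum" & is.finite(m$value) & m$value > 1.5)
  if (length(bad)) p <- c(p, paste0("row ", bad,
                                    ": fraction of injected activity > 1.5"))
  for (ph in unique(m$phase)) for (rg in unique(m$region)) {
    sel <- which(m$phase == ph & m$region == rg)
    if (length(sel) > 1 && any(diff(m$time_min[sel]) <= 0))
      p <- c(p, sprintf("non-increasing times within (%s, %s)", ph, rg))
  }
  inj <- ds$injections
  needi <- c("phase", "time_min", "amount_mg", "activity_MBq", "nuclide")
  if (!all(needi %in% names(inj))) {
    p <- c(p, paste("injections missing column(s):",
                    paste(setdiff(needi, names(inj)), collapse = ", ")))
  } else {
    if (!"pre" %in% inj$phase) p <- c(p, "missing pre-therapy injection")
    if (any(inj$amount_mg <= 0)) p <- c(p, "injection amount_mg must be > 0")
    if (any(inj$activity_MBq < 0)) p <- c(p, "injection activity must be >= 0")
    if ("therapy" %in% m$phase && !"therapy" %in% inj$phase)
      p <- c(p, "therapy measurements present but no therapy injection")
  }
  if (!inherits(ds$physiology, "patient_physiology"))
    p <- c(p, "physiology block missing or not a patient_physiology")
  p
}

.get_injection <- function(ds, phase) {
  row <- ds$injections[ds$injections$phase == phase, ]
  if (!nrow(row)) stop("missing ", phase, " injection")
  injection(row$time_min[1], row$amount_mg[1], row$activity_MBq[1],
            nuclide(row$nuclide[1]))
}

#' Write a patient dataset
#'
#' @param ds a `patient_dataset`.
#' @param base path basename; `<base>_measurements.csv` and
#'   `<base>_meta.json` are created.
#' @return `base`, invisibly.
#' @export
write_patient_dataset <- function(ds, base) {
  stopifnot(inherits(ds, "patient_dataset"))
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  m <- ds$measurements
  m$value <- signif(m$value, 12)
  write.csv(m, paste0(base, "_measurements.csv"), row.names = FALSE)
  meta <- list(patient_id = ds$patient_id,
               physiology = unclass(ds$physiology),
               injections = ds$injections,
               provenance = ds$provenance)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(base)
}

#' Read a patient dataset
#'
#' @param base path basename used by [write_patient_dataset()].
#' @return A validated `patient_dataset`.
#' @export
read_patient_dataset <- function(base) {
  mfile <- paste0(base, "_measurements.csv")
  jfile <- paste0(base, "_meta.json")
  if (!file.exists(mfile) || !file.exists(jfile))
    stop("dataset files not found for basename ", base)
  m <- read.csv(mfile, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(jfile, simplifyVector = TRUE)
  phys <- do.call(patient_physiology, as.list(meta$physiology))
  patient_dataset(meta$patient_id, phys, as.data.frame(meta$injections), m,
                  provenance = as.list(meta$provenance))
}
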