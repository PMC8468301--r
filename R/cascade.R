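# data_io: exclusion cascade ----------------------------------------------
#
# Routine TDM data sets carry records that cannot be used for model
# evaluation. The cascade removes them in a fixed order, attributing every
# removed record to exactly one stage:
#   1. patients whose dosing history is unusable (no dose records, or dose
#      records with missing time/amount, or samples preceding the first
#      recorded dose), together with all their samples;
#   2. concentrations below the lower limit of quantification (M1 method);
#   3. pharmacokinetically implausible concentrations: within one dosing
#      interval, a sample drawn at least `implausibility_window` days after
#      an earlier retained sample whose concentration it fails to undercut
#      is discarded (the later member of the pair), re-scanning until no
#      violation remains;
#   4. patients left without a single informative (detectable) concentration.

#' Cleaning thresholds for the exclusion cascade
#'
#' @param lloq_conc Lower limit of quantification for serum drug
#'   concentrations, ug/mL. The default is 2.68 ng/mL expressed in ug/mL.
#' @param ada_lloq Lower limit of quantification of the ADA assay, U/mL.
#' @param ada_positive_threshold ADA positivity threshold, U/mL.
#' @param implausibility_window Minimum time separation, in days, over which
#'   a concentration must decrease within a dosing interval.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(lloq_conc = 2.68e-3, ada_lloq = 3.13,
                            ada_positive_threshold = 6.6,
                            implausibility_window = 7) {
  stopifnot(lloq_conc > 0, ada_lloq > 0, implausibility_window > 0,
            ada_positive_threshold >= ada_lloq)
  structure(list(lloq_conc = lloq_conc, ada_lloq = ada_lloq,
                 ada_positive_threshold = ada_positive_threshold,
                 implausibility_window = implausibility_window),
            class = "cleaning_config")
}

#' Apply the exclusion cascade to an event table
#'
#' @param data An [event_table()].
#' @param cfg A [cleaning_config()].
#' @return A list with elements `data` (the cleaned [event_table()]) and
#'   `report` (an `exclusion_report` with per-stage removal counts and
#'   retained totals; samples are observation rows with a non-missing
#'   dependent value).
#' @export
apply_exclusion_cascade <- function(data, cfg = cleaning_config()) {
  stopifnot(inherits(data, "event_table"), inherits(cfg, "cleaning_config"))
  n_in_samples <- sum(obs_rows(data))
  n_in_patients <- length(patient_ids(data))

  # stage 1: unusable dosing records
  bad_patient <- vapply(patient_ids(data), function(p) {
    rows <- data[data$id == p, , drop = FALSE]
    doses <- rows[rows$evid == 1, , drop = FALSE]
    has_obs <- any(rows$evid == 0 & rows$mdv == 0)
    if (!has_obs) return(FALSE)           # handled at stage 4 if uninformative
    if (nrow(doses) == 0) return(TRUE)
    if (any(is.na(doses$time)) || any(is.na(doses$amt)) || any(doses$amt <= 0))
      return(TRUE)
    min(rows$time[rows$evid == 0 & rows$mdv == 0]) < min(doses$time)
  }, logical(1))
  stage1_ids <- patient_ids(data)[bad_patient]
  stage1_samples <- sum(obs_rows(data) & data$id %in% stage1_ids)
  keep <- !(data$id %in% stage1_ids)
  data <- data[keep, , drop = FALSE]

  # stage 2: BLQ observations (M1)
  blq <- obs_rows(data) & (data$blq | (!is.na(data$dv) & data$dv < cfg$lloq_conc))
  stage2_samples <- sum(blq)
  data <- data[!blq, , drop = FALSE]

  # stage 3: implausible observations
  window_h <- cfg$implausibility_window * HOURS_PER_DAY
  drop_idx <- integer(0)
  for (p in unique(data$id)) {
    prows <- which(data$id == p)
    dose_t <- sort(data$time[prows][data$evid[prows] == 1])
    oidx <- prows[data$evid[prows] == 0 & data$mdv[prows] == 0]
    if (length(oidx) < 2 || length(dose_t) == 0) next
    oidx <- oidx[order(data$time[oidx])]
    interval <- findInterval(data$time[oidx], dose_t)
    for (iv in unique(interval)) {
      in_iv <- oidx[interval == iv]
      kept_t <- numeric(0); kept_c <- numeric(0)
      for (j in in_iv) {
        tj <- data$time[j]; cj <- data$dv[j]
        violates <- length(kept_t) > 0 &&
          any(tj - kept_t >= window_h & cj >= kept_c)
        if (violates) drop_idx <- c(drop_idx, j)
        else { kept_t <- c(kept_t, tj); kept_c <- c(kept_c, cj) }
      }
    }
  }
  stage3_samples <- length(drop_idx)
  if (length(drop_idx)) data <- data[-drop_idx, , drop = FALSE]

  # stage 4: patients without informative concentrations
  informative <- tapply(obs_rows(data), data$id, sum)
  stage4_ids <- names(informative)[informative == 0]
  data <- data[!(data$id %in% stage4_ids), , drop = FALSE]

  data <- event_table(as.data.frame(data))
  report <- structure(list(
    missing_dosing_patients = length(stage1_ids),
    missing_dosing_samples = stage1_samples,
    blq_samples = stage2_samples,
    implausible_samples = stage3_samples,
    uninformative_patients = length(stage4_ids),
    retained = list(patients = length(patient_ids(data)),
                    samples = sum(obs_rows(data))),
    input = list(patients = n_in_patients, samples = n_in_samples)
  ), class = "exclusion_report")
  list(data = data, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade report\n")
  cat(sprintf("  input:               %d samples / %d patients\n",
              x$input$samples, x$input$patients))
  cat(sprintf("  missing dosing info: -%d samples (%d patients)\n",
              x$missing_dosing_samples, x$missing_dosing_patients))
  cat(sprintf("  BLQ (M1):            -%d samples\n", x$blq_samples))
  cat(sprintf("  implausible:         -%d samples\n", x$implausible_samples))
  cat(sprintf("  uninformative:       %d patients\n", x$uninformative_patients))
  cat(sprintf("  retained:            %d samples / %d patients\n",
              x$retained$samples, x$retained$patients))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An `exclusion_report` from [apply_exclusion_cascade()].
#' @param path Output path.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
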