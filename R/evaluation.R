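# evaluation: accuracy, bias, stratification, dose-escalation -------------
#
# Forecast errors are summarized on the log accuracy ratio ln(pred/obs):
# the median symmetric accuracy zeta = 100*(exp(median |ln(y/x)|) - 1) is a
# robust, symmetric percentage error ("50% of absolute percentage errors lie
# below zeta"), and the symmetric signed percentage bias
# SSPB = 100*sign(M)*(exp(|M|) - 1), M = median ln(y/x), penalizes over- and
# underprediction equally. Both are undefined for non-positive values.

check_pairs <- function(obs, pred) {
  if (length(obs) == 0 || length(pred) == 0) {
    stop("no observation/prediction pairs", call. = FALSE)
  }
  stopifnot(length(obs) == length(pred))
  if (any(is.na(obs)) || any(is.na(pred)) || any(obs <= 0) || any(pred <= 0)) {
    stop("observed and predicted concentrations must be positive", call. = FALSE)
  }
}

#' Median symmetric accuracy (percent)
#'
#' @param obs Observed concentrations (> 0).
#' @param pred Corresponding predicted concentrations (> 0).
#' @return `100 * (exp(median |ln(pred/obs)|) - 1)`, in percent.
#' @export
median_symmetric_accuracy <- function(obs, pred) {
  check_pairs(obs, pred)
  100 * (exp(stats::median(abs(log(pred / obs)))) - 1)
}

#' Symmetric signed percentage bias (percent)
#'
#' @inheritParams median_symmetric_accuracy
#' @return `100 * sign(M) * (exp(|M|) - 1)` with `M = median ln(pred/obs)`,
#'   in percent; positive values indicate overprediction.
#' @export
symmetric_signed_percentage_bias <- function(obs, pred) {
  check_pairs(obs, pred)
  m <- stats::median(log(pred / obs))
  100 * sign(m) * (exp(abs(m)) - 1)
}

MONTH_DAYS <- 30
SIX_MONTHS_DAYS <- 183

ADA_NEG_STRATA <- c("<=1 month", "1-6 months", ">6 months", "all_pred")
ADA_POS_STRATA <- c("before ADA+", "1st ADA+ <=1 month", ">1 month ADA+",
                    "all_pred")

#' Stratify prediction records by ADA status and time
#'
#' ADA-negative patients' predictions are grouped by time after the anchor
#' concentration (within 1 month, 1-6 months, beyond 6 months; 1 month = 30
#' days, 6 months = 183 days). ADA-positive patients' predictions are
#' grouped relative to the first ADA-positive measurement (before it, within
#' a month of it, more than a month after it). `all_pred` collects all
#' predictions of a group, excluding the anchor record, which is excluded
#' from every stratum.
#'
#' @param records A `prediction_record` data.frame (see [forecast()]).
#' @return A named list of two lists of record subsets:
#'   `ada_negative` and `ada_positive`.
#' @export
stratify_predictions <- function(records) {
  stopifnot(is.data.frame(records))
  r <- records[!records$anchor, , drop = FALSE]
  neg <- r[!r$ada_patient, , drop = FALSE]
  pos <- r[r$ada_patient, , drop = FALSE]
  if (nrow(pos) && any(is.na(pos$first_ada_time))) {
    stop("ADA-positive record without a first ADA-positive time", call. = FALSE)
  }
  dt <- neg$time_after_cmap
  neg_split <- list(
    neg[dt <= MONTH_DAYS, , drop = FALSE],
    neg[dt > MONTH_DAYS & dt <= SIX_MONTHS_DAYS, , drop = FALSE],
    neg[dt > SIX_MONTHS_DAYS, , drop = FALSE],
    neg
  )
  names(neg_split) <- ADA_NEG_STRATA
  td <- pos$time / HOURS_PER_DAY
  rel <- td - pos$first_ada_time
  pos_split <- list(
    pos[td < pos$first_ada_time, , drop = FALSE],
    pos[rel >= 0 & rel <= MONTH_DAYS, , drop = FALSE],
    pos[rel > MONTH_DAYS, , drop = FALSE],
    pos
  )
  names(pos_split) <- ADA_POS_STRATA
  list(ada_negative = neg_split, ada_positive = pos_split)
}

#' Dose-escalation classification settings
#'
#' @param target_trough Target trough concentration in ug/mL; troughs below
#'   it call for dose escalation.
#' @export
classification_config <- function(target_trough = 5) {
  stopifnot(target_trough > 0)
  structure(list(target_trough = target_trough),
            class = "classification_config")
}

#' Classify a trough prediction against the dose-escalation target
#'
#' "Positive" means dose escalation needed (trough below target). `TP`: both
#' observed and predicted below; `TN`: both at or above; `FP`: predicted
#' below, observed at or above; `FN`: predicted at or above, observed below.
#'
#' @param obs Observed trough concentration(s), ug/mL.
#' @param pred Predicted trough concentration(s), ug/mL.
#' @param cfg A [classification_config()].
#' @return Character vector in `c("TP", "FN", "TN", "FP")`.
#' @export
classify_trough <- function(obs, pred, cfg = classification_config()) {
  th <- cfg$target_trough
  ifelse(obs < th, ifelse(pred < th, "TP", "FN"),
                   ifelse(pred < th, "FP", "TN"))
}

#' Classification accuracy from confusion counts
#'
#' @param counts Named list or vector with `TP`, `FN`, `TN`, `FP`.
#' @return Accuracy `100 * (TP + TN) / total` in percent, rounded to one
#'   decimal as reported.
#' @export
summarize_classification <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("TP", "FN", "TN", "FP") %in% names(counts)))
  total <- counts$TP + counts$FN + counts$TN + counts$FP
  if (total == 0) stop("no classified trough samples", call. = FALSE)
  round(100 * (counts$TP + counts$TN) / total, 1)
}

confusion_counts <- function(labels) {
  as.list(table(factor(labels, levels = c("TP", "FN", "TN", "FP"))))
}

#' Evaluate a set of prediction records
#'
#' Computes per-stratum accuracy (zeta) and bias (SSPB), and dose-escalation
#' confusion counts over trough records split by sample-level ADA status.
#' Records with non-positive or missing observed/predicted values are
#' dropped from zeta/SSPB with a warning.
#'
#' @param records A `prediction_record` data.frame, typically row-bound over
#'   patients.
#' @param cfg A [classification_config()].
#' @return An `evaluation_summary` with elements `strata` (data.frame:
#'   `group`, `stratum`, `n`, `zeta`, `sspb`) and `classification`
#'   (data.frame: `group`, `TP`, `FN`, `TN`, `FP`, `accuracy`).
#' @export
evaluate_predictions <- function(records, cfg = classification_config()) {
  stopifnot(is.data.frame(records))
  usable <- !is.na(records$obs) & !is.na(records$pred) &
    records$obs > 0 & records$pred > 0
  if (any(!usable & !records$anchor)) {
    warning(sum(!usable & !records$anchor),
            " record(s) with non-positive observed/predicted values ",
            "excluded from zeta/SSPB", call. = FALSE)
  }
  strata <- stratify_predictions(records[usable | records$anchor, , drop = FALSE])
  tab <- do.call(rbind, lapply(names(strata), function(grp) {
    do.call(rbind, lapply(names(strata[[grp]]), function(st) {
      rr <- strata[[grp]][[st]]
      rr <- rr[!is.na(rr$obs) & rr$obs > 0 & rr$pred > 0, , drop = FALSE]
      data.frame(group = grp, stratum = st, n = nrow(rr),
                 zeta = if (nrow(rr)) median_symmetric_accuracy(rr$obs, rr$pred)
                        else NA_real_,
                 sspb = if (nrow(rr)) symmetric_signed_percentage_bias(rr$obs, rr$pred)
                        else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  tr <- records[records$trough & !records$anchor & usable, , drop = FALSE]
  cls <- do.call(rbind, lapply(c(FALSE, TRUE), function(adapos) {
    sub <- tr[tr$ada_sample == adapos, , drop = FALSE]
    cc <- confusion_counts(classify_trough(sub$obs, sub$pred, cfg))
    data.frame(group = if (adapos) "ada_positive" else "ada_negative",
               TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP,
               accuracy = if (sum(unlist(cc)) > 0)
                 summarize_classification(cc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(strata = tab, classification = cls,
                 target_trough = cfg$target_trough),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("Evaluation summary (target trough", x$target_trough, "ug/mL)\n\n")
  print(transform(x$strata, zeta = round(zeta, 1), sspb = round(sspb, 1)),
        row.names = FALSE)
  cat("\nDose-escalation classification (trough samples):\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation summary to JSON
#'
#' @param summary An `evaluation_summary`.
#' @param path Output path.
#' @export
write_evaluation_summary <- function(summary, path) {
  stopifnot(inherits(summary, "evaluation_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
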