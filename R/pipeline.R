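# pipeline: clean -> anchor -> MAP -> forecast -> evaluate -> VPC ---------

#' Forecast all patients of a cleaned data set with one model
#'
#' Runs the single-anchor Bayesian forecasting workflow patient by patient:
#' the first retained concentration is the anchor for MAP estimation, all
#' later observations are predicted.
#'
#' @param model A [poppk_model()].
#' @param data A cleaned [event_table()].
#' @param policy Covariate policy for predictions.
#' @return A `prediction_record` data.frame over all patients.
#' @export
forecast_cohort <- function(model, data,
                            policy = c("locf_at_anchor", "full")) {
  policy <- match.arg(policy)
  recs <- lapply(patient_ids(data), function(p) {
    task <- make_forecast_task(data, p, policy = policy)
    est <- estimate_ebes(model, task)
    forecast(model, est, task)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("prediction_record", "data.frame")
  out
}

#' Run the complete external-evaluation pipeline
#'
#' Cleans the data set, then for every model that is compatible with it:
#' MAP-forecasts every patient from their anchor concentration, computes
#' stratified accuracy/bias and dose-escalation classification, and runs a
#' prediction- and variability-corrected VPC. Incompatible models are
#' skipped with a recorded finding rather than failing the run.
#'
#' @param models A [poppk_model()] or list of them.
#' @param data An [event_table()] or path to a NONMEM-convention CSV.
#' @param policy Covariate policy for predictions.
#' @param cleaning A [cleaning_config()], or `NULL` to skip cleaning.
#' @param classification A [classification_config()].
#' @param vpc A [vpc_config()]; its seed is derived from `seed`.
#' @param seed Top-level seed; all stochastic stages derive labelled
#'   substream seeds from it.
#' @param outdir Optional output directory; when given, per-model
#'   predictions (CSV), evaluation summaries and VPC results (JSON), the
#'   exclusion report and the run configuration are written there.
#' @return A `pipeline_result`: `report` (exclusion report), `results`
#'   (per model: `predictions`, `summary`, `vpc`, `gof`), `skipped`
#'   (per-model findings), `seed`.
#' @export
run_pipeline <- function(models, data, policy = c("locf_at_anchor", "full"),
                         cleaning = cleaning_config(),
                         classification = classification_config(),
                         vpc = vpc_config(), seed = 1L, outdir = NULL) {
  policy <- match.arg(policy)
  if (is.character(data)) data <- parse_event_table(data)
  if (inherits(models, "poppk_model")) models <- list(models)
  nms <- vapply(models, function(m) m$name, character(1))
  names(models) <- nms
  report <- NULL
  if (!is.null(cleaning)) {
    cleaned <- apply_exclusion_cascade(data, cleaning)
    data <- cleaned$data
    report <- cleaned$report
  }
  results <- list()
  skipped <- list()
  for (nm in nms) {
    model <- models[[nm]]
    findings <- validate_against_dataset(model, data)
    if (length(findings)) {
      message("skipping model '", nm, "': ", paste(findings, collapse = "; "))
      skipped[[nm]] <- findings
      next
    }
    preds <- forecast_cohort(model, data, policy = policy)
    summary <- evaluate_predictions(preds, classification)
    vcfg <- vpc
    vcfg$seed <- derive_seed(seed, paste0("vpc:", nm))
    vres <- pvc_vpc(model, data, vcfg)
    results[[nm]] <- list(predictions = preds, summary = summary,
                          vpc = vres, gof = gof_table(preds))
  }
  out <- structure(list(report = report, results = results,
                        skipped = skipped, seed = seed, policy = policy),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(out, outdir)
  out
}

write_pipeline_result <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$report)) {
    write_exclusion_report(x$report, file.path(outdir, "exclusion_report.json"))
  }
  jsonlite::write_json(list(seed = x$seed, policy = x$policy,
                            models = names(x$results)),
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(x$results)) {
    res <- x$results[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    utils::write.csv(as.data.frame(res$predictions),
                     file.path(outdir, paste0(safe, "_predictions.csv")),
                     row.names = FALSE, na = "")
    write_evaluation_summary(res$summary,
                             file.path(outdir, paste0(safe, "_summary.json")))
    jsonlite::write_json(as.data.frame(res$vpc),
                         file.path(outdir, paste0(safe, "_vpc.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(outdir)
}

gof_stratum <- function(records) {
  td <- records$time / HOURS_PER_DAY
  dt <- records$time_after_cmap
  ifelse(records$anchor, "C_MAP",
  ifelse(!records$ada_patient,
         ifelse(dt <= MONTH_DAYS, ADA_NEG_STRATA[1],
         ifelse(dt <= SIX_MONTHS_DAYS, ADA_NEG_STRATA[2], ADA_NEG_STRATA[3])),
         ifelse(td < records$first_ada_time, ADA_POS_STRATA[1],
         ifelse(td - records$first_ada_time <= MONTH_DAYS, ADA_POS_STRATA[2],
                ADA_POS_STRATA[3]))))
}

#' Long-format goodness-of-fit table
#'
#' One row per prediction record with its time stratum, suitable for an
#' observed-versus-individual-predicted scatter with the anchor records
#' flagged.
#'
#' @param records A `prediction_record` data.frame.
#' @return A data.frame `id`, `obs`, `pred`, `group`, `stratum`, `anchor`.
#' @export
gof_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  data.frame(
    id = records$id,
    obs = records$obs,
    pred = records$pred,
    group = ifelse(records$ada_patient, "ada_positive", "ada_negative"),
    stratum = gof_stratum(records),
    anchor = records$anchor,
    stringsAsFactors = FALSE
  )
}

#' Observed-versus-predicted goodness-of-fit plot
#'
#' Identity line plus a guide at the target trough concentration; anchor
#' concentrations are drawn as triangles.
#'
#' @param records A `prediction_record` data.frame.
#' @param target_trough Guide line position, ug/mL.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
gof_plot <- function(records, target_trough = 5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("gof_plot() requires the ggplot2 package", call. = FALSE)
  }
  df <- gof_table(records)
  df <- df[!is.na(df$obs), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = obs, y = pred, color = group,
                                   shape = anchor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_hline(yintercept = target_trough, linetype = 2,
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = target_trough, linetype = 2,
                        color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "Observed concentration (ug/mL)",
                  y = "Individual predicted concentration (ug/mL)")
}
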