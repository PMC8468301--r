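# data_io: NONMEM-convention event tables --------------------------------
#
# An event table is a long data.frame with one row per dosing or observation
# event, times in hours since each patient's first record, doses in mg,
# concentrations in ug/mL and anti-drug-antibody (ADA) levels in U/mL.
# Covariate columns ride along on every row and are looked up with a
# last-observation-carried-forward policy.

EVENT_CORE_COLS <- c("id", "time", "evid", "amt", "dur", "dv", "mdv", "blq", "ada")

#' Construct an event table
#'
#' @param df A data.frame with at least columns `id`, `time`, `evid`
#'   (1 = dose, 0 = observation), `amt` (mg, dose rows), `dur` (infusion
#'   duration, hours, dose rows), `dv` (concentration, ug/mL, observation
#'   rows), `mdv` (1 = missing dependent value), `blq` (logical, below the
#'   lower limit of quantification) and `ada` (ADA concentration, U/mL, `NA`
#'   when not measured). Any further column is treated as a covariate.
#' @return The data sorted by patient and time, with class `event_table` and
#'   a `covariates` attribute listing the covariate columns.
#' @export
event_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("amt", "dur", "dv", "mdv", "blq", "ada")) {
    if (is.null(df[[col]])) {
      df[[col]] <- if (col == "blq") logical(nrow(df)) else
        if (col == "mdv") ifelse(df$evid == 1, 1L, 0L) else
          rep(NA_real_, nrow(df))
    }
  }
  miss <- setdiff(c("id", "time", "evid"), names(df))
  if (length(miss)) {
    stop("event table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$evid <- as.integer(df$evid)
  df$mdv <- as.integer(df$mdv)
  df$blq <- as.logical(df$blq) & !is.na(df$blq)
  df <- df[order(df$id, df$time, -df$evid, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  covs <- setdiff(names(df), EVENT_CORE_COLS)
  df <- df[, c(EVENT_CORE_COLS, covs), drop = FALSE]
  out <- structure(df, covariates = covs, class = c("event_table", "data.frame"))
  validate_event_table(out)
  out
}

validate_event_table <- function(x) {
  tt <- x$time[!is.na(x$time)]
  if (any(tt < 0)) stop("event times must be non-negative", call. = FALSE)
  d <- x$evid == 1
  if (any(d & !is.na(x$amt) & x$amt <= 0)) {
    stop("dose rows must have amount > 0", call. = FALSE)
  }
  if (any(d & !is.na(x$dur) & x$dur < 0)) {
    stop("infusion durations must be >= 0", call. = FALSE)
  }
  o <- x$evid == 0 & x$mdv == 0
  bad <- o & !x$blq & (is.na(x$dv) | x$dv < 0)
  if (any(bad)) {
    stop("observation rows must carry a concentration >= 0 or a BLQ flag (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Read an event table from a NONMEM-convention CSV file
#'
#' Expects columns `ID`, `TIME`, `AMT`, `DV`, `EVID`, `MDV` plus either `DUR`
#' (infusion duration) or `RATE` (infusion rate, from which the duration is
#' derived as `AMT/RATE`), an optional `ADA` column and arbitrary covariate
#' columns. `column_map` renames non-standard headers, e.g.
#' `c(id = "SUBJID", dv = "CONC")`.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping internal names (lower
#'   case) to file headers.
#' @param dv_unit Unit of the `DV` column: `"ug/mL"` (stored as-is) or
#'   `"ng/mL"` (converted to ug/mL, i.e. multiplied by 1e-3).
#' @param time_unit Unit of the `TIME` column, `"hours"` or `"days"`.
#' @return An [event_table()].
#' @export
parse_event_table <- function(path, column_map = NULL,
                              dv_unit = c("ug/mL", "ng/mL"),
                              time_unit = c("hours", "days")) {
  dv_unit <- match.arg(dv_unit)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  std <- c(id = "ID", time = "TIME", amt = "AMT", dur = "DUR", rate = "RATE",
           dv = "DV", evid = "EVID", mdv = "MDV", blq = "BLQ", ada = "ADA")
  if (!is.null(column_map)) std[names(column_map)] <- unname(column_map)
  pick <- function(key) {
    hit <- match(toupper(std[[key]]), toupper(nm))
    if (is.na(hit)) NULL else raw[[hit]]
  }
  mandatory <- c("id", "time", "dv", "evid")
  have <- vapply(mandatory, function(k) !is.null(pick(k)), logical(1))
  if (!all(have)) {
    stop("missing mandatory column(s): ",
         paste(std[mandatory[!have]], collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  df <- data.frame(
    id = as.character(pick("id")),
    time = as.numeric(pick("time")),
    evid = as.integer(pick("evid")),
    amt = if (is.null(pick("amt"))) NA_real_ else as.numeric(pick("amt")),
    dv = as.numeric(pick("dv")),
    mdv = if (is.null(pick("mdv"))) NA_integer_ else as.integer(pick("mdv")),
    stringsAsFactors = FALSE
  )
  if (time_unit == "days") df$time <- df$time * HOURS_PER_DAY
  if (dv_unit == "ng/mL") df$dv <- df$dv * 1e-3
  dur <- pick("dur")
  if (is.null(dur)) {
    rate <- pick("rate")
    dur <- if (is.null(rate)) rep(NA_real_, n) else df$amt / as.numeric(rate)
  }
  df$dur <- as.numeric(dur)
  df$blq <- if (is.null(pick("blq"))) FALSE else as.logical(pick("blq")) %in% TRUE
  df$ada <- if (is.null(pick("ada"))) NA_real_ else as.numeric(pick("ada"))
  if (is.na(df$mdv[1]) && all(is.na(df$mdv))) {
    df$mdv <- ifelse(df$evid == 1 | is.na(df$dv), 1L, 0L)
  }
  bad_dose <- df$evid == 1 & is.na(df$time)
  if (any(bad_dose)) {
    stop("dose row without a time (file row ",
         paste(which(bad_dose) + 1L, collapse = ", "), ")", call. = FALSE)
  }
  used <- toupper(std[c(mandatory, "amt", "dur", "rate", "mdv", "blq", "ada")])
  covs <- nm[!(toupper(nm) %in% used)]
  for (cv in covs) df[[tolower(cv)]] <- raw[[cv]]
  event_table(df)
}

#' Write an event table back to the CSV dialect read by [parse_event_table()]
#'
#' @param data An [event_table()].
#' @param path Output path.
#' @export
write_event_table <- function(data, path) {
  stopifnot(inherits(data, "event_table"))
  out <- as.data.frame(data)
  covs <- attr(data, "covariates")
  names(out)[match(EVENT_CORE_COLS, names(out))] <-
    c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV", "BLQ", "ADA")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

obs_rows <- function(data) data$evid == 0 & data$mdv == 0
dose_rows <- function(data) data$evid == 1

patient_ids <- function(data) unique(data$id)

#' Look up a covariate value at a time point under an imputation policy
#'
#' Policy `"locf_at_anchor"` freezes covariates at the anchor concentration:
#' for any `t` past the anchor it returns the last value measured at or
#' before the anchor. Policy `"full"` uses all measurements, returning the
#' last value at or before `t` (time-varying covariates).
#'
#' @param data An [event_table()].
#' @param patient Patient id.
#' @param name Covariate column name.
#' @param t Time (hours).
#' @param policy `"locf_at_anchor"` or `"full"`.
#' @param anchor Anchor time (hours); required for `"locf_at_anchor"`.
#' @return The covariate value.
#' @export
covariate_value_at <- function(data, patient, name, t,
                               policy = c("locf_at_anchor", "full"),
                               anchor = NULL) {
  policy <- match.arg(policy)
  rows <- data[data$id == patient, , drop = FALSE]
  if (!name %in% names(rows)) {
    stop("covariate '", name, "' not present for patient ", patient, call. = FALSE)
  }
  cutoff <- if (policy == "locf_at_anchor") {
    if (is.null(anchor)) stop("policy 'locf_at_anchor' needs an anchor time", call. = FALSE)
    min(t, anchor)
  } else t
  ok <- !is.na(rows[[name]]) & rows$time <= cutoff
  if (!any(ok)) {
    stop("no measurement of covariate '", name, "' for patient ", patient,
         " at or before t = ", signif(cutoff, 6), " h", call. = FALSE)
  }
  rows[[name]][max(which(ok))]
}

# ADA status ---------------------------------------------------------------

#' Patient- and sample-level ADA positivity
#'
#' A patient is ADA-positive if any measured ADA concentration exceeds the
#' positivity threshold. A sample is ADA-positive if the most recent ADA
#' measurement at or before the sample time exceeds it.
#'
#' @param data An [event_table()].
#' @param patient Patient id.
#' @param threshold Positivity threshold in U/mL (default 6.6).
#' @return `patient_ada_positive()`: logical. `first_ada_positive_time()`:
#'   time in hours of the first ADA-positive measurement, or `NA` if never
#'   positive. `sample_ada_status()`: logical for a sample time `t`.
#' @export
patient_ada_positive <- function(data, patient, threshold = 6.6) {
  a <- data$ada[data$id == patient]
  any(!is.na(a) & a > threshold)
}

#' @rdname patient_ada_positive
#' @export
first_ada_positive_time <- function(data, patient, threshold = 6.6) {
  rows <- data[data$id == patient, , drop = FALSE]
  pos <- !is.na(rows$ada) & rows$ada > threshold
  if (!any(pos)) NA_real_ else min(rows$time[pos])
}

#' @rdname patient_ada_positive
#' @param t Sample time (hours).
#' @export
sample_ada_status <- function(data, patient, t, threshold = 6.6) {
  rows <- data[data$id == patient, , drop = FALSE]
  ok <- !is.na(rows$ada) & rows$time <= t
  if (!any(ok)) return(FALSE)
  rows$ada[max(which(ok))] > threshold
}
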