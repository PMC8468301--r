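# vpc: prediction- and variability-corrected visual predictive checks -----
#
# The study design (dosing, sampling times, covariates) is replicated many
# times with fresh draws of eta, kappa and residual error. Observations and
# simulations are normalized within time-after-dose bins for the typical
# prediction (prediction correction) and for the typical between-replicate
# spread of each sampling point (variability correction), so that patients
# on different dose levels and covariate patterns can share one diagnostic.

#' Settings for a prediction- and variability-corrected VPC
#'
#' @param n_replicates Number of simulation replicates of the study
#'   population (default 1000).
#' @param percentiles Percentiles summarized per bin (default 5, 50, 95).
#' @param ci_level Level of the simulation-based confidence interval around
#'   each simulated percentile (default 0.95).
#' @param n_bins Number of quantile bins on time after dose (default 8).
#' @param seed Seed for the replicate simulations.
#' @export
vpc_config <- function(n_replicates = 1000, percentiles = c(5, 50, 95),
                       ci_level = 0.95, n_bins = 8, seed = 1L) {
  stopifnot(n_replicates >= 1, all(percentiles > 0 & percentiles < 100),
            ci_level > 0 && ci_level < 1, n_bins >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 percentiles = percentiles, ci_level = ci_level,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "vpc_config")
}

time_after_dose <- function(data, id, t) {
  vapply(seq_along(t), function(i) {
    dt <- data$time[data$id == id[i] & data$evid == 1]
    if (length(dt) == 0) return(t[i])
    prev <- dt[dt <= t[i]]
    if (length(prev) == 0) t[i] else t[i] - max(prev)
  }, numeric(1))
}

#' Simulate replicate observation sets for a VPC
#'
#' Each replicate redraws eta per patient, kappa per occasion and residual
#' error at the study's own dosing schedules, covariates and sampling times.
#' The typical prediction PRED (all random effects and residual errors zero)
#' is computed once per observation.
#'
#' @param model A [poppk_model()] compatible with the data set.
#' @param data A cleaned [event_table()].
#' @param cfg A [vpc_config()].
#' @return A `vpc_replicates` list: `design` (data.frame `id`, `time`,
#'   `tad`, `obs`, `pred`) and `sims` (matrix observations x replicates).
#' @export
simulate_replicates <- function(model, data, cfg = vpc_config()) {
  findings <- validate_against_dataset(model, data)
  if (length(findings)) {
    stop("model/data set incompatible:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  }
  o <- data[obs_rows(data), , drop = FALSE]
  design <- data.frame(id = o$id, time = o$time,
                       tad = time_after_dose(data, o$id, o$time),
                       obs = o$dv, pred = NA_real_)
  ids <- patient_ids(data)
  split_data <- lapply(ids, function(p) data[data$id == p, , drop = FALSE])
  names(split_data) <- ids
  om <- model$random$iiv_omega
  chol_om <- if (!is.null(om)) chol(om)
  iov <- model$random$iov_pi
  per_patient <- lapply(ids, function(p) {
    dp <- split_data[[p]]
    doses <- patient_doses(dp, p)
    idx <- which(design$id == p)
    if (length(idx) == 0) return(NULL)
    times <- design$time[idx]
    list(p = p, doses = doses, idx = idx, times = times,
         tpl = trajectory_template(model, dp, p, policy = "full",
                                   t_max = max(times)),
         occasions = if (!is.null(iov) && nrow(doses))
           as.character(sort(unique(occasion_of(doses$time, times))))
         else character(0))
  })
  per_patient <- Filter(Negate(is.null), per_patient)
  for (pp in per_patient) {
    traj <- template_trajectory(pp$tpl)
    design$pred[pp$idx] <-
      concentration_profile(model, pp$doses, traj, pp$times)$conc
  }
  sims <- with_seed(cfg$seed, {
    out <- matrix(NA_real_, nrow(design), cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      for (pp in per_patient) {
        eta <- if (!is.null(om)) {
          setNames(as.numeric(crossprod(chol_om, stats::rnorm(nrow(om)))),
                   rownames(om))
        }
        kappa <- if (length(pp$occasions)) {
          setNames(stats::rnorm(length(pp$occasions), 0, sqrt(iov)),
                   pp$occasions)
        }
        traj <- template_trajectory(pp$tpl, eta = eta, kappa = kappa)
        f <- concentration_profile(model, pp$doses, traj, pp$times)$conc
        out[pp$idx, r] <- simulate_observation(f, model$error)
      }
    }
    out
  })
  structure(list(design = design, sims = sims, cfg = cfg,
                 model = model$name),
            class = "vpc_replicates")
}

#' Prediction- and variability-correct a value
#'
#' The value is first scaled by `bin_pred_median / pred_ij` (prediction
#' correction); its residual from the bin's median typical prediction is
#' then scaled by `bin_sd_median / sd_ij` (variability correction), where
#' `sd_ij` is the between-replicate SD of the observation's simulated
#' values. Points with `sd_ij = 0` and a nonzero residual fall back to
#' prediction correction only (with a warning).
#'
#' @param y Observed or simulated value(s), ug/mL.
#' @param pred_ij Typical prediction for the observation (> 0).
#' @param bin_pred_median Median typical prediction in the bin.
#' @param sd_ij Between-replicate SD of the observation's simulations.
#' @param bin_sd_median Median of `sd_ij` over the bin.
#' @return Corrected value(s).
#' @export
pvc_transform <- function(y, pred_ij, bin_pred_median, sd_ij, bin_sd_median) {
  stopifnot(all(pred_ij > 0))
  pc <- y * bin_pred_median / pred_ij
  resid <- pc - bin_pred_median
  scale <- bin_sd_median / sd_ij
  degenerate <- sd_ij == 0
  if (any(degenerate & resid != 0)) {
    warning("zero simulation SD with nonzero residual; ",
            "prediction correction only for ",
            sum(degenerate & resid != 0), " value(s)", call. = FALSE)
  }
  scale[degenerate] <- 1
  bin_pred_median + resid * scale
}

#' Summarize corrected observations and simulations into VPC bands
#'
#' Bins time after dose into quantile bins, corrects observed and simulated
#' values with [pvc_transform()], and summarizes per bin: the observed
#' percentiles and, over replicates, the median and central confidence
#' interval of each simulated percentile. Bins with fewer than 2
#' observations are merged with their neighbor (with a warning).
#'
#' @param reps A `vpc_replicates` object from [simulate_replicates()].
#' @param cfg A [vpc_config()]; defaults to the one used for simulation.
#' @return A `vpc_result`: data.frame with one row per bin and percentile
#'   (`bin`, `tad_lo`, `tad_hi`, `n`, `percentile`, `obs`, `sim_med`,
#'   `sim_lo`, `sim_hi`).
#' @export
vpc_summary <- function(reps, cfg = NULL) {
  stopifnot(inherits(reps, "vpc_replicates"))
  cfg <- cfg %||% reps$cfg
  d <- reps$design
  sims <- reps$sims
  edges <- unique(qtl(d$tad, seq(0, 1, length.out = cfg$n_bins + 1)))
  if (length(edges) < 2) edges <- range(d$tad) + c(-1e-9, 1e-9)
  bin <- findInterval(d$tad, edges, rightmost.closed = TRUE, all.inside = TRUE)
  # merge undersized bins leftward
  repeat {
    cnt <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(cnt)[cnt < 2]
    if (length(small) == 0) break
    b <- as.integer(small[1])
    others <- setdiff(sort(unique(bin)), b)
    if (length(others) == 0) break
    nb <- others[which.min(abs(others - b))]
    warning("merging VPC bin with <2 observations into neighbor", call. = FALSE)
    bin[bin == b] <- nb
  }
  sd_ij <- apply(sims, 1, stats::sd)
  pr <- cfg$percentiles / 100
  alpha <- (1 - cfg$ci_level) / 2
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    in_b <- bin == b
    bpm <- stats::median(d$pred[in_b])
    bsm <- stats::median(sd_ij[in_b])
    obs_c <- pvc_transform(d$obs[in_b], d$pred[in_b], bpm, sd_ij[in_b], bsm)
    sim_c <- pvc_transform(sims[in_b, , drop = FALSE], d$pred[in_b], bpm,
                           sd_ij[in_b], bsm)
    obs_q <- qtl(obs_c, pr)
    sim_q <- apply(sim_c, 2, qtl, p = pr)           # percentiles x replicates
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = 1)
    data.frame(bin = b,
               tad_lo = min(d$tad[in_b]), tad_hi = max(d$tad[in_b]),
               n = sum(in_b),
               percentile = cfg$percentiles,
               obs = obs_q,
               sim_med = apply(sim_q, 1, stats::median),
               sim_lo = apply(sim_q, 1, qtl, p = alpha),
               sim_hi = apply(sim_q, 1, qtl, p = 1 - alpha))
  }))
  rownames(out) <- NULL
  structure(out, class = c("vpc_result", "data.frame"))
}

#' Run a full prediction- and variability-corrected VPC
#'
#' @inheritParams simulate_replicates
#' @return A `vpc_result` (see [vpc_summary()]).
#' @export
pvc_vpc <- function(model, data, cfg = vpc_config()) {
  vpc_summary(simulate_replicates(model, data, cfg))
}

#' Plot a VPC result (bands and observed percentiles)
#'
#' @param result A `vpc_result`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_vpc <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_vpc() requires the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(result)
  df$tad_mid <- (df$tad_lo + df$tad_hi) / 2 / HOURS_PER_DAY
  df$percentile <- factor(df$percentile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tad_mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs), linetype = 2) +
    ggplot2::labs(x = "Time after dose (days)",
                  y = "Corrected concentration (ug/mL)")
}
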