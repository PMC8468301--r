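test_that("zeta and SSPB match hand-computed values", {
  x <- c(10, 10, 10)
  expect_equal(median_symmetric_accuracy(x, x), 0)
  expect_equal(median_symmetric_accuracy(x, 2 * x), 100)
  expect_equal(symmetric_signed_percentage_bias(x, 1.25 * x), 25)
  expect_equal(symmetric_signed_percentage_bias(x, x / 1.25), -25)
  # |ln Q| = (0.1823, 0.4055, 0.1054), median 0.1823 -> 20.0%
  y <- c(12, 15, 9)
  expect_equal(median_symmetric_accuracy(x, y), 20, tolerance = 1e-12)
  expect_equal(symmetric_signed_percentage_bias(x, y), 20, tolerance = 1e-12)
  expect_error(median_symmetric_accuracy(numeric(0), numeric(0)), "pairs")
  expect_error(median_symmetric_accuracy(c(1, 0), c(1, 1)), "positive")
  expect_error(symmetric_signed_percentage_bias(c(1, 1), c(1, -2)), "positive")
})

test_that("metric invariants hold on random positive vectors", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    x <- stats::rlnorm(n, 1, 1)
    y <- stats::rlnorm(n, 1, 1)
    z_xy <- median_symmetric_accuracy(x, y)
    s_xy <- symmetric_signed_percentage_bias(x, y)
    # symmetry under swapping observed and predicted
    expect_equal(z_xy, median_symmetric_accuracy(y, x), tolerance = 1e-12)
    expect_equal(s_xy, -symmetric_signed_percentage_bias(y, x),
                 tolerance = 1e-12)
    # scale invariance
    expect_equal(z_xy, median_symmetric_accuracy(3.7 * x, 3.7 * y),
                 tolerance = 1e-10)
    expect_equal(s_xy, symmetric_signed_percentage_bias(3.7 * x, 3.7 * y),
                 tolerance = 1e-10)
    # accuracy bounds the absolute bias
    expect_gte(z_xy, abs(s_xy) - 1e-12)
  }
})

mk_records <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(id = "X", time = 0, time_after_cmap = 0, obs = 10,
                   pred = 10, ada_patient = FALSE, ada_sample = FALSE,
                   first_ada_time = NA_real_, trough = FALSE, anchor = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  class(df) <- c("prediction_record", "data.frame")
  df
}

test_that("records are stratified by ADA status and time after anchor", {
  recs <- mk_records(
    time = c(0, 20, 100, 400, 5, 10, 95, 150) * 24,
    time_after_cmap = c(0, 20, 100, 400, 0, 5, 90, 145),
    ada_patient = rep(c(FALSE, TRUE), each = 4),
    first_ada_time = rep(c(NA, 70), each = 4),
    anchor = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  s <- stratify_predictions(recs)
  expect_equal(s$ada_negative[["<=1 month"]]$time_after_cmap, 20)
  expect_equal(s$ada_negative[["1-6 months"]]$time_after_cmap, 100)
  expect_equal(s$ada_negative[[">6 months"]]$time_after_cmap, 400)
  expect_equal(nrow(s$ada_negative$all_pred), 3)       # anchor excluded
  # day 10 precedes the first ADA+ measurement (day 70)
  expect_equal(s$ada_positive[["before ADA+"]]$time, 10 * 24)
  # day 95 is within 30 days of day 70; day 150 is beyond a month
  expect_equal(s$ada_positive[["1st ADA+ <=1 month"]]$time, 95 * 24)
  expect_equal(s$ada_positive[[">1 month ADA+"]]$time, 150 * 24)
  expect_equal(nrow(s$ada_positive$all_pred), 3)
  # an ADA-positive record without an onset time is an error
  bad <- mk_records(ada_patient = TRUE, first_ada_time = NA_real_)
  expect_error(stratify_predictions(bad), "first ADA")
})

test_that("trough classification uses the escalation convention", {
  cfg <- classification_config()
  expect_equal(classify_trough(4.0, 3.0, cfg), "TP")
  expect_equal(classify_trough(6.0, 4.0, cfg), "FP")
  expect_equal(classify_trough(3.0, 7.0, cfg), "FN")
  expect_equal(classify_trough(8.0, 9.0, cfg), "TN")
  # the threshold itself means "no escalation" on both axes
  expect_equal(classify_trough(5.0, 5.0, cfg), "TN")
  expect_equal(classify_trough(5.0, 4.999, cfg), "FP")
})

test_that("classification accuracy reproduces printed confusion arithmetic", {
  expect_equal(summarize_classification(list(TP = 60, FN = 7, TN = 53, FP = 14)),
               84.3)
  expect_equal(summarize_classification(list(TP = 19, FN = 4, TN = 1, FP = 1)),
               80.0)
  expect_equal(summarize_classification(list(TP = 10, FN = 0, TN = 5, FP = 0)),
               100)
  expect_error(summarize_classification(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "no classified")
})

test_that("evaluate_predictions assembles strata and confusion counts", {
  recs <- mk_records(
    time = c(0, 1344, 2688, 4032, 5376) ,
    time_after_cmap = c(0, 56, 112, 168, 224),
    obs = c(15, 4.2, 6.0, 3.0, 8.0),
    pred = c(14, 3.5, 4.0, 6.0, 9.0),
    trough = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    anchor = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  ev <- evaluate_predictions(recs)
  cls <- ev$classification[ev$classification$group == "ada_negative", ]
  expect_equal(cls$TP, 1)   # obs 4.2 / pred 3.5
  expect_equal(cls$FP, 1)   # obs 6.0 / pred 4.0
  expect_equal(cls$FN, 1)   # obs 3.0 / pred 6.0
  expect_equal(cls$TN, 1)   # obs 8.0 / pred 9.0
  expect_equal(cls$accuracy, 50.0)
  allp <- ev$strata[ev$strata$group == "ada_negative" &
                      ev$strata$stratum == "all_pred", ]
  expect_equal(allp$n, 4)
  # non-positive pairs are excluded with a warning, not an error
  recs$obs[3] <- 0
  expect_warning(ev2 <- evaluate_predictions(recs), "non-positive")
  allp2 <- ev2$strata[ev2$strata$group == "ada_negative" &
                        ev2$strata$stratum == "all_pred", ]
  expect_equal(allp2$n, 3)
})
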