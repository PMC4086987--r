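# Confusion matrices, the metric suite and report formatting.

test_that("the confusion matrix counts reference-by-algorithm pairs", {
  cm <- confusion(c("NORM", "LBBB", "RBBB"), c("NORM", "NORM", "RBBB"))
  expect_equal(unclass(cm),
               matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L), nrow = 3,
                      dimnames = list(reference = c("NORM", "LBBB", "RBBB"),
                                      algorithm = c("NORM", "LBBB", "RBBB"))))
  expect_equal(sum(unclass(cm)), 3)
  y <- sample(c("NORM", "LBBB", "RBBB"), 50, replace = TRUE)
  self <- confusion(y, y)
  expect_equal(sum(diag(unclass(self))), 50)
  expect_true(all(metrics_from_confusion(self)$value == 100))
  expect_error(confusion("NORM", c("NORM", "LBBB")), "lengths differ")
  expect_error(confusion("NORM", "XXX", labels = c("NORM", "LBBB")), "not covered")
})

test_that("metric definitions reproduce the published-scale worked example", {
  cm3 <- new_confusion(matrix(
    c(29697L, 6339L, 408L,
      355L, 3770L, 0L,
      249L, 0L, 3227L),
    nrow = 3, byrow = TRUE,
    dimnames = list(reference = c("NORM", "LBBB", "RBBB"),
                    algorithm = c("NORM", "LBBB", "RBBB"))))
  met <- metrics_from_confusion(cm3)
  get <- function(cl, m) round_half_up(met$value[met$class == cl & met$metric == m], 1)
  expect_equal(get("NORM", "Sp"), 81.5)
  expect_equal(get("NORM", "NP"), 98.0)
  expect_equal(get("LBBB", "Se"), 91.4)
  expect_equal(get("LBBB", "PP"), 37.3)
  expect_equal(get("RBBB", "Se"), 92.8)
  expect_equal(get("RBBB", "PP"), 88.8)
  expect_equal(round_half_up(met$value[met$metric == "Acc"], 1), 83.3)
})

test_that("undefined metrics are NA, never 0 or 100", {
  # no RBBB predictions at all -> RBBB PP undefined; no LBBB reference -> Se undefined
  cm <- confusion(c("NORM", "NORM", "RBBB"), c("NORM", "NORM", "NORM"),
                  labels = c("NORM", "LBBB", "RBBB"))
  met <- metrics_from_confusion(cm)
  expect_true(is.na(met$value[met$class == "RBBB" & met$metric == "PP"]))
  expect_true(is.na(met$value[met$class == "LBBB" & met$metric == "Se"]))
  expect_equal(met$value[met$class == "RBBB" & met$metric == "Se"], 0)
  fmt <- format_metrics_table(met)
  expect_equal(fmt$value[met$class == "RBBB" & met$metric == "PP"], "-")
})

test_that("report rounding is half-up to one decimal", {
  expect_equal(round_half_up(81.25), 81.3)
  expect_equal(round_half_up(81.24), 81.2)
  expect_equal(round_half_up(98.05), 98.1)
  expect_equal(round_half_up(-1.25), -1.3)
  expect_equal(round_half_up(37.349, 1), 37.3)
})

test_that("per-record metrics agree with global metrics for a single record", {
  preds <- tibble::tibble(
    record_id = "r1",
    r_index = 1:6,
    label = factor(c("NORM", "NORM", "LBBB", "LBBB", "RBBB", "RBBB"),
                   levels = c("NORM", "LBBB", "RBBB")),
    predicted = factor(c("NORM", "LBBB", "LBBB", "LBBB", "RBBB", "NORM"),
                       levels = c("NORM", "LBBB", "RBBB")))
  per <- per_record_metrics(preds)
  glob <- metrics_from_confusion(confusion(preds$label, preds$predicted))
  expect_equal(nrow(per), 1)
  expect_equal(per$NORM_Sp, glob$value[glob$class == "NORM" & glob$metric == "Sp"])
  expect_equal(per$LBBB_Se, glob$value[glob$class == "LBBB" & glob$metric == "Se"])
  expect_equal(per$Acc, glob$value[glob$metric == "Acc"])
})

test_that("records with disjoint classes report only their present classes", {
  preds <- tibble::tibble(
    record_id = rep(c("rL", "rR"), each = 3),
    r_index = 1:6,
    label = factor(c("LBBB", "LBBB", "LBBB", "RBBB", "RBBB", "RBBB"),
                   levels = c("NORM", "LBBB", "RBBB")),
    predicted = factor(c("LBBB", "LBBB", "NORM", "RBBB", "RBBB", "RBBB"),
                       levels = c("NORM", "LBBB", "RBBB")))
  per <- per_record_metrics(preds)
  rl <- per[per$record_id == "rL", ]
  expect_true(is.na(rl$RBBB_Se))       # no RBBB beats in that record
  expect_equal(rl$LBBB_Se, 100 * 2 / 3)
  rr <- per[per$record_id == "rR", ]
  expect_true(is.na(rr$LBBB_Se))
  expect_equal(rr$RBBB_Se, 100)
  fmt <- format_metrics_table(per)
  expect_equal(fmt$LBBB_Se[per$record_id == "rR"], "-")
})

test_that("lead-configuration comparison reuses each run's own metrics", {
  mk_run <- function(acc_good) {
    n <- 40
    lab <- factor(rep(c("NORM", "LBBB", "RBBB"), length.out = n),
                  levels = c("NORM", "LBBB", "RBBB"))
    pred <- lab
    if (!acc_good) pred[1:10] <- factor("LBBB", levels = levels(lab))
    tibble::tibble(record_id = "x", r_index = 1:n, label = lab, predicted = pred)
  }
  runs <- list(A = mk_run(TRUE), B = mk_run(FALSE), AB = mk_run(TRUE))
  tab <- compare_lead_configs(runs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$Acc[tab$lead_config == "A"], 100)
  solo <- metrics_from_confusion(confusion(runs$B$label, runs$B$predicted))
  expect_equal(tab$Acc[tab$lead_config == "B"], solo$value[solo$metric == "Acc"])
  expect_warning(compare_lead_configs(runs[c("A", "B")]), "missing lead config")
})
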