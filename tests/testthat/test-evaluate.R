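mk_pred <- function(position, class) {
  structure(data.frame(position = position, z_mut_sens = 0, z_acc = 0,
                       score_active = 0, score_buried = 0,
                       predicted_class = class, flags = "",
                       stringsAsFactors = FALSE),
            class = c("prediction_table", "data.frame"))
}

test_that("confusion counts a 16-residue fixture by direct enumeration", {
  # 4 true active (3 predicted), 12 true non-active (10 predicted non-active)
  truth <- residue_truth(1:16, c(rep("active_site", 4), rep("buried", 6),
                                 rep("exposed_nonactive", 6)))
  pred_cls <- c("active_site", "active_site", "active_site", "buried",
                rep("buried", 4), "active_site", "active_site",
                rep("exposed_nonactive", 6))
  cc <- confusion(mk_pred(1:16, pred_cls), truth, "active_site")
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 2, fn = 1, tn = 10))

  # perfect predictions
  cc2 <- confusion(mk_pred(1:16, truth$true_class), truth, "active_site")
  expect_equal(cc2$fp + cc2$fn, 0)

  # labelled position without a prediction is excluded and logged
  expect_message(cc3 <- confusion(mk_pred(1:15, pred_cls[1:15]), truth, "active_site"),
                 "without a prediction")
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 15)

  # buried framing drops exclusion-listed positions
  truth_ex <- residue_truth(1:16, truth$true_class, exclusions = c(5L, 6L))
  cc4 <- confusion(mk_pred(1:16, pred_cls), truth_ex, "buried")
  expect_equal(cc4$tp + cc4$fp + cc4$tn + cc4$fn, 14)

  expect_error(confusion(mk_pred(20:25, rep("buried", 6)), truth, "buried"),
               class = "dmsites_validation_error")
})

test_that("metrics formulas match hand computation", {
  m <- class_metrics(confusion_counts(tp = 3, fp = 2, tn = 10, fn = 1))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 10 / 12)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$mcc, 28 / sqrt(2640))

  perfect <- class_metrics(confusion_counts(5, 0, 5, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, mcc = 1))

  degen <- class_metrics(confusion_counts(tp = 0, fp = 0, tn = 6, fn = 4))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$mcc, 0)          # zero-denominator convention
})

test_that("metrics agree with an independent correlation-based oracle", {
  # MCC of a 2x2 table equals the Pearson correlation of the binary
  # label vectors; sens/spec/acc reduce to conditional means. 1000 cases.
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- runif(n) < runif(1, 0.2, 0.8)
    pred <- runif(n) < runif(1, 0.2, 0.8)
    cc <- confusion_counts(tp = sum(pred & truth), fp = sum(pred & !truth),
                           tn = sum(!pred & !truth), fn = sum(!pred & truth))
    m <- class_metrics(cc)
    expect_equal(m$accuracy, mean(pred == truth))
    if (any(truth)) expect_equal(m$sensitivity, mean(pred[truth]))
    if (any(!truth)) expect_equal(m$specificity, mean(!pred[!truth]))
    oracle_mcc <- suppressWarnings(stats::cor(as.numeric(pred), as.numeric(truth)))
    if (is.na(oracle_mcc)) oracle_mcc <- 0
    expect_equal(m$mcc, oracle_mcc, tolerance = 1e-12)
  }
})

test_that("accuracy identity and MCC antisymmetry hold", {
  set.seed(13)
  for (i in 1:50) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                           sample(0:20, 1), sample(1:20, 1))
    m <- class_metrics(cc)
    P <- cc$tp + cc$fn; N <- cc$tn + cc$fp
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    }
    # swap positive/negative labelling: tp<->tn, fp<->fn; MCC is invariant
    # under the double swap and negated by swapping predictions only
    swapped <- class_metrics(confusion_counts(cc$tn, cc$fn, cc$tp, cc$fp))
    expect_equal(m$mcc, swapped$mcc)
    flipped <- class_metrics(confusion_counts(cc$fn, cc$tn, cc$fp, cc$tp))
    expect_equal(m$mcc, -flipped$mcc)
  }
})

test_that("pearson matches brute-force covariance formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), brute)
  expect_equal(pearson(x, y), 11 / sqrt(130))
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(1, 4)), class = "dmsites_degenerate_error")
  expect_error(pearson(x, y[1:3]), class = "dmsites_validation_error")
})

test_that("cross-dataset summaries are unweighted, order-invariant means", {
  rows <- data.frame(dataset = letters[1:4],
                     sensitivity = c(.5, .6, .7, .8), mcc = c(.1, .2, .3, .4))
  s <- summarize_datasets(rows)
  expect_equal(s[["sensitivity"]], 0.65)
  expect_equal(s[["mcc"]], 0.25)
  expect_equal(summarize_datasets(rows[sample(4), ]), s)
  one <- rows[2, ]
  expect_equal(summarize_datasets(one)[["sensitivity"]], 0.6)
  expect_error(summarize_datasets(rows[0, ]), class = "dmsites_validation_error")
})

test_that("metrics report writes the benchmark-style layout", {
  truth <- residue_truth(1:16, c(rep("active_site", 4), rep("buried", 6),
                                 rep("exposed_nonactive", 6)))
  rep1 <- evaluate_predictions(mk_pred(1:16, truth$true_class), truth, "ds1")
  expect_equal(nrow(rep1), 3L)
  expect_true(all(rep1$accuracy == 1))
  path <- tempfile(fileext = ".tsv")
  write_metrics_report(rep1, path)
  back <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$sensitivity_pct, rep(100, 3))
})
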