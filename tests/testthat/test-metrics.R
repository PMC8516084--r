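test_that("confusion counts match a hand tally on random labelings", {
  set.seed(14)
  for (rep in 1:3) {
    truth <- sample(c("GroupLow", "GroupHi"), 30, replace = TRUE)
    pred <- sample(c("GroupLow", "GroupHi"), 30, replace = TRUE)
    cc <- confusion_counts(pred, truth, positive = "GroupLow")
    tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in 1:30) {
      key <- if (pred[i] == "GroupLow" && truth[i] == "GroupLow") "tp"
        else if (pred[i] == "GroupLow") "fp"
        else if (truth[i] == "GroupLow") "fn" else "tn"
      tally[key] <- tally[key] + 1
    }
    expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
                 tally[c("tp", "fp", "tn", "fn")])
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 30)
  }
  # degenerate all-negative classifier: 5 positives among 50
  truth <- rep(c("GroupLow", "GroupHi"), c(5, 45))
  cc <- confusion_counts(rep("GroupHi", 50), truth)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 0, tn = 45, fn = 5))
})

test_that("accuracy follows (tp+tn)/total", {
  perfect <- confusion_counts(rep("GroupLow", 4), rep("GroupLow", 4))
  expect_error(accuracy(structure(list(tp = 0, fp = 0, tn = 0, fn = 0,
                                       positive = "GroupLow"),
                                  class = "confusion_counts")),
               "no scored samples")
  expect_equal(accuracy(perfect), 1)
  cc <- structure(list(tp = 3, fp = 1, tn = 4, fn = 2, positive = "GroupLow"),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 0.7)
})

test_that("AUC equals the all-pairs win fraction with half-credit ties", {
  # forced example: positives {0.9, 0.4}, negatives {0.5, 0.1}
  scores <- c(0.9, 0.4, 0.5, 0.1)
  truth <- c("GroupLow", "GroupLow", "GroupHi", "GroupHi")
  expect_equal(auc_score(scores, truth), 0.75)
  expect_equal(auc_score(c(5, 4, 3, 2), truth), 1)
  expect_equal(auc_score(rep(1, 4), truth), 0.5)
  # brute-force oracle over all positive/negative pairs, tied scores allowed
  set.seed(21)
  for (rep in 1:5) {
    truth <- sample(rep(c("GroupLow", "GroupHi"), c(12, 18)))
    scores <- sample(seq(0, 1, 0.125), 30, replace = TRUE)
    pos <- scores[truth == "GroupLow"]
    neg <- scores[truth == "GroupHi"]
    wins <- 0
    for (a in pos) for (b in neg)
      wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(auc_score(scores, truth), wins / (length(pos) * length(neg)))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(33)
  truth <- sample(rep(c("GroupLow", "GroupHi"), 10))
  scores <- rnorm(20)
  a <- auc_score(scores, truth)
  expect_equal(auc_score(exp(scores), truth), a)
  expect_equal(auc_score(100 + 3 * scores, truth), a)
})

test_that("swapping the positive class mirrors AUC and preserves G-mean", {
  set.seed(44)
  truth <- sample(rep(c("GroupLow", "GroupHi"), c(8, 12)))
  scores <- rnorm(20)
  a_low <- auc_score(scores, truth, positive = "GroupLow")
  a_hi <- suppressMessages(auc_score(-scores, truth, positive = "GroupHi"))
  expect_equal(a_low, a_hi)  # same orientation, opposite designation
  expect_equal(suppressMessages(auc_score(scores, truth, positive = "GroupHi")),
               1 - a_low)
  pred <- ifelse(scores > 0, "GroupLow", "GroupHi")
  g1 <- g_mean(confusion_counts(pred, truth, positive = "GroupLow"))
  g2 <- g_mean(confusion_counts(pred, truth, positive = "GroupHi"))
  expect_equal(g1, g2)
  expect_error(auc_score(scores, rep("GroupHi", 20)), "both classes")
})

test_that("G-mean and minority F-measure handle the degenerate cases", {
  perfect <- structure(list(tp = 5, fp = 0, tn = 45, fn = 0,
                            positive = "GroupLow"), class = "confusion_counts")
  expect_equal(g_mean(perfect), 1)
  expect_equal(f_measure_minority(perfect), 1)
  majority <- structure(list(tp = 0, fp = 0, tn = 45, fn = 5,
                             positive = "GroupLow"), class = "confusion_counts")
  expect_equal(g_mean(majority), 0)
  expect_equal(f_measure_minority(majority), 0)  # defined as 0 at tp == 0
  cc <- structure(list(tp = 6, fp = 2, tn = 10, fn = 3, positive = "GroupLow"),
                  class = "confusion_counts")
  expect_equal(f_measure_minority(cc), 12 / 17)
  sens_spec <- structure(list(tp = 81, fp = 36, tn = 64, fn = 19,
                              positive = "GroupLow"), class = "confusion_counts")
  expect_equal(g_mean(sens_spec), sqrt(0.81 * 0.64))
  empty_pos <- structure(list(tp = 0, fp = 0, tn = 9, fn = 0,
                              positive = "GroupLow"), class = "confusion_counts")
  expect_error(g_mean(empty_pos), "undefined")
})

test_that("all ratio metrics stay in [0,1] over random confusion counts", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(0:20, 4, replace = TRUE) + c(1, 0, 1, 0)  # tp,fn >=1 keeps classes non-empty
    cc <- structure(list(tp = n[1], fp = n[2], tn = n[3], fn = n[4],
                         positive = "GroupLow"), class = "confusion_counts")
    for (v in c(accuracy(cc), g_mean(cc), f_measure_minority(cc))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("the assembled report equals componentwise metric calls", {
  ds <- make_separable(n_per_class = 6, gap = 8, seed = 10)
  preds <- run_loo(ds, group_sizes(3, 3), centroid_base())
  rep <- evaluate_predictions(preds)
  cc <- confusion_counts(preds$predicted, preds$truth)
  expect_equal(rep$accuracy, accuracy(cc))
  expect_equal(rep$g_mean, g_mean(cc))
  expect_equal(rep$f_minority, f_measure_minority(cc))
  expect_equal(rep$auc, auc_score(-preds$score, preds$truth))
  expect_equal(rep$n_errors, cc$fp + cc$fn)
  # perfect separable run maxes every field
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$g_mean, 1)
  expect_equal(rep$f_minority, 1)
  expect_equal(rep$n_errors, 0)
})

test_that("report writer emits the five-row table in all formats", {
  ds <- make_separable(n_per_class = 5, gap = 8, seed = 12)
  rep <- evaluate_predictions(run_loo(ds, group_sizes(2, 2), centroid_base()))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  md <- withr::local_tempfile(fileext = ".md")
  write_report(list(base = rep, local_balanced = rep), csv, "csv")
  write_report(rep, jsn, "json")
  write_report(rep, md, "markdown")
  tab <- read.csv(csv)
  expect_equal(tab$metric,
               c("AUC", "accuracy", "G-mean", "F-meas (minority)", "# errors"))
  expect_equal(names(tab), c("metric", "base", "local_balanced"))
  parsed <- jsonlite::read_json(jsn)
  expect_equal(parsed$model$n_errors, 0)
  expect_equal(parsed$model$auc, 1)
  expect_match(readLines(md)[1], "metric")
})
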