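# Evaluation surface for imbalance-aware two-class classification:
# confusion counts, accuracy, rank AUC (via pROC), G-mean, minority
# F-measure, and the assembled report.

#' Confusion counts for two-class predictions
#'
#' Standard 2x2 counts with a declared positive class. The package
#' convention is that the minority / target class (`GroupLow`) is positive.
#'
#' @param predicted,truth character vectors of class labels (values in
#'   `GroupLow`/`GroupHi`), same length.
#' @param positive the positive class.
#' @return An object of class `"confusion_counts"`: list with `tp`, `fp`,
#'   `tn`, `fn` and the `positive` class.
#' @export
confusion_counts <- function(predicted, truth, positive = "GroupLow") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length", call. = FALSE)
  ok <- c("GroupLow", "GroupHi")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be GroupLow/GroupHi", call. = FALSE)
  pos <- match.arg(positive, ok)
  structure(list(
    tp = sum(predicted == pos & truth == pos),
    fp = sum(predicted == pos & truth != pos),
    tn = sum(predicted != pos & truth != pos),
    fn = sum(predicted != pos & truth == pos),
    positive = pos), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> positive = %s: tp %d, fp %d, tn %d, fn %d\n",
              x$positive, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Overall accuracy
#' @param cc a [confusion_counts()] object.
#' @return `(tp + tn) / total`.
#' @export
accuracy <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  if (total == 0) stop("no scored samples", call. = FALSE)
  (cc$tp + cc$tn) / total
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(sensitivity * specificity)`. Zero whenever either class is entirely
#' misclassified, which makes it the metric of choice for exposing
#' majority-state classifiers that plain accuracy rewards on imbalanced
#' data.
#'
#' @param cc a [confusion_counts()] object with both classes represented.
#' @return Value in `[0, 1]`.
#' @export
g_mean <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0)
    stop("g_mean undefined: a class has no samples", call. = FALSE)
  sqrt((cc$tp / (cc$tp + cc$fn)) * (cc$tn / (cc$tn + cc$fp)))
}

#' F-measure of the minority (positive) class
#'
#' Harmonic mean of precision and recall with the declared positive class,
#' `2 tp / (2 tp + fp + fn)` (beta = 1). Defined as 0 when `tp == 0` — the
#' value a degenerate all-majority classifier receives.
#'
#' @param cc a [confusion_counts()] object.
#' @return Value in `[0, 1]`.
#' @export
f_measure_minority <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$tp + cc$fp + cc$fn == 0)
    stop("f_measure undefined: no positive truth or predictions", call. = FALSE)
  if (cc$tp == 0) return(0)
  2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
}

#' Area under the ROC curve
#'
#' Computed with [pROC::roc()] with a fixed direction (higher score =
#' positive class): the probability that a uniformly random positive sample
#' outscores a uniformly random negative one, ties counting one half
#' (rank/Mann-Whitney formulation, equal to the trapezoidal ROC area). The
#' direction is never auto-flipped; an AUC below 0.5 is reported as computed
#' (with a message), since silent mirroring would hide a sign error.
#'
#' @param scores numeric scores, larger meaning more positive-like.
#' @param truth class labels.
#' @param positive the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth, positive = "GroupLow") {
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have the same length", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- match.arg(positive, c("GroupLow", "GroupHi"))
  neg <- setdiff(c("GroupLow", "GroupHi"), pos)
  if (!all(c(pos, neg) %in% truth))
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(neg, pos), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  if (a < 0.5)
    message(sprintf("AUC %.3f < 0.5: scores rank the negative class higher", a))
  a
}

# orient a GroupHi-high score vector so that larger = `positive`
orient_scores <- function(score_hi, positive) {
  if (positive == "GroupHi") score_hi else -score_hi
}

#' Assemble the full evaluation report
#'
#' Aggregates confusion counts, accuracy, AUC, G-mean, minority F-measure
#' and the error count from a prediction table — the row layout in which
#' results are reported throughout the package.
#'
#' @param preds an `"lbm_predictions"` data frame from [run_loo()] /
#'   [run_train_test()], or any data frame with columns `predicted`, `score`
#'   (`GroupHi`-high) and `truth`.
#' @param truth optional labels overriding `preds$truth`.
#' @param positive the positive (minority/target) class.
#' @return An object of class `"lbm_report"`: list with `confusion`,
#'   `accuracy`, `auc`, `g_mean`, `f_minority`, `n_errors`, `n`.
#' @export
evaluate_predictions <- function(preds, truth = NULL, positive = "GroupLow") {
  if (is.null(truth)) truth <- preds$truth
  if (is.null(truth)) stop("no truth labels supplied", call. = FALSE)
  if (anyNA(truth)) stop("truth labels contain NA", call. = FALSE)
  cc <- confusion_counts(preds$predicted, truth, positive)
  structure(list(
    confusion = cc,
    accuracy = accuracy(cc),
    auc = auc_score(orient_scores(preds$score, positive), truth, positive),
    g_mean = g_mean(cc),
    f_minority = f_measure_minority(cc),
    n_errors = cc$fp + cc$fn,
    n = cc$tp + cc$fp + cc$tn + cc$fn), class = "lbm_report")
}

#' @export
print.lbm_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<lbm_report> n = %d (positive = %s)\n",
    "  AUC               %.3f\n",
    "  accuracy          %.1f%%\n",
    "  G-mean            %.3f\n",
    "  F-meas (minority) %.3f\n",
    "  # errors          %d\n"),
    x$n, x$confusion$positive, x$auc, 100 * x$accuracy, x$g_mean,
    x$f_minority, x$n_errors))
  invisible(x)
}

report_row <- function(x) {
  data.frame(metric = c("AUC", "accuracy", "G-mean", "F-meas (minority)",
                        "# errors"),
             value = c(x$auc, x$accuracy, x$g_mean, x$f_minority, x$n_errors),
             stringsAsFactors = FALSE)
}

#' Write one or more evaluation reports to disk
#'
#' Emits the standard five-row metric table (AUC, accuracy, G-mean, minority
#' F-measure, error count), one column per report, as CSV, JSON or markdown.
#'
#' @param reports a single `"lbm_report"` or a named list of them (names
#'   become columns).
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (inherits(reports, "lbm_report")) reports <- list(model = reports)
  stopifnot(all(vapply(reports, inherits, TRUE, "lbm_report")))
  tab <- report_row(reports[[1]])["metric"]
  for (nm in names(reports)) tab[[nm]] <- report_row(reports[[nm]])$value
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      lapply(reports, function(r)
        list(auc = r$auc, accuracy = r$accuracy, g_mean = r$g_mean,
             f_minority = r$f_minority, n_errors = r$n_errors, n = r$n)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    fmt <- function(v) ifelse(v == round(v) & abs(v) >= 1, sprintf("%d", round(v)),
                              sprintf("%.3f", v))
    lines <- c(paste0("| metric | ", paste(names(reports), collapse = " | "), " |"),
               paste0("|", paste(rep("---|", length(reports) + 1), collapse = "")),
               vapply(seq_len(nrow(tab)), function(i)
                 paste0("| ", tab$metric[i], " | ",
                        paste(fmt(unlist(tab[i, -1])), collapse = " | "), " |"),
                 ""))
    writeLines(lines, path)
  }
  invisible(path)
}
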