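# Local-balanced model orchestration: one freshly trained base classifier
# per test sample, leave-one-out and train/test protocols, and group-size
# optimization by training-set AUC.

#' Per-class training-subset sizes
#'
#' The pair of tunable parameters of the local-balanced model: how many
#' nearest training samples to take from `GroupLow` and from `GroupHi` when
#' building the local training set for one test sample.
#'
#' @param n_low,n_hi positive integers.
#' @return An object of class `"group_sizes"`.
#' @export
group_sizes <- function(n_low, n_hi) {
  n_low <- as.integer(n_low); n_hi <- as.integer(n_hi)
  if (is.na(n_low) || is.na(n_hi) || n_low < 1 || n_hi < 1)
    stop("group sizes must be integers >= 1", call. = FALSE)
  structure(list(n_low = n_low, n_hi = n_hi), class = "group_sizes")
}

as_group_sizes <- function(x) {
  if (inherits(x, "group_sizes")) return(x)
  if (is.numeric(x) && length(x) == 2) return(group_sizes(x[1], x[2]))
  stop("sizes must be a group_sizes object or a length-2 numeric", call. = FALSE)
}

#' @export
print.group_sizes <- function(x, ...) {
  cat(sprintf("<group_sizes> n_low = %d, n_hi = %d\n", x$n_low, x$n_hi))
  invisible(x)
}

#' Support vector machine base classifier
#'
#' The default base classifier: a soft-margin SVM with radial kernel via
#' [e1071::svm()], at that implementation's defaults (`cost = 1`,
#' `gamma = 1/n_features`) — the local-balanced wrapper is evaluated with the
#' base learner's hyperparameters deliberately left untouched. Feature
#' scaling is handled by [scale_columns()] upstream, so `svm()`'s internal
#' scaling is off.
#'
#' Hard class labels are taken from the plain SVM decision (no
#' probabilities). The continuous score used for ROC/AUC is, by default, the
#' calibrated class probability of `GroupHi` (`score = "probability"`); set
#' `score = "decision"` for the raw decision value instead, oriented so that
#' larger means `GroupHi`. Probability calibration involves an internal
#' cross-validation, so fits are made reproducible by seeding from the
#' experiment seed.
#'
#' @param cost soft-margin cost `C`.
#' @param gamma radial kernel width; `NULL` means `1/n_features`.
#' @param score `"probability"` or `"decision"`.
#' @return An object of class `"lbm_base"`: a list with `name`,
#'   `fit(x, y, seed)` and `predict(model, newx)` (returning `label` and a
#'   `GroupHi`-high `score` per row).
#' @export
svm_base <- function(cost = 1, gamma = NULL,
                     score = c("probability", "decision")) {
  score <- match.arg(score)
  want_prob <- score == "probability"
  structure(list(
    name = "svm",
    hyperparameters = list(cost = cost, gamma = gamma, score = score),
    produces_score = TRUE,
    fit = function(x, y, seed = NULL) {
      if (!is.null(seed)) set.seed(seed)
      g <- if (is.null(gamma)) 1 / ncol(x) else gamma
      e1071::svm(x, y, kernel = "radial", cost = cost, gamma = g,
                 scale = FALSE, probability = want_prob)
    },
    predict = function(model, newx) {
      # hard labels come from the plain SVM decision: asking predict() for
      # probabilities makes it label by the calibrated probability argmax,
      # which can contradict the decision value on small training sets
      p <- stats::predict(model, newx)
      sc <- if (want_prob) {
        attr(stats::predict(model, newx, probability = TRUE),
             "probabilities")[, "GroupHi"]
      } else {
        dv <- attr(stats::predict(model, newx, decision.values = TRUE),
                   "decision.values")
        # column named "<first>/<second>"; positive decision value = first class
        if (startsWith(colnames(dv)[1], "GroupHi")) dv[, 1] else -dv[, 1]
      }
      list(label = as.character(p), score = unname(sc))
    }),
    class = "lbm_base")
}

#' Nearest-centroid base classifier
#'
#' A deliberately simple alternative base learner (class = nearer class
#' centroid; score = signed difference of centroid distances). Mainly useful
#' to exercise the pluggable base-classifier slot and for fast tests; any
#' classifier with a `fit`/`predict` pair of this shape can be used in its
#' place.
#'
#' @return An `"lbm_base"` object; see [svm_base()].
#' @export
centroid_base <- function() {
  structure(list(
    name = "centroid",
    hyperparameters = list(),
    produces_score = TRUE,
    fit = function(x, y, seed = NULL) {
      list(mu_low = colMeans(x[y == "GroupLow", , drop = FALSE]),
           mu_hi = colMeans(x[y == "GroupHi", , drop = FALSE]))
    },
    predict = function(model, newx) {
      d_low <- sqrt(rowSums(sweep(newx, 2, model$mu_low)^2))
      d_hi <- sqrt(rowSums(sweep(newx, 2, model$mu_hi)^2))
      sc <- d_low - d_hi  # larger when closer to the GroupHi centroid
      list(label = ifelse(sc > 0, "GroupHi", "GroupLow"), score = unname(sc))
    }),
    class = "lbm_base")
}

# train `base` on the rows of x named by the subset and score one test row
fit_on_subset <- function(x, labels, sub, base, seed, new_row) {
  ids <- c(sub$low_ids, sub$hi_ids)
  y <- factor(rep(c("GroupLow", "GroupHi"),
                  c(length(sub$low_ids), length(sub$hi_ids))),
              levels = c("GroupLow", "GroupHi"))
  model <- base$fit(x[ids, , drop = FALSE], y, seed)
  base$predict(model, matrix(new_row, nrow = 1,
                             dimnames = list(NULL, colnames(x))))
}

#' Classify one sample with its own local-balanced model
#'
#' The unit step of the method: exclude the test sample, rank the remaining
#' samples of each class by Euclidean distance to it, take the `sizes$n_low`
#' nearest `GroupLow` and `sizes$n_hi` nearest `GroupHi` samples, train the
#' base classifier on that subset only, and classify the one test sample.
#'
#' @param ds an [lbm_dataset()].
#' @param test_id the sample to classify.
#' @param sizes a [group_sizes()] pair.
#' @param base an `"lbm_base"` classifier, e.g. [svm_base()].
#' @param seed integer seed for any stochastic step of the base fit.
#' @param warn_clamp warn when sizes exceed available class counts.
#' @return A list of class `"lbm_prediction"`: `test_id`,
#'   `selected_low_ids`, `selected_hi_ids`, `predicted`, `score` (GroupHi
#'   high), `clamped`.
#' @export
fit_predict_one <- function(ds, test_id, sizes, base = svm_base(), seed = 1L,
                            warn_clamp = TRUE) {
  stopifnot(inherits(ds, "lbm_dataset"), inherits(base, "lbm_base"))
  check_two_classes(ds)
  dv <- distances_to_test(ds, test_id)
  labs <- as.character(ds$labels)
  names(labs) <- sample_ids(ds)
  tr_labs <- labs[dv$train_ids]
  if (!all(c("GroupLow", "GroupHi") %in% tr_labs))
    stop("after excluding test sample '", test_id,
         "' one class has no training samples", call. = FALSE)
  sub <- select_balanced_subset(dv, tr_labs, sizes, warn_clamp = warn_clamp)
  out <- fit_on_subset(ds$x, labs, sub, base, seed, ds$x[test_id, ])
  structure(
    list(test_id = test_id,
         selected_low_ids = sub$low_ids,
         selected_hi_ids = sub$hi_ids,
         predicted = out$label[1],
         score = out$score[1],
         clamped = sub$clamped),
    class = "lbm_prediction")
}

predictions_frame <- function(recs, truth) {
  df <- data.frame(
    test_id = vapply(recs, `[[`, "", "test_id"),
    truth = as.character(truth),
    predicted = vapply(recs, `[[`, "", "predicted"),
    score = vapply(recs, `[[`, 0, "score"),
    clamped = vapply(recs, `[[`, TRUE, "clamped"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "subsets") <- lapply(recs, function(r)
    list(low_ids = r$selected_low_ids, hi_ids = r$selected_hi_ids))
  names(attr(df, "subsets")) <- df$test_id
  class(df) <- c("lbm_predictions", "data.frame")
  df
}

#' Leave-one-out evaluation of the local-balanced model
#'
#' Runs [fit_predict_one()] for every sample: each sample is classified by a
#' model whose balanced training subset is drawn from all other samples. One
#' base-classifier fit is performed per sample. Per-sample seeds are derived
#' deterministically from `seed`, so two runs with the same configuration
#' and seed are identical; the per-sample fits are independent, and results
#' are ordered by the dataset's sample order regardless of execution order.
#'
#' @inheritParams fit_predict_one
#' @return An object of class `"lbm_predictions"`: a data frame with columns
#'   `test_id`, `truth`, `predicted`, `score`, `clamped`, and an attribute
#'   `"subsets"` recording, for each test sample, which training samples its
#'   local model used.
#' @export
run_loo <- function(ds, sizes, base = svm_base(), seed = 1L,
                    warn_clamp = TRUE) {
  stopifnot(inherits(ds, "lbm_dataset"))
  check_two_classes(ds)
  tab <- table(ds$labels)
  if (any(tab < 2))
    stop("leave-one-out needs >= 2 samples per class", call. = FALSE)
  ids <- sample_ids(ds)
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    recs[[i]] <- tryCatch(
      fit_predict_one(ds, ids[i], sizes, base, seed = seed + i,
                      warn_clamp = warn_clamp && i == 1L),
      error = function(e) stop("sample '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
  }
  predictions_frame(recs, ds$labels)
}

#' Classify a held-out test set with local-balanced models
#'
#' For each test sample, the balanced nearest subsets are drawn from the
#' training set only and a fresh base classifier is fitted on them. The two
#' datasets must share an identical feature set, and no sample id may appear
#' in both (leakage guard).
#'
#' @param train,test [lbm_dataset()]s with identical `feature_ids`.
#' @inheritParams fit_predict_one
#' @return An `"lbm_predictions"` data frame (one row per test sample); see
#'   [run_loo()].
#' @export
run_train_test <- function(train, test, sizes, base = svm_base(), seed = 1L,
                           warn_clamp = TRUE) {
  stopifnot(inherits(train, "lbm_dataset"), inherits(test, "lbm_dataset"))
  check_two_classes(train)
  if (!identical(feature_ids(train), feature_ids(test))) {
    diff <- union(setdiff(feature_ids(train), feature_ids(test)),
                  setdiff(feature_ids(test), feature_ids(train)))
    stop("train/test feature sets differ",
         if (length(diff)) paste0(": ", paste(utils::head(diff, 5), collapse = ", "),
                                  if (length(diff) > 5) ", ..." else "") else
           " (same names, different order)", call. = FALSE)
  }
  overlap <- intersect(sample_ids(train), sample_ids(test))
  if (length(overlap))
    stop("test sample id(s) present in training set: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  labs <- as.character(train$labels)
  names(labs) <- sample_ids(train)
  ids <- sample_ids(test)
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    diffs <- sweep(train$x, 2, test$x[i, ], "-")
    dv <- structure(list(test_id = ids[i],
                         train_ids = sample_ids(train),
                         distances = sqrt(rowSums(diffs^2))),
                    class = "lbm_distances")
    sub <- select_balanced_subset(dv, labs, sizes,
                                  warn_clamp = warn_clamp && i == 1L)
    out <- fit_on_subset(train$x, labs, sub, base, seed + i, test$x[i, ])
    recs[[i]] <- list(test_id = ids[i],
                      selected_low_ids = sub$low_ids,
                      selected_hi_ids = sub$hi_ids,
                      predicted = out$label[1],
                      score = out$score[1],
                      clamped = sub$clamped)
  }
  predictions_frame(recs, test$labels)
}

#' Choose group sizes by maximizing leave-one-out AUC
#'
#' The only parameters optimized in a local-balanced analysis are the two
#' subset sizes. For every candidate pair in `grid` this runs a full
#' leave-one-out pass over the (training) data and computes the AUC of the
#' resulting scores (positive class `GroupLow`); the pair with the largest
#' AUC wins, ties broken by smaller `n_low`, then smaller `n_hi`. Grid
#' points that fail to run are skipped with a warning.
#'
#' @param ds the labelled (training) dataset.
#' @param base an `"lbm_base"` classifier.
#' @param grid a data frame with columns `n_low`, `n_hi`, or a list of
#'   [group_sizes()]; see [default_size_grid()].
#' @param seed experiment seed (same role as in [run_loo()]).
#' @return A list with `best` (a [group_sizes()]) and `table` (data frame
#'   `n_low`, `n_hi`, `auc` for every evaluated grid point, `NA` where
#'   skipped).
#' @export
optimize_group_sizes <- function(ds, base = svm_base(), grid, seed = 1L) {
  if (is.data.frame(grid)) {
    stopifnot(all(c("n_low", "n_hi") %in% names(grid)))
    grid <- Map(function(a, b) group_sizes(a, b), grid$n_low, grid$n_hi)
  }
  if (!length(grid)) stop("empty size grid", call. = FALSE)
  tab <- data.frame(n_low = vapply(grid, `[[`, 0L, "n_low"),
                    n_hi = vapply(grid, `[[`, 0L, "n_hi"),
                    auc = NA_real_)
  for (k in seq_along(grid)) {
    tab$auc[k] <- tryCatch({
      preds <- run_loo(ds, grid[[k]], base, seed = seed, warn_clamp = FALSE)
      auc_score(orient_scores(preds$score, "GroupLow"), preds$truth,
                positive = "GroupLow")
    }, error = function(e) {
      warning("skipping sizes (", grid[[k]]$n_low, ", ", grid[[k]]$n_hi,
              "): ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  if (all(is.na(tab$auc))) stop("no feasible grid point", call. = FALSE)
  ord <- order(-tab$auc, tab$n_low, tab$n_hi, na.last = TRUE)
  best <- tab[ord[1], ]
  list(best = group_sizes(best$n_low, best$n_hi), table = tab)
}

#' Default group-size search grid
#'
#' All pairs with `n_low`, `n_hi` in `2 ... min(cap, class size - 1)`, plus
#' the clamped pair (full class sizes), under which the local-balanced model
#' reduces to the base classifier. The upper bound of 2..cap is a pragmatic
#' default; group sizes are dataset-specific and any grid can be supplied.
#'
#' @param ds the labelled dataset.
#' @param cap upper bound on per-class candidate sizes (default 30).
#' @return A data frame with columns `n_low`, `n_hi`.
#' @export
default_size_grid <- function(ds, cap = 30L) {
  tab <- table(ds$labels)
  lo <- seq(2L, max(2L, min(cap, tab[["GroupLow"]] - 1L)))
  hi <- seq(2L, max(2L, min(cap, tab[["GroupHi"]] - 1L)))
  g <- expand.grid(n_low = lo, n_hi = hi)
  rbind(g, data.frame(n_low = tab[["GroupLow"]], n_hi = tab[["GroupHi"]]))
}
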