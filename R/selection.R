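# Nearest-neighbour sample selection: the distance computation and the
# per-class balanced subset choice at the heart of the local-balanced model.

#' Euclidean distances from one test sample to all training samples
#'
#' Distances are computed in the full n-dimensional feature space of the
#' matrix as given — i.e. on exactly the (already preprocessed) matrix that
#' will be handed to the classifier. The test sample itself is excluded.
#'
#' @param ds an [lbm_dataset()].
#' @param test_id sample id of the test sample.
#' @return A list of class `"lbm_distances"`: `test_id`, `train_ids` (all
#'   other sample ids, in storage order) and `distances` (same order).
#' @examples
#' ds <- lbm_dataset(rbind(a = c(0, 0), b = c(3, 4)), c("GroupLow", "GroupHi"))
#' distances_to_test(ds, "a")$distances  # 5
#' @export
distances_to_test <- function(ds, test_id) {
  stopifnot(inherits(ds, "lbm_dataset"))
  ti <- match(test_id, sample_ids(ds))
  if (is.na(ti)) stop("unknown test sample id: ", test_id, call. = FALSE)
  if (nrow(ds$x) < 2) stop("need at least one training sample", call. = FALSE)
  others <- setdiff(seq_len(nrow(ds$x)), ti)
  diffs <- sweep(ds$x[others, , drop = FALSE], 2, ds$x[ti, ], "-")
  structure(
    list(test_id = test_id,
         train_ids = sample_ids(ds)[others],
         distances = sqrt(rowSums(diffs^2))),
    class = "lbm_distances")
}

#' Select the balanced per-class nearest training subsets
#'
#' Independently selects, for each class, the requested number of training
#' samples nearest to the test sample. This is the step that distinguishes
#' the local-balanced model from a plain local (kNN-subset) model: the two
#' class counts are separate tunable parameters, so the subset is balanced
#' (or deliberately ratioed) even when the farthest included member of one
#' class is much farther from the test sample than any member of the other.
#'
#' Ties in distance are broken by storage order (stable sort). If a class has
#' fewer training samples than requested, the whole class is used and the
#' result is flagged `clamped` (with a warning): in that limit the local
#' model coincides with the global base model.
#'
#' @param dv an `"lbm_distances"` object from [distances_to_test()].
#' @param labels class labels for the training samples, either a named vector
#'   / factor indexable by `dv$train_ids` or in the same order as
#'   `dv$train_ids`.
#' @param sizes a [group_sizes()] pair.
#' @param warn_clamp warn when a request exceeds a class size.
#' @return A list of class `"lbm_subset"`: `low_ids`, `hi_ids` (each ordered
#'   by increasing distance), `requested`, `clamped`.
#' @export
select_balanced_subset <- function(dv, labels, sizes, warn_clamp = TRUE) {
  stopifnot(inherits(dv, "lbm_distances"))
  sizes <- as_group_sizes(sizes)
  labels <- if (!is.null(names(labels))) as.character(labels[dv$train_ids])
            else as.character(labels)
  if (length(labels) != length(dv$train_ids))
    stop("labels must cover every training sample", call. = FALSE)
  pick <- function(class, n) {
    idx <- which(labels == class)
    if (!length(idx))
      stop("no training samples in class ", class, call. = FALSE)
    ord <- idx[order(dv$distances[idx])]  # order() is stable: ties keep storage order
    dv$train_ids[ord[seq_len(min(n, length(ord)))]]
  }
  n_low_avail <- sum(labels == "GroupLow")
  n_hi_avail <- sum(labels == "GroupHi")
  clamped <- sizes$n_low > n_low_avail || sizes$n_hi > n_hi_avail
  if (clamped && warn_clamp)
    warning(sprintf(
      "requested sizes (%d, %d) exceed available class sizes (%d, %d); using full class(es)",
      sizes$n_low, sizes$n_hi, n_low_avail, n_hi_avail), call. = FALSE)
  structure(
    list(low_ids = pick("GroupLow", sizes$n_low),
         hi_ids = pick("GroupHi", sizes$n_hi),
         requested = sizes,
         clamped = clamped),
    class = "lbm_subset")
}
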