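#' Two-class labelled feature dataset
#'
#' The canonical container used throughout the package: a numeric matrix with
#' samples in rows and features in columns, plus one binary class label per
#' sample. The two classes are always called `"GroupLow"` and `"GroupHi"`;
#' loaders map raw class names onto them (see [read_delimited()]). By
#' convention `GroupLow` is the minority / target class wherever the
#' distinction matters (metrics, binarization).
#'
#' @param x numeric matrix, samples in rows. Row names are taken as sample
#'   ids and column names as feature ids; missing names are synthesized
#'   (`s0001...`, `f0001...`).
#' @param labels character or factor of per-sample classes, values in
#'   `c("GroupLow", "GroupHi")`.
#' @param raw_labels optional character vector of the original class names
#'   before mapping, kept as metadata.
#'
#' @return An object of class `"lbm_dataset"`: a list with elements `x`
#'   (matrix), `labels` (factor with levels `GroupLow`, `GroupHi`) and
#'   `raw_labels`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' ds <- lbm_dataset(m, c("GroupLow", "GroupLow", "GroupHi", "GroupHi"))
#' ds
#' @export
lbm_dataset <- function(x, labels, raw_labels = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("length(labels) must equal nrow(x)", call. = FALSE)
  bad <- setdiff(unique(labels), c("GroupLow", "GroupHi"))
  if (length(bad))
    stop("labels must be 'GroupLow' or 'GroupHi'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("s%04d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature ids", call. = FALSE)
  if (!is.null(raw_labels) && length(raw_labels) != nrow(x))
    stop("raw_labels must have one entry per sample", call. = FALSE)
  structure(
    list(x = x,
         labels = factor(labels, levels = c("GroupLow", "GroupHi")),
         raw_labels = raw_labels),
    class = "lbm_dataset")
}

#' @export
print.lbm_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<lbm_dataset> %d samples x %d features (GroupLow: %d, GroupHi: %d)\n",
              nrow(x$x), ncol(x$x), tab[["GroupLow"]], tab[["GroupHi"]]))
  invisible(x)
}

#' @export
dim.lbm_dataset <- function(x) dim(x$x)

sample_ids  <- function(ds) rownames(ds$x)
feature_ids <- function(ds) colnames(ds$x)

#' Subset the samples of a dataset
#'
#' @param ds an [lbm_dataset()].
#' @param idx sample indices, ids or a logical vector.
#' @return An `lbm_dataset` with the selected samples.
#' @export
subset_samples <- function(ds, idx) {
  stopifnot(inherits(ds, "lbm_dataset"))
  if (is.character(idx)) idx <- match(idx, sample_ids(ds))
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  lbm_dataset(ds$x[idx, , drop = FALSE],
              as.character(ds$labels)[if (is.logical(idx)) which(idx) else idx],
              raw_labels = ds$raw_labels[idx])
}

# both classes present and non-empty; used before any classification run
check_two_classes <- function(ds) {
  tab <- table(ds$labels)
  if (any(tab == 0))
    stop("both classes must be non-empty (GroupLow: ", tab[["GroupLow"]],
         ", GroupHi: ", tab[["GroupHi"]], ")", call. = FALSE)
  invisible(ds)
}
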