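# Loaders and preprocessing for two-class feature tables.
#
# Canonical orientation is samples-in-rows throughout; files stored the other
# way round are transposed at load time via `transpose = TRUE`.

# map raw class names to GroupLow/GroupHi; default: lexicographically smaller
# raw label becomes GroupLow (deterministic in the absence of a declared map)
map_labels <- function(raw, mapping = NULL) {
  raw <- as.character(raw)
  classes <- sort(unique(raw))
  if (length(classes) != 2)
    stop("expected exactly 2 classes, found ", length(classes), ": ",
         paste(utils::head(classes, 5), collapse = ", "), call. = FALSE)
  if (is.null(mapping)) {
    # canonical group names pass through unchanged; otherwise the
    # lexicographically smaller raw label becomes GroupLow
    mapping <- if (setequal(classes, c("GroupLow", "GroupHi")))
      c(GroupLow = "GroupLow", GroupHi = "GroupHi")
    else c(GroupLow = classes[1], GroupHi = classes[2])
  } else {
    if (!setequal(names(mapping), c("GroupLow", "GroupHi")))
      stop("mapping must be a named vector c(GroupLow=, GroupHi=)", call. = FALSE)
    if (!setequal(unname(mapping), classes))
      stop("mapping classes (", paste(mapping, collapse = ", "),
           ") do not match classes in data (", paste(classes, collapse = ", "),
           ")", call. = FALSE)
  }
  ifelse(raw == mapping[["GroupLow"]], "GroupLow", "GroupHi")
}

#' Read a delimited two-class feature table
#'
#' Reads a CSV/TSV file with a header row, one label column, and numeric
#' feature columns, into an [lbm_dataset()]. A leading id column (named `id`,
#' `sample`, `sample_id`, or given explicitly) supplies sample ids; otherwise
#' ids are synthesized. The two raw class names are mapped to
#' `GroupLow`/`GroupHi`; by default the lexicographically smaller raw label
#' becomes `GroupLow`, or pass `mapping = c(GroupLow = ..., GroupHi = ...)`.
#'
#' @param path file path.
#' @param label_column name of the class-label column.
#' @param delimiter field separator, default `","`.
#' @param id_column optional name of a sample-id column; `NULL` autodetects.
#' @param mapping optional named vector declaring the raw-to-group mapping.
#' @param transpose if `TRUE`, the file stores samples in columns and is
#'   transposed after reading (the label row then names classes per column).
#' @return An [lbm_dataset()].
#' @export
read_delimited <- function(path, label_column = "class", delimiter = ",",
                           id_column = NULL, mapping = NULL,
                           transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (transpose) {
    rn <- df[[1]]
    df <- as.data.frame(t(df[, -1, drop = FALSE]), stringsAsFactors = FALSE)
    names(df) <- rn
    df <- cbind(id = rownames(df), df, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    if (is.null(id_column)) id_column <- "id"
  }
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path, call. = FALSE)
  if (is.null(id_column)) {
    cand <- intersect(c("id", "sample", "sample_id"), names(df))
    id_column <- if (length(cand)) cand[1] else NA_character_
  }
  ids <- if (!is.na(id_column) && id_column %in% names(df)) df[[id_column]]
         else sprintf("s%04d", seq_len(nrow(df)))
  raw <- df[[label_column]]
  feat <- df[, setdiff(names(df), c(label_column, id_column)), drop = FALSE]
  if (anyNA(feat) || any(feat == "", na.rm = TRUE))
    stop("missing values are not supported", call. = FALSE)
  num <- suppressWarnings(
    vapply(feat, function(col) as.numeric(col), numeric(nrow(feat))))
  if (nrow(feat) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(feat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value in row %d, column '%s': '%s'",
                 bad[1], colnames(num)[bad[2]], feat[bad[1], bad[2]]),
         call. = FALSE)
  }
  rownames(num) <- ids
  lbm_dataset(num, map_labels(raw, mapping), raw_labels = as.character(raw))
}

#' Write a dataset as a delimited file
#'
#' Inverse of [read_delimited()]: writes an `id` column, the feature columns,
#' and a `class` column holding the raw labels if present, else the group
#' labels. `read_delimited(write_delimited(ds))` round-trips values, ids and
#' labels.
#'
#' @param ds an [lbm_dataset()].
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(ds, path, delimiter = ",") {
  stopifnot(inherits(ds, "lbm_dataset"))
  lab <- if (!is.null(ds$raw_labels)) ds$raw_labels else as.character(ds$labels)
  # 17 significant digits: values survive the text round-trip bit-for-bit
  num <- apply(ds$x, 2, function(col) sprintf("%.17g", col))
  if (nrow(ds$x) == 1L) num <- matrix(num, nrow = 1)
  colnames(num) <- colnames(ds$x)
  df <- data.frame(id = sample_ids(ds), num, class = lab,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dense ARFF file into a labelled dataset
#'
#' Thin wrapper around [foreign::read.arff()] for data distributed in the
#' ARFF format (e.g. MALDI-MS bacterial fingerprint tables). The label
#' attribute must be nominal with two observed classes; sparse ARFF
#' (`{index value}` data lines) is rejected explicitly.
#'
#' @param path file path.
#' @param label_attribute name of the nominal class attribute.
#' @param mapping optional raw-to-group mapping as in [read_delimited()].
#' @return An [lbm_dataset()].
#' @export
read_arff <- function(path, label_attribute = "class", mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  dstart <- grep("^\\s*@data", lines, ignore.case = TRUE)[1]
  if (!is.na(dstart)) {
    body <- grep("^\\s*\\{", lines[-seq_len(dstart)], value = TRUE)
    if (length(body))
      stop("sparse ARFF dialect is not supported: ", path, call. = FALSE)
  }
  df <- foreign::read.arff(path)
  if (!label_attribute %in% names(df))
    stop("label attribute '", label_attribute, "' not found in ", path,
         call. = FALSE)
  raw <- as.character(df[[label_attribute]])
  feat <- df[, setdiff(names(df), label_attribute), drop = FALSE]
  if (!all(vapply(feat, is.numeric, logical(1))))
    stop("all non-label ARFF attributes must be numeric", call. = FALSE)
  num <- as.matrix(feat)
  if (anyNA(num)) stop("missing values are not supported", call. = FALSE)
  rownames(num) <- sprintf("s%04d", seq_len(nrow(num)))
  lbm_dataset(num, map_labels(raw, mapping), raw_labels = raw)
}

#' Binarize a multi-class dataset against one target class
#'
#' Collapses a dataset with two or more raw classes into the two-group form:
#' the target class becomes `GroupLow` (the minority/target convention) and
#' every other class becomes `GroupHi`. The original raw labels are retained
#' as metadata. Used e.g. to turn a 6-class satellite land-cover table into
#' target-vs-rest.
#'
#' @param ds an [lbm_dataset()] whose `raw_labels` carry >= 2 raw classes, or
#'   any dataset plus an explicit `raw` vector.
#' @param target raw class id to use as the target (`GroupLow`) class.
#' @param raw optional character vector of raw class labels overriding
#'   `ds$raw_labels`.
#' @return An [lbm_dataset()] with two classes.
#' @export
binarize_by_target <- function(ds, target, raw = NULL) {
  stopifnot(inherits(ds, "lbm_dataset"))
  if (is.null(raw)) raw <- ds$raw_labels
  if (is.null(raw)) stop("no raw labels available to binarize", call. = FALSE)
  raw <- as.character(raw)
  if (!as.character(target) %in% raw)
    stop("target class '", target, "' not present in raw labels", call. = FALSE)
  lab <- ifelse(raw == as.character(target), "GroupLow", "GroupHi")
  lbm_dataset(ds$x, lab, raw_labels = raw)
}

#' Normalize each sample to a constant total signal
#'
#' Divides every sample row by its total so that row sums equal 100
#' (`"percent100"`, the percent-of-total convention used for glycopeptide
#' abundance profiles) or 1 (`"unit1"`, total-ion-current normalization used
#' for imaging pixels). Exactly cancels any per-sample multiplicative
#' intensity drift.
#'
#' @param ds an [lbm_dataset()].
#' @param mode `"percent100"` or `"unit1"`.
#' @return The normalized dataset.
#' @export
normalize_total <- function(ds, mode = c("percent100", "unit1")) {
  stopifnot(inherits(ds, "lbm_dataset"))
  mode <- match.arg(mode)
  target <- if (mode == "percent100") 100 else 1
  rs <- rowSums(ds$x)
  if (any(rs == 0))
    stop("zero-sum sample row(s): ",
         paste(sample_ids(ds)[rs == 0], collapse = ", "), call. = FALSE)
  lbm_dataset(ds$x / rs * target, as.character(ds$labels),
              raw_labels = ds$raw_labels)
}

#' Center and scale feature columns
#'
#' Applies z-score scaling per column (mean 0, sd 1 with the n-1 denominator,
#' as `base::scale()` does). By default the statistics are computed over all
#' samples in `ds` — the whole-matrix convention under which a dataset is
#' scaled once before classification. Pass `stats_from` to compute the
#' statistics on a subset (e.g. training samples only) and apply them to all
#' rows, the leakage-free variant. Constant (zero-variance) columns, for
#' which scaling is undefined, are dropped with a warning.
#'
#' @param ds an [lbm_dataset()] with >= 2 samples.
#' @param stats_from optional sample ids or indices; scaling statistics are
#'   computed on these rows only.
#' @return The scaled dataset (possibly with fewer features).
#' @export
scale_columns <- function(ds, stats_from = NULL) {
  stopifnot(inherits(ds, "lbm_dataset"))
  if (nrow(ds$x) < 2) stop("need >= 2 samples to scale", call. = FALSE)
  ref <- if (is.null(stats_from)) ds$x else {
    idx <- if (is.character(stats_from)) match(stats_from, sample_ids(ds)) else stats_from
    if (anyNA(idx)) stop("unknown sample id(s) in stats_from", call. = FALSE)
    ds$x[idx, , drop = FALSE]
  }
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s): ",
            paste(utils::head(colnames(ds$x)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "", call. = FALSE)
  }
  keep <- !const
  if (!any(keep)) stop("all columns are constant; nothing to scale", call. = FALSE)
  sc <- sweep(sweep(ds$x[, keep, drop = FALSE], 2, mu[keep], "-"),
              2, sdv[keep], "/")
  lbm_dataset(sc, as.character(ds$labels), raw_labels = ds$raw_labels)
}

#' Remove features with no signal in any sample
#'
#' Drops feature columns that are zero for every sample (e.g. mass bins in
#' which no ion abundance was ever recorded). Idempotent.
#'
#' @param ds an [lbm_dataset()].
#' @return The dataset with all-zero features removed.
#' @export
drop_zero_features <- function(ds) {
  stopifnot(inherits(ds, "lbm_dataset"))
  keep <- colSums(ds$x != 0) > 0
  if (all(keep)) return(ds)
  lbm_dataset(ds$x[, keep, drop = FALSE], as.character(ds$labels),
              raw_labels = ds$raw_labels)
}

#' Apply a preprocessing recipe to a dataset
#'
#' Convenience wrapper applying, in order: zero-feature removal, total-signal
#' normalization, column scaling. This is the fixed order in which the three
#' steps are composed everywhere in the package.
#'
#' @param ds an [lbm_dataset()].
#' @param normalize `"none"`, `"percent100"` or `"unit1"`.
#' @param scale logical; apply [scale_columns()].
#' @param drop_zero logical; apply [drop_zero_features()] first.
#' @return The preprocessed dataset.
#' @export
preprocess <- function(ds, normalize = c("none", "percent100", "unit1"),
                       scale = FALSE, drop_zero = FALSE) {
  normalize <- match.arg(normalize)
  if (drop_zero) ds <- drop_zero_features(ds)
  if (normalize != "none") ds <- normalize_total(ds, normalize)
  if (scale) ds <- scale_columns(ds)
  ds
}
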