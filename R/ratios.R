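# Pairwise feature-ratio expansion.
#
# Ratios of features cancel any per-sample multiplicative intensity drift
# (c*a / c*b == a/b), and let classifiers that score features one at a time
# see relationships between features.

#' Expand a feature matrix with all non-redundant pairwise ratios
#'
#' Appends, to the `p` original features, the ratio `f_i / f_j` for every
#' pair `i < j` (one orientation per pair), giving `p + p(p-1)/2` features —
#' e.g. 5050 for `p = 100`. Column order is deterministic: originals in
#' input order, then pairs in lexicographic `(i, j)` order, named
#' `"fi/fj"`. Labels are unchanged.
#'
#' Denominator entries with `|x| < epsilon` are replaced by a
#' sign-preserving `epsilon` before dividing, so zero-heavy MS tables do not
#' produce infinities. The default epsilon is `1e-9` times the median
#' absolute nonzero value of the matrix.
#'
#' @param ds an [lbm_dataset()].
#' @param epsilon small positive guard for zero denominators; `NULL` for the
#'   data-driven default.
#' @return An [lbm_dataset()] with `p + p(p-1)/2` features (`p = 1` returns
#'   the input unchanged).
#' @examples
#' ds <- lbm_dataset(rbind(c(a = 2, b = 4, c = 8), c(1, 2, 4)),
#'                   c("GroupLow", "GroupHi"))
#' feat <- colnames(build_ratio_features(ds)$x)  # a, b, c, a/b, a/c, b/c
#' @export
build_ratio_features <- function(ds, epsilon = NULL) {
  stopifnot(inherits(ds, "lbm_dataset"))
  p <- ncol(ds$x)
  if (p < 2) return(ds)
  if (is.null(epsilon)) {
    nz <- abs(ds$x[ds$x != 0])
    epsilon <- if (length(nz)) 1e-9 * stats::median(nz) else 1e-9
  }
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  idx <- utils::combn(p, 2)
  num <- ds$x[, idx[1, ], drop = FALSE]
  den <- ds$x[, idx[2, ], drop = FALSE]
  guard <- abs(den) < epsilon
  den[guard] <- ifelse(den[guard] < 0, -epsilon, epsilon)
  ratios <- num / den
  colnames(ratios) <- paste0(colnames(ds$x)[idx[1, ]], "/",
                             colnames(ds$x)[idx[2, ]])
  lbm_dataset(cbind(ds$x, ratios), as.character(ds$labels),
              raw_labels = ds$raw_labels)
}
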