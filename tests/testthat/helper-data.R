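# Small fixture builders used across the suite. Everything is generated in
# code; no data files.

# labelled dataset from explicit coordinates
make_points <- function(coords, labels, ids = NULL) {
  x <- do.call(rbind, coords)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(nrow(x)))
  rownames(x) <- ids
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  lbm_dataset(x, labels)
}

# two well-separated random clusters, GroupLow first
make_separable <- function(n_per_class = 5, n_features = 3, gap = 10,
                           seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * n_features), n_per_class),
             matrix(rnorm(n_per_class * n_features) + gap, n_per_class))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per_class))
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  lbm_dataset(x, rep(c("GroupLow", "GroupHi"), each = n_per_class))
}

# random labelled dataset (no class structure)
make_random <- function(n = 20, p = 5, seed = 7, prop_low = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  rownames(x) <- sprintf("s%02d", seq_len(n))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  n_low <- max(1, round(n * prop_low))
  lbm_dataset(x, c(rep("GroupLow", n_low), rep("GroupHi", n - n_low)))
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# base-classifier wrapper that counts fit() calls (cost-model checks)
counting_base <- function(inner = centroid_base()) {
  n_fits <- new.env()
  n_fits$count <- 0L
  b <- structure(list(
    name = "counting",
    hyperparameters = list(),
    produces_score = TRUE,
    fit = function(x, y, seed = NULL) {
      n_fits$count <- n_fits$count + 1L
      inner$fit(x, y, seed)
    },
    predict = inner$predict), class = "lbm_base")
  list(base = b, counter = n_fits)
}
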