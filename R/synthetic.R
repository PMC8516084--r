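# Synthetic generators mimicking the three data regimes the local-balanced
# model targets: noisy peak/trough signal traces, MS-like abundance tables
# with per-sample multiplicative intensity drift, and imbalanced point
# clouds. All generators are bit-reproducible under a fixed seed.

#' Generate noisy hill/valley signal traces
#'
#' Each sample is a trace of `n_points` readings: a linear baseline of
#' random magnitude plus one Gaussian bump — positive for a "hill"
#' (`GroupLow`), negative for a "valley" (`GroupHi`) — at a random location,
#' width and height, plus additive Gaussian noise. Magnitude, location,
#' width and height all vary between samples, so no single reading separates
#' the classes; only the shape of the trace does. Class balance is 50:50
#' (`n_samples` must be even), with class order shuffled under the seed.
#'
#' Bump height and noise scale with the sample's baseline magnitude, mimicking
#' response-magnitude inconsistency between runs of an instrument.
#'
#' @param n_samples even number of traces.
#' @param n_points readings per trace (>= 10).
#' @param baseline_range range of the baseline level (arbitrary units).
#' @param slope_range range of the baseline slope per reading.
#' @param height_range bump height as a fraction of the baseline level.
#' @param width_range bump width (Gaussian sd, in readings); must be below
#'   `n_points`.
#' @param location_range bump centre (reading index).
#' @param noise_sd additive noise sd as a fraction of the baseline level.
#' @param seed integer seed.
#' @return An [lbm_dataset()] with `raw_labels` `"hill"`/`"valley"`;
#'   `GroupLow` = hill.
#' @export
gen_hill_valley <- function(n_samples = 400, n_points = 100,
                            baseline_range = c(10, 100),
                            slope_range = c(-0.01, 0.01),
                            height_range = c(0.2, 0.6),
                            width_range = c(3, 10),
                            location_range = c(15, 85),
                            noise_sd = 0.05, seed = 1L) {
  if (n_points < 10) stop("n_points must be >= 10", call. = FALSE)
  if (n_samples < 4 || n_samples %% 2 != 0)
    stop("n_samples must be an even number >= 4", call. = FALSE)
  if (max(width_range) >= n_points)
    stop("bump width must be smaller than n_points", call. = FALSE)
  if (min(location_range) < 1 || max(location_range) > n_points)
    stop("bump location must lie within 1..n_points", call. = FALSE)
  set.seed(seed)
  is_hill <- sample(rep(c(TRUE, FALSE), n_samples / 2))
  t_idx <- seq_len(n_points)
  x <- t(vapply(seq_len(n_samples), function(i) {
    b0 <- stats::runif(1, baseline_range[1], baseline_range[2])
    b1 <- stats::runif(1, slope_range[1], slope_range[2])
    h <- stats::runif(1, height_range[1], height_range[2]) * b0
    w <- stats::runif(1, width_range[1], width_range[2])
    ctr <- stats::runif(1, location_range[1], location_range[2])
    sgn <- if (is_hill[i]) 1 else -1
    b0 + b1 * (t_idx - (n_points + 1) / 2) +
      sgn * h * exp(-0.5 * ((t_idx - ctr) / w)^2) +
      stats::rnorm(n_points, sd = noise_sd * b0)
  }, numeric(n_points)))
  colnames(x) <- sprintf("t%03d", t_idx)
  rownames(x) <- sprintf("s%04d", seq_len(n_samples))
  lbm_dataset(x, ifelse(is_hill, "GroupLow", "GroupHi"),
              raw_labels = ifelse(is_hill, "hill", "valley"))
}

#' Generate an MS-like abundance table with per-sample intensity drift
#'
#' Emulates a quantified glycopeptide/metabolite table in which the
#' between-class difference is subtle and per-sample multiplicative
#' intensity drift dominates it. Each sample row is
#' `drift_i * (base_profile + class_effect + noise)`: the base profile is a
#' fixed, skewed abundance vector (few large peaks, many small ones, summing
#' to 100); `GroupHi` samples have the features in `effect_features` raised
#' by the fraction `effect_size`; `drift_i` is drawn uniformly from
#' `drift_range` and multiplies the whole row, as an inconsistent instrument
#' response would. The default drift range 0.85-1.15 realizes
#' run-to-run signal fluctuation above 10%.
#'
#' Because the drift is exactly multiplicative, [normalize_total()] removes
#' it completely; its dominance matters for pipelines working on the raw or
#' merely scaled table.
#'
#' @param n_per_class samples per class.
#' @param n_features number of features.
#' @param effect_size fractional increase of the affected features in
#'   `GroupHi` (default 0.2, a subtle 20% shift).
#' @param effect_features indices of the affected features.
#' @param drift_range range of the per-sample multiplicative drift factor.
#' @param noise_sd additive noise sd as a fraction of each feature's base
#'   abundance.
#' @param seed integer seed.
#' @return An [lbm_dataset()]; `GroupLow` = unmodified profile.
#' @export
gen_drift_table <- function(n_per_class = 21, n_features = 15,
                            effect_size = 0.2, effect_features = 1:4,
                            drift_range = c(0.85, 1.15), noise_sd = 0.08,
                            seed = 1L) {
  if (length(effect_features) == 0 && effect_size != 0)
    stop("effect_features must be non-empty when effect_size != 0",
         call. = FALSE)
  if (length(effect_features) && (min(effect_features) < 1 ||
                                  max(effect_features) > n_features))
    stop("effect_features out of range", call. = FALSE)
  set.seed(seed)
  # fixed skewed abundance shape (geometric decay), scaled to sum to 100
  profile <- 0.75^(seq_len(n_features) - 1)
  profile <- 100 * profile / sum(profile)
  effect <- numeric(n_features)
  effect[effect_features] <- effect_size * profile[effect_features]
  n <- 2L * n_per_class
  lab <- rep(c("GroupLow", "GroupHi"), each = n_per_class)
  x <- t(vapply(seq_len(n), function(i) {
    # one unit-uniform draw rescaled by hand: keeps the RNG stream aligned
    # across drift ranges (incl. the degenerate drift-free range)
    drift <- drift_range[1] +
      (drift_range[2] - drift_range[1]) * stats::runif(1)
    eff <- if (lab[i] == "GroupHi") effect else 0
    drift * (profile + eff + stats::rnorm(n_features, sd = noise_sd * profile))
  }, numeric(n_features)))
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  rownames(x) <- sprintf("s%04d", seq_len(n))
  lbm_dataset(x, lab,
              raw_labels = ifelse(lab == "GroupLow", "native", "modified"))
}

#' Generate two imbalanced Gaussian point clouds
#'
#' Two spherical Gaussian clouds in `n_features` dimensions whose centres
#' are `separation` apart (Euclidean), with the minority class (`GroupLow`,
#' the target) making up about a tenth of the data by default — the regime
#' in which a global classifier tends to collapse into the majority-state
#' model. The default dimensionality and separation are calibrated so that,
#' across seeds, a default global SVM does collapse (G-mean 0) on a
#' substantial fraction of draws, while balanced local training still
#' recovers the minority class.
#'
#' @param n_minority,n_majority class sizes (minority >= 2).
#' @param n_features dimensionality.
#' @param separation Euclidean distance between class centres.
#' @param sd within-class standard deviation per dimension.
#' @param seed integer seed.
#' @return An [lbm_dataset()]; `GroupLow` = minority.
#' @export
gen_imbalanced_clouds <- function(n_minority = 20, n_majority = 180,
                                  n_features = 6, separation = 2,
                                  sd = 1, seed = 1L) {
  if (n_minority < 2) stop("n_minority must be >= 2", call. = FALSE)
  set.seed(seed)
  n <- n_minority + n_majority
  lab <- rep(c("GroupLow", "GroupHi"), c(n_minority, n_majority))
  shift <- separation / sqrt(n_features)  # per-axis offset giving the stated distance
  x <- matrix(stats::rnorm(n * n_features, sd = sd), n, n_features)
  x[lab == "GroupLow", ] <- x[lab == "GroupLow", ] + shift
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  rownames(x) <- sprintf("s%04d", seq_len(n))
  lbm_dataset(x, lab, raw_labels = ifelse(lab == "GroupLow", "target", "rest"))
}
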