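#' Synthetic immunosignature configuration
#'
#' Describes a multi-class peptide-microarray simulation: log-normal
#' baseline intensities, a small planted subset of class-discriminative
#' peptides whose intensity distribution is shifted for one class each, the
#' rest pure noise, and optional missing-at-random entries.
#'
#' Defaults mirror the smaller of the two study designs the generator
#' emulates: 6 groups of 40 samples each, with a planted effect of 1.5 log2
#' units over a log2-scale noise sd of 0.5.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Samples per class; a scalar or a per-class
#'   vector (>= 2 each).
#' @param n_features Total number of peptide features.
#' @param n_informative_per_class Planted discriminative peptides per class;
#'   `n_informative_per_class * n_classes <= n_features`.
#' @param effect_size Mean intensity shift of a planted peptide in its class,
#'   in log2 units (>= 0).
#' @param noise_sd Log2-scale standard deviation of baseline intensities.
#' @param missing_rate Fraction of entries set missing at random, in \[0, 1).
#' @param shift_direction `"up"` (default; planted peptides shift up in their
#'   class), `"down"`, or `"mixed"` (alternating signs, yielding both `>=`
#'   and `<=` style signals).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 6, samples_per_class = 40,
                         n_features = 1000, n_informative_per_class = 5,
                         effect_size = 1.5, noise_sd = 0.5,
                         missing_rate = 0,
                         shift_direction = c("up", "down", "mixed"),
                         seed = 1) {
  shift_direction <- match.arg(shift_direction)
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("invalid `n_classes`: need >= 2")
  if (length(samples_per_class) == 1L)
    samples_per_class <- rep(samples_per_class, n_classes)
  if (length(samples_per_class) != n_classes || any(samples_per_class < 2))
    stop("invalid `samples_per_class`: need >= 2 per class")
  if (n_features < 1) stop("invalid `n_features`")
  if (n_informative_per_class < 0 ||
      n_informative_per_class * n_classes > n_features)
    stop("invalid `n_informative_per_class`: ",
         "n_informative_per_class * n_classes must be <= n_features")
  if (effect_size < 0) stop("invalid `effect_size`: need >= 0")
  if (noise_sd <= 0) stop("invalid `noise_sd`: need > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid `missing_rate`: need value in [0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_features = as.integer(n_features),
                 n_informative_per_class = as.integer(n_informative_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 shift_direction = shift_direction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic immunosignature matrix with known ground truth
#'
#' Baseline log2-intensities are N(0, `noise_sd`); for each class c, samples
#' of c get a `+effect_size` (or `-effect_size`, per `shift_direction`) mean
#' shift at each of c's planted peptides.  Intensities are returned on the
#' natural scale (`2^z`, positive, sub-10 magnitudes at the default sd), and
#' `missing_rate` of the entries are then masked uniformly at random.
#'
#' @param config A [synth_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth`, the planted ground truth: `informative` (class -> feature ids),
#'   `thresholds` (per planted feature, the natural-scale midpoint between
#'   the shifted and baseline means) and `direction` (per planted feature,
#'   `"up"` or `"down"`).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- sum(cfg$samples_per_class)
  M <- cfg$n_features
  classes <- sprintf("Class%02d", seq_len(cfg$n_classes))
  labels <- rep(classes, cfg$samples_per_class)
  feat_ids <- sprintf("P%05d", seq_len(M))

  z <- matrix(rnorm(n * M, 0, cfg$noise_sd), n, M,
              dimnames = list(sprintf("S%04d", seq_len(n)), feat_ids))

  n_inf <- cfg$n_informative_per_class * cfg$n_classes
  planted <- if (n_inf > 0) sample.int(M, n_inf) else integer(0)
  informative <- split(feat_ids[planted],
                       rep(classes, each = cfg$n_informative_per_class))[classes]
  if (n_inf == 0) informative <- stats::setNames(
    rep(list(character(0)), cfg$n_classes), classes)

  sign_of <- function(j) switch(cfg$shift_direction,
                                up = 1, down = -1,
                                mixed = if (j %% 2L == 0L) -1 else 1)
  directions <- character(0)
  for (ci in seq_len(cfg$n_classes)) {
    feats <- planted[seq_len(cfg$n_informative_per_class) +
                       (ci - 1L) * cfg$n_informative_per_class]
    rows <- labels == classes[ci]
    for (idx in seq_along(feats)) {
      s <- sign_of(idx)
      z[rows, feats[idx]] <- z[rows, feats[idx]] + s * cfg$effect_size
      directions <- c(directions,
                      stats::setNames(if (s > 0) "up" else "down",
                                      feat_ids[feats[idx]]))
    }
  }
  values <- 2^z
  if (cfg$missing_rate > 0) {
    n_miss <- round(cfg$missing_rate * n * M)
    values[sample.int(n * M, n_miss)] <- NA_real_
  }
  thresholds <- stats::setNames(
    2^(ifelse(directions == "up", 1, -1) * cfg$effect_size / 2),
    names(directions))
  list(matrix = expression_matrix(values, labels),
       truth = list(informative = informative,
                    thresholds = thresholds,
                    direction = directions))
}
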