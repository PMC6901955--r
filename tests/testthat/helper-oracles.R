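# Independent oracles used across the suite.

# Brute-force Gorodkin MCC straight from the covariance definition on
# explicit 0-1 indicator matrices.
mcc_oracle <- function(truth, pred) {
  classes <- sort(unique(truth))
  X <- 1 * outer(pred, classes, "==")
  Y <- 1 * outer(truth, classes, "==")
  covf <- function(A, B) {
    mean(vapply(seq_along(classes), function(k) {
      mean((A[, k] - mean(A[, k])) * (B[, k] - mean(B[, k])))
    }, numeric(1)))
  }
  num <- covf(X, Y)
  den <- sqrt(covf(X, X) * covf(Y, Y))
  if (den == 0) 0 else num / den
}

# Classical binary MCC from the 2x2 confusion counts.
binary_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Exhaustive minimum discernibility cover by subset enumeration.
min_cover_size <- function(D, labels) {
  n <- nrow(D)
  pairs <- which(outer(labels, labels, "!=") & upper.tri(diag(n)),
                 arr.ind = TRUE)
  neq <- D[pairs[, 1], , drop = FALSE] != D[pairs[, 2], , drop = FALSE]
  target <- rowSums(neq) > 0
  if (!any(target)) return(0L)
  M <- ncol(D)
  for (size in 1:M) {
    for (sub in utils::combn(M, size, simplify = FALSE)) {
      if (all(rowSums(neq[target, sub, drop = FALSE]) > 0)) return(size)
    }
  }
  M
}

# Labeled matrix where each signal class is defined by one peptide shifted
# up by `shift` log2 units (margin >> noise), over a most-prevalent
# background class that supplies the RIPPER default.
make_planted_rule_data <- function(n_signal_classes = 4, per_class = 15,
                                   n_background = 25, shift = 2,
                                   noise_sd = 0.2, n_extra = 2, seed = 1) {
  set.seed(seed)
  classes <- paste0("C", seq_len(n_signal_classes))
  labels <- c(rep(classes, each = per_class), rep("Background", n_background))
  n <- length(labels)
  M <- n_signal_classes + n_extra
  z <- matrix(rnorm(n * M, 0, noise_sd), n, M,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("pep%02d", seq_len(M))))
  for (k in seq_len(n_signal_classes))
    z[labels == classes[k], k] <- z[labels == classes[k], k] + shift
  list(matrix = expression_matrix(2^z, labels),
       planted = stats::setNames(sprintf("pep%02d", seq_len(n_signal_classes)),
                                 classes))
}

# A probe intensity vector violating every condition of every non-default
# rule (NULL when the rule set makes that infeasible).
all_false_probe <- function(rs) {
  conds <- do.call(rbind, lapply(rs$rules, `[[`, "conditions"))
  probe <- numeric(0)
  for (f in unique(conds$feature)) {
    le <- conds$threshold[conds$feature == f & conds$op == "<="]
    ge <- conds$threshold[conds$feature == f & conds$op == ">="]
    lo <- if (length(le)) max(le) else -Inf   # must sit above all <= bounds
    hi <- if (length(ge)) min(ge) else Inf    # and below all >= bounds
    if (lo >= hi) return(NULL)
    v <- if (is.infinite(lo)) hi / 2
         else if (is.infinite(hi)) lo + 1
         else (lo + hi) / 2
    probe[f] <- v
  }
  probe
}
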