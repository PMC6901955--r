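# Entropy-based recursive binary discretization with the MDL stopping
# criterion (Fayyad-Irani), per feature against the class label.  Features
# yielding no accepted cut are single-bin and discern nothing.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Supervised MDL discretization cut points
#'
#' Recursively splits a numeric feature at the midpoint minimizing the
#' class-entropy of the two halves, accepting a split only when its
#' information gain clears the minimum-description-length threshold.
#'
#' @param x Numeric feature values.
#' @param y Class labels.
#' @return Sorted numeric vector of accepted cut points (possibly empty).
#' @export
mdl_discretize <- function(x, y) {
  y <- as.integer(factor(y))
  o <- order(x)
  x <- x[o]; y <- y[o]
  K <- max(y)
  cuts <- numeric(0)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return()
    cnt <- tabulate(y[lo:hi], K)
    H <- entropy_bits(cnt)
    if (H == 0) return()
    # scan boundaries where the value changes
    best_gain <- -Inf; best_i <- NA_integer_
    left <- integer(K)
    for (i in lo:(hi - 1L)) {
      left[y[i]] <- left[y[i]] + 1L
      if (x[i] >= x[i + 1L]) next
      nl <- i - lo + 1L; nr <- n - nl
      if (nl < 2L || nr < 2L) next
      Hl <- entropy_bits(left); Hr <- entropy_bits(cnt - left)
      gain <- H - (nl * Hl + nr * Hr) / n
      if (gain > best_gain) {
        best_gain <- gain; best_i <- i
        best_parts <- c(Hl, Hr, nl, nr)
      }
    }
    if (is.na(best_i)) return()
    nl <- best_parts[3L]; nr <- best_parts[4L]
    kl <- sum(tabulate(y[lo:best_i], K) > 0)
    kr <- sum(tabulate(y[(best_i + 1L):hi], K) > 0)
    k <- sum(cnt > 0)
    delta <- log2(3^k - 2) -
      (k * H - kl * best_parts[1L] - kr * best_parts[2L])
    if (best_gain <= (log2(n - 1) + delta) / n) return()
    cuts <<- c(cuts, (x[best_i] + x[best_i + 1L]) / 2)
    recurse(lo, best_i)
    recurse(best_i + 1L, hi)
  }
  recurse(1L, length(x))
  sort(cuts)
}

# integer bin codes for one feature given its cut points
apply_cuts <- function(x, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}
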