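#' Build the one-cycle transition kernel over a length range
#'
#' Assembles the row-stochastic transition matrix of the repeat-length Markov
#' chain on the states `n_min:n_max`. Row `n` is [step_distribution()] at `n`
#' mapped to absolute lengths; transitions that would exit the range are
#' truncated to the nearest boundary state, conserving mass (rows always sum
#' to 1 — no mass is renormalised away).
#'
#' @param params a [stutter_params()].
#' @param n_min,n_max integer state range, `1 <= n_min < n_max`.
#' @return An object of class `transition_kernel`: list with `n_min`, `n_max`
#'   and `matrix` (rows/cols named by length).
#' @export
build_kernel <- function(params, n_min, n_max) {
  if (!(n_min >= 1 && n_min < n_max) ||
      n_min != round(n_min) || n_max != round(n_max))
    stop("need integer range 1 <= n_min < n_max", call. = FALSE)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  states <- n_min:n_max
  steps <- step_distribution(params, states)
  if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1,
                                           dimnames = list(NULL, .STEP_NAMES))
  k <- length(states)
  M <- matrix(0, k, k, dimnames = list(states, states))
  rows <- seq_len(k)
  for (j in seq_along(.STEP_OFFSETS)) {
    target <- pmin(pmax(states + .STEP_OFFSETS[j], n_min), n_max)
    idx <- cbind(rows, target - n_min + 1L)
    M[idx] <- M[idx] + steps[, j]
  }
  structure(list(n_min = n_min, n_max = n_max, matrix = M),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat(sprintf("<transition_kernel> states %d..%d (%d x %d)\n",
              x$n_min, x$n_max, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

## Propagate a delta at n0 through t cycles; returns the full trajectory as a
## (t+1) x states matrix (row i = distribution after i-1 cycles). The support
## covers everything reachable plus `margin` spare states so that truncation
## at the boundaries is numerically irrelevant.
.predict_trajectory <- function(params, n0, t, margin = 5L) {
  lo <- max(1L, as.integer(n0 - 3 * t - margin))
  hi <- as.integer(n0 + t + margin)
  if (hi <= lo) hi <- lo + 1L
  K <- build_kernel(params, lo, hi)$matrix
  states <- lo:hi
  v <- numeric(length(states))
  v[n0 - lo + 1L] <- 1
  out <- matrix(0, t + 1L, length(states), dimnames = list(0:t, states))
  out[1L, ] <- v
  if (t > 0) for (i in seq_len(t)) {
    v <- as.numeric(v %*% K)
    out[i + 1L, ] <- v
  }
  out
}

#' Predict the stutter histogram after a number of PCR cycles
#'
#' Propagates a delta distribution at the designed length `n0` through `t`
#' applications of the one-cycle kernel (the discrete-time Markov chain view
#' of amplification: one kernel step per cycle, applied to the whole length
#' distribution). At `t = 0` this is the perfect-synthesis assumption: all
#' mass at the designed length.
#'
#' @param params a [stutter_params()].
#' @param n0 designed repeat length (integer >= 1).
#' @param t nonnegative integer cycle count.
#' @param margin spare states kept beyond the reachable range (default 5).
#' @param locus_id label for the returned histogram.
#' @return A [repeat_histogram()] of frequencies summing to 1 (zero-mass bins
#'   dropped).
#' @examples
#' p <- default_stutter_params("AC")
#' predict_histogram(p, 20, 17)
#' @export
predict_histogram <- function(params, n0, t, margin = 5L,
                              locus_id = sprintf("model_t%d_l%d", t, n0)) {
  if (length(t) != 1 || t < 0 || t != round(t))
    stop("`t` must be a single nonnegative integer", call. = FALSE)
  if (length(n0) != 1 || n0 < 1 || n0 != round(n0))
    stop("`n0` must be a single integer >= 1", call. = FALSE)
  traj <- .predict_trajectory(params, as.integer(n0), as.integer(t), margin)
  v <- traj[nrow(traj), ]
  keep <- v > 0
  repeat_histogram(v[keep], repeats = as.integer(colnames(traj))[keep],
                   locus_id = locus_id)
}

#' Predict the stutter histogram of a two-allele mixture
#'
#' Convex combination `p * H(t, l1) + (1 - p) * H(t, l2)` of two single-allele
#' predictions, renormalised defensively. This is the model signal the
#' biallelic genotyper matches against measured histograms of unevenly
#' amplified heterozygous loci.
#'
#' @param params a [stutter_params()].
#' @param l1,l2 allele repeat lengths, `l1 <= l2`.
#' @param p proportion of the first allele, in \[0, 1\].
#' @param t nonnegative integer cycle count.
#' @return A [repeat_histogram()] of frequencies.
#' @export
predict_mixture <- function(params, l1, l2, p, t) {
  if (l1 > l2) stop("`l1` must not exceed `l2`", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  h1 <- predict_histogram(params, l1, t)
  h2 <- predict_histogram(params, l2, t)
  support <- sort(unique(c(h1$repeats, h2$repeats)))
  v <- numeric(length(support))
  v[match(h1$repeats, support)] <- v[match(h1$repeats, support)] + p * h1$counts
  v[match(h2$repeats, support)] <- v[match(h2$repeats, support)] +
    (1 - p) * h2$counts
  v <- v / sum(v)
  keep <- v > 0
  repeat_histogram(v[keep], repeats = support[keep],
                   locus_id = sprintf("model_t%d_l%d+%d_p%.2f", t, l1, l2, p))
}
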