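#' Repeat-number histogram
#'
#' A `repeat_histogram` holds, for one locus in one sample, the observed read
#' count (or frequency) at each repeat number. Repeat numbers are positive
#' integers in units of whole repeats; counts are nonnegative reals. Zero-count
#' bins are retained: the *support* of a histogram is the set of bins it
#' explicitly carries, which matters for the union-support distance below.
#'
#' @param counts numeric vector of counts, or a named numeric vector whose
#'   names are repeat numbers when `repeats` is missing.
#' @param repeats integer vector of repeat numbers (>= 1), parallel to
#'   `counts`. Duplicated bins are summed.
#' @param locus_id opaque locus label.
#' @return An object of class `repeat_histogram` with fields `locus_id`,
#'   `repeats` (ascending) and `counts`.
#' @examples
#' h <- repeat_histogram(c(5, 90, 5), repeats = c(19, 20, 21))
#' normalize_histogram(h)
#' @export
repeat_histogram <- function(counts, repeats = NULL, locus_id = "locus") {
  if (is.null(repeats)) {
    if (is.null(names(counts)))
      stop("`repeats` missing and `counts` is unnamed", call. = FALSE)
    repeats <- as.numeric(names(counts))
  }
  counts <- as.numeric(counts)
  if (length(counts) != length(repeats))
    stop("`counts` and `repeats` differ in length", call. = FALSE)
  if (anyNA(repeats) || anyNA(counts))
    stop("NA in histogram bins", call. = FALSE)
  if (any(repeats < 1) || any(repeats != round(repeats)))
    stop("repeat numbers must be integers >= 1", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be nonnegative", call. = FALSE)
  repeats <- as.integer(round(repeats))
  if (anyDuplicated(repeats)) {
    counts <- as.numeric(tapply(counts, repeats, sum))
    repeats <- sort(unique(repeats))
  } else {
    ord <- order(repeats)
    repeats <- repeats[ord]
    counts <- counts[ord]
  }
  structure(list(locus_id = as.character(locus_id)[1],
                 repeats = repeats, counts = counts),
            class = "repeat_histogram")
}

#' @export
print.repeat_histogram <- function(x, ...) {
  cat(sprintf("<repeat_histogram> locus '%s': %d bins, total %.6g\n",
              x$locus_id, length(x$repeats), histogram_total(x)))
  if (length(x$repeats)) {
    df <- data.frame(repeat_number = x$repeats, count = x$counts)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.repeat_histogram <- function(x, ...) {
  data.frame(locus_id = rep(x$locus_id, length(x$repeats)),
             repeat_number = x$repeats, count = x$counts,
             stringsAsFactors = FALSE)
}

#' Total mass of a histogram
#' @param h a [repeat_histogram()].
#' @return Sum of counts.
#' @export
histogram_total <- function(h) {
  stopifnot(inherits(h, "repeat_histogram"))
  sum(h$counts)
}

#' Normalize a histogram to frequencies
#'
#' Divides every count by the total, so the result sums to 1. Idempotent;
#' the support is unchanged.
#'
#' @param h a [repeat_histogram()] with positive total.
#' @return A `repeat_histogram` of frequencies.
#' @export
normalize_histogram <- function(h) {
  tot <- histogram_total(h)
  if (tot <= 0)
    stop("cannot normalize a histogram with zero total", call. = FALSE)
  repeat_histogram(h$counts / tot, repeats = h$repeats, locus_id = h$locus_id)
}

#' Align two histograms on their union support
#'
#' Returns paired value vectors over the ascending union of the two supports,
#' zero-filled where a histogram lacks a bin. This is the common frame on
#' which histogram distances are computed; bins observed by neither histogram
#' are *not* padded in (identical zero-padding on both sides would inflate
#' correlation).
#'
#' @param h1,h2 [repeat_histogram()]s with positive totals.
#' @return A list with `support` (integer vector) and numeric `v1`, `v2`.
#' @export
align_supports <- function(h1, h2) {
  stopifnot(inherits(h1, "repeat_histogram"), inherits(h2, "repeat_histogram"))
  if (histogram_total(h1) <= 0 || histogram_total(h2) <= 0)
    stop("align_supports: both histograms need a positive total", call. = FALSE)
  support <- sort(unique(c(h1$repeats, h2$repeats)))
  v1 <- v2 <- numeric(length(support))
  v1[match(h1$repeats, support)] <- h1$counts
  v2[match(h2$repeats, support)] <- h2$counts
  list(support = support, v1 = v1, v2 = v2)
}

#' Distance between two repeat-number histograms
#'
#' The default metric is one minus the Pearson correlation of the two
#' histograms aligned on their union support (range \[0, 2\]; 0 for
#' positively proportional histograms, 2 for perfect anticorrelation). The
#' metric is invariant to scaling either histogram, so counts and
#' frequencies are interchangeable.
#'
#' Degenerate case: if an aligned vector is constant the correlation is
#' undefined. Positively proportional pairs (which includes two identical
#' single-bin histograms) still return 0; any other constant-vector pair
#' returns the "no information" sentinel 1.0. Either way the result carries
#' a logical attribute `degenerate = TRUE` so single-bin comparisons can be
#' recognised as uninformative.
#'
#' Alternative metrics (computed on normalized frequencies over the union
#' support): `"chi_square"` (0.5 * sum (f1-f2)^2/(f1+f2)), `"euclidean"`,
#' and `"total_variation"` (0.5 * L1).
#'
#' @param h1,h2 [repeat_histogram()]s with positive totals.
#' @param metric one of `"one_minus_correlation"` (default), `"chi_square"`,
#'   `"euclidean"`, `"total_variation"`.
#' @return A single numeric distance, with attribute `degenerate` (logical).
#' @examples
#' a <- repeat_histogram(c(1, 2, 1), repeats = 9:11)
#' b <- repeat_histogram(c(1, 1, 2), repeats = 9:11)
#' histogram_distance(a, b)  # 1.5: Pearson r = -0.5
#' @export
histogram_distance <- function(h1, h2,
                               metric = c("one_minus_correlation", "chi_square",
                                          "euclidean", "total_variation")) {
  metric <- match.arg(metric)
  al <- align_supports(h1, h2)
  d <- .histogram_distance_vec(al$v1, al$v2, metric)
  d
}

## Distance on pre-aligned value vectors; shared with the genotyper hot path.
.histogram_distance_vec <- function(v1, v2, metric = "one_minus_correlation") {
  if (metric == "one_minus_correlation") {
    f1 <- v1 / sum(v1)
    f2 <- v2 / sum(v2)
    if (max(abs(f1 - f2)) < 1e-12) {
      ## positively proportional: distance 0 even when variance is zero
      deg <- length(v1) < 2 || max(f1) - min(f1) < 1e-15
      return(structure(0, degenerate = deg))
    }
    s1 <- max(v1) - min(v1)
    s2 <- max(v2) - min(v2)
    if (s1 == 0 || s2 == 0)
      return(structure(1.0, degenerate = TRUE))
    r <- .pearson(v1, v2)
    return(structure(min(max(1 - r, 0), 2), degenerate = FALSE))
  }
  f1 <- v1 / sum(v1)
  f2 <- v2 / sum(v2)
  d <- switch(metric,
    chi_square = {
      s <- f1 + f2
      keep <- s > 0
      0.5 * sum((f1[keep] - f2[keep])^2 / s[keep])
    },
    euclidean = sqrt(sum((f1 - f2)^2)),
    total_variation = 0.5 * sum(abs(f1 - f2)))
  structure(d, degenerate = FALSE)
}

.pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  dx <- x - mx
  dy <- y - my
  sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
}
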