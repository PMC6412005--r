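#' Prediction cache for the exhaustive genotyper
#'
#' Precomputes the model-predicted length distribution for every
#' (cycle count, candidate allele) pair on a shared support, so that a batch
#' of histograms (and every biallelic mixture, which is a convex combination
#' of two cached vectors) can be scored without re-propagating the Markov
#' chain. The support spans `1 .. max(length_range) + max(cycle_grid) + 5`.
#'
#' @param params a [stutter_params()].
#' @param length_range integer candidate allele lengths (default 5:60).
#' @param cycle_grid integer candidate cycle counts (default 0:60).
#' @return An object of class `genotyper_cache`.
#' @export
genotyper_cache <- function(params, length_range = 5:60, cycle_grid = 0:60) {
  if (!length(length_range) || !length(cycle_grid))
    stop("empty length range or cycle grid", call. = FALSE)
  length_range <- sort(unique(as.integer(length_range)))
  cycle_grid <- sort(unique(as.integer(cycle_grid)))
  if (any(cycle_grid < 0)) stop("cycle grid must be nonnegative", call. = FALSE)
  t_max <- max(cycle_grid)
  hi <- max(length_range) + t_max + 5L
  K <- build_kernel(params, 1L, hi)$matrix
  states <- 1:hi
  P <- matrix(0, length(length_range), hi)
  P[cbind(seq_along(length_range), length_range)] <- 1
  preds <- vector("list", length(cycle_grid))
  names(preds) <- cycle_grid
  j <- 1L
  for (t in 0:t_max) {
    if (t %in% cycle_grid) {
      preds[[j]] <- P
      j <- j + 1L
    }
    if (t < t_max) P <- P %*% K
  }
  structure(list(params = params, length_range = length_range,
                 cycle_grid = cycle_grid, states = states, preds = preds),
            class = "genotyper_cache")
}

#' @export
print.genotyper_cache <- function(x, ...) {
  cat(sprintf("<genotyper_cache> class %s: %d lengths x %d cycle counts\n",
              x$params$repeat_class, length(x$length_range),
              length(x$cycle_grid)))
  invisible(x)
}

## Measured histogram as a dense vector on the cache support (bins beyond the
## support would be unreachable by the model; kept in `extra` so the union
## support stays faithful).
.h_on_states <- function(h, n_states) {
  v <- numeric(n_states)
  inside <- h$repeats <= n_states
  v[h$repeats[inside]] <- h$counts[inside]
  list(v = v, extra = h$counts[!inside], extra_at = h$repeats[!inside])
}

## 1 - Pearson distance between a cached model vector and a measured vector,
## both dense on the cache support; union support = bins where either is
## positive (plus any measured bins beyond the support).
.dist_dense <- function(model_v, hv, metric = "one_minus_correlation") {
  mask <- model_v > 0 | hv$v > 0
  v1 <- c(model_v[mask], numeric(length(hv$extra)))
  v2 <- c(hv$v[mask], hv$extra)
  .histogram_distance_vec(v1, v2, metric)
}

#' Genotype call
#'
#' Result of the exhaustive mono-/biallelic genotyper for one histogram:
#' inferred allele(s), mixture proportion, best simulated cycle count, the
#' optimum distance (the raw confidence score; smaller is better), a batch
#' confidence percentile once ranked, and a status flag.
#'
#' @name genotype_call
NULL

.genotype_call <- function(locus_id, alleles, proportion, cycles, distance,
                           status, degenerate = FALSE) {
  structure(list(locus_id = locus_id, alleles = alleles,
                 proportion = proportion, cycles = cycles,
                 distance = distance, confidence_percentile = NA_real_,
                 status = status, degenerate = degenerate),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$status == "called") {
    al <- paste(x$alleles, collapse = "/")
    cat(sprintf(
      "<genotype_call> %s: alleles %s (p=%.2f), cycles %d, distance %.4g\n",
      x$locus_id, al, x$proportion, x$cycles, x$distance))
  } else {
    cat(sprintf("<genotype_call> %s: %s\n", x$locus_id, x$status))
  }
  invisible(x)
}

#' @export
as.data.frame.genotype_call <- function(x, ...) {
  data.frame(locus_id = x$locus_id,
             allele1 = if (length(x$alleles)) x$alleles[1] else NA_integer_,
             allele2 = if (length(x$alleles) > 1) x$alleles[2]
                       else if (length(x$alleles)) x$alleles[1]
                       else NA_integer_,
             proportion = x$proportion,
             cycles = x$cycles,
             distance = x$distance,
             percentile = x$confidence_percentile,
             status = x$status,
             stringsAsFactors = FALSE)
}

#' Monoallelic exhaustive genotyping
#'
#' Calls the underlying allele of a measured repeat-number histogram by
#' scoring it against the model-predicted stutter pattern of *every*
#' candidate (cycle count, allele length) pair and returning the argmin of
#' the histogram distance. Histograms with fewer than `min_coverage` raw
#' reads are not genotyped (status `"low_coverage"`). Ties break toward
#' smaller cycle count, then smaller allele.
#'
#' @param h measured [repeat_histogram()] of raw read counts.
#' @param params a [stutter_params()] (ignored when `cache` is given).
#' @param length_range,cycle_grid search grids (defaults 5:60 and 0:60).
#' @param min_coverage minimal total read count (default 5).
#' @param metric distance metric name.
#' @param cache optional prebuilt [genotyper_cache()].
#' @return A [genotype_call] object.
#' @examples
#' p <- default_stutter_params("AC")
#' h <- predict_histogram(p, 20, 17)
#' h$counts <- h$counts * 1000  # pretend 1000 reads
#' genotype_mono(h, p, length_range = 15:25, cycle_grid = seq(0, 30, 1))
#' @export
genotype_mono <- function(h, params, length_range = 5:60, cycle_grid = 0:60,
                          min_coverage = 5, metric = "one_minus_correlation",
                          cache = NULL) {
  stopifnot(inherits(h, "repeat_histogram"))
  if (is.null(cache))
    cache <- genotyper_cache(params, length_range, cycle_grid)
  if (histogram_total(h) < min_coverage)
    return(.genotype_call(h$locus_id, integer(0), NA_real_, NA_integer_,
                          NA_real_, "low_coverage"))
  hv <- .h_on_states(h, length(cache$states))
  best_d <- Inf; best_t <- NA_integer_; best_l <- NA_integer_; best_deg <- FALSE
  for (ti in seq_along(cache$cycle_grid)) {
    Pt <- cache$preds[[ti]]
    for (li in seq_along(cache$length_range)) {
      d <- .dist_dense(Pt[li, ], hv, metric)
      if (as.numeric(d) < best_d) {
        best_d <- as.numeric(d)
        best_t <- cache$cycle_grid[ti]
        best_l <- cache$length_range[li]
        best_deg <- isTRUE(attr(d, "degenerate"))
      }
    }
  }
  ## a degenerate comparison at distance 0 is an exact (delta-on-delta) match,
  ## still a valid call; only the 1.0 constant-vector sentinel is uninformative
  status <- if (best_deg && best_d > 0) "degenerate" else "called"
  .genotype_call(h$locus_id, best_l, 1.0, best_t, best_d, status, best_deg)
}

#' Biallelic exhaustive genotyping
#'
#' Extends the exhaustive search to two-allele mixtures: the argmin over
#' (cycle count, allele pair `l1 <= l2`, proportion `p` on a grid) of the
#' distance between the measured histogram and the overlaid model prediction
#' `p * H(t, l1) + (1 - p) * H(t, l2)`. Homozygous pairs (`l1 = l2`) are
#' included, so a pure single-allele signal collapses to a homozygous call.
#' Ties break toward smaller cycle count, then smaller allele separation,
#' then smaller first allele.
#'
#' @inheritParams genotype_mono
#' @param proportion_grid candidate proportions of the first allele
#'   (default `seq(0.1, 0.9, by = 0.1)`).
#' @return A [genotype_call] object (two alleles, ascending).
#' @export
genotype_biallelic <- function(h, params, length_range = 5:60,
                               cycle_grid = 0:60,
                               proportion_grid = seq(0.1, 0.9, by = 0.1),
                               min_coverage = 5,
                               metric = "one_minus_correlation",
                               cache = NULL) {
  stopifnot(inherits(h, "repeat_histogram"))
  if (!length(proportion_grid)) stop("empty proportion grid", call. = FALSE)
  if (is.null(cache))
    cache <- genotyper_cache(params, length_range, cycle_grid)
  if (histogram_total(h) < min_coverage)
    return(.genotype_call(h$locus_id, integer(0), NA_real_, NA_integer_,
                          NA_real_, "low_coverage"))
  hv <- .h_on_states(h, length(cache$states))
  L <- cache$length_range
  nl <- length(L)
  best <- list(d = Inf, t = NA_integer_, l1 = NA_integer_, l2 = NA_integer_,
               p = NA_real_, deg = FALSE)
  tol <- 1e-12
  for (ti in seq_along(cache$cycle_grid)) {
    Pt <- cache$preds[[ti]]
    tcur <- cache$cycle_grid[ti]
    for (i1 in seq_len(nl)) {
      v1 <- Pt[i1, ]
      ## homozygous candidate once (every p gives the same mixture; report 0.5)
      d <- .dist_dense(v1, hv, metric)
      dn <- as.numeric(d)
      if (dn < best$d - tol) {
        best <- list(d = dn, t = tcur, l1 = L[i1], l2 = L[i1],
                     p = 0.5, deg = isTRUE(attr(d, "degenerate")))
      } else if (abs(dn - best$d) <= tol &&
                 .lex_less(c(tcur, 0L, L[i1]),
                           c(best$t, best$l2 - best$l1, best$l1))) {
        best <- list(d = dn, t = tcur, l1 = L[i1], l2 = L[i1],
                     p = 0.5, deg = isTRUE(attr(d, "degenerate")))
      }
      if (i1 < nl) for (i2 in (i1 + 1L):nl) {
        v2 <- Pt[i2, ]
        for (p in proportion_grid) {
          mix <- p * v1 + (1 - p) * v2
          d <- .dist_dense(mix, hv, metric)
          dn <- as.numeric(d)
          if (dn < best$d - tol) {
            best <- list(d = dn, t = tcur, l1 = L[i1], l2 = L[i2], p = p,
                         deg = isTRUE(attr(d, "degenerate")))
          } else if (abs(dn - best$d) <= tol) {
            ## tie-break: smaller t, then smaller separation, then smaller l1
            cand <- c(tcur, L[i2] - L[i1], L[i1])
            inc <- c(best$t, best$l2 - best$l1, best$l1)
            if (.lex_less(cand, inc))
              best <- list(d = dn, t = tcur, l1 = L[i1], l2 = L[i2], p = p,
                           deg = isTRUE(attr(d, "degenerate")))
          }
        }
      }
    }
  }
  status <- if (best$deg && best$d > 0) "degenerate" else "called"
  .genotype_call(h$locus_id, c(best$l1, best$l2), best$p, best$t, best$d,
                 status, best$deg)
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Genotype a batch of histograms
#'
#' Builds the prediction cache once and genotypes every histogram, returning
#' a calls table ready for [rank_confidence()].
#'
#' @param hists list of [repeat_histogram()]s.
#' @param params a [stutter_params()].
#' @param mode `"mono"` or `"biallelic"`.
#' @param ... further arguments passed to [genotype_mono()] /
#'   [genotype_biallelic()] (`length_range`, `cycle_grid`, `min_coverage`,
#'   `proportion_grid`, `metric`).
#' @param length_range,cycle_grid search grids used to build the cache.
#' @return A data frame with one row per histogram (columns `locus_id`,
#'   `allele1`, `allele2`, `proportion`, `cycles`, `distance`, `percentile`,
#'   `status`).
#' @export
genotype_histograms <- function(hists, params, mode = c("mono", "biallelic"),
                                length_range = 5:60, cycle_grid = 0:60, ...) {
  mode <- match.arg(mode)
  cache <- genotyper_cache(params, length_range, cycle_grid)
  calls <- lapply(hists, function(h) {
    if (mode == "mono") genotype_mono(h, params, cache = cache, ...)
    else genotype_biallelic(h, params, cache = cache, ...)
  })
  do.call(rbind, lapply(calls, as.data.frame))
}

#' Rank genotype calls by confidence percentile
#'
#' Assigns each called result a percentile of its optimum distance within
#' the batch: 0 for the smallest distance (highest confidence), 100 for the
#' largest, `100 * (rank - 1) / (n - 1)` in between. Tied distances share
#' the smaller percentile; the assignment is invariant to input order.
#' Non-called rows keep `NA`.
#'
#' @param calls a calls data frame ([genotype_histograms()]) or list of
#'   [genotype_call] objects.
#' @return The calls data frame with the `percentile` column filled.
#' @export
rank_confidence <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, lapply(calls, as.data.frame))
  stopifnot(is.data.frame(calls))
  idx <- which(calls$status == "called")
  if (!length(idx)) return(calls)
  d <- calls$distance[idx]
  r <- rank(d, ties.method = "min")
  pct <- if (length(idx) == 1L) 0 else 100 * (r - 1) / (length(idx) - 1)
  calls$percentile[idx] <- pct
  calls
}
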