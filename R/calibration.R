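#' Calibration record
#'
#' One measured histogram for a (repeat class, designed length, time point)
#' combination of an amplification calibration panel. The
#' `designed_signal_fraction` — the fraction of reads at exactly the designed
#' length — is computed on construction and drives [filter_calibration()]:
#' records in which the designed signal has been eroded below the analysis
#' threshold (default 5%) are too noisy to calibrate on.
#'
#' @param repeat_class repeat-unit class label.
#' @param designed_length designed (synthesis-verified) repeat length.
#' @param time_point label, e.g. `"T1"`, `"T2"`, `"T3"`.
#' @param cycles effective PCR cycle count for the time point (integer >= 0),
#'   or `NA` when cycles are to be fitted.
#' @param histogram the measured [repeat_histogram()].
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(repeat_class, designed_length, time_point,
                               cycles, histogram) {
  stopifnot(inherits(histogram, "repeat_histogram"))
  tot <- histogram_total(histogram)
  if (tot <= 0) stop("calibration record needs a nonempty histogram",
                     call. = FALSE)
  at_n0 <- histogram$counts[histogram$repeats == designed_length]
  frac <- if (length(at_n0)) sum(at_n0) / tot else 0
  structure(list(repeat_class = as.character(repeat_class)[1],
                 designed_length = as.integer(designed_length),
                 time_point = as.character(time_point)[1],
                 cycles = if (is.na(cycles)) NA_integer_ else as.integer(cycles),
                 histogram = histogram,
                 designed_signal_fraction = frac),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(
    "<calibration_record> %s n0=%d %s (cycles %s): %d bins, signal %.1f%%\n",
    x$repeat_class, x$designed_length, x$time_point,
    ifelse(is.na(x$cycles), "free", x$cycles),
    length(x$histogram$repeats), 100 * x$designed_signal_fraction))
  invisible(x)
}

#' Filter calibration records by designed-signal fraction
#'
#' Keeps exactly the records whose fraction of reads at the designed length
#' is at least `threshold` (default 5%, the standard lower analysis
#' threshold below which a measurement is deemed too noisy); order
#' preserving.
#'
#' @param records list of [calibration_record()]s.
#' @param threshold fraction in \[0, 1\].
#' @return The retained sublist.
#' @export
filter_calibration <- function(records, threshold = 0.05) {
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  keep <- vapply(records, function(r) r$designed_signal_fraction >= threshold,
                 logical(1))
  records[keep]
}

## Predictions for every record under one parameter set: one kernel over the
## pooled support, all designed lengths propagated jointly to the largest
## cycle count needed. Returns a list of numeric vectors named by repeat
## number, parallel to `records`.
.predict_for_records <- function(params, records, cycles) {
  stopifnot(length(cycles) == length(records))
  n0s <- vapply(records, `[[`, 0L, "designed_length")
  t_max <- max(cycles)
  lo <- max(1L, min(n0s) - 3L * t_max - 5L)
  hi <- max(n0s) + t_max + 5L
  K <- build_kernel(params, lo, hi)$matrix
  states <- lo:hi
  uniq <- sort(unique(n0s))
  P <- matrix(0, length(uniq), length(states))
  P[cbind(seq_along(uniq), match(uniq, states))] <- 1
  need <- split(seq_along(records), cycles)   # record indices per cycle count
  preds <- vector("list", length(records))
  for (t in 0:t_max) {
    key <- as.character(t)
    if (!is.null(need[[key]])) {
      for (i in need[[key]]) {
        v <- P[match(n0s[i], uniq), ]
        names(v) <- states
        preds[[i]] <- v
      }
    }
    if (t < t_max) P <- P %*% K
  }
  preds
}

#' Calibration objective: mean squared histogram distance
#'
#' The model-fit score minimised during calibration: the sum over all
#' included records of the squared distance between the model-predicted
#' histogram at the record's (cycles, designed length) and the measured
#' histogram, divided by the number of records. The default distance is
#' 1 - Pearson correlation on the union support ([histogram_distance()]).
#'
#' @param params a [stutter_params()].
#' @param records filtered list of [calibration_record()]s, single repeat
#'   class matching `params`.
#' @param cycles_by_timepoint optional named vector overriding each record's
#'   own `cycles` by time-point label.
#' @param metric distance metric name (see [histogram_distance()]).
#' @return The nonnegative objective value.
#' @export
calibration_objective <- function(params, records,
                                  cycles_by_timepoint = NULL,
                                  metric = "one_minus_correlation") {
  if (!length(records))
    stop("empty calibration dataset (after filtering?)", call. = FALSE)
  cls <- unique(vapply(records, `[[`, "", "repeat_class"))
  if (length(cls) > 1)
    stop("records span several repeat classes; calibrate each separately",
         call. = FALSE)
  cycles <- .effective_cycles(records, cycles_by_timepoint)
  preds <- .predict_for_records(params, records, cycles)
  d2 <- vapply(seq_along(records), function(i) {
    h <- records[[i]]$histogram
    v <- preds[[i]]
    states <- as.integer(names(v))
    keep <- v > 0
    support <- sort(unique(c(states[keep], h$repeats)))
    v1 <- numeric(length(support)); v2 <- v1
    v1[match(states[keep], support)] <- v[keep]
    v2[match(h$repeats, support)] <- h$counts
    as.numeric(.histogram_distance_vec(v1, v2, metric))^2
  }, numeric(1))
  sum(d2) / length(records)
}

.effective_cycles <- function(records, cycles_by_timepoint = NULL) {
  vapply(records, function(r) {
    if (!is.null(cycles_by_timepoint) &&
        r$time_point %in% names(cycles_by_timepoint))
      return(as.integer(cycles_by_timepoint[[r$time_point]]))
    if (is.na(r$cycles))
      stop(sprintf("record %s/%s has no cycle count and none supplied",
                   r$repeat_class, r$time_point), call. = FALSE)
    r$cycles
  }, integer(1))
}

## Coefficient <-> optimiser-space mapping: slopes and intercepts live on
## very different scales, so optimise in units of a per-coefficient scale.
.COEF_SCALE <- c(up_slope = 1e-4, up_intercept = 1e-3,
                 down_slope_1 = 1e-4, down_intercept_1 = 1e-3,
                 down_slope_2 = 1e-4, down_intercept_2 = 1e-3,
                 down_slope_3 = 1e-4, down_intercept_3 = 1e-3)

.params_from_theta <- function(theta, template) {
  coefs <- theta * .COEF_SCALE
  do.call(stutter_params,
          c(list(repeat_class = template$repeat_class,
                 model_family = template$model_family),
            as.list(setNames(coefs, names(.COEF_SCALE)))))
}

.theta_from_params <- function(params) {
  vapply(names(.COEF_SCALE), function(k) params[[k]], numeric(1)) / .COEF_SCALE
}

#' Fit stutter model parameters to a calibration dataset
#'
#' Quasi-Newton (BFGS) minimisation of [calibration_objective()] over the
#' eight linear coefficients of the one-cycle kernel, for a single repeat
#' class. The objective is nonconvex, so the local optimiser is restarted
#' from `n_starts` seeded random initialisations around a small-positive
#' prior (plus `init` itself when given); the best result is returned.
#'
#' With `cycles_mode = "free"` the effective cycle count of each non-zero
#' time point is additionally searched on an integer outer grid (time points
#' mapped to 0 stay pinned), with the continuous fit nested inside; supply
#' grids via `cycle_grids` (a named list of integer vectors by time-point
#' label).
#'
#' @param records filtered [calibration_record()]s of one repeat class.
#' @param init optional [stutter_params()] starting point (also fixes repeat
#'   class and model family; default `Linear1up3dw` for the records' class).
#' @param cycles_mode `"fixed"` (use each record's cycles) or `"free"`.
#' @param cycle_grids named list of candidate integer cycle grids, one per
#'   time point, used when `cycles_mode = "free"`.
#' @param n_starts number of random restarts (default 8).
#' @param seed integer seed for the restarts.
#' @param metric distance metric name.
#' @param maxit,reltol BFGS control parameters.
#' @return An object of class `stutter_fit`: list with `params`,
#'   `cycles_by_timepoint`, `objective_value`, `converged`, `iterations`,
#'   `n_records`.
#' @export
fit_stutter_model <- function(records, init = NULL,
                              cycles_mode = c("fixed", "free"),
                              cycle_grids = NULL,
                              n_starts = 8L, seed = 1L,
                              metric = "one_minus_correlation",
                              maxit = 500L, reltol = 1e-12) {
  cycles_mode <- match.arg(cycles_mode)
  if (!length(records))
    stop("empty calibration dataset (after filtering?)", call. = FALSE)
  cls <- unique(vapply(records, `[[`, "", "repeat_class"))
  if (length(cls) > 1)
    stop("records span several repeat classes; calibrate each separately",
         call. = FALSE)
  if (is.null(init)) init <- stutter_params(cls, model_family = "Linear1up3dw")

  tps <- sort(unique(vapply(records, `[[`, "", "time_point")))
  if (cycles_mode == "fixed") {
    cyc <- vapply(tps, function(tp) {
      unique(vapply(records[vapply(records, `[[`, "", "time_point") == tp],
                    `[[`, integer(1), "cycles"))[1]
    }, integer(1))
    return(.fit_continuous(records, init, setNames(cyc, tps), n_starts, seed,
                           metric, maxit, reltol))
  }

  ## free mode: exhaustive product over supplied per-timepoint grids
  if (is.null(cycle_grids))
    stop("cycles_mode = \"free\" needs `cycle_grids`", call. = FALSE)
  fixed0 <- setNames(rep(0L, length(tps)), tps)
  grids <- lapply(tps, function(tp) {
    g <- cycle_grids[[tp]]
    if (is.null(g)) 0L else as.integer(g)
  })
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- tps
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    cyc <- setNames(as.integer(combos[i, ]), tps)
    fit <- .fit_continuous(records, init, cyc, n_starts, seed, metric,
                           maxit, reltol)
    if (is.null(best) || fit$objective_value < best$objective_value)
      best <- fit
  }
  best
}

## First-order method-of-moments warm start: after t cycles at low dose, the
## mass of the k-step satellite peak of a length-n0 histogram is roughly
## t * p_k(n0), so the satellite fractions at the earliest amplified time
## point give direct step-probability estimates; a line through them over
## the designed lengths seeds the slopes and intercepts near the right
## basin, where the flat squared-correlation objective is hard to cross.
.moment_start <- function(records, cycles) {
  use <- which(cycles > 0)
  if (!length(use)) return(NULL)
  t_min <- min(cycles[use])
  use <- use[cycles[use] == t_min]
  n0s <- vapply(records[use], `[[`, 0L, "designed_length")
  est <- vapply(records[use], function(r) {
    f <- r$histogram$counts / sum(r$histogram$counts)
    at <- function(k) {
      v <- f[r$histogram$repeats == r$designed_length + k]
      if (length(v)) v else 0
    }
    c(at(1), at(-1), at(-2), at(-3)) / t_min
  }, numeric(4))
  coefs <- numeric(length(.COEF_SCALE))
  names(coefs) <- names(.COEF_SCALE)
  for (j in 1:4) {
    p_hat <- est[j, ]
    ab <- if (length(unique(n0s)) >= 2) {
      cf <- coef(lm(p_hat ~ n0s))
      c(max(cf[[2]], 0), max(cf[[1]], 0))
    } else c(mean(p_hat) / mean(n0s), 0)
    coefs[2L * j - 1L] <- ab[1]
    coefs[2L * j] <- ab[2]
  }
  coefs / .COEF_SCALE
}

.fit_continuous <- function(records, init, cycles_by_timepoint, n_starts,
                            seed, metric, maxit, reltol) {
  template <- init
  fn <- function(theta) {
    calibration_objective(.params_from_theta(theta, template), records,
                          cycles_by_timepoint = cycles_by_timepoint,
                          metric = metric)
  }
  starts <- list(.theta_from_params(init))
  cyc <- .effective_cycles(records, cycles_by_timepoint)
  mom <- tryCatch(.moment_start(records, cyc), error = function(e) NULL)
  if (!is.null(mom) && all(is.finite(mom))) starts <- c(starts, list(mom))
  if (n_starts > 1) {
    set.seed(as.integer(seed))
    for (i in seq_len(n_starts - 1L)) {
      ## small-positive-slope prior: coefficients ~ U(0, 5) in scale units,
      ## i.e. slopes up to 5e-4 and intercepts up to 5e-3
      starts[[length(starts) + 1L]] <- runif(length(.COEF_SCALE), 0, 5)
    }
  }
  best <- NULL
  total_iter <- 0L
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, fn, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    total_iter <- total_iter + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  ## the squared 1-correlation objective is extremely flat near its optimum
  ## (quartic-like in the residual), where quasi-Newton steps stall; polish
  ## the best start with a simplex pass and a final quasi-Newton run
  polish <- tryCatch(
    optim(best$par, fn, method = "Nelder-Mead",
          control = list(maxit = 4000L, reltol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    total_iter <- total_iter + polish$counts[["function"]]
    best <- polish
  }
  polish <- tryCatch(
    optim(best$par, fn, method = "BFGS",
          control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    total_iter <- total_iter + polish$counts[["function"]]
    best <- polish
  }
  structure(list(params = .params_from_theta(best$par, template),
                 cycles_by_timepoint = cycles_by_timepoint,
                 objective_value = best$value,
                 converged = best$convergence == 0,
                 iterations = total_iter,
                 n_records = length(records)),
            class = "stutter_fit")
}

#' @export
print.stutter_fit <- function(x, ...) {
  cat(sprintf("<stutter_fit> class %s: objective %.4g over %d records (%s)\n",
              x$params$repeat_class, x$objective_value, x$n_records,
              if (x$converged) "converged" else "not converged"))
  cat("  cycles:", paste(names(x$cycles_by_timepoint),
                         x$cycles_by_timepoint, sep = "=", collapse = " "), "\n")
  print(x$params)
  invisible(x)
}

#' Best-fitting simulated cycle count for a measured histogram
#'
#' With the genotype (designed length) known, finds the integer cycle count
#' whose model prediction is nearest the measured histogram — the "simulated
#' cycles" readout used to compare amplification conditions (enzymes,
#' dilutions). Ties break toward smaller `t`.
#'
#' @param histogram measured [repeat_histogram()].
#' @param params a [stutter_params()].
#' @param n0 known designed repeat length.
#' @param cycle_grid integer candidate cycle counts (default 0:60).
#' @param metric distance metric name.
#' @return List with `cycles`, `distance`, `degenerate` (logical: the best
#'   comparison was a degenerate constant-vector case).
#' @export
fit_simulated_cycles <- function(histogram, params, n0, cycle_grid = 0:60,
                                 metric = "one_minus_correlation") {
  stopifnot(inherits(histogram, "repeat_histogram"))
  if (!length(cycle_grid)) stop("empty cycle grid", call. = FALSE)
  cycle_grid <- sort(unique(as.integer(cycle_grid)))
  t_max <- max(cycle_grid)
  traj <- .predict_trajectory(params, as.integer(n0), t_max)
  states <- as.integer(colnames(traj))
  best_t <- NA_integer_; best_d <- Inf; best_deg <- FALSE
  for (t in cycle_grid) {
    v <- traj[t + 1L, ]
    keep <- v > 0
    support <- sort(unique(c(states[keep], histogram$repeats)))
    v1 <- numeric(length(support)); v2 <- v1
    v1[match(states[keep], support)] <- v[keep]
    v2[match(histogram$repeats, support)] <- histogram$counts
    d <- .histogram_distance_vec(v1, v2, metric)
    if (as.numeric(d) < best_d) {
      best_d <- as.numeric(d)
      best_t <- t
      best_deg <- isTRUE(attr(d, "degenerate"))
    }
  }
  list(cycles = best_t, distance = best_d, degenerate = best_deg)
}
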