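## Model-family registry -------------------------------------------------
##
## A model family is a provider of one-cycle step distributions: a function
## f(params, n) -> matrix over offsets {+1, 0, -1, -2, -3} for a vector of
## repeat lengths n. Only "Linear1up3dw" ships with a concrete form; competitor
## families can be registered through the same interface.

.stutter_families <- new.env(parent = emptyenv())

#' Register a stutter model family
#'
#' A family is a function `f(params, n)` receiving a [stutter_params()] object
#' and an integer vector of repeat lengths, and returning a numeric matrix
#' with `length(n)` rows and columns named `"+1", "0", "-1", "-2", "-3"` —
#' the one-cycle step distribution at each length (rows must sum to 1).
#' Competitor one-cycle models can be plugged in this way and used by every
#' downstream operation (kernel construction, prediction, calibration,
#' genotyping).
#'
#' @param name family name.
#' @param step_fun the provider function described above.
#' @return `name`, invisibly.
#' @export
register_stutter_family <- function(name, step_fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(step_fun))
  assign(name, step_fun, envir = .stutter_families)
  invisible(name)
}

#' List registered stutter model families
#' @return Character vector of family names.
#' @export
stutter_families <- function() sort(ls(.stutter_families))

.get_family <- function(name) {
  if (!exists(name, envir = .stutter_families, inherits = FALSE))
    stop(sprintf("unknown model family '%s'; registered: %s", name,
                 paste(stutter_families(), collapse = ", ")), call. = FALSE)
  get(name, envir = .stutter_families, inherits = FALSE)
}

## Offsets a slippage event can take in one cycle, in reporting order.
.STEP_OFFSETS <- c(1L, 0L, -1L, -2L, -3L)
.STEP_NAMES <- c("+1", "0", "-1", "-2", "-3")

#' One-cycle slippage parameters for a repeat class
#'
#' Parameters of the `Linear1up3dw` kernel (or a registered competitor
#' family) for one repeat-unit class. Each per-cycle mutation probability is
#' linear in the current repeat length `n`:
#' `p_up = up_slope * n + up_intercept` for a one-unit elongation, and
#' `p_down_k = down_slope_k * n + down_intercept_k` for a k-unit contraction,
#' k in 1..3. Evaluated probabilities are clamped to \[0, 1\]; see
#' [step_distribution()] for the full normalisation rules. Classes are
#' calibrated individually and never share parameters.
#'
#' @param repeat_class repeat-unit class label, conventionally one of
#'   `"A"`, `"C"`, `"AC"`, `"AG"`, `"AT"` (extensible).
#' @param up_slope,up_intercept linear coefficients of the +1 step.
#' @param down_slope_1,down_intercept_1 coefficients of the -1 step.
#' @param down_slope_2,down_intercept_2 coefficients of the -2 step.
#' @param down_slope_3,down_intercept_3 coefficients of the -3 step.
#' @param model_family name of a registered family; default `"Linear1up3dw"`.
#' @return An object of class `stutter_params`.
#' @examples
#' p <- stutter_params("AC", up_slope = 2e-4, down_slope_1 = 1e-3,
#'                     down_slope_2 = 2e-4, down_slope_3 = 5e-5)
#' step_distribution(p, 20)
#' @export
stutter_params <- function(repeat_class,
                           up_slope = 0, up_intercept = 0,
                           down_slope_1 = 0, down_intercept_1 = 0,
                           down_slope_2 = 0, down_intercept_2 = 0,
                           down_slope_3 = 0, down_intercept_3 = 0,
                           model_family = "Linear1up3dw") {
  coefs <- c(up_slope = up_slope, up_intercept = up_intercept,
             down_slope_1 = down_slope_1, down_intercept_1 = down_intercept_1,
             down_slope_2 = down_slope_2, down_intercept_2 = down_intercept_2,
             down_slope_3 = down_slope_3, down_intercept_3 = down_intercept_3)
  stopifnot(is.numeric(coefs), !anyNA(coefs))
  structure(c(list(repeat_class = as.character(repeat_class)[1],
                   model_family = model_family),
              as.list(coefs)),
            class = "stutter_params")
}

#' @export
print.stutter_params <- function(x, ...) {
  cat(sprintf("<stutter_params> class %s, family %s\n",
              x$repeat_class, x$model_family))
  cat(sprintf("  up:    slope %.4g  intercept %.4g\n", x$up_slope, x$up_intercept))
  for (k in 1:3)
    cat(sprintf("  down%d: slope %.4g  intercept %.4g\n", k,
                x[[paste0("down_slope_", k)]], x[[paste0("down_intercept_", k)]]))
  invisible(x)
}

#' Default per-class stutter parameters
#'
#' Realistic-scale kernel coefficients for each repeat class, used as the
#' synthetic-data generator's ground truth and as a sensible starting point
#' before calibration. Dinucleotide classes use a per-cycle total mutation
#' probability of ~2.5e-2 at 20 repeats; mononucleotides are twice as
#' slippage-prone. The AT class reuses the same family although measured AT
#' stutter is known to follow a distinct, poorly Markovian pattern — treat
#' AT fits with caution.
#'
#' @param repeat_class one of `"A"`, `"C"`, `"AC"`, `"AG"`, `"AT"`.
#' @return A [stutter_params()] object.
#' @export
default_stutter_params <- function(repeat_class = c("AC", "AG", "AT", "A", "C")) {
  repeat_class <- match.arg(repeat_class)
  base <- c(up = 2e-4, d1 = 1e-3, d2 = 2e-4, d3 = 5e-5)
  mult <- switch(repeat_class, A = 2, C = 2, AC = 1, AG = 1, AT = 2)
  s <- base * mult
  stutter_params(repeat_class,
                 up_slope = s[["up"]],
                 down_slope_1 = s[["d1"]],
                 down_slope_2 = s[["d2"]],
                 down_slope_3 = s[["d3"]])
}

## Vectorised step distribution for the linear 1-up/3-down family.
## Returns a length(n) x 5 matrix over .STEP_NAMES.
.linear1up3dw_steps <- function(params, n) {
  n <- as.numeric(n)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  p_up <- clamp01(params$up_slope * n + params$up_intercept)
  p_d1 <- clamp01(params$down_slope_1 * n + params$down_intercept_1)
  p_d2 <- clamp01(params$down_slope_2 * n + params$down_intercept_2)
  p_d3 <- clamp01(params$down_slope_3 * n + params$down_intercept_3)
  s <- p_up + p_d1 + p_d2 + p_d3
  over <- s > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / s, 1)
    p_up <- p_up * sc; p_d1 <- p_d1 * sc; p_d2 <- p_d2 * sc; p_d3 <- p_d3 * sc
    s <- pmin(s, 1)
  }
  p_stay <- 1 - s
  ## contractions below one repeat are impossible: move their mass to the
  ## largest feasible contraction, or to "stay" when none exists (n = 1)
  i3 <- n - 3 < 1
  p_d2[i3] <- p_d2[i3] + p_d3[i3]; p_d3[i3] <- 0
  i2 <- n - 2 < 1
  p_d1[i2] <- p_d1[i2] + p_d2[i2]; p_d2[i2] <- 0
  i1 <- n - 1 < 1
  p_stay[i1] <- p_stay[i1] + p_d1[i1]; p_d1[i1] <- 0
  m <- cbind(p_up, p_stay, p_d1, p_d2, p_d3)
  colnames(m) <- .STEP_NAMES
  m
}

register_stutter_family("Linear1up3dw", .linear1up3dw_steps)

#' One-cycle step distribution at a given repeat length
#'
#' Probability that a single PCR cycle leaves a repeat tract of length `n`
#' unchanged, elongates it by one unit, or contracts it by 1–3 units. For the
#' `Linear1up3dw` family every mutation probability is `slope * n + intercept`
#' clamped to \[0, 1\]; if the four mutation probabilities sum above 1 they
#' are rescaled to sum exactly 1 (stay probability 0), otherwise the stay
#' probability absorbs the remainder. Contractions that would drop the length
#' below one repeat are redirected to the largest feasible contraction (or to
#' stay at `n = 1`).
#'
#' @param params a [stutter_params()].
#' @param n repeat length, integer >= 1 (vectorised).
#' @return For scalar `n`, a named probability vector over offsets
#'   `"+1", "0", "-1", "-2", "-3"`; for vector `n`, a matrix with one row per
#'   length. Rows sum to 1.
#' @export
step_distribution <- function(params, n) {
  stopifnot(inherits(params, "stutter_params"))
  if (any(n < 1) || any(n != round(n)))
    stop("repeat length must be an integer >= 1", call. = FALSE)
  fam <- .get_family(params$model_family)
  m <- fam(params, n)
  if (length(n) == 1L) {
    v <- m[1, ]
    names(v) <- .STEP_NAMES
    return(v)
  }
  m
}
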