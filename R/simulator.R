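#' Simulation configuration
#'
#' Configuration of the molecule-level branching-process PCR stutter
#' simulator. Each cycle every existing molecule is copied with probability
#' `efficiency`; every *new* copy mutates its repeat length once according to
#' [step_distribution()] at the template's current length, while templates
#' persist unchanged. After `cycles` cycles, `reads` molecules are sampled
#' (without replacement when possible) and binned into a histogram.
#'
#' This is deliberately richer than the Markov-chain predictor, which applies
#' one kernel step per cycle to the *whole* population: in the branching
#' process only newly synthesised molecules acquire slippage, so a random
#' final molecule has undergone about `cycles * efficiency / (1 + efficiency)`
#' synthesis events rather than `cycles`. Comparing the two quantifies the
#' adequacy of the whole-population simplification (see the package
#' vignette).
#'
#' @param params a [stutter_params()].
#' @param alleles one or two designed repeat lengths.
#' @param proportions allele proportions summing to 1 (default equal).
#' @param initial_molecules starting molecule count (split across alleles by
#'   `proportions`, rounded).
#' @param cycles nonnegative integer PCR cycle count.
#' @param efficiency per-cycle replication probability in (0, 1].
#' @param reads number of molecules sampled into the output histogram.
#' @param seed integer seed; the simulation is fully reproducible per seed.
#' @param locus_id label for the output histogram.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, alleles, proportions = NULL,
                              initial_molecules = 1000L, cycles = 30L,
                              efficiency = 1.0, reads = 1000L, seed = 1L,
                              locus_id = "sim") {
  stopifnot(inherits(params, "stutter_params"))
  alleles <- as.integer(alleles)
  if (!length(alleles) %in% 1:2 || any(alleles < 1))
    stop("`alleles` must be one or two repeat lengths >= 1", call. = FALSE)
  if (is.null(proportions))
    proportions <- rep(1 / length(alleles), length(alleles))
  if (length(proportions) != length(alleles) ||
      abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("`proportions` must be nonnegative and sum to 1", call. = FALSE)
  if (efficiency <= 0 || efficiency > 1)
    stop("`efficiency` must lie in (0, 1]", call. = FALSE)
  if (cycles < 0 || cycles != round(cycles))
    stop("`cycles` must be a nonnegative integer", call. = FALSE)
  if (initial_molecules < 1) stop("need at least one starting molecule",
                                  call. = FALSE)
  structure(list(params = params, alleles = alleles,
                 proportions = proportions,
                 initial_molecules = as.integer(initial_molecules),
                 cycles = as.integer(cycles), efficiency = efficiency,
                 reads = as.integer(reads), seed = as.integer(seed),
                 locus_id = locus_id),
            class = "simulation_config")
}

.POP_GUARD <- 1e8

#' Simulate PCR stutter at the molecule level
#'
#' Runs the branching process described in [simulation_config()] and samples
#' a read histogram. Sampling is exact multivariate-hypergeometric (without
#' replacement) when `reads` does not exceed the final population; otherwise
#' it falls back to sampling with replacement and flags the fact in the
#' audit record.
#'
#' @param config a [simulation_config()].
#' @return A [repeat_histogram()] of read counts, with the ground-truth
#'   audit record (config, final population by length, total molecules,
#'   `sampled_with_replacement` flag) attached as attribute `"audit"`.
#' @examples
#' p <- default_stutter_params("AC")
#' cfg <- simulation_config(p, alleles = 20, initial_molecules = 500,
#'                          cycles = 20, efficiency = 0.5, reads = 500,
#'                          seed = 7)
#' simulate_pcr(cfg)
#' @export
simulate_pcr <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  hi <- max(config$alleles) + config$cycles + 5L
  pop <- numeric(hi)  # molecule counts by repeat length 1..hi
  n0 <- round(config$initial_molecules * config$proportions)
  n0[1] <- config$initial_molecules - sum(n0[-1])
  pop[config$alleles] <- pop[config$alleles] + n0
  steps <- step_distribution(config$params, 1:hi)
  for (cyc in seq_len(config$cycles)) {
    occupied <- which(pop > 0)
    new_counts <- rbinom(length(occupied), size = pop[occupied],
                         prob = config$efficiency)
    for (k in seq_along(occupied)) {
      nn <- new_counts[k]
      if (nn == 0) next
      len <- occupied[k]
      off <- rmultinom(1, nn, steps[len, ])[, 1]
      targets <- pmin(pmax(len + .STEP_OFFSETS, 1L), hi)
      for (j in seq_along(targets))
        pop[targets[j]] <- pop[targets[j]] + off[j]
    }
    if (sum(pop) > .POP_GUARD)
      stop(sprintf(paste0("population exceeded %g molecules at cycle %d; ",
                          "use simulate_pcr_distribution() for large regimes"),
                   .POP_GUARD, cyc), call. = FALSE)
  }
  total <- sum(pop)
  occupied <- which(pop > 0)
  with_replacement <- config$reads > total
  if (!with_replacement) {
    ## sequential multivariate hypergeometric draw
    remaining <- config$reads
    left <- total
    reads <- numeric(length(occupied))
    for (k in seq_along(occupied)) {
      ni <- pop[occupied[k]]
      x <- rhyper(1, ni, left - ni, remaining)
      reads[k] <- x
      remaining <- remaining - x
      left <- left - ni
      if (remaining == 0) break
    }
  } else {
    reads <- rmultinom(1, config$reads, pop[occupied] / total)[, 1]
  }
  keep <- reads > 0
  h <- repeat_histogram(reads[keep], repeats = occupied[keep],
                        locus_id = config$locus_id)
  attr(h, "audit") <- list(config = config,
                           population_by_length = setNames(pop[occupied],
                                                           occupied),
                           total_molecules = total,
                           sampled_with_replacement = with_replacement)
  h
}

#' Expected length distribution of the branching process
#'
#' Deterministic expectation-mode twin of [simulate_pcr()]: propagates the
#' expected repeat-length distribution of the branching process exactly via
#' the recursion `v_{t+1} = (v_t + efficiency * v_t K) / (1 + efficiency)`.
#' At efficiency 1 this equals the binomial mixture
#' `sum_k choose(t, k) K^k / 2^t` of kernel powers. No randomness; `reads`
#' and `seed` are ignored.
#'
#' @param config a [simulation_config()].
#' @return A [repeat_histogram()] of frequencies.
#' @export
simulate_pcr_distribution <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  hi <- max(config$alleles) + config$cycles + 5L
  K <- build_kernel(config$params, 1L, hi)$matrix
  v <- numeric(hi)
  v[config$alleles] <- config$proportions
  e <- config$efficiency
  for (cyc in seq_len(config$cycles))
    v <- (v + e * as.numeric(v %*% K)) / (1 + e)
  keep <- v > 0
  repeat_histogram(v[keep], repeats = which(keep),
                   locus_id = config$locus_id)
}
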