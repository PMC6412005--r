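#' Generate a synthetic calibration dataset
#'
#' Emulates a synthetic-plasmid amplification panel: for each combination of
#' repeat class, designed length and time point, a measured repeat-number
#' histogram is produced from known ground-truth kernel parameters. Two
#' generation modes exist:
#' \describe{
#'   \item{`"noiseless"`}{the exact Markov-chain prediction at the time
#'     point's cycle count, scaled to `reads` (no sampling noise) — the
#'     regime for parameter-recovery studies;}
#'   \item{`"sampled"`}{a seeded [simulate_pcr()] branching run with
#'     `efficiency` and `initial_molecules`, i.e. realistic molecule-level
#'     noise.}
#' }
#'
#' @param classes repeat classes to include (default `"AC"`).
#' @param lengths designed repeat lengths (default `c(15, 25, 35)`).
#' @param timepoints named integer vector of effective cycle counts per time
#'   point (default `c(T1 = 0, T2 = 17, T3 = 47)`, the nested-PCR protocol:
#'   a direct-sequencing time point, one 17-cycle PCR, and 30 + 17 cycles).
#' @param params_list named list of ground-truth [stutter_params()] per
#'   class; defaults to [default_stutter_params()] for each class.
#' @param mode `"noiseless"` or `"sampled"`.
#' @param reads reads per histogram.
#' @param efficiency,initial_molecules branching-process settings for
#'   `"sampled"` mode. The default efficiency 0.25 keeps a 47-cycle run of
#'   1000 starting molecules well under the simulator's population guard
#'   (emulating the strongly plateau-limited amplification of a long nested
#'   protocol).
#' @param seed integer seed (drives `"sampled"` mode; one sub-seed per
#'   record).
#' @return A list of [calibration_record()]s with the ground-truth parameter
#'   list attached as attribute `"truth"`.
#' @export
generate_calibration_dataset <- function(classes = "AC",
                                         lengths = c(15L, 25L, 35L),
                                         timepoints = c(T1 = 0L, T2 = 17L,
                                                        T3 = 47L),
                                         params_list = NULL,
                                         mode = c("noiseless", "sampled"),
                                         reads = 1000L,
                                         efficiency = 0.25,
                                         initial_molecules = 1000L,
                                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(names(timepoints)) || any(!nzchar(names(timepoints))))
    stop("`timepoints` must be a named vector of cycle counts", call. = FALSE)
  if (is.null(params_list))
    params_list <- setNames(lapply(classes, default_stutter_params), classes)
  records <- list()
  i <- 0L
  for (cl in classes) {
    p <- params_list[[cl]]
    if (is.null(p)) stop(sprintf("no parameters for class '%s'", cl),
                         call. = FALSE)
    for (n0 in lengths) for (tp in names(timepoints)) {
      t <- as.integer(timepoints[[tp]])
      i <- i + 1L
      id <- sprintf("%s_n%d_%s", cl, n0, tp)
      h <- if (mode == "noiseless") {
        hh <- predict_histogram(p, n0, t, locus_id = id)
        repeat_histogram(hh$counts * reads, repeats = hh$repeats,
                         locus_id = id)
      } else {
        cfg <- simulation_config(p, alleles = n0,
                                 initial_molecules = initial_molecules,
                                 cycles = t, efficiency = efficiency,
                                 reads = reads,
                                 seed = as.integer(seed) + 1000L * i,
                                 locus_id = id)
        sim <- simulate_pcr(cfg)
        attr(sim, "audit") <- NULL
        sim
      }
      records[[i]] <- calibration_record(cl, n0, tp, t, h)
    }
  }
  attr(records, "truth") <- params_list
  records
}

#' Write a synthetic calibration fixture to disk
#'
#' Generates a calibration dataset with [generate_calibration_dataset()] and
#' writes it as a calibration TSV plus a ground-truth JSON sidecar (the
#' generating parameters and generation settings), for use by
#' parameter-recovery harnesses. Output is byte-identical for identical
#' arguments and seed.
#'
#' @param dir output directory (created if needed).
#' @param basename file stem (default `"calibration"`).
#' @param ... arguments passed to [generate_calibration_dataset()].
#' @param seed integer seed.
#' @return Invisibly, a list with `data_path`, `truth_path` and the records.
#' @export
make_calibration_fixture <- function(dir, basename = "calibration",
                                     seed = 1L, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- generate_calibration_dataset(seed = seed, ...)
  data_path <- file.path(dir, paste0(basename, ".tsv"))
  truth_path <- file.path(dir, paste0(basename, ".truth.json"))
  write_calibration_tsv(records, data_path,
                        provenance = sprintf("strstutter synthetic calibration fixture (seed %d)",
                                             as.integer(seed)))
  truth <- attr(records, "truth")
  classes <- lapply(truth, function(p) {
    c(list(model_family = p$model_family),
      setNames(lapply(.PARAM_COEFS, function(k) p[[k]]), .PARAM_COEFS))
  })
  names(classes) <- vapply(truth, `[[`, "", "repeat_class")
  jsonlite::write_json(list(format_version = 1L, seed = as.integer(seed),
                            classes = classes),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(data_path = data_path, truth_path = truth_path,
                 records = records))
}
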