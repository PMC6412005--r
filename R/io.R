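## File formats -----------------------------------------------------------
##
## All tabular formats are UTF-8 TSV with a header row; lines starting with
## "#" are provenance/comment lines and are skipped on read. Model parameters
## travel as versioned JSON keyed by repeat class.

.read_tsv <- function(path, required) {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("cannot read '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("'%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat-number histograms from TSV
#'
#' Expects columns `locus_id`, `repeat_number`, `count` (header required;
#' rows may be unordered). Duplicate (locus, repeat) bins are summed with a
#' warning. Lines starting with `#` are ignored.
#'
#' @param path TSV file path.
#' @return A named list of [repeat_histogram()]s, one per locus.
#' @export
read_histogram_tsv <- function(path) {
  df <- .read_tsv(path, c("locus_id", "repeat_number", "count"))
  out <- lapply(split(df, df$locus_id), function(g) {
    if (anyDuplicated(g$repeat_number))
      warning(sprintf("locus '%s': duplicate repeat-number bins summed",
                      g$locus_id[1]), call. = FALSE)
    repeat_histogram(g$count, repeats = g$repeat_number,
                     locus_id = g$locus_id[1])
  })
  out[order(names(out))]
}

#' Write repeat-number histograms to TSV
#'
#' @param hists a [repeat_histogram()] or list of them.
#' @param path output file path.
#' @param provenance optional character vector of provenance lines written
#'   as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hists, path, provenance = NULL) {
  if (inherits(hists, "repeat_histogram")) hists <- list(hists)
  df <- do.call(rbind, lapply(hists, as.data.frame))
  .write_tsv(df, path, provenance)
}

.PARAM_COEFS <- c("up_slope", "up_intercept",
                  "down_slope_1", "down_intercept_1",
                  "down_slope_2", "down_intercept_2",
                  "down_slope_3", "down_intercept_3")

#' Write stutter model parameters to JSON
#'
#' The file is a JSON object with a `format_version` field and a `classes`
#' object keyed by repeat class, each entry holding `model_family` and the
#' named linear coefficients.
#'
#' @param params_list a [stutter_params()] or (possibly named) list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stutter_params <- function(params_list, path) {
  if (inherits(params_list, "stutter_params")) params_list <- list(params_list)
  classes <- lapply(params_list, function(p) {
    c(list(model_family = p$model_family),
      setNames(lapply(.PARAM_COEFS, function(k) p[[k]]), .PARAM_COEFS))
  })
  names(classes) <- vapply(params_list, `[[`, "", "repeat_class")
  jsonlite::write_json(list(format_version = 1L, classes = classes), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read stutter model parameters from JSON
#'
#' @param path a JSON file written by [write_stutter_params()].
#' @return A named list of [stutter_params()], keyed by repeat class.
#' @export
read_stutter_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1)
    stop(sprintf("'%s': unsupported or missing format_version", path),
         call. = FALSE)
  out <- lapply(names(obj$classes), function(cl) {
    e <- obj$classes[[cl]]
    do.call(stutter_params,
            c(list(repeat_class = cl,
                   model_family = e$model_family %||% "Linear1up3dw"),
              setNames(lapply(.PARAM_COEFS, function(k) e[[k]] %||% 0),
                       .PARAM_COEFS)))
  })
  names(out) <- names(obj$classes)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a calibration dataset from TSV
#'
#' Expects columns `repeat_class`, `designed_length`, `time_point`,
#' `repeat_number`, `count`. Each (class, designed length, time point) group
#' becomes one [calibration_record()]; effective cycle numbers are taken from
#' `cycles_by_timepoint`.
#'
#' @param path TSV path.
#' @param cycles_by_timepoint named integer vector mapping time-point labels
#'   to effective PCR cycle counts. Defaults to the nested-PCR protocol
#'   mapping `c(T0 = 0, T1 = 0, T2 = 17, T3 = 47)`.
#' @return A list of [calibration_record()]s.
#' @export
read_calibration_tsv <- function(path,
                                 cycles_by_timepoint = c(T0 = 0L, T1 = 0L,
                                                         T2 = 17L, T3 = 47L)) {
  df <- .read_tsv(path, c("repeat_class", "designed_length", "time_point",
                          "repeat_number", "count"))
  key <- paste(df$repeat_class, df$designed_length, df$time_point, sep = "\r")
  groups <- split(df, key)
  recs <- lapply(groups, function(g) {
    tp <- g$time_point[1]
    if (!tp %in% names(cycles_by_timepoint))
      stop(sprintf("'%s': time point '%s' absent from cycles_by_timepoint",
                   path, tp), call. = FALSE)
    h <- repeat_histogram(g$count, repeats = g$repeat_number,
                          locus_id = sprintf("%s_n%d_%s", g$repeat_class[1],
                                             g$designed_length[1], tp))
    calibration_record(repeat_class = g$repeat_class[1],
                       designed_length = g$designed_length[1],
                       time_point = tp,
                       cycles = cycles_by_timepoint[[tp]],
                       histogram = h)
  })
  names(recs) <- NULL
  ord <- order(vapply(recs, `[[`, "", "repeat_class"),
               vapply(recs, `[[`, 0, "designed_length"),
               vapply(recs, `[[`, "", "time_point"))
  recs[ord]
}

#' Write calibration records to TSV
#' @param records list of [calibration_record()]s.
#' @param path output path.
#' @param provenance optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_calibration_tsv <- function(records, path, provenance = NULL) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(repeat_class = r$repeat_class,
               designed_length = r$designed_length,
               time_point = r$time_point,
               repeat_number = r$histogram$repeats,
               count = r$histogram$counts,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(df, path, provenance)
}

#' Read a leaf-to-allele assignment table
#'
#' Two-column TSV `cell`, `allele` mapping tree leaves to called alleles.
#'
#' @param path TSV path.
#' @return Named vector (names = cells) of alleles.
#' @export
read_allele_assignment <- function(path) {
  df <- .read_tsv(path, c("cell", "allele"))
  setNames(df$allele, df$cell)
}

#' Write genotype calls to TSV
#' @param calls a data frame as returned by [genotype_histograms()] /
#'   [rank_confidence()].
#' @param path output path.
#' @param provenance optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, provenance = NULL) {
  .write_tsv(calls, path, provenance)
}

#' Read genotype calls from TSV
#' @param path a file written by [write_calls_tsv()].
#' @return A data frame of calls.
#' @export
read_calls_tsv <- function(path) {
  .read_tsv(path, c("locus_id", "allele1", "allele2", "proportion",
                    "cycles", "distance", "percentile", "status"))
}
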