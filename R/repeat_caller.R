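#' Locus definition for the repeat-number caller
#'
#' Describes one amplicon of an STR panel: the repeat unit, the designed
#' repeat count, the immediate flanking sequences (which identify the locus
#' at the read edges), and the repeat-count search range. Flanks must not
#' start or end with a partial copy of the repeat unit, otherwise the
#' repeat/flank boundary — and hence the called length — is ambiguous.
#'
#' @param locus_id locus label.
#' @param unit repeat unit sequence (e.g. `"AC"`).
#' @param designed_length designed repeat count.
#' @param left_flank,right_flank DNA strings flanking the repeat tract.
#' @param k_min,k_max inclusive repeat-count search range (default
#'   `designed_length` ± 10, floored at 1).
#' @return An object of class `locus_definition`.
#' @export
locus_definition <- function(locus_id, unit, designed_length,
                             left_flank, right_flank,
                             k_min = max(1L, designed_length - 10L),
                             k_max = designed_length + 10L) {
  unit <- toupper(unit); left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  if (!nzchar(left_flank) || !nzchar(right_flank))
    stop("flanks must be non-empty", call. = FALSE)
  if (.ends_with_partial_unit(left_flank, unit) ||
      .starts_with_partial_unit(right_flank, unit))
    stop("flanks must not begin/end with a partial or full repeat unit",
         call. = FALSE)
  if (k_min < 1 || k_min > k_max)
    stop("need 1 <= k_min <= k_max", call. = FALSE)
  structure(list(locus_id = as.character(locus_id)[1], unit = unit,
                 designed_length = as.integer(designed_length),
                 left_flank = left_flank, right_flank = right_flank,
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "locus_definition")
}

.ends_with_partial_unit <- function(flank, unit) {
  first <- substr(unit, 1, 1)
  substr(flank, nchar(flank), nchar(flank)) == first
}

.starts_with_partial_unit <- function(flank, unit) {
  last <- substr(unit, nchar(unit), nchar(unit))
  substr(flank, 1, 1) == last
}

#' Read a locus panel from TSV
#'
#' Columns: `locus_id`, `unit`, `designed_length`, `left_flank`,
#' `right_flank`, `k_min`, `k_max`.
#'
#' @param path TSV path.
#' @return List of [locus_definition()]s.
#' @export
read_locus_panel <- function(path) {
  df <- .read_tsv(path, c("locus_id", "unit", "designed_length",
                          "left_flank", "right_flank", "k_min", "k_max"))
  lapply(seq_len(nrow(df)), function(i)
    locus_definition(df$locus_id[i], df$unit[i], df$designed_length[i],
                     df$left_flank[i], df$right_flank[i],
                     df$k_min[i], df$k_max[i]))
}

.hamming_prefix <- function(read, flank, from_end = FALSE) {
  n <- nchar(flank)
  if (nchar(read) < n) return(Inf)
  seg <- if (from_end) substr(read, nchar(read) - n + 1, nchar(read))
         else substr(read, 1, n)
  sum(utf8ToInt(seg) != utf8ToInt(flank))
}

#' Match a read to a locus panel by its flanks
#'
#' A read belongs to a locus when its start matches the left flank and its
#' end matches the right flank, each within `max_mismatch` substitutions.
#' Exactly one panel hit is required; zero hits or two and more hits return
#' a no-match with a reason.
#'
#' @param read DNA string (a merged amplicon read).
#' @param panel list of [locus_definition()]s.
#' @param max_mismatch per-flank substitution budget (default 2).
#' @return The matching [locus_definition()], or an object of class
#'   `no_match` whose `reason` field is `"no_hit"` or `"ambiguous"`.
#' @export
match_locus <- function(read, panel, max_mismatch = 2L) {
  read <- toupper(read)
  hits <- which(vapply(panel, function(lc) {
    nchar(read) > nchar(lc$left_flank) + nchar(lc$right_flank) &&
      .hamming_prefix(read, lc$left_flank) <= max_mismatch &&
      .hamming_prefix(read, lc$right_flank, from_end = TRUE) <= max_mismatch
  }, logical(1)))
  if (length(hits) == 1L) return(panel[[hits]])
  structure(list(reason = if (length(hits)) "ambiguous" else "no_hit"),
            class = "no_match")
}

#' Call the repeat number of a read by best-scoring reference
#'
#' Builds, for every candidate repeat count `k` in the locus's search range,
#' the reference `left_flank + unit^k + right_flank`, globally aligns the
#' read against each (match +1, mismatch -1, gap -2), and returns the `k`
#' with the highest alignment score. Ties break toward the `k` nearest the
#' designed length, then the smaller `k`. Reads whose best score falls below
#' `min_score_frac * nchar(read)` are no-calls.
#'
#' @param read DNA string.
#' @param locus a [locus_definition()].
#' @param min_score_frac no-call floor as a fraction of read length
#'   (default 0.6).
#' @return List with `repeat_number` (NA on no-call) and `score`.
#' @export
call_repeat_number <- function(read, locus, min_score_frac = 0.6) {
  read <- toupper(read)
  ks <- locus$k_min:locus$k_max
  refs <- paste0(locus$left_flank, strrep(locus$unit, ks), locus$right_flank)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs),
    subject = Biostrings::DNAString(read),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
  best <- max(scores)
  if (best < min_score_frac * nchar(read))
    return(list(repeat_number = NA_integer_, score = best))
  cand <- ks[scores == best]
  cand <- cand[order(abs(cand - locus$designed_length), cand)]
  list(repeat_number = cand[1], score = best)
}

#' Aggregate reads into per-locus repeat-number histograms
#'
#' Matches each read to the panel, calls its repeat number, and counts calls
#' per (locus, repeat number). Unmatched, ambiguous and uncallable reads are
#' tallied in a QC report. The result is independent of read order.
#'
#' @param reads character vector of read sequences, or a FASTA/FASTQ path
#'   (plain or gzipped; read via `Biostrings`).
#' @param panel list of [locus_definition()]s.
#' @param max_mismatch per-flank substitution budget for locus matching.
#' @param min_score_frac no-call floor, see [call_repeat_number()].
#' @return List with `histograms` (named list of [repeat_histogram()]s, one
#'   per locus with at least one call) and `qc` (counts: `total`, `matched`,
#'   `no_hit`, `ambiguous`, `no_call`, `called`).
#' @export
reads_to_histograms <- function(reads, panel, max_mismatch = 2L,
                                min_score_frac = 0.6) {
  if (length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  qc <- c(total = length(reads), matched = 0L, no_hit = 0L, ambiguous = 0L,
          no_call = 0L, called = 0L)
  tallies <- list()
  for (rd in reads) {
    lc <- match_locus(rd, panel, max_mismatch)
    if (inherits(lc, "no_match")) {
      qc[lc$reason] <- qc[lc$reason] + 1L
      next
    }
    qc["matched"] <- qc["matched"] + 1L
    call <- call_repeat_number(rd, lc, min_score_frac)
    if (is.na(call$repeat_number)) {
      qc["no_call"] <- qc["no_call"] + 1L
      next
    }
    qc["called"] <- qc["called"] + 1L
    key <- lc$locus_id
    kk <- as.character(call$repeat_number)
    if (is.null(tallies[[key]])) tallies[[key]] <- integer(0)
    tallies[[key]][kk] <- (if (kk %in% names(tallies[[key]]))
      tallies[[key]][[kk]] else 0L) + 1L
  }
  hists <- lapply(names(tallies), function(id)
    repeat_histogram(as.numeric(tallies[[id]]),
                     repeats = as.integer(names(tallies[[id]])),
                     locus_id = id))
  names(hists) <- names(tallies)
  if (length(hists)) hists <- hists[order(names(hists))]
  list(histograms = hists, qc = as.list(qc))
}
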