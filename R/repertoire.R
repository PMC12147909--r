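#' Construct a TCR repertoire
#'
#' A repertoire is a tibble of clonotypes for one sample, one row per clone,
#' carrying sample metadata as attributes. Clones are keyed by the CDR3
#' nucleotide sequence (`cdr3_nt`); rows sharing a key are merged by summing
#' read counts, keeping the majority V/J call. Clone frequencies are
#' recomputed from read counts so they always sum to 1.
#'
#' @param clones A data frame with at least `cdr3_nt` and `read_count`.
#'   Optional columns: `cdr3_aa`, `v_call`, `j_call`, `productive`. Missing
#'   amino-acid sequences are translated from `cdr3_nt`; missing productivity
#'   flags are inferred (in-frame, no stop codon).
#' @param sample_id,patient_id Sample and patient identifiers.
#' @param compartment `"blood"` or `"tumor"`.
#' @param timepoint Timepoint label (e.g. `"baseline"`, `"post_chemo"`).
#' @param merge_duplicates Merge rows sharing a `cdr3_nt` key (default `TRUE`).
#'
#' @return A `tcr_repertoire`: a tibble with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_call`, `j_call`, `read_count`, `frequency`, `productive`, sorted by
#'   decreasing frequency (ties by key), with metadata attributes.
#' @examples
#' rep <- tcr_repertoire(
#'   data.frame(cdr3_nt = c("TGTGCTTTT", "TGTTGGTTC"), read_count = c(60, 40)),
#'   sample_id = "s1", patient_id = "p1"
#' )
#' rep$frequency # 0.6, 0.4
#' @export
tcr_repertoire <- function(clones, sample_id, patient_id = NA_character_,
                           compartment = c("blood", "tumor"),
                           timepoint = "baseline",
                           merge_duplicates = TRUE) {
  compartment <- match.arg(compartment)
  if (!is.data.frame(clones) || nrow(clones) == 0L) {
    abort("`clones` must be a data frame with at least one row.",
          class = "clonotrace_empty_repertoire")
  }
  for (col in c("cdr3_nt", "read_count")) {
    if (!col %in% names(clones)) {
      abort(sprintf("`clones` lacks required column '%s'.", col),
            class = "clonotrace_format_error")
    }
  }
  x <- as_tibble(clones)
  x$cdr3_nt <- toupper(as.character(x$cdr3_nt))
  bad <- !nzchar(x$cdr3_nt) | grepl("[^ACGT]", x$cdr3_nt)
  if (any(bad)) {
    abort(sprintf("%d clone(s) have an empty or non-ACGT `cdr3_nt`.", sum(bad)))
  }
  if (any(is.na(x$read_count) | x$read_count < 0)) {
    abort("`read_count` must be non-negative and non-missing.")
  }
  if (!"cdr3_aa" %in% names(x)) x$cdr3_aa <- translate_nt(x$cdr3_nt)
  if (!"v_call" %in% names(x)) x$v_call <- ""
  if (!"j_call" %in% names(x)) x$j_call <- ""
  x$v_call <- dplyr::coalesce(as.character(x$v_call), "")
  x$j_call <- dplyr::coalesce(as.character(x$j_call), "")
  if (!"productive" %in% names(x)) {
    x$productive <- infer_productive(x$cdr3_nt, x$cdr3_aa)
  }
  x$cdr3_aa <- dplyr::coalesce(as.character(x$cdr3_aa), "")

  x <- x[, c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "read_count", "productive")]
  if (merge_duplicates && anyDuplicated(x$cdr3_nt)) {
    x <- x |>
      group_by(.data$cdr3_nt) |>
      summarise(
        cdr3_aa = majority_call(.data$cdr3_aa, .data$read_count),
        v_call = majority_call(.data$v_call, .data$read_count),
        j_call = majority_call(.data$j_call, .data$read_count),
        read_count = sum(.data$read_count),
        productive = any(.data$productive),
        .groups = "drop"
      )
  }
  total <- sum(x$read_count)
  if (total <= 0) abort("Total read count is zero; cannot compute frequencies.")
  x$frequency <- x$read_count / total
  x <- x[order(-x$frequency, x$cdr3_nt), c("cdr3_nt", "cdr3_aa", "v_call",
                                           "j_call", "read_count", "frequency",
                                           "productive")]
  new_tcr_repertoire(x, sample_id = as.character(sample_id),
                     patient_id = as.character(patient_id),
                     compartment = compartment,
                     timepoint = as.character(timepoint))
}

# weighted majority vote with deterministic lexicographic tie-break
majority_call <- function(values, weights) {
  tab <- tapply(weights, values, sum)
  names(tab)[order(-tab, names(tab))][1]
}

new_tcr_repertoire <- function(x, sample_id, patient_id, compartment, timepoint) {
  structure(
    x,
    sample_id = sample_id, patient_id = patient_id,
    compartment = compartment, timepoint = timepoint,
    class = c("tcr_repertoire", class(tibble())))
}

#' Test or coerce to a TCR repertoire
#'
#' `as_tcr_repertoire()` accepts a `tcr_repertoire` unchanged, or any data
#' frame with `cdr3_nt` and `read_count` columns (constructed with default
#' metadata). Analysis functions use it so plain tibbles flow through pipes.
#'
#' @param x A `tcr_repertoire` or data frame.
#' @param ... Passed to [tcr_repertoire()] when coercing.
#' @return A `tcr_repertoire`.
#' @export
as_tcr_repertoire <- function(x, ...) {
  if (is_tcr_repertoire(x)) return(x)
  if (is.data.frame(x)) {
    dots <- list(...)
    if (is.null(dots$sample_id)) dots$sample_id <- "sample"
    return(do.call(tcr_repertoire, c(list(clones = x), dots)))
  }
  abort("Cannot coerce object to a `tcr_repertoire`.")
}

#' @rdname as_tcr_repertoire
#' @export
is_tcr_repertoire <- function(x) inherits(x, "tcr_repertoire")

#' Repertoire metadata
#'
#' @param x A `tcr_repertoire`.
#' @return One-row tibble with `sample_id`, `patient_id`, `compartment`,
#'   `timepoint`, and `n_clones`.
#' @export
rep_meta <- function(x) {
  stopifnot(is_tcr_repertoire(x))
  tibble(
    sample_id = attr(x, "sample_id"),
    patient_id = attr(x, "patient_id"),
    compartment = attr(x, "compartment"),
    timepoint = attr(x, "timepoint"),
    n_clones = nrow(x)
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  meta <- rep_meta(x)
  cat(sprintf("<tcr_repertoire> sample %s (patient %s, %s, %s): %d clones\n",
              meta$sample_id, meta$patient_id, meta$compartment,
              meta$timepoint, meta$n_clones))
  NextMethod()
}

# frequencies of a repertoire-like input, validated to sum to 1
rep_frequencies <- function(x, tol = 1e-6) {
  f <- if (is.numeric(x)) x else {
    if (!is.data.frame(x) || !"frequency" %in% names(x)) {
      abort("Input must be numeric frequencies or a data frame with a `frequency` column.")
    }
    x$frequency
  }
  if (length(f) == 0L) abort("No clones present.",
                             class = "clonotrace_empty_repertoire")
  if (any(f < 0 | f > 1)) abort("Frequencies must lie in [0, 1].")
  if (abs(sum(f) - 1) > tol) {
    abort(sprintf("Frequencies sum to %.6f, not 1; renormalize first.", sum(f)))
  }
  f
}

#' Group repertoires into a longitudinal patient series
#'
#' @param reps List of `tcr_repertoire` objects from the same patient and
#'   compartment, in increasing timepoint order (the list order is taken as
#'   the temporal order; timepoint labels must be distinct).
#' @return A `patient_series` (the validated list, with `patient_id` attribute).
#' @export
patient_series <- function(reps) {
  if (is_tcr_repertoire(reps)) reps <- list(reps)
  if (!length(reps) || !all(vapply(reps, is_tcr_repertoire, logical(1)))) {
    abort("`reps` must be a non-empty list of `tcr_repertoire` objects.")
  }
  pid <- unique(vapply(reps, attr, character(1), "patient_id"))
  if (length(pid) != 1L) abort("All repertoires must share one `patient_id`.")
  tps <- vapply(reps, attr, character(1), "timepoint")
  if (anyDuplicated(tps)) abort("Timepoint labels must be distinct within a series.")
  structure(reps, patient_id = pid, timepoints = tps, class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> patient %s: %d timepoints (%s)\n",
              attr(x, "patient_id"), length(x),
              paste(attr(x, "timepoints"), collapse = ", ")))
  invisible(x)
}
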