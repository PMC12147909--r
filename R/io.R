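#' Read an AIRR Rearrangement clone table
#'
#' Reads a tab-separated file following the AIRR Rearrangement schema column
#' names (`junction`, `junction_aa`, `v_call`, `j_call`, `duplicate_count`,
#' `productive`) into a [tcr_repertoire()]. Rows sharing a `junction`
#' nucleotide sequence are merged by summing `duplicate_count`; frequencies
#' are recomputed from the merged counts.
#'
#' @param path Path to a TSV file with a header row.
#' @param sample_id,patient_id,compartment,timepoint Sample metadata; by
#'   default `sample_id` is the file name without extension.
#' @return A `tcr_repertoire`.
#' @export
read_airr <- function(path, sample_id = NULL, patient_id = NA_character_,
                      compartment = "blood", timepoint = "baseline") {
  x <- read_clone_tsv(path, required = c("junction", "junction_aa", "v_call",
                                         "j_call", "duplicate_count",
                                         "productive"))
  clones <- tibble(
    cdr3_nt = toupper(as.character(x$junction)),
    cdr3_aa = as.character(x$junction_aa),
    v_call = as.character(x$v_call),
    j_call = as.character(x$j_call),
    read_count = as.numeric(x$duplicate_count),
    productive = parse_airr_logical(x$productive)
  )
  tcr_repertoire(clones,
                 sample_id = sample_id %||% strip_ext(path),
                 patient_id = patient_id, compartment = compartment,
                 timepoint = timepoint)
}

#' Read a MiXCR-style clone table
#'
#' Reads the MiXCR clone-table export dialect (`cloneCount`, `cloneFraction`,
#' `nSeqCDR3`, `aaSeqCDR3`, plus V/J hit columns). Productivity is inferred
#' from the amino-acid sequence: a stop symbol `*`, a frameshift symbol `_`,
#' or an amino-acid length inconsistent with the nucleotide length marks the
#' clone non-productive. Frequencies are recomputed from read counts after
#' merging rows sharing a nucleotide sequence, so repertoires read from
#' equivalent AIRR and MiXCR files are identical.
#'
#' @inheritParams read_airr
#' @return A `tcr_repertoire`.
#' @export
read_mixcr <- function(path, sample_id = NULL, patient_id = NA_character_,
                       compartment = "blood", timepoint = "baseline") {
  x <- read_clone_tsv(path, required = c("cloneCount", "cloneFraction",
                                         "nSeqCDR3", "aaSeqCDR3"))
  v <- mixcr_best_hit(x, c("bestVHit", "allVHitsWithScore", "vHit"))
  j <- mixcr_best_hit(x, c("bestJHit", "allJHitsWithScore", "jHit"))
  nt <- toupper(as.character(x$nSeqCDR3))
  aa <- as.character(x$aaSeqCDR3)
  clones <- tibble(
    cdr3_nt = nt,
    cdr3_aa = aa,
    v_call = v,
    j_call = j,
    read_count = as.numeric(x$cloneCount),
    productive = infer_productive(nt, aa)
  )
  tcr_repertoire(clones,
                 sample_id = sample_id %||% strip_ext(path),
                 patient_id = patient_id, compartment = compartment,
                 timepoint = timepoint)
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: `read_airr(write_airr(rep, f))` reproduces the
#' clone keys, read counts, and frequencies exactly.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  rep <- as_tcr_repertoire(rep)
  out <- tibble(
    junction = rep$cdr3_nt,
    junction_aa = rep$cdr3_aa,
    v_call = rep$v_call,
    j_call = rep$j_call,
    duplicate_count = rep$read_count,
    productive = ifelse(rep$productive, "T", "F")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a VDJdb-style reference table of CDR3-antigen pairs
#'
#' Expects columns `cdr3`, `antigen.epitope`, `antigen.species`, and
#' `vdjdb.score`. Pairs with a confidence score below `min_score` are
#' dropped (the default keeps scores above zero) and duplicated
#' (sequence, epitope) pairs are collapsed to one row.
#'
#' @param path Path to a TSV file.
#' @param min_score Minimum confidence score retained (default 1).
#' @return Tibble with `cdr3_aa`, `antigen_epitope`, `antigen_species`, `score`.
#' @export
read_reference_pairs <- function(path, min_score = 1) {
  x <- read_clone_tsv(path,
                      required = c("cdr3", "antigen.epitope", "antigen.species",
                                   "vdjdb.score"),
                      allow_empty = TRUE)
  out <- tibble(
    cdr3_aa = as.character(x$cdr3),
    antigen_epitope = as.character(x$antigen.epitope),
    antigen_species = as.character(x$antigen.species),
    score = as.integer(x$vdjdb.score)
  ) |>
    filter(.data$score >= min_score) |>
    distinct(.data$cdr3_aa, .data$antigen_epitope, .keep_all = TRUE)
  if (nrow(out) == 0L) warn("Reference table contains no retained pairs.")
  out
}

#' Read a sample manifest
#'
#' A CSV with columns `sample_id`, `patient_id`, `compartment`, `timepoint`,
#' `path`. The (patient, compartment, timepoint) triple must be unique.
#'
#' @param path Path to the manifest CSV.
#' @return Tibble of manifest rows.
#' @export
read_manifest <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "patient_id", "compartment", "timepoint", "path")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("Manifest lacks column(s): %s.", paste(missing, collapse = ", ")),
          class = "clonotrace_format_error")
  }
  key <- paste(x$patient_id, x$compartment, x$timepoint)
  if (anyDuplicated(key)) {
    abort("Manifest has duplicated (patient_id, compartment, timepoint) rows.")
  }
  as_tibble(x[, need])
}

# ---- internal reader helpers -------------------------------------------------

read_clone_tsv <- function(path, required, allow_empty = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("File %s lacks required column(s): %s.",
                  basename(path), paste(missing, collapse = ", ")),
          class = "clonotrace_format_error")
  }
  if (nrow(x) == 0L && !allow_empty) {
    abort(sprintf("File %s contains no clone rows.", basename(path)),
          class = "clonotrace_empty_repertoire")
  }
  x
}

parse_airr_logical <- function(x) {
  if (is.logical(x)) return(x)
  toupper(trimws(as.character(x))) %in% c("T", "TRUE", "1", "YES")
}

mixcr_best_hit <- function(x, candidates) {
  col <- intersect(candidates, names(x))
  if (!length(col)) return(rep("", nrow(x)))
  raw <- as.character(x[[col[1]]])
  # "TRBV9*00(1234.5),TRBV6-1*00(12)" -> "TRBV9"
  vapply(raw, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    first <- strsplit(s, ",", fixed = TRUE)[[1]][1]
    sub("[(*].*$", "", first)
  }, character(1), USE.NAMES = FALSE)
}

strip_ext <- function(path) sub("\\.[^.]*$", "", basename(path))
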