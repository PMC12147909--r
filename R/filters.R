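#' Filter a repertoire by read support and productivity
#'
#' Removes clones with fewer than `min_reads` reads (strictly less than: a
#' clone at exactly `min_reads` is kept) and, by default, clones whose CDR3
#' is non-productive (out of frame or containing a stop codon). Very
#' low-read clones are dominated by sequencing artifacts of abnormal length
#' and frequent frameshifts, which motivates the default 50-read cutoff.
#' Frequencies are recomputed from the surviving read counts so they sum to
#' 1; set `renormalize = FALSE` to keep the pre-filter frequencies for
#' sensitivity checks.
#'
#' @param rep A `tcr_repertoire` (or coercible data frame).
#' @param min_reads Minimum read count retained (default 50).
#' @param productive_only Drop non-productive clones (default `TRUE`).
#' @param renormalize Recompute frequencies over survivors (default `TRUE`).
#' @return A filtered `tcr_repertoire`.
#' @examples
#' rep <- tcr_repertoire(
#'   data.frame(cdr3_nt = c("TGTGCTTTT", "TGTTGGTTC", "TGTAAATTC"),
#'              read_count = c(60, 50, 49)),
#'   sample_id = "s1"
#' )
#' nrow(filter_clones(rep)) # 2: the 49-read clone is removed, 50 is kept
#' @export
filter_clones <- function(rep, min_reads = 50, productive_only = TRUE,
                          renormalize = TRUE) {
  rep <- as_tcr_repertoire(rep)
  keep <- rep$read_count >= min_reads
  if (productive_only) keep <- keep & rep$productive
  if (!any(keep)) {
    abort("All clones removed by filtering; sample is unusable.",
          class = "clonotrace_empty_repertoire")
  }
  out <- rep[keep, , drop = FALSE]
  if (renormalize) out$frequency <- out$read_count / sum(out$read_count)
  new_tcr_repertoire(as_tibble(out),
                     sample_id = attr(rep, "sample_id"),
                     patient_id = attr(rep, "patient_id"),
                     compartment = attr(rep, "compartment"),
                     timepoint = attr(rep, "timepoint"))
}
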