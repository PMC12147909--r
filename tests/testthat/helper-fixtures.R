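# in-code fixtures: small repertoires and clone-table files built on the fly

`%or%` <- function(a, b) if (is.null(a)) b else a

# valid in-frame C...F keys for constructing clone sets by hand
key_pool <- function(n) {
  cods <- c("GCT", "GGA", "CAT", "AAA", "TGG", "CAA", "GAA", "TAT", "AGA",
            "CTG", "ATC", "TCA", "GTT", "CCG", "ACA", "AAC")
  if (n <= length(cods)^2) {
    grid <- expand.grid(a = cods, b = cods, stringsAsFactors = FALSE)
    return(paste0("TGT", grid$a[seq_len(n)], grid$b[seq_len(n)], "TTT"))
  }
  stopifnot(n <= length(cods)^3)
  grid <- expand.grid(a = cods, b = cods, c = cods, stringsAsFactors = FALSE)
  paste0("TGT", grid$a[seq_len(n)], grid$b[seq_len(n)], grid$c[seq_len(n)], "TTT")
}

# repertoire with given read counts (all productive, in-frame sequences)
make_rep <- function(counts, sample_id = "s1", patient_id = "p1",
                     timepoint = "baseline", compartment = "blood",
                     keys = NULL) {
  nt <- keys %or% key_pool(length(counts))
  tcr_repertoire(
    data.frame(cdr3_nt = nt, read_count = counts),
    sample_id = sample_id, patient_id = patient_id,
    compartment = compartment, timepoint = timepoint
  )
}

# repertoire with explicit frequencies (scaled to integer counts)
make_rep_freq <- function(freqs, total = 1e6, ...) {
  make_rep(round(freqs * total), ...)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

airr_row <- function(junction, count, aa = NULL, productive = "T",
                     v = "TRBV9", j = "TRBJ1-1") {
  data.frame(junction = junction,
             junction_aa = aa %or% strrep("A", nchar(junction) / 3),
             v_call = v, j_call = j,
             duplicate_count = count, productive = productive)
}

mixcr_row <- function(nt, count, fraction, aa, v = "TRBV9*00(100)",
                      j = "TRBJ1-1*00(90)") {
  data.frame(cloneCount = count, cloneFraction = fraction,
             nSeqCDR3 = nt, aaSeqCDR3 = aa,
             bestVHit = v, bestJHit = j)
}

# small patient series: clone presence given as a list of key vectors
make_series <- function(presence, patient_id = "p1", counts = NULL) {
  tps <- paste0("t", seq_along(presence))
  reps <- lapply(seq_along(presence), function(i) {
    keys <- presence[[i]]
    cts <- if (is.null(counts)) rep(100, length(keys)) else counts[[i]]
    tcr_repertoire(
      data.frame(cdr3_nt = keys, read_count = cts),
      sample_id = paste0(patient_id, "_", tps[i]),
      patient_id = patient_id, timepoint = tps[i]
    )
  })
  patient_series(reps)
}

# independent two-sided minlike binomial p-value: plain enumeration with the
# pure <= rule (no relative guard); oracle for the implementation
binom_enum_oracle <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1]])
}
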