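# internal helpers shared across modules

# standard genetic code, nucleotide triplet -> single-letter amino acid
# ('*' = stop). Kept internal; only complete in-frame codons are translated.
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# translate in-frame nucleotide strings; sequences whose length is not a
# multiple of 3 get NA (frameshift, handled by productivity inference)
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return(NA_character_)
    codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    aa <- .codon_table[codons]
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# productivity: in-frame, translatable, no stop codon, aa consistent with nt
infer_productive <- function(cdr3_nt, cdr3_aa = NULL) {
  aa <- translate_nt(cdr3_nt)
  ok <- !is.na(aa) & !grepl("*", aa, fixed = TRUE)
  if (!is.null(cdr3_aa)) {
    given <- !is.na(cdr3_aa) & nzchar(cdr3_aa)
    # a declared aa with stop or frameshift marker is non-productive
    ok[given] <- ok[given] &
      !grepl("[*_]", cdr3_aa[given]) &
      nchar(cdr3_aa[given]) * 3L == nchar(cdr3_nt[given])
  }
  ok
}

# round half away from zero (frequencies are non-negative here, so this is
# round-half-up); documented convention for observed counts in the
# binomial sharing test
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number strictly between 0 and 1.", name))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
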