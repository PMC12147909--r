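# readers, clone canonicalization, and the read-support/productivity filter

test_that("AIRR reader merges rows sharing a junction and recomputes frequencies", {
  keys <- key_pool(2)
  f <- write_tsv_fixture(rbind(
    airr_row(keys[1], 40), airr_row(keys[2], 30), airr_row(keys[1], 20)
  ))
  rep <- read_airr(f)
  expect_s3_class(rep, "tcr_repertoire")
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$read_count[rep$cdr3_nt == keys[1]], 60)
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-12)

  f1 <- write_tsv_fixture(airr_row(keys[1], 100))
  one <- read_airr(f1)
  expect_equal(nrow(one), 1L)
  expect_identical(one$frequency, 1)
})

test_that("AIRR reader fails with a named format error on missing columns and empty files", {
  bad <- write_tsv_fixture(data.frame(junction_aa = "CAAF", v_call = "TRBV9",
                                      j_call = "TRBJ1", duplicate_count = 1,
                                      productive = "T"))
  expect_error(read_airr(bad), "junction", class = "clonotrace_format_error")
  empty <- write_tsv_fixture(airr_row(key_pool(1), 10)[0, ])
  expect_error(read_airr(empty), class = "clonotrace_empty_repertoire")
})

test_that("MiXCR reader infers productivity from the amino-acid sequence", {
  nt <- key_pool(3)
  f <- write_tsv_fixture(rbind(
    mixcr_row(nt[1], 50, 0.5, "CAA*F"),                  # stop symbol
    mixcr_row(substr(nt[2], 1, 10), 30, 0.3, "CAA_F"),   # frameshift
    mixcr_row(nt[3], 20, 0.2, "CHAF")
  ))
  rep <- read_mixcr(f)
  expect_equal(sum(rep$productive), 1L)
  expect_false(rep$productive[rep$cdr3_nt == nt[1]])
  expect_false(rep$productive[rep$cdr3_nt == toupper(substr(nt[2], 1, 10))])
})

test_that("the same clone set in AIRR and MiXCR dialects yields equal repertoires", {
  keys <- key_pool(3)
  counts <- c(500, 300, 200)
  aa <- vapply(keys, function(k) {
    paste(vapply(seq(1, nchar(k), 3), function(i) {
      c(TGT = "C", GCT = "A", GGA = "G", CAT = "H", AAA = "K", TTT = "F",
        TGG = "W", CAA = "Q", GAA = "E", TAT = "Y", AGA = "R", CTG = "L",
        ATC = "I", TCA = "S", GTT = "V", CCG = "P", ACA = "T",
        AAC = "N")[substr(k, i, i + 2)]
    }, character(1)), collapse = "")
  }, character(1))
  fa <- write_tsv_fixture(do.call(rbind, Map(function(k, c, a) {
    airr_row(k, c, aa = a, v = "TRBV9", j = "TRBJ1-1")
  }, keys, counts, aa)))
  fm <- write_tsv_fixture(do.call(rbind, Map(function(k, c, a) {
    mixcr_row(k, c, c / 1000, a)
  }, keys, counts, aa)))
  ra <- read_airr(fa, sample_id = "s")
  rm_ <- read_mixcr(fm, sample_id = "s")
  expect_identical(as.data.frame(ra), as.data.frame(rm_))
})

test_that("write_airr round-trips keys, counts, and frequencies bit-identically", {
  rep <- make_rep(c(123, 45, 6789, 50))
  path <- tempfile(fileext = ".tsv")
  rt <- read_airr(write_airr(rep, path), sample_id = attr(rep, "sample_id"))
  expect_identical(rt$cdr3_nt, rep$cdr3_nt)
  expect_identical(rt$read_count, as.numeric(rep$read_count))
  expect_identical(rt$frequency, rep$frequency)
  expect_identical(rt$productive, rep$productive)
})

test_that("the read filter is strict at the threshold and renormalizes survivors", {
  rep <- make_rep(c(60, 50, 49))
  kept <- filter_clones(rep)
  expect_equal(sort(kept$read_count), c(50, 60))
  expect_equal(sum(kept$frequency), 1, tolerance = 1e-12)
  expect_true(min(kept$read_count) >= 50)

  # already clean: filtering is the identity apart from renormalization
  clean <- make_rep(c(600, 500))
  expect_equal(as.data.frame(filter_clones(clean)), as.data.frame(clean))
})

test_that("non-productive clones are removed and frequencies renormalized", {
  keys <- key_pool(2)
  stopped <- paste0(substr(keys[2], 1, 3), "TAA", substr(keys[2], 7, nchar(keys[2])))
  rep <- tcr_repertoire(
    data.frame(cdr3_nt = c(keys[1], stopped), read_count = c(60, 70)),
    sample_id = "s1"
  )
  expect_false(rep$productive[rep$cdr3_nt == stopped])
  kept <- filter_clones(rep)
  expect_equal(nrow(kept), 1L)
  expect_identical(kept$frequency, 1)
  expect_error(filter_clones(rep, min_reads = 1000),
               class = "clonotrace_empty_repertoire")
})

test_that("reference pairs keep only positive-score, deduplicated entries", {
  f <- write_tsv_fixture(data.frame(
    cdr3 = c("CASSA", "CASSB", "CASSC", "CASSB"),
    antigen.epitope = c("E1", "E2", "E3", "E2"),
    antigen.species = c("CMV", "EBV", "CMV", "EBV"),
    vdjdb.score = c(0, 1, 2, 1)
  ))
  pairs <- read_reference_pairs(f)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$cdr3_aa, c("CASSB", "CASSC"))

  fe <- write_tsv_fixture(data.frame(cdr3 = character(),
                                     antigen.epitope = character(),
                                     antigen.species = character(),
                                     vdjdb.score = integer()))
  expect_warning(empty <- read_reference_pairs(fe), "no retained pairs")
  expect_equal(nrow(empty), 0L)

  fb <- write_tsv_fixture(data.frame(cdr3 = "CASSA", vdjdb.score = 1))
  expect_error(read_reference_pairs(fb), class = "clonotrace_format_error")
})

test_that("records differing only in V call merge with counts summed and majority call", {
  keys <- key_pool(1)
  rep <- tcr_repertoire(
    data.frame(cdr3_nt = rep(keys, 3), read_count = c(50, 30, 40),
               v_call = c("TRBV5", "TRBV5", "TRBV9")),
    sample_id = "s1"
  )
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$read_count, 120)
  expect_equal(rep$v_call, "TRBV5")
})

test_that("manifest reading enforces required columns and unique sample triples", {
  m <- data.frame(sample_id = c("a", "b"), patient_id = "p1",
                  compartment = "blood", timepoint = c("baseline", "baseline"),
                  path = c("x.tsv", "y.tsv"))
  f <- tempfile(fileext = ".csv")
  readr::write_csv(m, f, progress = FALSE)
  expect_error(read_manifest(f), "duplicated")
  m$timepoint <- c("baseline", "post_chemo")
  readr::write_csv(m, f, progress = FALSE)
  expect_equal(nrow(read_manifest(f)), 2L)
})
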