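# motif extraction, clustering, two-step annotation, expansion association

test_that("interior motifs trim three residues from each end", {
  expect_setequal(extract_motifs("CASSLGQAYEQYF", k = 3),
                  c("SLG", "LGQ", "GQA", "QAY", "AYE"))
  expect_identical(extract_motifs(strrep("A", 25), k = 3), character())
  expect_identical(extract_motifs("CASLGQYF", k = 2), "LG")
  # length exactly k + 6: a single motif
  expect_identical(extract_motifs("CASLGQYFW", k = 3), "LGQ")
  expect_identical(extract_motifs("CASYF", k = 3), character())
})

test_that("local clusters require fold enrichment over background and min count", {
  clones <- tibble::tibble(
    cdr3_aa = c(sprintf("CAS%sQRSTA%sYF", LETTERS[1:5], LETTERS[1:5]),
                sprintf("CAT%sWNP%sGMYF", LETTERS[1:4], LETTERS[5:8])),
    patient_id = rep(c("p1", "p2", "p3"), 3),
    v_call = "TRBV9"
  )
  # background containing QRST at the same frequency as the sample: gated out
  bg_hot <- tibble::tibble(motif = "QRST", freq = 0.6)
  attr(bg_hot, "pseudo") <- 1e-6
  cl_hot <- build_clusters(clones, background = bg_hot, k = 4)
  expect_false("L4:QRST" %in% cl_hot$cluster_id)
  # background lacking the motif: pseudocount makes it strongly enriched
  bg_cold <- tibble::tibble(motif = "ZZZZ", freq = 0.5)
  attr(bg_cold, "pseudo") <- 1e-6
  cl_cold <- build_clusters(clones, background = bg_cold, k = 4)
  expect_true("L4:QRST" %in% cl_cold$cluster_id)
  qrst <- cl_cold[cl_cold$cluster_id == "L4:QRST", ]
  expect_equal(qrst$n_unique_seqs, 5L)
  expect_equal(qrst$n_patients, 3L)
})

test_that("identical and Hamming-1 sequences form global clusters", {
  clones <- tibble::tibble(
    cdr3_aa = c("CASSLGQAYEQYF", "CASSLGQAYEQYF", "CASSLGQAYEGYF",
                "CATTWNPKGMYFA"),
    patient_id = c("p1", "p2", "p3", "p4")
  )
  bg <- tibble::tibble(motif = character(), freq = numeric())
  attr(bg, "pseudo") <- 1  # no local clusters possible
  cl <- build_clusters(clones, background = bg, k = 4)
  glob <- cl[cl$type == "global", ]
  # identical sequences (p1, p2) share a cluster; the Hamming-1 pair
  # (CASSLGQAYEQYF / CASSLGQAYEGYF) shares another
  same_cluster <- vapply(glob$members, function(m) {
    all(c("p1", "p2") %in% m$patient_id) && length(unique(m$cdr3_aa)) == 1L
  }, logical(1))
  expect_true(any(same_cluster))
  ham1 <- vapply(glob$members, function(m) {
    setequal(unique(m$cdr3_aa), c("CASSLGQAYEQYF", "CASSLGQAYEGYF"))
  }, logical(1))
  expect_true(any(ham1))
  expect_false(any(vapply(glob$members, function(m) "CATTWNPKGMYFA" %in% m$cdr3_aa,
                          logical(1))))
})

test_that("high-confidence filtering enforces sizes, patients, and V bias", {
  mk_cluster <- function(n_seq, n_pat, v) {
    tibble::tibble(
      cluster_id = "L4:TEST", type = "local", motif = "TEST",
      n_unique_seqs = n_seq, n_patients = n_pat, n_reference = 0L,
      members = list(tibble::tibble(
        clone_key = paste0("c", seq_len(n_seq)),
        cdr3_aa = paste0("CASS", seq_len(n_seq), "TESTYF"),
        patient_id = rep_len(paste0("p", seq_len(n_pat)), n_seq),
        v_call = v, is_reference = FALSE
      ))
    )
  }
  vbg <- c(TRBV9 = 0.05, TRBV5 = 0.95)
  # 3 seqs, 3 patients, modal V 3/3 against background 0.05: retained
  keep <- filter_high_confidence(mk_cluster(3, 3, "TRBV9"), v_background = vbg)
  expect_equal(nrow(keep), 1L)
  # binomial tail oracle: P(X >= 3), X ~ Bin(3, 0.05)
  expect_equal(keep$v_bias_p, 0.05^3, tolerance = 1e-12)
  # 5 seqs from 2 patients: removed
  expect_equal(nrow(filter_high_confidence(mk_cluster(5, 2, "TRBV9"),
                                           v_background = vbg)), 0L)
  # 2 seqs: removed
  expect_equal(nrow(filter_high_confidence(mk_cluster(2, 2, "TRBV9"),
                                           v_background = vbg)), 0L)
  # common V gene: no bias, removed
  expect_equal(nrow(filter_high_confidence(mk_cluster(3, 3, "TRBV5"),
                                           v_background = vbg)), 0L)
})

test_that("two-step annotation assigns the most common named antigen", {
  sim <- simulate_reference_and_motifs(sim_config(
    seed = 95, n_background_clones = 300, planted_motifs = 2,
    planted_group_size = 6, n_reference_decoys = 10
  ))
  ann <- annotate_two_step(sim$clones, sim$reference)
  planted <- sim$truth
  for (i in seq_len(nrow(planted))) {
    cid <- paste0("L4:", planted$motif[i])
    hit <- ann$clusters[ann$clusters$cluster_id == cid, ]
    expect_equal(nrow(hit), 1L)
    expect_identical(hit$inferred_antigen, planted$antigen[i])
  }
  # every annotated clone carries exactly one antigen
  expect_false(anyDuplicated(ann$clones$clone_key) > 0)

  # no reference: zero annotations, identical step-1 clusters
  ann0 <- annotate_two_step(sim$clones, sim$reference[0, ])
  expect_equal(nrow(ann0$clones), 0L)
  expect_identical(ann0$clusters$cluster_id, ann$clusters$cluster_id)
  expect_true(all(is.na(ann0$clusters$inferred_antigen)))
})

test_that("ties between reference antigens break lexicographically with a flag", {
  clones <- tibble::tibble(
    cdr3_aa = sprintf("CAS%sQRSTA%sYF", LETTERS[1:4], LETTERS[1:4]),
    patient_id = paste0("p", 1:4),
    v_call = "TRBV9"
  )
  reference <- tibble::tibble(
    cdr3_aa = sprintf("CAT%sQRSTW%sYF", LETTERS[5:6], LETTERS[5:6]),
    antigen_epitope = c("E1", "E2"),
    antigen_species = c("EBV", "CMV")
  )
  bg <- tibble::tibble(motif = character(), freq = numeric())
  attr(bg, "pseudo") <- 1e-4
  ann <- annotate_two_step(clones, reference, k = 4, background = bg,
                           vbias_alpha = 1.01)
  hit <- ann$clusters[ann$clusters$cluster_id == "L4:QRST", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$inferred_antigen, "CMV")  # lexicographic winner
  expect_true(hit$antigen_tie)
})

test_that("clusters and annotations are independent of clone frequency", {
  sim <- simulate_reference_and_motifs(sim_config(
    seed = 96, n_background_clones = 250, planted_motifs = 2,
    planted_group_size = 5, n_reference_decoys = 5
  ))
  clones <- sim$clones
  clones$frequency <- runif(nrow(clones))
  ann1 <- annotate_two_step(clones, sim$reference)
  clones$frequency <- sample(clones$frequency)
  ann2 <- annotate_two_step(clones, sim$reference)
  expect_identical(ann1$clusters$cluster_id, ann2$clusters$cluster_id)
  expect_identical(ann1$clones, ann2$clones)
})

test_that("expansion-target association reports the cross-product odds ratio", {
  # table (10, 90; 5, 195): OR = (10*195)/(90*5) = 4.333...
  clones <- tibble::tibble(
    clone_key = paste0("c", 1:300),
    expansion = rep(c("hyper_expanded", "non_expanded"), c(100, 200))
  )
  targeted <- c(paste0("c", 1:10), paste0("c", 101:105))
  ann <- structure(list(
    clusters = tibble::tibble(),
    clones = tibble::tibble(clone_key = targeted,
                            cdr3_aa = "x", patient_id = "p",
                            inferred_antigen = rep(c("CMV", "EBV"),
                                                   c(10, 5))),
    n_reference = 15L
  ), class = "tcr_annotation")
  res <- expansion_target_association(ann, clones)
  expect_equal(res$overall$odds_ratio, (10 * 195) / (90 * 5), tolerance = 1e-12)
  # two-sided Fisher p from the hypergeometric enumeration oracle
  enum_p <- local({
    support <- 0:15
    probs <- dhyper(support, 15, 285, 100)
    sum(probs[probs <= dhyper(10, 15, 285, 100) * (1 + 1e-7)])
  })
  expect_equal(res$overall$p_value, enum_p, tolerance = 1e-10)
  expect_equal(nrow(res$per_antigen), 2L)
  expect_true(all(res$per_antigen$p_adjusted >= res$per_antigen$p_value - 1e-15))

  # degenerate margin: only hyper-expanded clones annotated
  ann2 <- ann
  ann2$clones <- ann$clones[1:10, ]
  res2 <- expansion_target_association(ann2, clones)
  expect_true(is.infinite(res2$overall$odds_ratio))
  expect_match(res2$overall$note, "unbounded")
})
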