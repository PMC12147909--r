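# generator properties: determinism, truth recovery, structural features

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_background_clones = 300, total_reads = 2e4)
  a <- simulate_repertoire(cfg)
  b <- simulate_repertoire(cfg)
  expect_identical(as.data.frame(a$repertoire), as.data.frame(b$repertoire))
  expect_identical(a$truth, b$truth)

  scfg <- sim_config(seed = 12, n_background_clones = 200, total_reads = 1e4,
                     n_timepoints = 3)
  s1 <- simulate_series(scfg)
  s2 <- simulate_series(scfg)
  expect_identical(lapply(s1$series, as.data.frame),
                   lapply(s2$series, as.data.frame))
  expect_identical(s1$truth, s2$truth)

  mcfg <- sim_config(seed = 13, n_background_clones = 150, planted_motifs = 3)
  expect_identical(simulate_reference_and_motifs(mcfg),
                   simulate_reference_and_motifs(mcfg))
})

test_that("unknown config fields and infeasible hyper-expanded mass are rejected", {
  expect_error(sim_config(nonsense = 1), "Unknown")
  cfg <- sim_config(seed = 14, n_hyperexpanded = 20,
                    hyper_freq_min = 0.1, hyper_freq_max = 0.15)
  expect_error(simulate_repertoire(cfg), "infeasible")
})

test_that("estimated hyper-expanded mass tracks the planted truth at deep reads", {
  cfg <- sim_config(seed = 15, n_background_clones = 2000, total_reads = 1e6,
                    n_hyperexpanded = 4)
  sim <- simulate_repertoire(cfg)
  # the estimand: total latent mass of clones above the 0.002 threshold
  truth_mass <- sum(sim$truth$true_freq[sim$truth$true_freq > 0.002])
  est <- hyperexpanded_fraction(sim$repertoire)
  expect_lt(abs(est - truth_mass), 0.03)
})

test_that("a flat background without hyper-expansion is nearly even after filtering", {
  cfg <- sim_config(seed = 16, n_background_clones = 1000, total_reads = 5e5,
                    n_hyperexpanded = 0, bg_sdlog = 0.2)
  rep <- filter_clones(simulate_repertoire(cfg)$repertoire)
  expect_gt(normalized_shannon(rep), 0.95)
})

test_that("generated sequences are valid in-frame CDR3s with controlled productivity", {
  cfg <- sim_config(seed = 17, n_background_clones = 500, total_reads = 5e4)
  r <- simulate_repertoire(cfg)$repertoire
  expect_true(all(grepl("^TGT", r$cdr3_nt)))
  expect_true(all(nchar(r$cdr3_nt) %% 3 == 0))
  expect_true(all(grepl("^C", r$cdr3_aa[r$productive])))
  expect_true(all(grepl("F$", r$cdr3_aa[r$productive])))
  expect_false(any(grepl("\\*", r$cdr3_aa[r$productive])))
  expect_true(any(!r$productive))  # the productivity filter has work to do
})

test_that("post-treatment depletion of non-expanded clones lowers diversity", {
  set.seed(18)
  cfg <- sim_config(n_background_clones = 600, total_reads = 1e5,
                    n_timepoints = 2, nonexpanded_depletion = 0.4,
                    drift_sd = 0.1)
  deltas <- replicate(15, {
    s <- simulate_series(cfg)$series
    normalized_shannon(filter_clones(s[[2]])) -
      normalized_shannon(filter_clones(s[[1]]))
  })
  expect_lt(median(deltas), 0)
})

test_that("redetection probability rises with clone size in simulated series", {
  set.seed(19)
  cfg <- sim_config(n_background_clones = 800, total_reads = 4e4,
                    n_timepoints = 3)
  series <- replicate(10, simulate_series(cfg)$series, simplify = FALSE)
  curve <- persistence_by_size_curve(series, n_bins = 5)
  props <- curve$prop_persistent[!is.na(curve$prop_persistent)]
  expect_gt(length(props), 2)
  expect_true(all(diff(props) >= -1e-12))
})

test_that("tumor sharing follows the logistic size model at its extremes", {
  set.seed(20)
  blood <- simulate_repertoire(sim_config(n_background_clones = 300,
                                          total_reads = 3e4))$repertoire
  always <- simulate_paired_tumor(blood, sim_config(sharing_intercept = 50,
                                                    tumor_reads = 1e6,
                                                    tumor_private_factor = 0.01))
  expect_gt(overlap_summary(blood, always$repertoire)$n_common,
            0.95 * nrow(blood))
  never <- simulate_paired_tumor(blood, sim_config(sharing_intercept = -80,
                                                   sharing_slope = 0))
  expect_equal(overlap_summary(blood, never$repertoire)$n_common, 0L)
})

test_that("outcome generator matches its analytic censoring expectation", {
  set.seed(21)
  cfg <- sim_config()
  div <- tibble::tibble(patient_id = paste0("p", 1:4000), value = runif(4000))
  cl <- simulate_cohort_outcomes(div, cfg)
  # P(censored | hazard h) = E[S(C)] = (1 - exp(-h * cmax)) / (h * cmax)
  h <- cfg$baseline_hazard * ifelse(cl$group == "low", cfg$hr_low_diversity, 1)
  p_cens <- mean((1 - exp(-h * cfg$censor_max)) / (h * cfg$censor_max))
  se <- sqrt(p_cens * (1 - p_cens) / nrow(cl))
  expect_lt(abs(mean(cl$event == 0) - p_cens), 3 * se + 0.01)
})

test_that("cohorts span a wide hyper-expansion range with bimodal size structure", {
  cohort <- simulate_cohort(sim_config(seed = 22, n_background_clones = 2000,
                                       total_reads = 2e5), n_patients = 15)
  hf <- vapply(cohort$repertoires,
               function(r) hyperexpanded_fraction(filter_clones(r)), numeric(1))
  expect_gt(max(hf) - min(hf), 0.2)
  expect_true(all(hf <= 1))
  expect_equal(nrow(cohort$truth[!duplicated(cohort$truth$patient_id), ]), 15L)
})
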