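# persistence classification and the exact-binomial random-sharing test

test_that("persistence labels follow the detection definitions", {
  keys <- key_pool(3)
  s <- make_series(list(
    keys[1:3], keys[c(1, 2)], keys[1], c(keys[1], keys[2])
  ))
  lab <- classify_persistence(s)
  got <- setNames(as.character(lab$label), lab$cdr3_nt)
  expect_identical(got[[keys[1]]], "persistent")  # 4/4
  expect_identical(got[[keys[2]]], "recurrent")   # 3/4
  expect_identical(got[[keys[3]]], "transient")   # 1/4
  expect_equal(lab$n_samples_total, rep(4L, 3))
})

test_that("single-sample series are rejected for persistence analysis", {
  s1 <- make_series(list(key_pool(2)))
  expect_error(classify_persistence(s1), class = "clonotrace_single_sample")
})

test_that("persistence labels partition the union of observed clones", {
  set.seed(81)
  cfg <- sim_config(n_background_clones = 400, total_reads = 3e4,
                    n_timepoints = 3)
  for (i in 1:5) {
    s <- simulate_series(cfg)$series
    lab <- classify_persistence(s)
    union_keys <- unique(unlist(lapply(s, function(r) r$cdr3_nt)))
    expect_setequal(lab$cdr3_nt, union_keys)
    expect_equal(sum(table(lab$label)), length(union_keys))
    # independent recount: set membership per sample
    recount <- vapply(lab$cdr3_nt, function(k) {
      sum(vapply(s, function(r) k %in% r$cdr3_nt, logical(1)))
    }, integer(1))
    expect_identical(unname(recount), lab$n_samples_detected)
  }
})

test_that("persistent+recurrent baseline mass sums the redetected baseline frequencies", {
  keys <- key_pool(6)
  # baseline counts: persistent 10 and 20, recurrent 5, transient 65 (of 100)
  s <- make_series(
    list(keys[1:6], keys[1:3], keys[1:2]),
    counts = list(c(10, 20, 5, 30, 20, 15), rep(10, 3), rep(10, 2))
  )
  expect_equal(persistent_recurrent_baseline_mass(s), 0.35, tolerance = 1e-12)

  all_trans <- make_series(list(keys[1:2], keys[3:4]))
  expect_equal(persistent_recurrent_baseline_mass(all_trans), 0)
  all_pers <- make_series(list(keys[1:2], keys[1:2]))
  expect_equal(persistent_recurrent_baseline_mass(all_pers), 1)
})

test_that("persistence-by-size curve reports per-bin proportions with NA for empty bins", {
  keys <- key_pool(4)
  s <- make_series(list(keys, keys))   # everything persistent
  curve <- persistence_by_size_curve(list(s), n_bins = 3)
  expect_true(all(curve$prop_persistent[curve$n_clones > 0] == 1))
  # clones all at one frequency: middle bin holds them, outer bins empty
  expect_true(anyNA(curve$prop_persistent))
  expect_true(all(is.na(curve$prop_persistent[curve$n_clones == 0])))
})

test_that("minlike binomial p-values match independent oracles", {
  # observed equal to the null expectation: p-value 1, call neutral
  # paired: 1000 unique clones, clone 1 at exactly 1% (999 of 99,900 reads)
  pool <- key_pool(1000)
  bt <- binomial_sharing_test(
    make_rep_freq(c(0.01, 0.99), total = 1e6, keys = pool[1:2]),
    make_rep(c(999, rep(99, 999)), keys = pool)
  )
  # trials = 1000, baseline p = 0.01, paired freq 0.01 -> x = 10 = n*p
  row <- bt[bt$baseline_freq == 0.01, ]
  expect_equal(row$observed, 10L)
  expect_equal(row$p_value, 1, tolerance = 1e-6)
  expect_identical(as.character(row$call), "neutral")

  # absent clone: lower tail contributes (1-p)^n = 0.999^1000
  pool2 <- key_pool(1001)
  base <- make_rep_freq(c(0.001, 0.999), total = 1e6, keys = pool2[1:2])
  paired <- make_rep(rep(1, 1000), keys = pool2[-1])
  bt2 <- binomial_sharing_test(base, paired)
  row2 <- bt2[bt2$baseline_freq == 0.001, ]
  expect_equal(row2$observed, 0L)
  expect_gte(row2$p_value, 0.999^1000)
  expect_equal(row2$p_value, binom_enum_oracle(0, 1000, 0.001),
               tolerance = 1e-10)
  expect_identical(as.character(row2$call), "neutral")

  # random triples: enumeration oracle and the standard exact test agree
  set.seed(82)
  for (i in 1:50) {
    n <- sample(10:2000, 1)
    p <- runif(1, 1e-4, 0.3)
    x <- sample(0:n, 1)
    ours <- clonotrace:::binom_minlike_pvalue(x, n, p)
    expect_equal(ours, binom.test(x, n, p)$p.value, tolerance = 1e-10)
    expect_equal(ours, binom_enum_oracle(x, n, p), tolerance = 1e-7)
    if (dbinom(x, n, p) > 0) expect_gt(ours, 0)  # positive unless the pmf
    expect_lte(ours, 1)                          # itself underflows
  }
})

test_that("observed counts round half away from zero and calls follow Bonferroni", {
  expect_equal(clonotrace:::round_half_up(3.5), 4)
  expect_equal(clonotrace:::round_half_up(2.5), 3)
  expect_equal(clonotrace:::round_half_up(2.4), 2)

  set.seed(83)
  b <- make_rep(rpois(300, 500) + 50)
  q <- resample_repertoire(b)
  res <- binomial_sharing_test(b, q, alpha = 0.05)
  m <- nrow(b)
  expect_equal(res$p_bonferroni, pmin(1, m * res$p_value), tolerance = 1e-12)
  brute_sig <- res$cdr3_nt[m * res$p_value < 0.05]
  expect_setequal(res$cdr3_nt[res$call != "neutral"], brute_sig)
  # directions match the sign of observed - expected
  sig <- res[res$call != "neutral", ]
  if (nrow(sig)) {
    expect_true(all((sig$call == "enriched") ==
                      (sig$observed > sig$trials * sig$baseline_freq)))
  }
  expect_error(binomial_sharing_test(b, q, alpha = 1.5), "alpha")
})

test_that("diversity trajectories summarise groups and pair patients correctly", {
  div <- tibble::tibble(
    patient_id = rep(paste0("p", 1:3), each = 2),
    timepoint = rep(c("baseline", "post"), 3),
    group = "all",
    value = c(0.2, 0.2, 0.4, 0.4, 0.6, 0.6)
  )
  traj <- diversity_trajectory(div, timepoint_levels = c("baseline", "post"))
  expect_equal(traj$summary$median, c(0.4, 0.4))
  # identical paired values: no signed ranks, p reported as 1
  expect_equal(traj$tests$p_value, 1)
  expect_equal(traj$tests$n_pairs, 3L)

  # fewer than two pairs: omitted with a warning
  div2 <- div[div$patient_id != "p1" | div$timepoint != "post", ]
  div2 <- div2[!(div2$patient_id %in% c("p2") & div2$timepoint == "post"), ]
  expect_warning(diversity_trajectory(div2,
                                      timepoint_levels = c("baseline", "post")),
                 "paired")
  expect_error(diversity_trajectory(div[, -1]), "lacks")
})
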