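#' Classify clone persistence across a longitudinal series
#'
#' For each clone observed in at least one sample of a patient's series:
#' `persistent` if detected in all samples, `transient` if detected in
#' exactly one, `recurrent` if detected in more than one but not all.
#' Detection is presence of the CDR3 nucleotide key after filtering; no
#' abundance threshold beyond the input read filter is applied. The three
#' labels partition the observed clones. With a single sample the
#' persistent and transient definitions collide, so single-sample series
#' are rejected.
#'
#' @param series A [patient_series()] with at least two repertoires.
#' @return Tibble with `cdr3_nt`, `label` (factor persistent/recurrent/
#'   transient), `n_samples_detected`, `n_samples_total`.
#' @export
classify_persistence <- function(series) {
  if (is.list(series) && !inherits(series, "patient_series")) {
    series <- patient_series(series)
  }
  n_total <- length(series)
  if (n_total < 2L) {
    abort("Persistence needs >= 2 samples; skip persistence analysis for single-sample patients.",
          class = "clonotrace_single_sample")
  }
  keys <- unlist(lapply(series, function(r) unique(r$cdr3_nt)), use.names = FALSE)
  det <- table(keys)
  lab <- ifelse(det == n_total, "persistent",
                ifelse(det == 1L, "transient", "recurrent"))
  tibble(
    cdr3_nt = names(det),
    label = factor(as.character(lab),
                   levels = c("persistent", "recurrent", "transient")),
    n_samples_detected = as.integer(det),
    n_samples_total = n_total
  )
}

#' Baseline mass of persistent and recurrent clones
#'
#' The summed baseline frequency of clones redetected in at least one later
#' sample (persistent or recurrent). High values indicate a repertoire whose
#' large clones are stable over the disease course.
#'
#' @param series A [patient_series()]; the first repertoire is the baseline.
#' @return A number in `[0, 1]`.
#' @export
persistent_recurrent_baseline_mass <- function(series) {
  labels <- classify_persistence(series)
  keep <- labels$cdr3_nt[labels$label != "transient"]
  baseline <- series[[1]]
  sum(baseline$frequency[baseline$cdr3_nt %in% keep])
}

#' Persistence composition by baseline clone size
#'
#' Pools clones present at baseline across a collection of patient series,
#' bins them uniformly in log10 baseline frequency, and reports the
#' proportion of each persistence category per bin. Empty bins are reported
#' with `NA` proportions rather than zero.
#'
#' @param series_list List of [patient_series()] objects.
#' @param n_bins Number of log10-frequency bins (default 6).
#' @return Tibble with `bin`, `lower`, `upper`, `n_clones`, and
#'   `prop_persistent`, `prop_recurrent`, `prop_transient`.
#' @export
persistence_by_size_curve <- function(series_list, n_bins = 6) {
  if (inherits(series_list, "patient_series")) series_list <- list(series_list)
  pooled <- purrr::map(series_list, function(s) {
    labels <- classify_persistence(s)
    baseline <- s[[1]]
    inner_join(tibble(cdr3_nt = baseline$cdr3_nt,
                      frequency = baseline$frequency),
               labels, by = "cdr3_nt")
  }) |> list_rbind()
  lf <- log10(pooled$frequency)
  edges <- bin_edges(lf, n_bins)
  idx <- assign_bins(lf, edges)
  prop_in_bin <- function(lab) {
    vapply(seq_len(n_bins), function(b) {
      inb <- idx == b
      if (!any(inb)) return(NA_real_)
      mean(pooled$label[inb] == lab)
    }, numeric(1))
  }
  tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    n_clones = as.integer(tabulate(idx, n_bins)),
    prop_persistent = prop_in_bin("persistent"),
    prop_recurrent = prop_in_bin("recurrent"),
    prop_transient = prop_in_bin("transient")
  )
}

#' Exact binomial enrichment/depletion test against a baseline repertoire
#'
#' Tests, clone by clone, whether a clone's representation in a paired
#' sample is compatible with random sharing from the baseline repertoire.
#' For each baseline clone the null success probability is its baseline
#' frequency; the number of trials is the unique clone count of the paired
#' sample (a lower-bound estimate of the number of T cells surveyed); the
#' observed count is the clone's paired frequency multiplied by the trials,
#' rounded to the nearest integer (half away from zero), zero when absent.
#' The two-sided p-value is the exact minimum-likelihood binomial
#' probability: the sum of the probabilities of all outcomes no more likely
#' than the observed one (with the conventional `1 + 1e-7` relative guard
#' against floating-point noise when comparing densities, as in
#' [stats::binom.test()]). Bonferroni correction multiplies by the number
#' of baseline clones tested; calls are `enriched`/`depleted` by the sign
#' of `observed - trials * baseline_freq` when the corrected p-value is
#' below `alpha`, otherwise `neutral`.
#'
#' Only clones present at baseline are testable (the null probability is the
#' baseline frequency); clones private to the paired sample are excluded and
#' their count is attached as the `n_private_paired` attribute.
#'
#' @param baseline,paired Filtered, normalized `tcr_repertoire` objects.
#' @param alpha Significance level after Bonferroni correction (default 0.05).
#' @return Tibble with one row per baseline clone: `cdr3_nt`,
#'   `baseline_freq`, `paired_freq`, `trials`, `observed`, `p_value`,
#'   `p_bonferroni`, `call`.
#' @export
binomial_sharing_test <- function(baseline, paired, alpha = 0.05) {
  stopifnot_scalar_prob(alpha, "alpha")
  baseline <- as_tcr_repertoire(baseline)
  paired <- as_tcr_repertoire(paired)
  if (nrow(baseline) == 0L) abort("Baseline repertoire is empty.")
  n <- nrow(paired)
  paired_freq <- setNames(paired$frequency, paired$cdr3_nt)
  pf <- unname(paired_freq[baseline$cdr3_nt])
  pf[is.na(pf)] <- 0
  x <- round_half_up(pf * n)
  p <- baseline$frequency
  pv <- vapply(seq_along(p), function(i) binom_minlike_pvalue(x[i], n, p[i]),
               numeric(1))
  m <- length(p)
  pb <- pmin(1, m * pv)
  expected <- n * p
  call <- rep("neutral", m)
  sig <- pb < alpha
  call[sig & x > expected] <- "enriched"
  call[sig & x < expected] <- "depleted"
  out <- tibble(
    cdr3_nt = baseline$cdr3_nt,
    baseline_freq = p,
    paired_freq = pf,
    trials = n,
    observed = as.integer(x),
    p_value = pv,
    p_bonferroni = pb,
    call = factor(call, levels = c("enriched", "depleted", "neutral"))
  )
  attr(out, "n_private_paired") <- sum(!paired$cdr3_nt %in% baseline$cdr3_nt)
  out
}

# exact two-sided binomial p-value, minimum-likelihood method, by direct
# enumeration of the pmf over 0..n
binom_minlike_pvalue <- function(x, n, p) {
  if (p >= 1) return(1)
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Group diversity trajectories over timepoints
#'
#' Summarises a per-sample diversity table (one value per patient per
#' timepoint) as group medians with interquartile range, and tests the
#' change between consecutive timepoints within each group with a paired
#' Wilcoxon signed-rank test over the patients observed at both timepoints.
#'
#' @param div Data frame with columns `patient_id`, `timepoint`, `group`,
#'   `value` (at most one row per patient and timepoint).
#' @param timepoint_levels Optional character vector giving the temporal
#'   order of timepoints; defaults to order of first appearance.
#' @return List with `summary` (group x timepoint medians, IQR, n) and
#'   `tests` (paired signed-rank p per group and consecutive timepoint
#'   pair; pairs with fewer than 2 complete patients are omitted with a
#'   warning).
#' @export
diversity_trajectory <- function(div, timepoint_levels = NULL) {
  need <- c("patient_id", "timepoint", "group", "value")
  missing <- setdiff(need, names(div))
  if (length(missing)) {
    abort(sprintf("`div` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(paste(div$patient_id, div$timepoint))) {
    abort("Each patient may contribute at most one value per timepoint.")
  }
  lv <- timepoint_levels %||% unique(as.character(div$timepoint))
  div <- as_tibble(div) |>
    mutate(timepoint = factor(as.character(.data$timepoint), levels = lv))
  summary <- div |>
    group_by(.data$group, .data$timepoint) |>
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q25 = as.numeric(quantile(.data$value, 0.25)),
      q75 = as.numeric(quantile(.data$value, 0.75)),
      .groups = "drop"
    )
  tests <- list()
  for (g in unique(div$group)) {
    dg <- div[div$group == g, ]
    for (i in seq_len(length(lv) - 1L)) {
      a <- dg[dg$timepoint == lv[i], c("patient_id", "value")]
      b <- dg[dg$timepoint == lv[i + 1L], c("patient_id", "value")]
      pairs <- inner_join(a, b, by = "patient_id", suffix = c("_a", "_b"))
      if (nrow(pairs) < 2L) {
        warn(sprintf("Fewer than 2 paired observations for group '%s' (%s vs %s); test omitted.",
                     g, lv[i], lv[i + 1L]))
        next
      }
      pval <- suppressWarnings(
        wilcox.test(pairs$value_a, pairs$value_b, paired = TRUE, exact = FALSE)$p.value
      )
      if (is.nan(pval)) pval <- 1 # all differences zero: no signed ranks
      tests[[length(tests) + 1L]] <- tibble(
        group = g, from = lv[i], to = lv[i + 1L],
        n_pairs = nrow(pairs), p_value = pval
      )
    }
  }
  list(summary = summary,
       tests = if (length(tests)) list_rbind(tests) else
         tibble(group = character(), from = character(), to = character(),
                n_pairs = integer(), p_value = numeric()))
}
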