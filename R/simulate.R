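# Synthetic repertoire generators. These emulate the statistical structure
# the analysis assumes -- a right-skewed clone-size distribution with a
# separated hyper-expanded tail, size-dependent longitudinal redetection,
# limited blood-tumor sharing that increases with blood clone size, planted
# specificity motifs with reference pairs, and a proportional-hazards
# outcome linked to diversity -- so that every stage of the pipeline can be
# exercised and scored against known truth without patient data.

#' Simulation configuration
#'
#' Collects the parameters of all generators with defaults emulating the
#' study conditions: a log-normal background clone-size law (sigma 1.5),
#' hyper-expanded clones planted at target frequencies Uniform(0.002,
#' 0.15) so cohort-level hyper-expanded mass spans roughly 0.5%-65% as
#' `n_hyperexpanded` varies 0-12, four timepoints with log-normal
#' frequency drift and post-treatment depletion of non-expanded clones,
#' logistic blood-size-dependent tumor sharing, planted interior motifs
#' with named-antigen reference pairs, and an exponential outcome model
#' with a hazard ratio for the low-diversity group.
#'
#' @param seed Integer seed; generators seeded with it are fully
#'   deterministic (same config, same output). `NULL` leaves the RNG state
#'   untouched.
#' @param ... Overrides for any default listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = NULL, ...) {
  cfg <- list(
    seed = seed,
    # repertoire
    n_background_clones = 5000,
    background_law = "lognormal", # or "pareto"
    bg_meanlog = 0, bg_sdlog = 1.5, pareto_alpha = 1.5,
    n_hyperexpanded = 5,
    hyper_freq_min = 0.002, hyper_freq_max = 0.15,
    total_reads = 1e6,
    nonproductive_rate = 0.02,
    aa_length_range = c(10L, 16L),
    n_v_genes = 30L, n_j_genes = 13L,
    # longitudinal series
    n_timepoints = 4,
    timepoint_labels = c("baseline", "post_chemo", "post_cystectomy", "followup"),
    drift_sd = 0.3,
    nonexpanded_depletion = 0.5,
    # paired tumor
    tumor_reads = 2e5,
    tumor_private_factor = 0.3,
    sharing_intercept = 2.9, sharing_slope = 1.5,
    tumor_size_sd = 1.0,
    # planted specificity groups
    n_patients = 10,
    planted_motifs = 10,
    planted_group_size = 8,
    motif_length = 4,
    reference_per_motif = 3,
    n_reference_decoys = 50,
    p_hyper_planted = 0.4, p_hyper_background = 0.01,
    antigen_names = c("CMV", "EBV", "InfluenzaA", "HCV", "YFV"),
    # outcome model (time in months)
    baseline_hazard = 0.05,
    hr_low_diversity = 2.0,
    censor_max = 80,
    # cohort
    max_cohort_hyper_mass = 0.65,
    cohort_hyper_range = c(0L, 12L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown sim_config field(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
}

# evaluate expr under a temporary RNG state, restoring the caller's state
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- sequence generation ----------------------------------------------------

non_stop_codons <- function() {
  names(.codon_table)[.codon_table != "*"]
}

# random in-frame CDR3 nucleotide sequences: TGT (C) start, TTT/TTC (F)
# terminus to resemble C...F junctions (cosmetic realism only), random
# non-stop codons in between; guaranteed unique within the call
random_cdr3_nt <- function(n, aa_len_range = c(10L, 16L)) {
  gen <- function(m) {
    L <- sample(seq(aa_len_range[1], aa_len_range[2]), m, replace = TRUE)
    vapply(L, function(l) {
      paste0("TGT",
             paste(sample(non_stop_codons(), l - 2L, replace = TRUE), collapse = ""),
             sample(c("TTT", "TTC"), 1L))
    }, character(1))
  }
  out <- gen(n)
  while (anyDuplicated(out)) {
    dup <- duplicated(out)
    out[dup] <- gen(sum(dup))
  }
  out
}

random_cdr3_aa <- function(n, aa_len_range = c(10L, 16L)) {
  translate_nt(random_cdr3_nt(n, aa_len_range))
}

random_v_calls <- function(n, n_genes) {
  sample(paste0("TRBV", seq_len(n_genes)), n, replace = TRUE)
}

# ---- repertoire -------------------------------------------------------------

#' Simulate a single repertoire with planted hyper-expanded clones
#'
#' Background clone weights are drawn from the configured law (log-normal
#' by default); `n_hyperexpanded` clones are injected at target frequencies
#' Uniform(`hyper_freq_min`, `hyper_freq_max`); read counts are a
#' multinomial draw of `total_reads` from the normalized frequencies. A
#' small fraction of clones is made non-productive (stop codon) so the
#' productivity filter is exercised downstream; the standard read filter is
#' applied downstream as for real data, not here. Clones receiving zero
#' reads are dropped.
#'
#' @param config A [sim_config()].
#' @param patient_id,sample_id,timepoint,compartment Sample metadata.
#' @return List with `repertoire` (a `tcr_repertoire` of observed counts)
#'   and `truth` (tibble `cdr3_nt`, `true_freq`, `class`
#'   hyper/background, `productive`).
#' @export
simulate_repertoire <- function(config = sim_config(), patient_id = "p1",
                                sample_id = NULL, timepoint = "baseline",
                                compartment = "blood") {
  maybe_seed(config)
  lat <- simulate_latent(config)
  obs <- observe_latent(lat, config$total_reads)
  rep <- tcr_repertoire(obs,
                        sample_id = sample_id %||% paste0(patient_id, "_", timepoint),
                        patient_id = patient_id, compartment = compartment,
                        timepoint = timepoint)
  list(repertoire = rep,
       truth = lat[, c("cdr3_nt", "true_freq", "class", "productive")])
}

# latent clone table: sequences, true frequencies, classes
simulate_latent <- function(config) {
  n_h <- config$n_hyperexpanded
  hyper_freq <- if (n_h > 0) runif(n_h, config$hyper_freq_min, config$hyper_freq_max)
                else numeric()
  mass <- sum(hyper_freq)
  if (mass >= 0.95) {
    abort(sprintf("Planted hyper-expanded mass %.2f leaves no room for the background; infeasible config.",
                  mass))
  }
  n_bg <- config$n_background_clones
  w <- switch(config$background_law,
              lognormal = rlnorm(n_bg, config$bg_meanlog, config$bg_sdlog),
              pareto = (1 / runif(n_bg))^(1 / config$pareto_alpha),
              abort("`background_law` must be 'lognormal' or 'pareto'."))
  p <- c(hyper_freq, w / sum(w) * (1 - mass))
  n <- n_h + n_bg
  nt <- random_cdr3_nt(n, config$aa_length_range)
  productive <- runif(n) >= config$nonproductive_rate
  nt[!productive] <- insert_stop(nt[!productive])
  tibble(
    cdr3_nt = nt,
    cdr3_aa = translate_nt(nt),
    v_call = random_v_calls(n, config$n_v_genes),
    j_call = sample(paste0("TRBJ", seq_len(config$n_j_genes)), n, replace = TRUE),
    true_freq = p,
    class = c(rep("hyper", n_h), rep("background", n_bg)),
    productive = productive
  )
}

# replace a middle codon with TAA to make a sequence non-productive
insert_stop <- function(nt) {
  vapply(nt, function(s) {
    n_codons <- nchar(s) / 3L
    pos <- sample(2:(n_codons - 1L), 1L)
    paste0(substr(s, 1L, (pos - 1L) * 3L), "TAA",
           substr(s, pos * 3L + 1L, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

# multinomial read sampling of a latent table; zero-read clones unobserved
observe_latent <- function(lat, reads) {
  counts <- as.integer(rmultinom(1, reads, lat$true_freq))
  keep <- counts > 0L
  tibble(
    cdr3_nt = lat$cdr3_nt[keep],
    cdr3_aa = lat$cdr3_aa[keep],
    v_call = lat$v_call[keep],
    j_call = lat$j_call[keep],
    read_count = counts[keep],
    productive = lat$productive[keep]
  )
}

#' Resample a repertoire multinomially from its own frequencies
#'
#' Draws a technical replicate under the random-sharing null: read counts
#' are a fresh multinomial draw from the repertoire's clone frequencies.
#' Used to calibrate [binomial_sharing_test()].
#'
#' @param rep A `tcr_repertoire`.
#' @param reads Total reads of the replicate (default: the input's total).
#' @param sample_id Identifier for the replicate.
#' @return A `tcr_repertoire`.
#' @export
resample_repertoire <- function(rep, reads = NULL, sample_id = "resample") {
  rep <- as_tcr_repertoire(rep)
  reads <- reads %||% sum(rep$read_count)
  counts <- as.integer(rmultinom(1, reads, rep$frequency))
  keep <- counts > 0L
  tcr_repertoire(
    tibble(cdr3_nt = rep$cdr3_nt[keep], cdr3_aa = rep$cdr3_aa[keep],
           v_call = rep$v_call[keep], j_call = rep$j_call[keep],
           read_count = counts[keep], productive = rep$productive[keep]),
    sample_id = sample_id, patient_id = attr(rep, "patient_id"),
    compartment = attr(rep, "compartment"), timepoint = attr(rep, "timepoint")
  )
}

# ---- longitudinal series ----------------------------------------------------

#' Simulate a longitudinal patient series
#'
#' The baseline latent repertoire drifts between timepoints by log-normal
#' steps of standard deviation `drift_sd`; at the first post-baseline
#' timepoint the latent frequencies of non-expanded clones (true class
#' background) are multiplied by `nonexpanded_depletion` and renormalized,
#' emulating treatment-induced depletion of small clones and the resulting
#' diversity decrease. Each timepoint is an independent multinomial read
#' draw, which makes redetection probability increase with clone size.
#'
#' @param config A [sim_config()] with `n_timepoints >= 2`.
#' @param patient_id Patient identifier.
#' @return List with `series` (a [patient_series()]) and `truth` (tibble of
#'   latent frequencies per clone and timepoint).
#' @export
simulate_series <- function(config = sim_config(), patient_id = "p1") {
  if (config$n_timepoints < 2) abort("`n_timepoints` must be >= 2.")
  maybe_seed(config)
  lat <- simulate_latent(config)
  labels <- config$timepoint_labels[seq_len(config$n_timepoints)]
  labels[is.na(labels)] <- paste0("t", which(is.na(labels)))
  p <- lat$true_freq
  reps <- vector("list", config$n_timepoints)
  truth <- vector("list", config$n_timepoints)
  for (t in seq_len(config$n_timepoints)) {
    if (t > 1L) {
      p <- p * exp(rnorm(length(p), 0, config$drift_sd))
      if (t == 2L) {
        p[lat$class == "background"] <- p[lat$class == "background"] *
          config$nonexpanded_depletion
      }
      p <- p / sum(p)
    }
    lat_t <- lat
    lat_t$true_freq <- p
    obs <- observe_latent(lat_t, config$total_reads)
    reps[[t]] <- tcr_repertoire(obs,
                                sample_id = paste0(patient_id, "_", labels[t]),
                                patient_id = patient_id, compartment = "blood",
                                timepoint = labels[t])
    truth[[t]] <- tibble(cdr3_nt = lat$cdr3_nt, timepoint = labels[t],
                         latent_freq = p, class = lat$class)
  }
  list(series = patient_series(reps), truth = list_rbind(truth))
}

# ---- paired tumor -----------------------------------------------------------

#' Simulate a tumor repertoire paired to a blood repertoire
#'
#' Each blood clone enters the tumor pool with probability
#' `plogis(sharing_intercept + sharing_slope * log10(blood frequency))`,
#' so larger blood clones are more likely to be shared. Shared clones get
#' tumor weights equal to their blood frequency perturbed by log-normal
#' noise (`tumor_size_sd` on the log scale); the tumor adds
#' `tumor_private_factor * n_blood` private clones (the majority of the
#' tumor repertoire, emulating limited recirculation), and the observed
#' tumor sample is a multinomial draw of `tumor_reads`.
#'
#' @param blood A blood `tcr_repertoire`.
#' @param config A [sim_config()].
#' @return List with `repertoire` (tumor `tcr_repertoire`) and `truth`
#'   (tibble `cdr3_nt`, `shared`, `true_freq`).
#' @export
simulate_paired_tumor <- function(blood, config = sim_config()) {
  maybe_seed(config)
  blood <- as_tcr_repertoire(blood)
  pr <- stats::plogis(config$sharing_intercept +
                        config$sharing_slope * log10(blood$frequency))
  shared <- runif(nrow(blood)) < pr
  w_shared <- blood$frequency[shared] *
    exp(rnorm(sum(shared), 0, config$tumor_size_sd))
  n_priv <- max(1L, round(config$tumor_private_factor * nrow(blood)))
  w_priv <- rlnorm(n_priv, config$bg_meanlog, config$bg_sdlog)
  w_priv <- w_priv / sum(w_priv) * max(1e-12, 1 - min(0.5, sum(w_shared)))
  nt_priv <- random_cdr3_nt(n_priv, config$aa_length_range)
  lat <- tibble(
    cdr3_nt = c(blood$cdr3_nt[shared], nt_priv),
    cdr3_aa = c(blood$cdr3_aa[shared], translate_nt(nt_priv)),
    v_call = c(blood$v_call[shared], random_v_calls(n_priv, config$n_v_genes)),
    j_call = c(blood$j_call[shared],
               sample(paste0("TRBJ", seq_len(config$n_j_genes)), n_priv,
                      replace = TRUE)),
    true_freq = c(w_shared, w_priv) / sum(c(w_shared, w_priv)),
    productive = c(blood$productive[shared], rep(TRUE, n_priv))
  )
  obs <- observe_latent(lat, config$tumor_reads)
  rep <- tcr_repertoire(obs,
                        sample_id = paste0(attr(blood, "sample_id"), "_tumor"),
                        patient_id = attr(blood, "patient_id"),
                        compartment = "tumor",
                        timepoint = attr(blood, "timepoint"))
  list(repertoire = rep,
       truth = tibble(cdr3_nt = lat$cdr3_nt,
                      shared = c(rep(TRUE, sum(shared)), rep(FALSE, n_priv)),
                      true_freq = lat$true_freq))
}

# ---- planted specificity groups ---------------------------------------------

#' Simulate clones with planted specificity groups and a reference table
#'
#' Plants `planted_motifs` specificity groups of `planted_group_size`
#' clones each among a background of random clones spread over
#' `n_patients` patients. Group members share an interior amino-acid motif
#' and a V gene; each planted motif is carried by `reference_per_motif`
#' reference sequences labelled with a named antigen, alongside random
#' decoy reference pairs. Planted clones are hyper-expanded with elevated
#' probability (`p_hyper_planted` vs `p_hyper_background`), so inferred
#' targets associate with expansion by construction.
#'
#' @param config A [sim_config()].
#' @return List with `clones` (tibble `clone_key`, `cdr3_aa`,
#'   `patient_id`, `v_call`, `expansion`, `group_id`), `reference`
#'   (tibble as from [read_reference_pairs()]), and `truth` (tibble
#'   `group_id`, `motif`, `antigen`).
#' @export
simulate_reference_and_motifs <- function(config = sim_config()) {
  maybe_seed(config)
  aa_alphabet <- setdiff(unique(unname(.codon_table)), c("*", "C", "F"))
  n_bg <- config$n_background_clones
  bg_aa <- random_cdr3_aa(n_bg, config$aa_length_range)

  k <- config$motif_length
  n_groups <- config$planted_motifs
  motifs <- character(0)
  while (length(motifs) < n_groups) {
    motifs <- unique(c(motifs,
                       paste(sample(aa_alphabet, k, replace = TRUE), collapse = "")))
  }
  antigens <- rep_len(config$antigen_names, max(n_groups, 1L))

  seq_with_motif <- function(motif) {
    L <- sample(seq(max(12L, k + 6L), 16L), 1L)
    start <- sample(4:(L - 3L - k + 1L), 1L)
    body <- c("C", sample(aa_alphabet, L - 2L, replace = TRUE), "F")
    body[(start):(start + k - 1L)] <- strsplit(motif, "")[[1]]
    paste(body, collapse = "")
  }

  planted <- vector("list", n_groups)
  group_v <- random_v_calls(n_groups, config$n_v_genes)
  for (g in seq_len(n_groups)) {
    size <- config$planted_group_size
    pats <- sample(paste0("pt", seq_len(config$n_patients)),
                   min(4L, config$n_patients))
    planted[[g]] <- tibble(
      cdr3_aa = vapply(seq_len(size), function(i) seq_with_motif(motifs[g]),
                       character(1)),
      patient_id = rep_len(pats, size),
      v_call = group_v[g],
      group_id = paste0("grp", g)
    )
  }
  planted <- list_rbind(planted)
  clones <- bind_rows(
    tibble(cdr3_aa = bg_aa,
           patient_id = sample(paste0("pt", seq_len(config$n_patients)), n_bg,
                               replace = TRUE),
           v_call = random_v_calls(n_bg, config$n_v_genes),
           group_id = NA_character_),
    planted
  )
  clones <- clones[!duplicated(clones$cdr3_aa), , drop = FALSE]
  clones$clone_key <- paste0("cl", seq_len(nrow(clones)))
  p_hyper <- ifelse(is.na(clones$group_id), config$p_hyper_background,
                    config$p_hyper_planted)
  clones$expansion <- factor(
    ifelse(runif(nrow(clones)) < p_hyper, "hyper_expanded", "non_expanded"),
    levels = c("hyper_expanded", "non_expanded"))

  ref_planted <- purrr::map(seq_len(n_groups), function(g) {
    tibble(
      cdr3_aa = vapply(seq_len(config$reference_per_motif),
                       function(i) seq_with_motif(motifs[g]), character(1)),
      antigen_epitope = paste0("EPI_", g),
      antigen_species = antigens[g],
      score = sample(1:3, config$reference_per_motif, replace = TRUE)
    )
  }) |> list_rbind()
  decoys <- tibble(
    cdr3_aa = random_cdr3_aa(config$n_reference_decoys, config$aa_length_range),
    antigen_epitope = paste0("DECOY_", seq_len(config$n_reference_decoys)),
    antigen_species = sample(config$antigen_names, config$n_reference_decoys,
                             replace = TRUE),
    score = sample(1:3, config$n_reference_decoys, replace = TRUE)
  )
  reference <- bind_rows(ref_planted, decoys) |>
    distinct(.data$cdr3_aa, .data$antigen_epitope, .keep_all = TRUE)
  list(
    clones = as_tibble(clones[, c("clone_key", "cdr3_aa", "patient_id",
                                  "v_call", "expansion", "group_id")]),
    reference = reference,
    truth = tibble(group_id = paste0("grp", seq_len(n_groups)),
                   motif = motifs[seq_len(n_groups)],
                   antigen = antigens[seq_len(n_groups)])
  )
}

# ---- outcomes ---------------------------------------------------------------

#' Simulate clinical outcomes linked to diversity
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hr_low_diversity^I(low group)`, where the low group
#' is the below-median diversity split; censoring times are uniform on
#' `(0, censor_max)` (the default window yields roughly 20% censoring at
#' the default hazard).
#'
#' @param diversity Data frame with `patient_id` and `value` (per-patient
#'   diversity), or a named numeric vector.
#' @param config A [sim_config()].
#' @return Tibble with `patient_id`, `time` (months), `event` (0/1),
#'   `group` (low/high), `diversity`.
#' @export
simulate_cohort_outcomes <- function(diversity, config = sim_config()) {
  maybe_seed(config)
  if (is.numeric(diversity)) {
    diversity <- tibble(patient_id = names(diversity) %||%
                          paste0("p", seq_along(diversity)),
                        value = unname(diversity))
  }
  grp <- median_split(diversity$value)
  h <- config$baseline_hazard *
    ifelse(grp == "low", config$hr_low_diversity, 1)
  t_event <- rexp(nrow(diversity), rate = h)
  t_cens <- runif(nrow(diversity), 0, config$censor_max)
  tibble(
    patient_id = diversity$patient_id,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = grp,
    diversity = diversity$value
  )
}

# ---- cohort -----------------------------------------------------------------

#' Simulate a cross-sectional cohort of repertoires
#'
#' One repertoire per patient with `n_hyperexpanded` drawn uniformly from
#' `cohort_hyper_range`; a patient whose planted hyper-expanded mass
#' exceeds `max_cohort_hyper_mass` is redrawn, keeping cohort-level
#' hyper-expanded fractions within the emulated 0-65% range.
#'
#' @param config A [sim_config()].
#' @param n_patients Number of patients.
#' @return List with `repertoires` (named list of raw `tcr_repertoire`s)
#'   and `truth` (tibble of per-patient truths).
#' @export
simulate_cohort <- function(config = sim_config(), n_patients = 100) {
  maybe_seed(config)
  cfg_i <- config
  cfg_i$seed <- NULL
  reps <- vector("list", n_patients)
  truths <- vector("list", n_patients)
  rng <- config$cohort_hyper_range
  for (i in seq_len(n_patients)) {
    pid <- sprintf("p%03d", i)
    repeat {
      cfg_i$n_hyperexpanded <- sample(seq(rng[1], rng[2]), 1L)
      sim <- try(simulate_repertoire(cfg_i, patient_id = pid), silent = TRUE)
      if (inherits(sim, "try-error")) next
      hyper_mass <- sum(sim$truth$true_freq[sim$truth$class == "hyper"])
      if (hyper_mass <= config$max_cohort_hyper_mass) break
    }
    reps[[i]] <- sim$repertoire
    truths[[i]] <- mutate(sim$truth, patient_id = pid)
    names(reps)[i] <- pid
  }
  list(repertoires = reps, truth = list_rbind(truths))
}
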