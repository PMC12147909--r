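# End-to-end orchestration: simulate (or ingest) -> filter -> diversity ->
# dynamics -> overlap -> annotation -> survival, writing tabular reports.

#' Pipeline configuration
#'
#' All stage parameters in one validated list. Defaults follow the
#' analysis conventions used throughout the package: 0.002 hyper-expansion
#' threshold, 50-read filter, alpha 0.05 for the sharing test, median
#' split for survival. The demo scale (12 patients, 1,200 background
#' clones, 150,000 reads, 3 timepoints) keeps a full run to a couple of
#' minutes. Unknown fields are rejected.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the whole run is deterministic given the
#'   config (identical reruns are byte-identical).
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    n_patients = 12,
    n_timepoints = 3,
    n_background_clones = 1200,
    total_reads = 150000,
    tumor_reads = 40000,
    n_hyperexpanded_range = c(0L, 8L),
    min_reads = 50,
    threshold = 0.002,
    alpha = 0.05,
    n_bins = 8,
    k = c(3, 4),
    enrichment_fold = 10,
    min_count = 3,
    min_seqs = 3,
    min_patients = 3,
    vbias_alpha = 0.05,
    n_reference = 30,
    n_reference_decoys = 40,
    split = "median"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown pipeline_config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (cfg$threshold <= 0 || cfg$threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  if (cfg$min_reads < 0) abort("`min_reads` must be non-negative.")
  structure(cfg, class = "pipeline_config")
}

#' Validate manifest and clinical tables
#'
#' Returns machine-readable diagnostics instead of failing, so callers can
#' decide what is fatal. Checks: required manifest columns, duplicated
#' (patient, compartment, timepoint) rows, duplicated sample ids,
#' unresolvable file paths, and manifest patients missing from the
#' clinical table (those are excluded from survival analysis only).
#'
#' @param manifest Data frame of manifest rows (see [read_manifest()]).
#' @param clinical Optional clinical data frame with `patient_id`.
#' @return Tibble of diagnostics with `level` (error/warning) and
#'   `message`; zero rows when clean.
#' @export
validate_inputs <- function(manifest, clinical = NULL) {
  diags <- list()
  add <- function(level, message) {
    diags[[length(diags) + 1L]] <<- tibble(level = level, message = message)
  }
  need <- c("sample_id", "patient_id", "compartment", "timepoint", "path")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    add("error", sprintf("manifest lacks column(s): %s",
                         paste(missing, collapse = ", ")))
    return(list_rbind(diags))
  }
  key <- paste(manifest$patient_id, manifest$compartment, manifest$timepoint)
  if (anyDuplicated(key)) {
    add("error", sprintf("duplicated (patient, compartment, timepoint): %s",
                         paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (anyDuplicated(manifest$sample_id)) {
    add("error", "duplicated sample_id in manifest")
  }
  unresolved <- manifest$path[!file.exists(manifest$path)]
  if (length(unresolved)) {
    add("error", sprintf("unresolvable path(s): %s",
                         paste(unresolved, collapse = "; ")))
  }
  if (!is.null(clinical)) {
    lost <- setdiff(unique(manifest$patient_id), clinical$patient_id)
    if (length(lost)) {
      add("warning",
          sprintf("patient(s) missing from clinical table (excluded from survival): %s",
                  paste(lost, collapse = ", ")))
    }
  }
  if (!length(diags)) {
    return(tibble(level = character(), message = character()))
  }
  list_rbind(diags)
}

#' Run the full demonstration pipeline
#'
#' Simulates a longitudinal cohort with paired tumor samples, writes the
#' simulated inputs as AIRR TSVs plus a manifest, reads them back, applies
#' the read/productivity filters, and runs every analysis stage, writing
#' `diversity.tsv`, `persistence.tsv`, `sharing_tests.tsv`, `overlap.tsv`,
#' `annotations.tsv`, `survival.json`, and `run_manifest.json` (package
#' version, parameters, input checksums) to the output directory. The run
#' is deterministic given the config: rerunning with the same config
#' produces byte-identical outputs. Outputs are written to a `.partial`
#' file and renamed on completion, so an interrupted stage leaves its
#' partial output marked.
#'
#' @param config A [pipeline_config()].
#' @return Named list of output file paths, invisibly; the report tables
#'   are also returned in the `tables` element.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(config$out_dir, "input")
  dir.create(input_dir, showWarnings = FALSE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "clonotrace_pipeline_error", parent = e)
    })
  }
  emit_tsv <- function(x, name) {
    path <- file.path(config$out_dir, name)
    partial <- paste0(path, ".partial")
    readr::write_tsv(x, partial, progress = FALSE)
    file.rename(partial, path)
    path
  }

  # -- simulate inputs and write them as AIRR files + manifest
  sim <- stage("simulate", {
    scfg <- sim_config(
      n_background_clones = config$n_background_clones,
      total_reads = config$total_reads,
      tumor_reads = config$tumor_reads,
      n_timepoints = config$n_timepoints
    )
    rows <- list()
    rng <- config$n_hyperexpanded_range
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("pt%02d", i)
      scfg$n_hyperexpanded <- sample(seq(rng[1], rng[2]), 1L)
      ser <- simulate_series(scfg, patient_id = pid)$series
      tum <- simulate_paired_tumor(ser[[1]], scfg)$repertoire
      for (r in c(unclass(ser), list(tum))) {
        sid <- attr(r, "sample_id")
        path <- file.path(input_dir, paste0(sid, ".tsv"))
        write_airr(r, path)
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sid, patient_id = pid,
          compartment = attr(r, "compartment"),
          timepoint = attr(r, "timepoint"), path = path
        )
      }
    }
    manifest <- list_rbind(rows)
    readr::write_csv(manifest, file.path(input_dir, "manifest.csv"),
                     progress = FALSE)
    manifest
  })

  # -- ingest + filter
  reps <- stage("ingest", {
    diags <- validate_inputs(sim)
    if (any(diags$level == "error")) {
      abort(paste(diags$message, collapse = "; "))
    }
    out <- purrr::pmap(sim, function(sample_id, patient_id, compartment,
                                     timepoint, path) {
      filter_clones(read_airr(path, sample_id = sample_id,
                              patient_id = patient_id,
                              compartment = compartment,
                              timepoint = timepoint),
                    min_reads = config$min_reads)
    })
    setNames(out, sim$sample_id)
  })

  # -- diversity
  diversity_tbl <- stage("diversity", {
    purrr::map(reps, diversity_summary, threshold = config$threshold) |>
      list_rbind() |>
      left_join(sim[, c("sample_id", "patient_id", "compartment", "timepoint")],
                by = "sample_id")
  })
  out_div <- emit_tsv(diversity_tbl, "diversity.tsv")

  blood_series <- stage("series", {
    pids <- unique(sim$patient_id)
    setNames(lapply(pids, function(pid) {
      ids <- sim$sample_id[sim$patient_id == pid & sim$compartment == "blood"]
      patient_series(reps[ids])
    }), pids)
  })

  # -- persistence
  persistence_tbl <- stage("persistence", {
    purrr::imap(blood_series, function(s, pid) {
      mutate(classify_persistence(s), patient_id = pid, .before = 1)
    }) |> list_rbind()
  })
  out_pers <- emit_tsv(persistence_tbl, "persistence.tsv")

  # -- sharing tests: baseline vs last blood timepoint per patient
  sharing_tbl <- stage("sharing", {
    purrr::imap(blood_series, function(s, pid) {
      mutate(binomial_sharing_test(s[[1]], s[[length(s)]],
                                   alpha = config$alpha),
             patient_id = pid, .before = 1)
    }) |> list_rbind()
  })
  out_shar <- emit_tsv(sharing_tbl, "sharing_tests.tsv")

  # -- blood-tumor overlap
  overlap_tbl <- stage("overlap", {
    purrr::map(unique(sim$patient_id), function(pid) {
      blood <- blood_series[[pid]][[1]]
      tum_id <- sim$sample_id[sim$patient_id == pid & sim$compartment == "tumor"]
      mutate(overlap_summary(blood, reps[[tum_id[1]]]), patient_id = pid,
             .before = 1)
    }) |> list_rbind()
  })
  out_ovl <- emit_tsv(overlap_tbl, "overlap.tsv")

  # -- specificity annotation on pooled baseline blood clones; the
  #    reference emulates a curated database: a sample of cohort sequences
  #    labelled with named antigens plus random decoys
  annotation_tbl <- stage("annotate", {
    pooled <- purrr::imap(blood_series, function(s, pid) {
      b <- s[[1]]
      tibble(clone_key = paste(pid, b$cdr3_nt, sep = "|"),
             cdr3_nt = b$cdr3_nt, cdr3_aa = b$cdr3_aa,
             v_call = b$v_call, patient_id = pid,
             frequency = b$frequency)
    }) |> list_rbind()
    hits <- pooled[sample(nrow(pooled), min(config$n_reference, nrow(pooled))), ]
    reference <- bind_rows(
      tibble(cdr3_aa = hits$cdr3_aa,
             antigen_epitope = paste0("EPI", seq_len(nrow(hits))),
             antigen_species = rep_len(c("CMV", "EBV", "InfluenzaA"), nrow(hits)),
             score = 1L),
      tibble(cdr3_aa = random_cdr3_aa(config$n_reference_decoys),
             antigen_epitope = paste0("DEC", seq_len(config$n_reference_decoys)),
             antigen_species = rep_len(c("CMV", "EBV", "InfluenzaA"),
                                       config$n_reference_decoys),
             score = 1L)
    )
    ann <- annotate_two_step(pooled, reference, k = config$k,
                             enrichment_fold = config$enrichment_fold,
                             min_count = config$min_count,
                             min_seqs = config$min_seqs,
                             min_patients = config$min_patients,
                             vbias_alpha = config$vbias_alpha)
    tidy(ann)
  })
  out_ann <- emit_tsv(annotation_tbl, "annotations.tsv")

  # -- survival on baseline blood diversity
  survival_out <- stage("survival", {
    base <- diversity_tbl[diversity_tbl$compartment == "blood" &
                            diversity_tbl$timepoint ==
                              diversity_tbl$timepoint[1], ]
    base <- distinct(base, .data$patient_id, .keep_all = TRUE)
    clinical <- simulate_cohort_outcomes(
      tibble(patient_id = base$patient_id, value = base$normalized_shannon)
    )
    test <- survival_group_test(clinical, clinical$group)
    cox <- cox_fit(cbind(clinical, group_low = as.integer(clinical$group == "low")),
                   "group_low")
    list(
      n_patients = nrow(clinical),
      split = config$split,
      group_test = as.list(test),
      cox = lapply(seq_len(nrow(cox)), function(i) as.list(cox[i, ]))
    )
  })
  out_surv <- file.path(config$out_dir, "survival.json")
  jsonlite::write_json(survival_out, paste0(out_surv, ".partial"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  file.rename(paste0(out_surv, ".partial"), out_surv)

  # -- run manifest (no timestamp: reruns must be byte-identical)
  manifest_out <- file.path(config$out_dir, "run_manifest.json")
  checksums <- tools::md5sum(sort(sim$path))
  jsonlite::write_json(
    list(
      package = "clonotrace",
      version = as.character(utils::packageVersion("clonotrace")),
      parameters = unclass(config),
      input_checksums = as.list(checksums)
    ),
    paste0(manifest_out, ".partial"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE
  )
  file.rename(paste0(manifest_out, ".partial"), manifest_out)

  invisible(list(
    files = c(diversity = out_div, persistence = out_pers,
              sharing_tests = out_shar, overlap = out_ovl,
              annotations = out_ann, survival = out_surv,
              run_manifest = manifest_out),
    tables = list(diversity = diversity_tbl, persistence = persistence_tbl,
                  sharing_tests = sharing_tbl, overlap = overlap_tbl,
                  annotations = annotation_tbl),
    survival = survival_out
  ))
}
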