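# Specificity grouping of CDR3 amino-acid sequences and antigen annotation.
#
# The grouping engine is a deliberately simplified stand-in for full
# specificity-clustering tools such as GLIPH2: local similarity is captured
# by interior k-mers (trimming 3 residues from each end of the CDR3) gated
# by fold-enrichment over a naive background, and global similarity by
# groups of equal-length sequences within Hamming distance 1. All
# downstream cluster filtering and the two-step annotation logic operate on
# these clusters. Clone frequency plays no role anywhere in this module.

#' Interior k-mer motifs of a CDR3 amino-acid sequence
#'
#' Returns all contiguous k-mers of the sequence interior, obtained by
#' trimming 3 residues from each end (the germline-encoded flanks carry
#' little specificity information). Sequences shorter than `k + 6` have no
#' interior k-mers; sequences of 25 or more residues are of abnormal length
#' and are excluded from motif analysis.
#'
#' @param cdr3_aa A single amino-acid sequence.
#' @param k Motif length, typically 3 or 4.
#' @return Character vector of distinct motifs (possibly empty).
#' @examples
#' extract_motifs("CASSLGQAYEQYF", k = 3) # k-mers of interior "SLGQAYE"
#' @export
extract_motifs <- function(cdr3_aa, k = 3) {
  stopifnot(length(cdr3_aa) == 1L)
  n <- nchar(cdr3_aa)
  if (n >= 25L || n < k + 6L) return(character())
  interior <- substr(cdr3_aa, 4L, n - 3L)
  m <- nchar(interior)
  unique(substring(interior, 1:(m - k + 1L), k:m))
}

#' Motif background frequencies from a naive repertoire
#'
#' Tabulates interior k-mer frequencies (fraction of distinct sequences
#' containing each motif) over a pool of CDR3 amino-acid sequences, for use
#' as the enrichment background in [build_clusters()]. `default_motif_background()`
#' generates the pool from the package's synthetic naive-repertoire
#' generator with a fixed internal seed (20,000 sequences), so the table is
#' deterministic and reproducible; it is cached per `k` within a session.
#' Motifs absent from the background are assigned the pseudo-frequency
#' `0.5 / n_sequences` when gating.
#'
#' @param sequences Character vector of CDR3 amino-acid sequences.
#' @param k Motif length.
#' @return Tibble with `motif` and `freq`, with attributes `n_seqs` and
#'   `pseudo`.
#' @export
motif_background <- function(sequences, k = 3) {
  seqs <- unique(sequences)
  tab <- motif_seq_table(seqs, k)
  counts <- table(tab$motif)
  out <- tibble(motif = names(counts), freq = as.numeric(counts) / length(seqs))
  attr(out, "n_seqs") <- length(seqs)
  attr(out, "pseudo") <- 0.5 / length(seqs)
  out
}

.bg_cache <- new.env(parent = emptyenv())

#' @rdname motif_background
#' @param n Number of synthetic naive sequences in the default pool.
#' @export
default_motif_background <- function(k = 3, n = 20000) {
  key <- sprintf("k%d_n%d", k, n)
  if (!is.null(.bg_cache[[key]])) return(.bg_cache[[key]])
  seqs <- with_preserved_seed(902140 + k, random_cdr3_aa(n))
  bg <- motif_background(seqs, k)
  .bg_cache[[key]] <- bg
  bg
}

# long table (motif, seq) over distinct sequences; k-mer extraction
# vectorised across sequences
motif_seq_table <- function(seqs, k) {
  n <- nchar(seqs)
  ok <- which(n < 25L & n >= k + 6L)
  if (!length(ok)) return(tibble(motif = character(), seq = character()))
  pieces <- lapply(ok, function(i) {
    interior <- substr(seqs[i], 4L, n[i] - 3L)
    m <- nchar(interior)
    unique(substring(interior, 1:(m - k + 1L), k:m))
  })
  tibble(motif = unlist(pieces, use.names = FALSE),
         seq = rep(seqs[ok], lengths(pieces)))
}

#' Build specificity clusters from CDR3 amino-acid sequences
#'
#' Groups clones by local and global sequence similarity, independently of
#' clone frequency. Local clusters are keyed by an interior k-mer motif
#' whose frequency among the input sequences is at least `enrichment_fold`
#' times its background frequency and that occurs in at least `min_count`
#' distinct sequences. Global clusters are groups of two or more
#' equal-length sequences identical up to one position (Hamming distance 1
#' around a shared pattern). A clone may belong to several clusters.
#'
#' @param clones Data frame with `cdr3_aa` (required) and optionally
#'   `patient_id`, `v_call`, `cdr3_nt`, and a logical `is_reference` column
#'   (used by [annotate_two_step()]).
#' @param background Motif background table from [motif_background()]; one
#'   per `k` as a list, or `NULL` to use [default_motif_background()].
#' @param k Integer vector of motif lengths (default `c(3, 4)`).
#' @param enrichment_fold Minimum fold enrichment over background (default 10).
#' @param min_count Minimum distinct sequences in a local cluster (default 3).
#' @return A tibble of clusters: `cluster_id`, `type` (local/global),
#'   `motif`, `n_unique_seqs`, `n_patients`, `n_reference`, and a `members`
#'   list-column of per-clone rows. The cohort V-gene usage table is
#'   attached as attribute `v_background`.
#' @export
build_clusters <- function(clones, background = NULL, k = c(3, 4),
                           enrichment_fold = 10, min_count = 3) {
  if (nrow(clones) == 0L) return(empty_clusters())
  x <- as_tibble(clones)
  if (!"cdr3_aa" %in% names(x)) abort("`clones` needs a `cdr3_aa` column.")
  if (!"patient_id" %in% names(x)) x$patient_id <- "patient"
  if (!"v_call" %in% names(x)) x$v_call <- ""
  if (!"is_reference" %in% names(x)) x$is_reference <- FALSE
  if (!"clone_key" %in% names(x)) {
    x$clone_key <- if ("cdr3_nt" %in% names(x)) x$cdr3_nt else
      paste(x$cdr3_aa, x$patient_id, sep = "|")
  }
  x <- x[nchar(x$cdr3_aa) < 25L, , drop = FALSE]
  if (nrow(x) == 0L) return(empty_clusters())

  seqs <- unique(x$cdr3_aa)
  n_seqs <- length(seqs)

  clusters <- list()
  for (kk in k) {
    bg <- if (is.null(background)) default_motif_background(kk)
          else if (is.data.frame(background)) background
          else background[[as.character(kk)]]
    tab <- motif_seq_table(seqs, kk)
    if (!nrow(tab)) next
    counts <- table(tab$motif)
    freq <- as.numeric(counts) / n_seqs
    bg_freq <- bg$freq[match(names(counts), bg$motif)]
    bg_freq[is.na(bg_freq)] <- attr(bg, "pseudo")
    pass <- counts >= min_count & freq >= enrichment_fold * bg_freq
    keep <- names(counts)[pass]
    if (length(keep)) {
      by_motif <- split(tab$seq, tab$motif)[keep]
      clusters <- c(clusters, lapply(keep, function(m) {
        list(cluster_id = paste0("L", kk, ":", m), type = "local", motif = m,
             seqs = by_motif[[m]])
      }))
    }
  }

  # identical sequences carried by different clones form a global group of
  # their own (Hamming distance 0)
  seq_counts <- table(x$cdr3_aa)
  multi <- names(seq_counts)[seq_counts >= 2L]
  if (length(multi)) {
    clusters <- c(clusters, lapply(multi, function(s) {
      list(cluster_id = paste0("G:", nchar(s), ":=", s), type = "global",
           motif = s, seqs = s)
    }))
  }

  # global: equal-length sequences within Hamming distance 1 share a
  # one-position wildcard pattern; duplicate member sets are collapsed
  pat_tab <- wildcard_patterns(seqs)
  by_pat <- split(pat_tab$seq, pat_tab$pattern)
  by_pat <- by_pat[lengths(by_pat) >= 2L]
  if (length(by_pat)) {
    member_key <- vapply(by_pat, function(s) paste(sort(s), collapse = ";"),
                         character(1))
    first <- !duplicated(member_key)
    ids <- names(by_pat)[first]
    clusters <- c(clusters, lapply(ids, function(p) {
      list(cluster_id = paste0("G:", p), type = "global", motif = p,
           seqs = by_pat[[p]])
    }))
  }

  if (!length(clusters)) return(empty_clusters(v_background_of(x)))
  rows <- lapply(clusters, function(cl) {
    mem <- x[x$cdr3_aa %in% cl$seqs,
             c("clone_key", "cdr3_aa", "patient_id", "v_call", "is_reference")]
    tibble(
      cluster_id = cl$cluster_id, type = cl$type, motif = cl$motif,
      n_unique_seqs = length(unique(mem$cdr3_aa[!mem$is_reference])),
      n_patients = length(unique(mem$patient_id[!mem$is_reference])),
      n_reference = sum(mem$is_reference),
      members = list(mem)
    )
  })
  out <- list_rbind(rows) |> arrange(.data$cluster_id)
  attr(out, "v_background") <- v_background_of(x)
  out
}

empty_clusters <- function(v_background = NULL) {
  out <- tibble(cluster_id = character(), type = character(), motif = character(),
                n_unique_seqs = integer(), n_patients = integer(),
                n_reference = integer(), members = list())
  attr(out, "v_background") <- v_background
  out
}

# cohort V-gene usage over distinct non-reference sequences
v_background_of <- function(x) {
  d <- distinct(x[!x$is_reference & nzchar(x$v_call), c("cdr3_aa", "v_call")])
  if (!nrow(d)) return(NULL)
  tab <- table(d$v_call)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

# all one-position wildcard replacements of each distinct sequence
wildcard_patterns <- function(seqs) {
  n <- nchar(seqs)
  pieces <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]; L <- n[i]
    vapply(seq_len(L), function(p) {
      paste0(substr(s, 1, p - 1L), ".", substr(s, p + 1L, L))
    }, character(1))
  })
  tibble(pattern = paste0(n[rep(seq_along(seqs), n)], ":",
                          unlist(pieces, use.names = FALSE)),
         seq = rep(seqs, n))
}

#' Filter clusters to high confidence
#'
#' Retains clusters with at least `min_seqs` unique member sequences from
#' at least `min_patients` patients, and with significant V-gene usage
#' bias: a one-sided exact binomial test that the modal V gene among member
#' sequences exceeds its cohort-background proportion, retained when
#' `p < vbias_alpha`. When member V calls are unavailable the V-bias test
#' is skipped with a warning.
#'
#' @param clusters Output of [build_clusters()].
#' @param min_seqs,min_patients Minimum unique sequences and patients.
#' @param vbias_alpha Significance level of the V-bias test.
#' @param v_background Named vector of cohort V-gene proportions; defaults
#'   to the table attached by [build_clusters()].
#' @return The filtered cluster tibble, with added `v_modal` and `v_bias_p`.
#' @export
filter_high_confidence <- function(clusters, min_seqs = 3, min_patients = 3,
                                   vbias_alpha = 0.05, v_background = NULL) {
  v_background <- v_background %||% attr(clusters, "v_background")
  out <- clusters[clusters$n_unique_seqs >= min_seqs &
                    clusters$n_patients >= min_patients, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  if (is.null(v_background)) {
    warn("No V calls available; V-bias filter skipped.")
    out$v_modal <- NA_character_
    out$v_bias_p <- NA_real_
    return(out)
  }
  stats_ <- purrr::map(out$members, function(mem) {
    d <- distinct(mem[!mem$is_reference & nzchar(mem$v_call),
                      c("cdr3_aa", "v_call")])
    if (!nrow(d)) return(tibble(v_modal = NA_character_, v_bias_p = NA_real_))
    tab <- sort(table(d$v_call), decreasing = TRUE)
    v <- names(tab)[1]
    xx <- as.integer(tab[1])
    nn <- nrow(d)
    p0 <- unname(v_background[v])
    if (is.na(p0)) p0 <- 1 / max(length(v_background), 1L)
    tibble(v_modal = v, v_bias_p = 1 - pbinom(xx - 1L, nn, p0))
  }) |> list_rbind()
  out$v_modal <- stats_$v_modal
  out$v_bias_p <- stats_$v_bias_p
  keep <- !is.na(out$v_bias_p) & out$v_bias_p < vbias_alpha
  out[keep, , drop = FALSE]
}

#' Two-step antigen annotation of specificity clusters
#'
#' Implements the two-step annotation logic: (1) cluster the patient clones
#' alone and keep high-confidence clusters; (2) recluster the patient
#' clones together with a reference set of CDR3-antigen pairs, so that the
#' reference cannot bias the original cluster formation. Clusters found in
#' both runs (matched by cluster key) whose run-2 counterpart co-groups at
#' least one reference sequence are annotated with the reference antigen;
#' with multiple antigens the most common named antigen wins, ties broken
#' lexicographically and flagged. Member clones inherit their cluster's
#' antigen; a clone in several annotated clusters takes the antigen of the
#' cluster with most members.
#'
#' @param clones Data frame of patient clones (see [build_clusters()]).
#' @param reference Reference pairs from [read_reference_pairs()] (columns
#'   `cdr3_aa`, `antigen_species`; an empty table yields zero annotations
#'   but identical step-1 clusters).
#' @param k,background,enrichment_fold,min_count Passed to [build_clusters()].
#' @param min_seqs,min_patients,vbias_alpha Passed to [filter_high_confidence()].
#' @return An object of class `tcr_annotation`: list with `clusters`
#'   (step-1 high-confidence clusters with `inferred_antigen`,
#'   `antigen_tie`), `clones` (per-clone `clone_key`, `cdr3_aa`,
#'   `patient_id`, `inferred_antigen`), and `n_reference`.
#' @export
annotate_two_step <- function(clones, reference, k = c(3, 4), background = NULL,
                              enrichment_fold = 10, min_count = 3,
                              min_seqs = 3, min_patients = 3,
                              vbias_alpha = 0.05) {
  run1 <- build_clusters(clones, background = background, k = k,
                         enrichment_fold = enrichment_fold,
                         min_count = min_count)
  run1 <- filter_high_confidence(run1, min_seqs = min_seqs,
                                 min_patients = min_patients,
                                 vbias_alpha = vbias_alpha)
  run1$inferred_antigen <- NA_character_
  run1$antigen_tie <- FALSE

  ref_ok <- !is.null(reference) && nrow(reference) > 0L
  if (ref_ok && nrow(run1) > 0L) {
    ref_rows <- tibble(
      cdr3_aa = reference$cdr3_aa,
      patient_id = "reference",
      v_call = "",
      is_reference = TRUE,
      clone_key = paste0("ref|", seq_len(nrow(reference))),
      antigen_species = reference$antigen_species
    )
    pat <- as_tibble(clones)
    if (!"patient_id" %in% names(pat)) pat$patient_id <- "patient"
    if (!"v_call" %in% names(pat)) pat$v_call <- ""
    pat$is_reference <- FALSE
    pat$antigen_species <- NA_character_
    if (!"clone_key" %in% names(pat)) {
      pat$clone_key <- if ("cdr3_nt" %in% names(pat)) pat$cdr3_nt else
        paste(pat$cdr3_aa, pat$patient_id, sep = "|")
    }
    cols <- c("cdr3_aa", "patient_id", "v_call", "is_reference", "clone_key",
              "antigen_species")
    run2 <- build_clusters(bind_rows(pat[, cols], ref_rows[, cols]),
                           background = background, k = k,
                           enrichment_fold = enrichment_fold,
                           min_count = min_count)
    antigen_by_seq <- setNames(ref_rows$antigen_species, ref_rows$clone_key)
    run2_ann <- run2[run2$n_reference > 0L, , drop = FALSE]
    if (nrow(run2_ann) > 0L) {
      inferred <- purrr::map(run2_ann$members, function(mem) {
        ag <- antigen_by_seq[mem$clone_key[mem$is_reference]]
        tab <- sort(table(ag), decreasing = TRUE)
        top <- names(tab)[order(-tab, names(tab))]
        tibble(antigen = top[1],
               tie = sum(tab == tab[top[1]]) > 1L)
      }) |> list_rbind()
      hit <- match(run1$cluster_id, run2_ann$cluster_id)
      found <- !is.na(hit)
      run1$inferred_antigen[found] <- inferred$antigen[hit[found]]
      run1$antigen_tie[found] <- inferred$tie[hit[found]]
    }
  }

  clone_ann <- annotate_members(run1)
  structure(
    list(clusters = run1, clones = clone_ann,
         n_reference = if (ref_ok) nrow(reference) else 0L),
    class = "tcr_annotation"
  )
}

# per-clone antigen from annotated clusters: largest cluster wins,
# ties broken by lexicographic antigen then cluster id
annotate_members <- function(clusters) {
  ann <- clusters[!is.na(clusters$inferred_antigen), , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(tibble(clone_key = character(), cdr3_aa = character(),
                  patient_id = character(), inferred_antigen = character()))
  }
  long <- purrr::pmap(list(ann$members, ann$inferred_antigen,
                           ann$n_unique_seqs, ann$cluster_id),
                      function(mem, ag, nseq, cid) {
    mem <- mem[!mem$is_reference, c("clone_key", "cdr3_aa", "patient_id")]
    mem$inferred_antigen <- ag
    mem$cluster_size <- nseq
    mem$cluster_id <- cid
    mem
  }) |> list_rbind()
  long |>
    arrange(desc(.data$cluster_size), .data$inferred_antigen, .data$cluster_id) |>
    distinct(.data$clone_key, .keep_all = TRUE) |>
    select("clone_key", "cdr3_aa", "patient_id", "inferred_antigen")
}

#' @export
print.tcr_annotation <- function(x, ...) {
  cat(sprintf("<tcr_annotation> %d high-confidence clusters (%d annotated), %d annotated clones\n",
              nrow(x$clusters), sum(!is.na(x$clusters$inferred_antigen)),
              nrow(x$clones)))
  invisible(x)
}

#' @rdname annotate_two_step
#' @param x A `tcr_annotation`.
#' @param ... Unused.
#' @method tidy tcr_annotation
#' @export
tidy.tcr_annotation <- function(x, ...) x$clones

#' @rdname annotate_two_step
#' @method glance tcr_annotation
#' @export
glance.tcr_annotation <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_annotated_clusters = sum(!is.na(x$clusters$inferred_antigen)),
         n_annotated_clones = nrow(x$clones),
         n_reference = x$n_reference)
}

#' Association between inferred targets and clonal expansion
#'
#' Two analyses on annotated clones: (i) a 2x2 association between having
#' an inferred antigen target and being hyper-expanded, reporting the
#' sample odds ratio (cross-product ratio) and the two-sided Fisher exact
#' p-value; (ii) per-antigen one-sided Fisher exact tests for target
#' enrichment among hyper-expanded clones, Benjamini-Hochberg adjusted.
#' With an empty table margin the odds ratio is undefined and reported as
#' `NA` (or `Inf` with a direction note when only one off-diagonal cell is
#' empty).
#'
#' @param annotation A `tcr_annotation` from [annotate_two_step()].
#' @param expansion Data frame with `clone_key` and `expansion`
#'   (`hyper_expanded` / `non_expanded`) covering every clone.
#' @return List with `overall` (one-row tibble: counts, `odds_ratio`,
#'   `p_value`, `note`) and `per_antigen` (tibble: `antigen`, counts,
#'   `p_value`, `p_adjusted`).
#' @export
expansion_target_association <- function(annotation, expansion) {
  stopifnot(inherits(annotation, "tcr_annotation"))
  need <- c("clone_key", "expansion")
  if (!all(need %in% names(expansion))) {
    abort("`expansion` needs columns `clone_key` and `expansion`.")
  }
  exp_tbl <- as_tibble(expansion)
  ann <- annotation$clones
  exp_tbl$has_target <- exp_tbl$clone_key %in% ann$clone_key
  exp_tbl$antigen <- ann$inferred_antigen[match(exp_tbl$clone_key, ann$clone_key)]
  hyper <- exp_tbl$expansion == "hyper_expanded"

  a <- sum(hyper & exp_tbl$has_target)
  b <- sum(hyper & !exp_tbl$has_target)
  c_ <- sum(!hyper & exp_tbl$has_target)
  d <- sum(!hyper & !exp_tbl$has_target)
  note <- NA_character_
  if ((a + b) == 0L || (c_ + d) == 0L || (a + c_) == 0L || (b + d) == 0L) {
    or <- NA_real_
    note <- "odds ratio undefined: empty table margin"
    pv <- NA_real_
  } else {
    or <- (a * d) / (b * c_)
    if (!is.finite(or)) note <- "odds ratio unbounded: zero off-diagonal cell"
    pv <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))$p.value
  }
  overall <- tibble(
    n_hyper_target = a, n_hyper_untargeted = b,
    n_non_target = c_, n_non_untargeted = d,
    odds_ratio = or, p_value = pv, note = note
  )

  antigens <- sort(unique(stats::na.omit(exp_tbl$antigen)))
  per_antigen <- purrr::map(antigens, function(ag) {
    is_ag <- !is.na(exp_tbl$antigen) & exp_tbl$antigen == ag
    tab <- matrix(c(sum(hyper & is_ag), sum(hyper & !is_ag),
                    sum(!hyper & is_ag), sum(!hyper & !is_ag)),
                  nrow = 2, byrow = TRUE)
    tibble(antigen = ag,
           n_hyper = tab[1, 1], n_non = tab[2, 1],
           p_value = fisher.test(tab, alternative = "greater")$p.value)
  }) |> list_rbind()
  if (nrow(per_antigen)) {
    per_antigen$p_adjusted <- p.adjust(per_antigen$p_value, method = "BH")
  } else {
    per_antigen <- tibble(antigen = character(), n_hyper = integer(),
                          n_non = integer(), p_value = numeric(),
                          p_adjusted = numeric())
  }
  list(overall = overall, per_antigen = per_antigen)
}
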