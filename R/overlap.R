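#' Clones common to two repertoires
#'
#' Intersects two repertoires on the CDR3 nucleotide key and reports the
#' per-clone frequencies on each side.
#'
#' @param a,b `tcr_repertoire` objects (or coercible data frames).
#' @return Tibble with `cdr3_nt`, `freq_a`, `freq_b`, one row per common
#'   clone (possibly zero rows).
#' @export
common_clones <- function(a, b) {
  a <- as_tcr_repertoire(a); b <- as_tcr_repertoire(b)
  inner_join(
    tibble(cdr3_nt = a$cdr3_nt, freq_a = a$frequency),
    tibble(cdr3_nt = b$cdr3_nt, freq_b = b$frequency),
    by = "cdr3_nt"
  )
}

#' Overlap summary between two repertoires
#'
#' The number of common clones and the total frequency mass they carry in
#' each repertoire (the relative size of common clones).
#'
#' @inheritParams common_clones
#' @return One-row tibble: `sample_a`, `sample_b`, `n_common`,
#'   `mass_common_in_a`, `mass_common_in_b`.
#' @export
overlap_summary <- function(a, b) {
  a <- as_tcr_repertoire(a); b <- as_tcr_repertoire(b)
  shared <- common_clones(a, b)
  tibble(
    sample_a = attr(a, "sample_id"),
    sample_b = attr(b, "sample_id"),
    n_common = nrow(shared),
    mass_common_in_a = sum(shared$freq_a),
    mass_common_in_b = sum(shared$freq_b)
  )
}

#' Percentage of shared clones by clone-size bin
#'
#' Bins the clones of the reference repertoire uniformly in log10 frequency
#' and reports, per bin, the percentage of clones also present in the other
#' repertoire. The reported `upper` edge is the bin end on the log10 scale
#' (the natural x-coordinate when plotting). Empty bins are reported with
#' `NA` rather than zero.
#'
#' @inheritParams common_clones
#' @param n_bins Number of bins (at least 2).
#' @param reference Which repertoire's clones are binned: `"a"` or `"b"`.
#' @return Tibble with `bin`, `lower`, `upper`, `n_clones`, `n_common`,
#'   `pct_common`.
#' @export
sharing_by_size_bin <- function(a, b, n_bins = 10, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (!is.numeric(n_bins) || n_bins < 2) abort("`n_bins` must be >= 2.")
  a <- as_tcr_repertoire(a); b <- as_tcr_repertoire(b)
  ref <- if (reference == "a") a else b
  other <- if (reference == "a") b else a
  lf <- log10(ref$frequency)
  edges <- bin_edges(lf, n_bins)
  idx <- assign_bins(lf, edges)
  shared <- ref$cdr3_nt %in% other$cdr3_nt
  n_in <- tabulate(idx, n_bins)
  n_sh <- tabulate(idx[shared], n_bins)
  tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    n_clones = as.integer(n_in),
    n_common = as.integer(n_sh),
    pct_common = ifelse(n_in > 0, 100 * n_sh / n_in, NA_real_)
  )
}

#' Size correlation of shared clones with enrichment coloring
#'
#' For clones shared between two samples (optionally restricted to clones
#' hyper-expanded in `a`, or to an explicit clone set such as the persistent
#' clones of a series), computes the Spearman correlation of log10
#' frequencies, an ordinary least-squares fit of `log10(freq_b)` on
#' `log10(freq_a)` (the identity line `slope = 1, intercept = 0` is the
#' random-sharing expectation), and per-clone enrichment/depletion calls
#' from [binomial_sharing_test()] with `a` as baseline.
#'
#' @inheritParams common_clones
#' @param hyperexpanded_only Restrict to clones hyper-expanded in `a`.
#' @param threshold Hyper-expansion threshold (default 0.002).
#' @param restrict Optional character vector of clone keys to retain
#'   (e.g. persistent clones).
#' @param alpha Significance level for the enrichment calls.
#' @return An object of class `shared_size_cor`: list with `clones`
#'   (per-clone tibble incl. `call`), `rho`, `rho_p`, `slope`, `intercept`,
#'   `n`. With fewer than 3 shared clones after restriction the correlation
#'   and fit are `NA` with a warning. Use [tidy()] / [glance()] for tabular
#'   views.
#' @export
shared_size_correlation <- function(a, b, hyperexpanded_only = FALSE,
                                    threshold = 0.002, restrict = NULL,
                                    alpha = 0.05) {
  a <- as_tcr_repertoire(a); b <- as_tcr_repertoire(b)
  shared <- common_clones(a, b)
  if (hyperexpanded_only) shared <- shared[shared$freq_a > threshold, ]
  if (!is.null(restrict)) shared <- shared[shared$cdr3_nt %in% restrict, ]
  tests <- binomial_sharing_test(a, b, alpha = alpha) |>
    select("cdr3_nt", "p_value", "p_bonferroni", "call")
  shared <- left_join(shared, tests, by = "cdr3_nt")
  out <- list(clones = shared, n = nrow(shared),
              rho = NA_real_, rho_p = NA_real_,
              slope = NA_real_, intercept = NA_real_)
  if (nrow(shared) < 3L) {
    warn("Fewer than 3 shared clones after restriction; correlation omitted.")
  } else {
    la <- log10(shared$freq_a); lb <- log10(shared$freq_b)
    ct <- suppressWarnings(cor.test(la, lb, method = "spearman", exact = FALSE))
    fit <- lm(lb ~ la)
    out$rho <- unname(ct$estimate)
    out$rho_p <- ct$p.value
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
  }
  structure(out, class = "shared_size_cor")
}

#' @export
print.shared_size_cor <- function(x, ...) {
  cat(sprintf("<shared_size_cor> %d shared clones; Spearman rho = %.3f; fit: slope %.3f, intercept %.3f\n",
              x$n, x$rho, x$slope, x$intercept))
  invisible(x)
}

#' @rdname shared_size_correlation
#' @param x A `shared_size_cor` object.
#' @param ... Unused.
#' @method tidy shared_size_cor
#' @export
tidy.shared_size_cor <- function(x, ...) x$clones

#' @rdname shared_size_correlation
#' @method glance shared_size_cor
#' @export
glance.shared_size_cor <- function(x, ...) {
  tibble(n = x$n, rho = x$rho, rho_p = x$rho_p,
         slope = x$slope, intercept = x$intercept,
         n_enriched = sum(x$clones$call == "enriched", na.rm = TRUE),
         n_depleted = sum(x$clones$call == "depleted", na.rm = TRUE))
}
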