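#' Normalized Shannon diversity (Pielou evenness) of a repertoire
#'
#' Computes `-1/log(N) * sum(p_i * log(p_i))`, where `N` is the number of
#' clones and `p_i` their frequencies. The value lies in `[0, 1]`: 1 for a
#' perfectly even repertoire, approaching 0 when a single clone dominates.
#' The base of the logarithm cancels; natural logs are used internally. A
#' single-clone repertoire returns 0 by convention (the limit of a maximally
#' uneven repertoire; the normalizing `log(1)` is zero).
#'
#' @param x A `tcr_repertoire`, a data frame with a `frequency` column, or a
#'   numeric vector of frequencies summing to 1.
#' @return A number in `[0, 1]`.
#' @examples
#' normalized_shannon(rep(0.25, 4)) # 1
#' normalized_shannon(c(0.5, 0.25, 0.125, 0.125)) # 0.875
#' @export
normalized_shannon <- function(x) {
  p <- rep_frequencies(x)
  n <- length(p)
  if (n == 1L) return(0)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n)
}

#' Classify clones by expansion status
#'
#' Labels each clone `hyper_expanded` when its frequency strictly exceeds
#' `threshold` (default 0.002, i.e. 0.2% of the repertoire) and
#' `non_expanded` otherwise. A clone exactly at the threshold is
#' non-expanded: hyper-expansion means frequency *exceeding* the threshold,
#' and equality is assigned to the non-expanded class.
#'
#' @param rep A `tcr_repertoire` or data frame with a `frequency` column.
#' @param threshold Frequency threshold (default 0.002).
#' @return The input as a tibble with an added `expansion` factor column
#'   (levels `hyper_expanded`, `non_expanded`).
#' @export
classify_expansion <- function(rep, threshold = 0.002) {
  f <- rep_frequencies(rep)
  out <- if (is.data.frame(rep)) as_tibble(rep) else tibble(frequency = f)
  out$expansion <- factor(ifelse(f > threshold, "hyper_expanded", "non_expanded"),
                          levels = c("hyper_expanded", "non_expanded"))
  out
}

#' Total frequency carried by hyper-expanded clones
#'
#' The summed frequency of clones above the hyper-expansion threshold; the
#' fraction of all T cells that belong to hyper-expanded clones.
#'
#' @inheritParams classify_expansion
#' @return A number in `[0, 1]`.
#' @export
hyperexpanded_fraction <- function(rep, threshold = 0.002) {
  f <- rep_frequencies(rep)
  sum(f[f > threshold])
}

#' Per-sample diversity and expansion summary
#'
#' @inheritParams classify_expansion
#' @return One-row tibble: `sample_id`, `n_clones`, `normalized_shannon`,
#'   `hyperexpanded_fraction`, `n_hyperexpanded`, and
#'   `pct_unique_hyperexpanded` (the percentage of unique clones that are
#'   hyper-expanded).
#' @export
diversity_summary <- function(rep, threshold = 0.002) {
  f <- rep_frequencies(rep)
  sid <- if (is_tcr_repertoire(rep)) attr(rep, "sample_id") else NA_character_
  nh <- sum(f > threshold)
  tibble(
    sample_id = sid,
    n_clones = length(f),
    normalized_shannon = normalized_shannon(f),
    hyperexpanded_fraction = sum(f[f > threshold]),
    n_hyperexpanded = nh,
    pct_unique_hyperexpanded = 100 * nh / length(f)
  )
}

#' Clone-size distribution weighted by clone size
#'
#' Histogram of `log10(frequency)` with each clone weighted by its
#' frequency, so bin masses represent the distribution of *cells* across
#' clone sizes rather than of clones. Bins are uniform in log10 frequency
#' between the observed minimum and maximum; bin masses sum to 1.
#'
#' @inheritParams classify_expansion
#' @param n_bins Number of bins.
#' @return Tibble with `bin`, `lower`, `upper` (log10 frequency edges),
#'   `n_clones`, and `mass`.
#' @export
weighted_size_distribution <- function(rep, n_bins = 30) {
  f <- rep_frequencies(rep)
  lf <- log10(f)
  edges <- bin_edges(lf, n_bins)
  idx <- assign_bins(lf, edges)
  tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    n_clones = as.integer(tabulate(idx, n_bins)),
    mass = as.numeric(tapply(f, factor(idx, levels = seq_len(n_bins)), sum,
                             default = 0))
  )
}

#' Top clones carrying a cumulative frequency mass
#'
#' Returns the smallest set of largest clones whose cumulative frequency
#' reaches `mass` (default 0.75, as used to limit bubble plots to the top
#' clones carrying 75% of the repertoire). Clones are taken in decreasing
#' frequency order, ties broken by clone key.
#'
#' @inheritParams classify_expansion
#' @param mass Cumulative frequency to cover, in `(0, 1]`.
#' @return The selected clones as a tibble (same columns as the input).
#' @export
top_clones_by_mass <- function(rep, mass = 0.75) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass > 1) {
    abort("`mass` must lie in (0, 1].")
  }
  f <- rep_frequencies(rep)
  out <- if (is.data.frame(rep)) as_tibble(rep) else tibble(frequency = f)
  key <- if ("cdr3_nt" %in% names(out)) out$cdr3_nt else seq_along(f)
  ord <- order(-out$frequency, key)
  out <- out[ord, , drop = FALSE]
  k <- which(cumsum(out$frequency) >= mass - 1e-12)[1]
  if (is.na(k)) k <- nrow(out)
  out[seq_len(k), , drop = FALSE]
}

# uniform bin edges over the span of x, widened when degenerate so that a
# single-valued input falls in one bin
bin_edges <- function(x, n_bins) {
  r <- range(x)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1)
}

# right-closed bins; values at the top edge go to the last bin
assign_bins <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx == 0L] <- 1L
  idx
}
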