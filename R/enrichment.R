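#' Log binomial coefficient
#'
#' `log(choose(n, k))` computed through the log-gamma function, stable for
#' the genome-scale counts (tens of thousands of genes) where naive
#' factorials overflow.
#'
#' @param n,k Non-negative integers, `k <= n` (vectorised).
#' @return Natural log of the binomial coefficient.
#' @export
log_binomial <- function(n, k) {
  if (any(n < 0 | k < 0 | k > n)) {
    stop("log_binomial requires 0 <= k <= n", call. = FALSE)
  }
  # sum-of-logs over the shorter factor sequence keeps the absolute error
  # near machine precision; lgamma differences lose ~1e-12 at genome scale
  one <- function(n1, k1) {
    m <- min(k1, n1 - k1)
    if (m == 0) return(0)
    if (m > 1e6) return(lgamma(n1 + 1) - lgamma(k1 + 1) - lgamma(n1 - k1 + 1))
    i <- seq_len(m)
    sum(log((n1 - m + i) / i))
  }
  mapply(one, n, k)
}

# log hypergeometric pmf: P(X = i) for i successes in a sample of n from a
# population of N with K successes
log_hyper_pmf <- function(N, K, n, i) {
  log_binomial(K, i) + log_binomial(N - K, n - i) - log_binomial(N, n)
}

# numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Upper tail of the hypergeometric distribution
#'
#' The over-representation probability `P(X >= k)` of observing `k` or more
#' positive genes in a sample of `n` genes drawn without replacement from a
#' population of `N` genes containing `K` positives. The tail is summed in
#' log space (log-sum-exp over log-gamma terms) and clipped to `[0, 1]`.
#'
#' @param N Population size (genes in the genome).
#' @param K Population positives (genome genes carrying the feature).
#' @param n Sample size (genes in the set).
#' @param k Sample positives.
#' @return The tail probability.
#' @examples
#' hypergeom_upper_tail(N = 25, K = 8, n = 11, k = 6)  # ~0.0433
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (N < 1 || K < 0 || n < 0 || k < 0 || K > N || n > N || k > min(K, n)) {
    stop("hypergeometric domain violation: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  lo_support <- max(0, n - (N - K))  # X >= n - (N-K) always holds
  if (k <= lo_support) return(1)
  i <- k:min(K, n)
  p <- exp(log_sum_exp(log_hyper_pmf(N, K, n, i)))
  min(max(p, 0), 1)
}

#' One-tailed Fisher's exact test (enrichment in set 1)
#'
#' Exact probability, under fixed margins, of a 2x2 contingency at least as
#' enriched in set 1 as observed: with rows (set-1 positives `a`, set-1
#' negatives `b`) and (set-2 positives `c`, set-2 negatives `d`), this is
#' the hypergeometric upper tail with `N = a+b+c+d`, `K = a+c`, `n = a+b`,
#' `k = a`. The direction is explicit: set 1 is tested for enrichment over
#' set 2.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return One-tailed p-value.
#' @examples
#' fisher_one_tailed(6, 5, 2, 12)  # ~0.043
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || a + b + c + d < 1) {
    stop("contingency counts must be non-negative with positive total",
         call. = FALSE)
  }
  hypergeom_upper_tail(N = a + b + c + d, K = a + c, n = a + b, k = a)
}

#' Gene-set over-representation report
#'
#' For each gene set: the hypergeometric upper-tail probability of its
#' positive count against a genome reference frequency (`K` positives among
#' `N` genes). For each ordered pair of sets: the one-tailed Fisher exact
#' test of the first set being enriched over the second. No multiple-testing
#' correction is applied.
#'
#' `K`, the number of genome genes carrying the feature, has no default: it
#' must be measured (or supplied) for the reference annotation in use.
#'
#' @param calls Gene-call tibble from [call_genes()] (`gene_id`, `has_pair`).
#' @param gene_sets Named list of character vectors of gene ids.
#' @param N Population size (e.g. 32120 for the mouse gene catalogue used as
#'   reference).
#' @param K Population positives. Required.
#' @return An object of class `motiflink_enrichment`: list with `sets`
#'   (per-set counts and hypergeometric p), `fisher` (pairwise one-tailed
#'   results), `N`, `K`, and `unknown_genes` (ids absent from `calls`,
#'   excluded from counts with a warning).
#' @export
test_overrepresentation <- function(calls, gene_sets, N, K) {
  if (missing(K) || is.null(K)) {
    stop("`K` (genome positive count) is required and has no default",
         call. = FALSE)
  }
  if (missing(N) || is.null(N)) stop("`N` (genome size) is required", call. = FALSE)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (any(lengths(gene_sets) == 0L)) {
    stop("empty gene set: ", paste(names(gene_sets)[lengths(gene_sets) == 0L],
                                   collapse = ", "), call. = FALSE)
  }
  unknown <- purrr::map(gene_sets, ~ setdiff(.x, calls$gene_id))
  if (any(lengths(unknown) > 0L)) {
    warning("gene ids absent from calls (excluded): ",
            paste(unlist(unknown), collapse = ", "), call. = FALSE)
  }
  counts <- purrr::imap(gene_sets, function(ids, nm) {
    ids <- intersect(ids, calls$gene_id)
    k <- sum(calls$has_pair[calls$gene_id %in% ids])
    tibble::tibble(set = nm, n = length(ids), k = k)
  })
  sets <- dplyr::bind_rows(counts) |>
    dplyr::mutate(p_hypergeom = purrr::map2_dbl(.data$n, .data$k,
                                                ~ hypergeom_upper_tail(N, K, .x, .y)))
  pairs <- tidyr::expand_grid(set1 = sets$set, set2 = sets$set) |>
    dplyr::filter(.data$set1 != .data$set2)
  fisher <- pairs |>
    dplyr::left_join(dplyr::select(sets, set1 = "set", n1 = "n", k1 = "k"),
                     by = "set1") |>
    dplyr::left_join(dplyr::select(sets, set2 = "set", n2 = "n", k2 = "k"),
                     by = "set2") |>
    dplyr::mutate(p_fisher = purrr::pmap_dbl(
      list(.data$k1, .data$n1 - .data$k1, .data$k2, .data$n2 - .data$k2),
      fisher_one_tailed
    ))
  structure(
    list(sets = sets, fisher = fisher, N = N, K = K,
         unknown_genes = unlist(unknown, use.names = FALSE)),
    class = "motiflink_enrichment"
  )
}

#' @export
print.motiflink_enrichment <- function(x, ...) {
  cat("Gene-set over-representation (exact tests, uncorrected)\n")
  cat(sprintf("Genome reference: N = %d genes, K = %d positives\n", x$N, x$K))
  cat("\nPer-set hypergeometric upper tail:\n")
  for (i in seq_len(nrow(x$sets))) {
    s <- x$sets[i, ]
    cat(sprintf("  %-10s %d/%d positive   HT p = %.4g\n",
                s$set, s$k, s$n, s$p_hypergeom))
  }
  cat("\nPairwise one-tailed Fisher (row set enriched over column set):\n")
  for (i in seq_len(nrow(x$fisher))) {
    f <- x$fisher[i, ]
    cat(sprintf("  %s (%d/%d) vs %s (%d/%d)   FET p = %.4g\n",
                f$set1, f$k1, f$n1, f$set2, f$k2, f$n2, f$p_fisher))
  }
  invisible(x)
}

#' Tidy an over-representation result
#'
#' One row per test: per-set hypergeometric rows (`test = "hypergeometric"`)
#' followed by pairwise Fisher rows (`test = "fisher_one_tailed"`).
#'
#' @param x A `motiflink_enrichment` object.
#' @param ... Unused.
#' @return A tibble with columns `test`, `set`, `comparison`, `n`, `k`,
#'   `p.value`.
#' @export
tidy.motiflink_enrichment <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$sets, test = "hypergeometric", set = .data$set,
                     comparison = "genome", n = .data$n, k = .data$k,
                     p.value = .data$p_hypergeom),
    dplyr::transmute(x$fisher, test = "fisher_one_tailed", set = .data$set1,
                     comparison = .data$set2, n = .data$n1, k = .data$k1,
                     p.value = .data$p_fisher)
  )
}

#' Glance at an over-representation result
#'
#' @param x A `motiflink_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: `N`, `K`, `n_sets`, `min_p_hypergeom`,
#'   `min_p_fisher`.
#' @export
glance.motiflink_enrichment <- function(x, ...) {
  tibble::tibble(
    N = x$N, K = x$K, n_sets = nrow(x$sets),
    min_p_hypergeom = min(x$sets$p_hypergeom),
    min_p_fisher = if (nrow(x$fisher) > 0L) min(x$fisher$p_fisher) else NA_real_
  )
}

#' Plot an over-representation result
#'
#' Bar chart of per-set positive fractions, annotated with the
#' hypergeometric p-value and the genome reference frequency as a dashed
#' line.
#'
#' @param object A `motiflink_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motiflink_enrichment <- function(object, ...) {
  d <- dplyr::mutate(object$sets,
                     fraction = .data$k / .data$n,
                     label = sprintf("%d/%d\np = %.3g", .data$k, .data$n,
                                     .data$p_hypergeom))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_hline(yintercept = object$K / object$N, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.2,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.15), expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "fraction of genes with linked pair",
                  title = "Gene-set over-representation",
                  subtitle = sprintf("dashed line: genome frequency %d/%d",
                                     object$K, object$N)) +
    ggplot2::theme_minimal()
}
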