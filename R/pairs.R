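#' Pair motif hits under a spacing constraint
#'
#' Forms every (first-motif, second-motif) combination on the same chromosome
#' whose inner gap — end of the leftmost hit to start of the rightmost hit on
#' the forward axis — lies within `[0, max_spacing]`. Either motif may come
#' first on the axis and all four strand combinations are admitted (site
#' orientation is reported, not filtered). Overlapping hits are never pairs:
#' spacing presupposes separated sites.
#'
#' The 100 bp default bound is inclusive (`spacing == max_spacing` is kept);
#' `strict = TRUE` flips to an exclusive bound.
#'
#' @param hits_a,hits_b Hits tibbles (e.g. conserved non-coding SOX9 and GLI
#'   hits). Column prefixes in the output use each tibble's `motif` values
#'   via `label_a`/`label_b`.
#' @param max_spacing Maximum inner gap in nt (default 100).
#' @param strict Exclusive spacing bound if TRUE (default FALSE).
#' @param label_a,label_b Column-name prefixes for the two motif roles.
#' @return A tibble with one row per pair: `chrom`, `<a>_start`, `<a>_end`,
#'   `<a>_strand`, `<b>_start`, `<b>_end`, `<b>_strand`, `spacing`,
#'   `upstream_motif` (which role is leftmost), `pair_start`, `pair_end`
#'   (window from first hit start to second hit end), sorted by `chrom` then
#'   `pair_start`.
#' @export
find_linked_pairs <- function(hits_a, hits_b, max_spacing = 100L,
                              strict = FALSE, label_a = "sox9",
                              label_b = "gli") {
  empty <- tibble::tibble(chrom = character())
  a <- dplyr::select(hits_a, "chrom", a_start = "start", a_end = "end",
                     a_strand = "strand")
  b <- dplyr::select(hits_b, "chrom", b_start = "start", b_end = "end",
                     b_strand = "strand")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(empty_pairs(label_a, label_b))
  }
  pairs <- dplyr::inner_join(a, b, by = "chrom", relationship = "many-to-many")
  pairs <- pairs |>
    dplyr::mutate(
      spacing = pmax(.data$a_start, .data$b_start) -
        pmin(.data$a_end, .data$b_end),
      upstream_motif = ifelse(.data$a_start <= .data$b_start, label_a, label_b),
      pair_start = pmin(.data$a_start, .data$b_start),
      pair_end = pmax(.data$a_end, .data$b_end)
    )
  keep <- if (strict) {
    pairs$spacing >= 0L & pairs$spacing < max_spacing
  } else {
    pairs$spacing >= 0L & pairs$spacing <= max_spacing
  }
  pairs <- pairs[keep, , drop = FALSE] |>
    dplyr::arrange(.data$chrom, .data$pair_start, .data$pair_end)
  names(pairs) <- sub("^a_", paste0(label_a, "_"), names(pairs))
  names(pairs) <- sub("^b_", paste0(label_b, "_"), names(pairs))
  pairs
}

empty_pairs <- function(label_a = "sox9", label_b = "gli") {
  out <- tibble::tibble(
    chrom = character(), a_start = integer(), a_end = integer(),
    a_strand = character(), b_start = integer(), b_end = integer(),
    b_strand = character(), spacing = integer(), upstream_motif = character(),
    pair_start = integer(), pair_end = integer()
  )
  names(out) <- sub("^a_", paste0(label_a, "_"), names(out))
  names(out) <- sub("^b_", paste0(label_b, "_"), names(out))
  out
}

#' Flag pairs with an intervening TCF site
#'
#' `intervening_tcf` is TRUE iff some TCF hit lies entirely within the gap
#' strictly between the pair's two hits ("between" read strictly: a TCF hit
#' overlapping either site does not count).
#'
#' @param pairs Pair tibble from [find_linked_pairs()].
#' @param tcf_hits Hits tibble of (conservation-filtered) TCF occurrences.
#' @param label_a,label_b The role prefixes used when pairing.
#' @return `pairs` with an added logical `intervening_tcf` column.
#' @export
annotate_intervening_tcf <- function(pairs, tcf_hits, label_a = "sox9",
                                     label_b = "gli") {
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, intervening_tcf = logical()))
  }
  a_end <- pairs[[paste0(label_a, "_end")]]
  b_end <- pairs[[paste0(label_b, "_end")]]
  a_start <- pairs[[paste0(label_a, "_start")]]
  b_start <- pairs[[paste0(label_b, "_start")]]
  gap_start <- pmin(a_end, b_end)
  gap_end <- pmax(a_start, b_start)
  flag <- purrr::map_lgl(seq_len(nrow(pairs)), function(i) {
    t <- tcf_hits[tcf_hits$chrom == pairs$chrom[i], ]
    if (nrow(t) == 0L) return(FALSE)
    any(t$start >= gap_start[i] & t$end <= gap_end[i])
  })
  dplyr::mutate(pairs, intervening_tcf = flag)
}

#' Per-gene positivity calls from assigned pairs
#'
#' A gene is positive once it has at least one linked pair assigned to it,
#' regardless of pair multiplicity; a pair tied between genes makes each of
#' them positive.
#'
#' @param pairs Pair tibble carrying a `genes` list-column (see
#'   [assign_to_gene()]).
#' @param genes Gene-model tibble; every gene appears in the output.
#' @return A tibble `gene_id`, `has_pair`, `n_pairs` covering all genes.
#' @export
call_genes <- function(pairs, genes) {
  counts <- if (nrow(pairs) == 0L) {
    tibble::tibble(gene_id = character(), n_pairs = integer())
  } else {
    tibble::tibble(gene_id = unlist(pairs$genes)) |>
      dplyr::count(.data$gene_id, name = "n_pairs")
  }
  tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
                  has_pair = .data$n_pairs > 0L) |>
    dplyr::select("gene_id", "has_pair", "n_pairs")
}
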