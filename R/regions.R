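#' Read gene models from BED12 or GTF
#'
#' Loads gene structures and collapses multiple transcripts of one gene to a
#' single model: the union of their exons and the widest transcript span.
#' For BED12 the record name is the gene id; for GTF the `gene_id` attribute
#' of `exon` features is used.
#'
#' @param path Annotation file path.
#' @param format `"bed12"` or `"gtf"` (default guessed from the extension).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span), and `exons`, a list-column of
#'   `start`/`end` tibbles (sorted, disjoint, within the span).
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  format <- match.arg(tolower(format), c("bed12", "gtf"))
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) return(empty_gene_models())
    ex <- rtracklayer::blocks(gr)
    models <- tibble::tibble(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      exons = purrr::map(seq_along(ex), function(i) {
        r <- ex[[i]]
        tibble::tibble(start = GenomicRanges::start(r) - 1L,
                       end = GenomicRanges::end(r))
      })
    )
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L) return(empty_gene_models())
    models <- tibble::tibble(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    ) |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(
        exons = list(tibble::tibble(start, end)),
        start = min(.data$start), end = max(.data$end), .groups = "drop"
      ) |>
      dplyr::select("gene_id", "chrom", "strand", "start", "end", "exons")
  }
  validate_gene_models(collapse_gene_models(models))
}

empty_gene_models <- function() {
  tibble::tibble(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 exons = list())
}

# one model per gene id: widest span, union of exons
collapse_gene_models <- function(models) {
  models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      exons = list(merge_intervals(dplyr::bind_rows(.data$exons))),
      .groups = "drop"
    )
}

# union of possibly overlapping intervals -> sorted disjoint intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  r <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (models$start[i] >= models$end[i]) {
      stop(sprintf("gene '%s' has an empty span", models$gene_id[i]), call. = FALSE)
    }
    if (nrow(ex) > 0L &&
        (min(ex$start) < models$start[i] || max(ex$end) > models$end[i])) {
      stop(sprintf("gene '%s' has an exon outside its transcript span",
                   models$gene_id[i]), call. = FALSE)
    }
  }
  models
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column whitespace-separated file: chrom, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$length, tab$chrom)
}

#' Partition chromosomes into exonic / intronic / intergenic intervals
#'
#' The non-coding search space of the screen is `intronic + intergenic`.
#' Exonic takes precedence where genes overlap: a base inside any exon is
#' not non-coding for any gene. With `exclude = "cds"` the "exonic" class is
#' narrowed to coding exons only; gene models read from plain BED12/GTF exon
#' features carry no CDS information, in which case all exons are treated as
#' coding.
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param chrom_lengths Named vector of chromosome lengths covering all
#'   annotated chromosomes.
#' @param exclude `"exons"` (default: all exons are excluded from non-coding
#'   space, UTRs included) or `"cds"`.
#' @return A tibble `chrom`, `start`, `end`, `class` whose intervals tile
#'   each chromosome exactly.
#' @export
build_region_mask <- function(genes, chrom_lengths, exclude = c("exons", "cds")) {
  exclude <- match.arg(exclude)
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0L) {
    stop("no chromosome length for: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  too_long <- genes$end > chrom_lengths[genes$chrom]
  if (any(too_long)) {
    stop(sprintf("gene '%s' extends beyond chromosome '%s'",
                 genes$gene_id[which(too_long)[1]],
                 genes$chrom[which(too_long)[1]]), call. = FALSE)
  }
  out <- purrr::map(names(chrom_lengths), function(chr) {
    len <- unname(chrom_lengths[[chr]])
    g <- genes[genes$chrom == chr, ]
    whole <- IRanges::IRanges(1L, len)
    if (nrow(g) == 0L) {
      return(tibble::tibble(chrom = chr, start = 0L, end = len,
                            class = "intergenic"))
    }
    spans <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    ex_tbl <- dplyr::bind_rows(g$exons)
    exonic <- if (nrow(ex_tbl) > 0L) {
      IRanges::reduce(IRanges::IRanges(ex_tbl$start + 1L, ex_tbl$end))
    } else IRanges::IRanges()
    intronic <- IRanges::setdiff(spans, exonic)
    intergenic <- IRanges::setdiff(whole, spans)
    to_tbl <- function(r, cls) {
      if (length(r) == 0L) return(NULL)
      tibble::tibble(chrom = chr, start = IRanges::start(r) - 1L,
                     end = IRanges::end(r), class = cls)
    }
    dplyr::bind_rows(to_tbl(exonic, "exonic"), to_tbl(intronic, "intronic"),
                     to_tbl(intergenic, "intergenic")) |>
      dplyr::arrange(.data$start)
  })
  dplyr::bind_rows(out)
}

#' Restrict intervals to non-coding space
#'
#' Drops every row whose interval overlaps an exonic interval of the mask by
#' one or more bases; a binding site overlapping coding sequence is not a
#' non-coding site.
#'
#' @param x Tibble with `chrom`, `start`, `end` columns (e.g. motif hits).
#' @param mask Region mask from [build_region_mask()].
#' @return The non-coding subset of `x`.
#' @export
filter_noncoding <- function(x, mask) {
  if (nrow(x) == 0L) return(x)
  ex <- mask[mask$class == "exonic", ]
  if (nrow(ex) == 0L) return(x)
  q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  s <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::countOverlaps(q, s, minoverlap = 1L)
  x[hits == 0L, , drop = FALSE]
}

#' Assign an interval to gene(s)
#'
#' An interval inside one or more gene spans is assigned to all of them; an
#' intergenic interval goes to the nearest gene by edge distance within
#' `max_flank`, with ties assigned to all tied genes; beyond `max_flank` the
#' assignment is empty. The attribution rule for intergenic sites is a
#' documented package choice (nearest gene, 50 kb default flank).
#'
#' @param x Tibble with `chrom`, `start`, `end`.
#' @param genes Gene-model tibble.
#' @param max_flank Maximum edge distance (nt) for intergenic assignment.
#' @return `x` with an added list-column `genes` (character vectors, possibly
#'   empty, sorted for determinism).
#' @export
assign_to_gene <- function(x, genes, max_flank = 50000L) {
  assigned <- purrr::pmap(list(x$chrom, x$start, x$end), function(chrom, start, end) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0L) return(character())
    inside <- g$start < end & start < g$end
    if (any(inside)) return(sort(g$gene_id[inside]))
    dist <- pmax(g$start - end, start - g$end)  # edge gap, 0 when touching
    dmin <- min(dist)
    if (dmin > max_flank) return(character())
    sort(g$gene_id[dist == dmin])
  })
  dplyr::mutate(x, genes = assigned)
}
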