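#' Run the full linked-site screen
#'
#' Orchestrates the stage chain scan -> conserve -> restrict -> pair ->
#' call: scans the reference for the motif set on both strands, keeps hits
#' perfectly conserved against the partner species in the alignments,
#' restricts to inter-/intragenic non-coding space, pairs the SOX9-role and
#' GLI-role hits under the spacing constraint, annotates pair-window
#' conservation across the species panel and intervening TCF sites, assigns
#' pairs to genes, and calls per-gene positivity. Filter-stage counts are
#' recorded so exclusions are auditable.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param maf MAF tibble from [read_maf()] or a MAF file path.
#' @param genes Gene-model tibble from [read_gene_models()] or an annotation
#'   path (BED12/GTF).
#' @param chrom_lengths Named vector, chrom.sizes path, or NULL (derived
#'   from the genome sequence lengths).
#' @param motifs Motif set; must contain `sox9_name` and `gli_name` rows
#'   (and `tcf_name` for TCF annotation, if present).
#' @param partner_species Conservation filter partner (default `"human"`).
#' @param species_panel Panel for the descriptive conservation percentage
#'   (default: all species in `maf`).
#' @param max_spacing Maximum inner gap between paired sites, inclusive
#'   (default 100 nt); `strict` flips to an exclusive bound.
#' @param strict Exclusive spacing bound if TRUE.
#' @param max_flank Intergenic gene-assignment flank (default 50000 nt).
#' @param exclude `"exons"` or `"cds"` — what counts as coding space.
#' @param sox9_name,gli_name,tcf_name Motif labels for the three roles.
#' @return Object of class `motiflink_screen`: list with `hits` (all raw
#'   hits), `conserved_hits`, `noncoding_hits`, `pairs` (with gene
#'   assignment, pair-window conservation, `intervening_tcf`), `calls`
#'   ([call_genes()] table), `stage_counts`, `params`.
#' @export
screen_linked_sites <- function(genome, maf, genes, chrom_lengths = NULL,
                                motifs = default_motifs(),
                                partner_species = "human",
                                species_panel = NULL,
                                max_spacing = 100L, strict = FALSE,
                                max_flank = 50000L,
                                exclude = c("exons", "cds"),
                                sox9_name = "SOX9", gli_name = "GLI",
                                tcf_name = "TCF") {
  exclude <- match.arg(exclude)
  genome <- as_named_sequences(genome)
  if (is.character(maf)) maf <- read_maf(maf)
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(nchar(genome), names(genome))
  } else if (is.character(chrom_lengths) && length(chrom_lengths) == 1L) {
    chrom_lengths <- read_chrom_sizes(chrom_lengths)
  }
  bad_chr <- setdiff(unique(genes$chrom), names(genome))
  if (length(bad_chr) > 0L) {
    stop("annotation chromosomes absent from genome: ",
         paste(bad_chr, collapse = ", "), call. = FALSE)
  }
  if (!all(c(sox9_name, gli_name) %in% motifs$name)) {
    stop(sprintf("motif set must contain '%s' and '%s'", sox9_name, gli_name),
         call. = FALSE)
  }
  if (is.null(species_panel)) species_panel <- unique(maf$species)

  hits <- scan_genome(genome, motifs)
  ann <- annotate_conservation(hits, maf, partner_species, species_panel)
  conserved <- ann[which(ann$conserved), , drop = FALSE]
  mask <- build_region_mask(genes, chrom_lengths, exclude)
  noncoding <- filter_noncoding(conserved, mask)

  pairs <- find_linked_pairs(noncoding[noncoding$motif == sox9_name, ],
                             noncoding[noncoding$motif == gli_name, ],
                             max_spacing = max_spacing, strict = strict)
  pairs <- annotate_window_conservation(pairs, maf, species_panel)
  tcf <- noncoding[noncoding$motif == tcf_name, ]
  pairs <- annotate_intervening_tcf(pairs, tcf)
  pairs <- assign_to_gene(
    dplyr::mutate(pairs, start = .data$pair_start, end = .data$pair_end),
    genes, max_flank = max_flank
  ) |>
    dplyr::select(-"start", -"end")
  calls <- call_genes(pairs, genes)

  stage_counts <- tibble::tibble(
    stage = c("raw_hits", "conserved_hits", "noncoding_hits", "pairs",
              "positive_genes"),
    n = c(nrow(hits), nrow(conserved), nrow(noncoding), nrow(pairs),
          sum(calls$has_pair))
  )
  structure(
    list(hits = hits, conserved_hits = conserved, noncoding_hits = noncoding,
         pairs = pairs, calls = calls, stage_counts = stage_counts,
         params = list(partner_species = partner_species,
                       species_panel = species_panel,
                       max_spacing = max_spacing, strict = strict,
                       max_flank = max_flank, exclude = exclude,
                       motifs = motifs)),
    class = "motiflink_screen"
  )
}

# descriptive conservation over each pair's whole window (both sites + gap)
annotate_window_conservation <- function(pairs, maf, species_panel) {
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, pct_conservation = numeric(),
                         species_present = list()))
  }
  refs <- maf[maf$is_ref, ]
  blocks <- split(maf, maf$block)
  rec <- purrr::pmap(list(pairs$chrom, pairs$pair_start, pairs$pair_end),
                     function(chrom, start, end) {
    cand <- refs[refs$chrom == chrom & refs$start <= start & refs$end >= end, ]
    if (nrow(cand) == 0L) {
      return(tibble::tibble(pct_conservation = NA_real_,
                            species_present = list(character())))
    }
    b <- blocks[[as.character(cand$block[1])]]
    r <- conservation_percentage(b, start, end, species_panel)
    tibble::tibble(pct_conservation = r$pct_identical,
                   species_present = r$species_present)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(rec))
}

#' @export
print.motiflink_screen <- function(x, ...) {
  cat("Linked-site screen\n")
  cat(sprintf("  partner species: %s; panel: %s\n", x$params$partner_species,
              paste(x$params$species_panel, collapse = ", ")))
  cat(sprintf("  max spacing: %d nt (%s); gene flank: %d nt\n",
              x$params$max_spacing,
              if (x$params$strict) "exclusive" else "inclusive",
              x$params$max_flank))
  cat("  stage counts:\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("    %-16s %d\n", x$stage_counts$stage[i], x$stage_counts$n[i]))
  }
  invisible(x)
}

#' Tidy a screen result into the per-gene pair detail table
#'
#' One row per (pair, assigned gene): the detail columns of the screen
#' (site positions and orientations, spacing, pair-window conservation
#' percentage and species, intervening TCF flag).
#'
#' @param x A `motiflink_screen` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.motiflink_screen <- function(x, ...) {
  p <- x$pairs
  if (nrow(p) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          sox9_start = integer(), sox9_strand = character(),
                          gli_start = integer(), gli_strand = character(),
                          spacing = integer(), pct_conservation = numeric(),
                          species_present = character(),
                          intervening_tcf = logical()))
  }
  p |>
    dplyr::mutate(species_present = purrr::map_chr(.data$species_present,
                                                   paste, collapse = ","),
                  gene_id = purrr::map(.data$genes,
                                       ~ if (length(.x)) .x else NA_character_)) |>
    tidyr::unnest("gene_id") |>
    dplyr::select("gene_id", "chrom", "sox9_start", "sox9_strand",
                  "gli_start", "gli_strand", "spacing", "pct_conservation",
                  "species_present", "intervening_tcf")
}

#' Glance at a screen result
#'
#' @param x A `motiflink_screen` object.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @export
glance.motiflink_screen <- function(x, ...) {
  tidyr::pivot_wider(x$stage_counts, names_from = "stage", values_from = "n")
}

#' Plot the site architecture of called pairs
#'
#' One panel row per assigned gene, drawing the SOX9 and GLI sites as
#' oriented arrows on the locus axis with the spacing between them —
#' a per-gene site-architecture summary of the screen.
#'
#' @param object A `motiflink_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motiflink_screen <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no linked pairs") +
             ggplot2::theme_void())
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(d, gene_id = .data$gene_id, motif = "SOX9",
                     start = .data$sox9_start, strand = .data$sox9_strand,
                     spacing = .data$spacing),
    dplyr::transmute(d, gene_id = .data$gene_id, motif = "GLI",
                     start = .data$gli_start, strand = .data$gli_strand,
                     spacing = .data$spacing)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$start, y = .data$gene_id,
                               colour = .data$motif, shape = .data$strand)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene_id), colour = "grey60") +
    ggplot2::scale_shape_manual(values = c("+" = 62, "-" = 60)) +
    ggplot2::labs(x = "reference position (nt)", y = NULL,
                  title = "Linked SOX9-GLI sites by gene") +
    ggplot2::theme_minimal()
}

#' Write screen outputs to disk
#'
#' Emits `hits.tsv` (all raw hits), `pairs.tsv` (the tidy per-gene detail
#' table), `pairs.bed` (BED6 of pair windows), and `gene_calls.tsv`.
#'
#' @param screen A `motiflink_screen` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(screen$hits, file.path(dir, "hits.tsv"))
  detail <- tidy(screen)
  readr::write_tsv(detail, file.path(dir, "pairs.tsv"))
  p <- screen$pairs
  bed <- if (nrow(p) == 0L) character() else {
    sprintf("%s\t%d\t%d\t%s\t0\t+", p$chrom, p$pair_start, p$pair_end,
            sprintf("pair_%04d", seq_len(nrow(p))))
  }
  writeLines(bed, file.path(dir, "pairs.bed"))
  readr::write_tsv(screen$calls, file.path(dir, "gene_calls.tsv"))
  readr::write_tsv(screen$stage_counts, file.path(dir, "stage_counts.tsv"))
  invisible(dir)
}
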