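#' Configuration for the synthetic alignment generator
#'
#' The generator emulates the statistical structure the screen assumes:
#' star-phylogeny multi-species alignments of gene loci in which perfectly
#' conserved SOX9-GLI pairs are planted in non-exonic sequence at a
#' controlled per-gene frequency, surrounded by neutrally diverged sequence.
#'
#' Defaults mirror the screened study design: an 11-gene "HC" set planted at
#' probability 6/11 and a 14-gene "PC" set at 2/14 (the observed positive
#' fractions of the two differentiation-stage gene sets), a six-species
#' mammalian panel, pair spacing uniform on 0..100 nt, mouse-like 42% GC,
#' and per-species divergence of 10% substitutions and 1% single-base
#' deletions per site.
#'
#' @param n_hc_genes,n_pc_genes Genes in the two emitted sets.
#' @param f_hi,f_lo Per-gene probability of one planted pair in each set.
#' @param locus_length Nucleotides per gene locus (one locus per
#'   chromosome).
#' @param species_panel Species ids; the first is the reference.
#' @param spacing_range Inclusive bounds for planted inner spacing (nt).
#' @param substitution_rate,indel_rate Per-base, per-species event
#'   probabilities for non-reference rows; indels are single-base deletions
#'   (a gap character; column structure preserved).
#' @param protect_planted Exempt planted motif windows from noise in every
#'   species, so planted sites are perfectly conserved.
#' @param gc_content Reference base composition.
#' @param sox9,gli IUPAC consensus strings used for planting (must match the
#'   motifs later scanned for).
#' @param seed Integer seed for the single RNG stream.
#' @return A validated list of class `motiflink_synth_config`.
#' @export
synth_config <- function(n_hc_genes = 11L, n_pc_genes = 14L,
                         f_hi = 6 / 11, f_lo = 2 / 14,
                         locus_length = 3000L,
                         species_panel = c("mouse", "human", "chimpanzee",
                                           "canine", "bovine", "opossum"),
                         spacing_range = c(0L, 100L),
                         substitution_rate = 0.10, indel_rate = 0.01,
                         protect_planted = TRUE, gc_content = 0.42,
                         sox9 = "WWCAAWG", gli = "GACCACCCA",
                         seed = 1L) {
  cfg <- list(n_hc_genes = as.integer(n_hc_genes),
              n_pc_genes = as.integer(n_pc_genes),
              f_hi = f_hi, f_lo = f_lo,
              locus_length = as.integer(locus_length),
              species_panel = species_panel,
              spacing_range = as.integer(spacing_range),
              substitution_rate = substitution_rate, indel_rate = indel_rate,
              protect_planted = isTRUE(protect_planted),
              gc_content = gc_content, sox9 = toupper(sox9),
              gli = toupper(gli), seed = as.integer(seed))
  probs <- c(cfg$f_hi, cfg$f_lo, cfg$substitution_rate, cfg$indel_rate,
             cfg$gc_content)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_hc_genes < 0L || cfg$n_pc_genes < 0L) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  if (length(cfg$spacing_range) != 2L ||
      cfg$spacing_range[1] > cfg$spacing_range[2] || cfg$spacing_range[1] < 0L) {
    stop("spacing_range must be ordered non-negative bounds", call. = FALSE)
  }
  validate_iupac(cfg$sox9); validate_iupac(cfg$gli)
  min_len <- 2L * (nchar(cfg$sox9) + nchar(cfg$gli)) + cfg$spacing_range[2]
  if (cfg$locus_length <= min_len) {
    stop(sprintf("locus_length must exceed %d to place a gene and a pair", min_len),
         call. = FALSE)
  }
  if (length(cfg$species_panel) < 1L || anyDuplicated(cfg$species_panel)) {
    stop("species_panel must be non-empty with unique ids", call. = FALSE)
  }
  structure(cfg, class = "motiflink_synth_config")
}

# uniform draw from the sequences satisfying an IUPAC consensus
draw_motif_instance <- function(consensus) {
  sets <- validate_iupac(consensus)
  paste(purrr::map_chr(sets, ~ .x[sample.int(length(.x), 1L)]), collapse = "")
}

# random reference sequence at the configured GC
draw_sequence <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), len, replace = TRUE, prob = p)
}

#' Generate one synthetic gene locus with its alignment rows
#'
#' Draws an i.i.d. reference sequence, places a two-exon gene body in the
#' middle of the locus, optionally plants one SOX9-GLI pair (uniform strands
#' and order, spacing uniform over `spacing_range`) at a uniformly chosen
#' non-exonic position, and derives each non-reference species row by
#' per-base substitution and single-base-deletion noise. Uses the current
#' RNG state; seed via [simulate_dataset()] or `set.seed()`.
#'
#' @param config A [synth_config()].
#' @param gene_index Integer used to name the locus and gene.
#' @param plant_probability Per-gene probability of one planted pair.
#' @return List with `chrom`, `gene_id`, `ref_seq`, `rows` (named character
#'   vector of aligned texts, reference first), `gene` (one-row gene-model
#'   tibble), `truth` (one-row truth tibble).
#' @export
generate_locus <- function(config, gene_index, plant_probability) {
  L <- config$locus_length
  chrom <- sprintf("locus_%04d", gene_index)
  gene_id <- sprintf("gene_%04d", gene_index)
  ref <- draw_sequence(L, config$gc_content)

  # two-exon gene body occupying the middle ~30% of the locus
  gs <- floor(0.35 * L); ge <- floor(0.65 * L)
  span <- ge - gs
  exons <- tibble::tibble(
    start = c(gs, ge - floor(0.25 * span)),
    end = c(gs + floor(0.25 * span), ge)
  )
  gene <- tibble::tibble(gene_id = gene_id, chrom = chrom, strand = "+",
                         start = gs, end = ge, exons = list(exons))

  truth <- tibble::tibble(
    gene_id = gene_id, chrom = chrom, planted = FALSE,
    sox9_start = NA_integer_, sox9_strand = NA_character_,
    gli_start = NA_integer_, gli_strand = NA_character_,
    spacing = NA_integer_, pair_start = NA_integer_, pair_end = NA_integer_
  )
  protected <- integer()

  if (stats::runif(1) < plant_probability) {
    s <- config$spacing_range[1] +
      sample.int(config$spacing_range[2] - config$spacing_range[1] + 1L, 1L) - 1L
    sox9_first <- stats::runif(1) < 0.5
    w_sox9 <- nchar(config$sox9); w_gli <- nchar(config$gli)
    width <- w_sox9 + s + w_gli
    # windows must fit inside one non-exonic segment
    segs <- tibble::tibble(start = c(0L, exons$end[1], ge),
                           end = c(gs, exons$start[2], L))
    segs <- segs[segs$end - segs$start >= width, ]
    if (nrow(segs) == 0L) {
      stop("locus too short to place gene body and planted pair", call. = FALSE)
    }
    n_pos <- segs$end - segs$start - width + 1L
    seg <- segs[sample.int(nrow(segs), 1L, prob = n_pos), ]
    pos <- seg$start + sample.int(seg$end - seg$start - width + 1L, 1L) - 1L
    first_w <- if (sox9_first) w_sox9 else w_gli
    first_start <- pos
    second_start <- pos + first_w + s
    sox9_start <- if (sox9_first) first_start else second_start
    gli_start <- if (sox9_first) second_start else first_start
    sox9_strand <- sample(c("+", "-"), 1L)
    gli_strand <- sample(c("+", "-"), 1L)
    sox9_seq <- draw_motif_instance(config$sox9)
    gli_seq <- draw_motif_instance(config$gli)
    if (sox9_strand == "-") sox9_seq <- reverse_complement(sox9_seq)
    if (gli_strand == "-") gli_seq <- reverse_complement(gli_seq)
    ref[(sox9_start + 1L):(sox9_start + w_sox9)] <-
      strsplit(sox9_seq, "")[[1]]
    ref[(gli_start + 1L):(gli_start + w_gli)] <-
      strsplit(gli_seq, "")[[1]]
    protected <- c((sox9_start + 1L):(sox9_start + w_sox9),
                   (gli_start + 1L):(gli_start + w_gli))
    truth$planted <- TRUE
    truth$sox9_start <- sox9_start; truth$sox9_strand <- sox9_strand
    truth$gli_start <- gli_start; truth$gli_strand <- gli_strand
    truth$spacing <- s
    truth$pair_start <- pos; truth$pair_end <- pos + width
  }

  rows <- c(stats::setNames(list(ref), config$species_panel[1]),
            purrr::map(config$species_panel[-1], function(sp) {
              mutate_row(ref, config, protected)
            }))
  names(rows) <- config$species_panel
  list(chrom = chrom, gene_id = gene_id,
       ref_seq = paste(ref, collapse = ""),
       rows = purrr::map_chr(rows, paste, collapse = ""),
       gene = gene, truth = truth)
}

# derive one partner row from the reference by per-base noise
mutate_row <- function(ref, config, protected) {
  n <- length(ref)
  out <- ref
  u <- stats::runif(n)
  del <- u < config$indel_rate
  sub <- !del & u < config$indel_rate + config$substitution_rate
  if (config$protect_planted && length(protected) > 0L) {
    del[protected] <- FALSE
    sub[protected] <- FALSE
  }
  if (any(sub)) {
    bases <- c("A", "C", "G", "T")
    # substitute with a uniformly chosen *different* base
    out[sub] <- purrr::map_chr(ref[sub], function(b) {
      sample(setdiff(bases, b), 1L)
    })
  }
  out[del] <- "-"
  out
}

#' Simulate a full synthetic dataset in memory
#'
#' Generates `n_hc_genes + n_pc_genes` loci (one chromosome each): HC-like
#' genes planted at `f_hi`, PC-like at `f_lo`. One alignment block per locus
#' covers the whole locus across the species panel. Deterministic for a
#' fixed seed.
#'
#' @param config A [synth_config()].
#' @return List of class `motiflink_synth`: `genome` (named character
#'   vector), `maf` (alignment tibble as from [read_maf()]), `genes`
#'   (gene-model tibble), `chrom_lengths`, `gene_sets` (list `HC`, `PC`),
#'   `truth` (truth tibble), `config`.
#' @export
simulate_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_hc_genes + config$n_pc_genes
  f <- c(rep(config$f_hi, config$n_hc_genes),
         rep(config$f_lo, config$n_pc_genes))
  loci <- purrr::map(seq_len(n), ~ generate_locus(config, .x, f[.x]))
  ref_sp <- config$species_panel[1]
  maf <- purrr::imap(loci, function(lc, b) {
    purrr::imap(lc$rows, function(text, sp) {
      size <- nchar(gsub("-", "", text, fixed = TRUE))
      tibble::tibble(block = b, species = sp, chrom = lc$chrom,
                     start = 0L, end = size, strand = "+",
                     src_size = if (sp == ref_sp) config$locus_length else size,
                     text = text, is_ref = sp == ref_sp)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  genome <- stats::setNames(purrr::map_chr(loci, "ref_seq"),
                            purrr::map_chr(loci, "chrom"))
  genes <- dplyr::bind_rows(empty_gene_models(), purrr::map(loci, "gene"))
  truth <- dplyr::bind_rows(purrr::map(loci, "truth"))
  if (n == 0L) {
    maf <- tibble::tibble(block = integer(), species = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          src_size = integer(), text = character(),
                          is_ref = logical())
  }
  ids <- genes$gene_id
  structure(
    list(genome = genome, maf = maf, genes = genes,
         chrom_lengths = stats::setNames(rep(config$locus_length, n),
                                         names(genome)),
         gene_sets = list(HC = ids[seq_len(config$n_hc_genes)],
                          PC = if (config$n_pc_genes > 0L)
                            ids[config$n_hc_genes + seq_len(config$n_pc_genes)]
                          else character()),
         truth = truth, config = config),
    class = "motiflink_synth"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: `genome.fa`,
#' `alignment.maf`, `genes.bed` (BED12), `chrom.sizes`, `hc_genes.txt`,
#' `pc_genes.txt` (one id per line), and `truth.tsv` (seed recorded in a
#' header comment). Byte-identical for a fixed seed.
#'
#' @param sim A `motiflink_synth` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeLines(as.character(unlist(purrr::imap(as.list(sim$genome), function(s, nm) {
    c(paste0(">", nm), substring(s, seq(1, nchar(s), 60),
                                 pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
  }))), fa)
  write_maf(sim$maf, file.path(dir, "alignment.maf"))
  writeLines(purrr::pmap_chr(sim$genes, function(gene_id, chrom, strand, start,
                                                 end, exons) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom, start, end, gene_id, strand, start, end, nrow(exons),
            paste0(paste(exons$end - exons$start, collapse = ","), ","),
            paste0(paste(exons$start - start, collapse = ","), ","))
  }), file.path(dir, "genes.bed"))
  writeLines(sprintf("%s\t%d", names(sim$chrom_lengths),
                     unname(sim$chrom_lengths)),
             file.path(dir, "chrom.sizes"))
  writeLines(sim$gene_sets$HC, file.path(dir, "hc_genes.txt"))
  writeLines(sim$gene_sets$PC, file.path(dir, "pc_genes.txt"))
  truth_path <- file.path(dir, "truth.tsv")
  writeLines(sprintf("# seed: %d", sim$config$seed), truth_path)
  suppressWarnings(utils::write.table(sim$truth, truth_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(dir)
}
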