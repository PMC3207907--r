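#' Read multiz-style multiple alignment blocks (MAF)
#'
#' Parses the UCSC MAF dialect: blocks introduced by `a` lines, sequences on
#' `s` lines of the form `s src start size strand srcSize text`. The first
#' `s` line of each block is the reference species. Species ids are extracted
#' from `src` as the prefix before the first dot (`mm9.chr1` -> species
#' `mm9`, chrom `chr1`); a dot-free `src` is used as both.
#'
#' All coordinates are converted to the forward reference axis, 0-based
#' half-open: for a `-` strand row the stored `start` is
#' `srcSize - start - size`.
#'
#' @param path Path to a MAF text file.
#' @return A tibble with one row per aligned sequence: `block` (integer id in
#'   file order), `species`, `chrom`, `start`, `end` (forward-axis, 0-based
#'   half-open), `strand`, `src_size`, `text` (aligned characters incl. `-`
#'   gaps), `is_ref`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  empty <- tibble::tibble(
    block = integer(), species = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    src_size = integer(), text = character(), is_ref = logical()
  )
  rows <- list()
  block <- 0L
  n_in_block <- 0L
  block_width <- NA_integer_
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^a($|\\s)", line)) {
      block <- block + 1L
      n_in_block <- 0L
      block_width <- NA_integer_
    } else if (grepl("^s\\s", line)) {
      if (block == 0L) {
        stop(sprintf("MAF parse error at line %d: 's' line before any 'a' line", i),
             call. = FALSE)
      }
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) != 7L) {
        stop(sprintf("MAF parse error at line %d: expected 7 fields on 's' line, got %d",
                     i, length(f)), call. = FALSE)
      }
      src <- f[2]
      start <- suppressWarnings(as.integer(f[3]))
      size <- suppressWarnings(as.integer(f[4]))
      strand <- f[5]
      src_size <- suppressWarnings(as.integer(f[6]))
      text <- f[7]
      if (anyNA(c(start, size, src_size)) || !strand %in% c("+", "-")) {
        stop(sprintf("MAF parse error at line %d: malformed 's' line", i),
             call. = FALSE)
      }
      ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ungapped != size) {
        stop(sprintf("MAF parse error at line %d: size %d does not match %d non-gap characters",
                     i, size, ungapped), call. = FALSE)
      }
      if (is.na(block_width)) {
        block_width <- nchar(text)
      } else if (nchar(text) != block_width) {
        stop(sprintf("MAF parse error at line %d: ragged row (width %d, block width %d)",
                     i, nchar(text), block_width), call. = FALSE)
      }
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      fwd_start <- if (strand == "+") start else src_size - start - size
      n_in_block <- n_in_block + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = block, species = species, chrom = chrom,
        start = fwd_start, end = fwd_start + size, strand = strand,
        src_size = src_size, text = toupper(text), is_ref = n_in_block == 1L
      )
    }
    # other line types (track lines, 'i'/'e'/'q' rows, comments, blanks) ignored
  }
  if (length(rows) == 0L) return(empty)
  maf <- dplyr::bind_rows(rows)
  dup <- maf |>
    dplyr::count(.data$block, .data$species) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop(sprintf("MAF parse error: species '%s' appears twice in block %d",
                 dup$species[1], dup$block[1]), call. = FALSE)
  }
  maf
}

#' Write alignment blocks to MAF
#'
#' Inverse of [read_maf()]: emits `a`/`s` lines with coordinates converted
#' back to source-strand convention.
#'
#' @param maf A MAF tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in unique(maf$block)) {
    rows <- maf[maf$block == b, ]
    rows <- rows[order(!rows$is_ref), ]
    writeLines("", con)
    writeLines("a score=0.0", con)
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      size <- r$end - r$start
      src_start <- if (r$strand == "+") r$start else r$src_size - r$end
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         r$species, r$chrom, src_start, size, r$strand,
                         r$src_size, r$text), con)
    }
  }
  invisible(path)
}

#' Map a reference interval to alignment column indices
#'
#' Returns the 0-based alignment columns holding the reference bases of
#' `[start, end)` within one block: one column per reference base, skipping
#' reference-gap (insertion) columns.
#'
#' @param ref_text Aligned reference row text (with `-` gaps).
#' @param ref_start Forward-axis 0-based start of the reference row.
#' @param start,end Reference interval, 0-based half-open.
#' @return Integer vector of 0-based column indices, length `end - start`.
#' @export
ref_interval_to_columns <- function(ref_text, ref_start, start, end) {
  stopifnot(end > start)
  chars <- strsplit(ref_text, "", fixed = TRUE)[[1]]
  base_cols <- which(chars != "-") - 1L          # 0-based columns of ref bases
  span <- length(base_cols)
  if (start < ref_start || end > ref_start + span) {
    stop(sprintf("interval [%d,%d) outside block reference span [%d,%d)",
                 start, end, ref_start, ref_start + span), call. = FALSE)
  }
  base_cols[(start - ref_start + 1L):(end - ref_start)]
}

# split a block's rows into per-species character matrices once
block_char_matrix <- function(block_rows) {
  texts <- strsplit(block_rows$text, "", fixed = TRUE)
  names(texts) <- block_rows$species
  texts
}

#' Is a motif hit perfectly conserved in a partner species?
#'
#' TRUE iff, at every alignment column holding a reference base of
#' `[start, end)`, the partner row exists, is not a gap, and is identical to
#' the reference base (case-insensitive). Any gap or mismatch, or a partner
#' species absent from the block, gives FALSE: an indel destroys the
#' binding-site sequence.
#'
#' @param block_rows The rows of a single MAF block (tibble subset).
#' @param start,end Reference interval of the hit, 0-based half-open.
#' @param partner_species Species id to compare against (e.g. `"human"`).
#' @return Logical scalar.
#' @export
is_perfectly_conserved <- function(block_rows, start, end, partner_species) {
  ref <- block_rows[block_rows$is_ref, ]
  stopifnot(nrow(ref) == 1L)
  cols <- ref_interval_to_columns(ref$text, ref$start, start, end)
  partner <- block_rows[block_rows$species == partner_species & !block_rows$is_ref, ]
  if (nrow(partner) == 0L) return(FALSE)
  rc <- strsplit(ref$text, "", fixed = TRUE)[[1]][cols + 1L]
  pc <- strsplit(partner$text[1], "", fixed = TRUE)[[1]][cols + 1L]
  all(pc != "-" & toupper(pc) == toupper(rc))
}

#' Conservation percentage of a window across a species panel
#'
#' The descriptive conservation metric: the percentage of reference columns
#' in `[start, end)` at which every panel species present in the block
#' matches the reference base without a gap. When no panel species besides
#' the reference is aligned, the percentage is vacuously 100 and
#' `species_present` contains the reference alone, so downstream reporting
#' can flag it.
#'
#' @param block_rows Rows of one MAF block.
#' @param start,end Reference window, 0-based half-open; must be non-empty.
#' @param species_panel Character vector of species ids to assess (the
#'   reference species may be included; it always matches itself).
#' @return A one-row tibble: `pct_identical`, `n_columns`,
#'   `species_present` (list-column of species ids with full non-gap
#'   coverage of the window, reference first).
#' @export
conservation_percentage <- function(block_rows, start, end, species_panel) {
  if (end <= start) stop("zero-length window", call. = FALSE)
  stopifnot(length(species_panel) > 0L)
  ref <- block_rows[block_rows$is_ref, ]
  stopifnot(nrow(ref) == 1L)
  cols <- ref_interval_to_columns(ref$text, ref$start, start, end)
  texts <- block_char_matrix(block_rows)
  ref_chars <- toupper(texts[[ref$species]][cols + 1L])
  partners <- setdiff(intersect(species_panel, block_rows$species), ref$species)
  col_ok <- rep(TRUE, length(cols))
  present <- ref$species
  for (sp in partners) {
    sp_chars <- toupper(texts[[sp]][cols + 1L])
    col_ok <- col_ok & sp_chars != "-" & sp_chars == ref_chars
    if (all(sp_chars != "-")) present <- c(present, sp)
  }
  tibble::tibble(
    pct_identical = 100 * sum(col_ok) / length(cols),
    n_columns = length(cols),
    species_present = list(present)
  )
}

#' Annotate motif hits with conservation status
#'
#' Looks up, for each hit, the single MAF block that fully contains it on the
#' reference axis, then records perfect conservation against the partner
#' species and the descriptive panel conservation percentage. Hits not fully
#' contained in any single block are dropped (with a message giving the
#' count): multiz block boundaries rarely split short motifs, and stitching
#' blocks is deliberately avoided.
#'
#' @param hits Hits tibble from [scan_genome()].
#' @param maf MAF tibble from [read_maf()].
#' @param partner_species The conservation filter partner (default
#'   `"human"`).
#' @param species_panel Panel for the descriptive percentage (default: all
#'   species in `maf`).
#' @return `hits` with added columns `conserved` (logical),
#'   `pct_conservation`, `species_present` (list-column); rows outside the
#'   alignment are removed.
#' @export
annotate_conservation <- function(hits, maf, partner_species = "human",
                                  species_panel = NULL) {
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits, conserved = logical(),
                         pct_conservation = numeric(),
                         species_present = list()))
  }
  if (is.null(species_panel)) species_panel <- unique(maf$species)
  refs <- maf[maf$is_ref, ]
  blocks <- split(maf, maf$block)

  annotate_one <- function(chrom, start, end) {
    cand <- refs[refs$chrom == chrom & refs$start <= start & refs$end >= end, ]
    if (nrow(cand) == 0L) {
      return(tibble::tibble(conserved = NA, pct_conservation = NA_real_,
                            species_present = list(character())))
    }
    b <- blocks[[as.character(cand$block[1])]]
    cons <- is_perfectly_conserved(b, start, end, partner_species)
    rec <- conservation_percentage(b, start, end, species_panel)
    tibble::tibble(conserved = cons, pct_conservation = rec$pct_identical,
                   species_present = rec$species_present)
  }

  ann <- purrr::pmap(list(hits$chrom, hits$start, hits$end), annotate_one)
  out <- dplyr::bind_cols(hits, dplyr::bind_rows(ann))
  n_out <- sum(is.na(out$conserved))
  if (n_out > 0L) {
    message(sprintf("%d hit(s) not fully contained in a single alignment block: dropped",
                    n_out))
  }
  out[!is.na(out$conserved), , drop = FALSE]
}
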