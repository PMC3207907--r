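#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every position of `seq` whose window matches the consensus on the
#' forward strand and, when `both_strands`, every window whose reverse
#' complement matches (reported on strand `-`). Coordinates are 0-based
#' half-open on the forward reference axis; `matched_seq` is always the
#' forward-strand reference substring. Overlapping hits are all reported.
#' `N` in the sequence never matches.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @param consensus IUPAC consensus string (length >= 4).
#' @param name Motif label carried into the output.
#' @param both_strands Scan the minus strand too.
#' @param chrom Sequence id carried into the output.
#' @param offset Added to all reported coordinates (use when `seq` is a
#'   slice of a larger reference).
#' @return Tibble with columns `motif`, `chrom`, `start`, `end`, `strand`,
#'   `matched_seq`, sorted by `start` then strand (`+` before `-`).
#' @examples
#' scan_sequence("ATCAATG", "WWCAAWG")
#' @export
scan_sequence <- function(seq, consensus, name = consensus,
                          both_strands = TRUE, chrom = "chr", offset = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L, offset >= 0)
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd_sets <- validate_iupac(consensus)
  L <- length(fwd_sets)
  empty <- tibble::tibble(
    motif = character(), chrom = character(),
    start = integer(), end = integer(),
    strand = character(), matched_seq = character()
  )
  if (n < L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- chars %in% c("A", "C", "G", "T")
  bad <- chars[!ok & chars != "N"]
  if (length(bad) > 0L) {
    stop(sprintf("sequence contains non-nucleotide character '%s'", bad[1]),
         call. = FALSE)
  }

  match_starts <- function(sets) {
    hit <- rep(TRUE, n - L + 1L)
    for (p in seq_len(L)) {
      hit <- hit & chars[p:(n - L + p)] %in% sets[[p]]
    }
    which(hit) - 1L  # 0-based window starts
  }

  starts_plus <- match_starts(fwd_sets)
  res <- list()
  if (length(starts_plus) > 0L) {
    res$plus <- tibble::tibble(
      motif = name, chrom = chrom,
      start = starts_plus + as.integer(offset),
      end = starts_plus + as.integer(offset) + L,
      strand = "+",
      matched_seq = substring(seq, starts_plus + 1L, starts_plus + L)
    )
  }
  if (both_strands) {
    rev_sets <- validate_iupac(iupac_reverse_complement(consensus))
    starts_minus <- match_starts(rev_sets)
    if (length(starts_minus) > 0L) {
      res$minus <- tibble::tibble(
        motif = name, chrom = chrom,
        start = starts_minus + as.integer(offset),
        end = starts_minus + as.integer(offset) + L,
        strand = "-",
        matched_seq = substring(seq, starts_minus + 1L, starts_minus + L)
      )
    }
  }
  if (length(res) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(res), .data$start, .data$strand)
}

#' Scan a genome for a motif set
#'
#' Applies [scan_sequence()] to every record of a genome for every motif of a
#' motif set.
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a (possibly line-wrapped,
#'   multi-record) FASTA file.
#' @param motifs A motif-set tibble ([motif_set()], [default_motifs()]).
#' @return A hits tibble (columns as in [scan_sequence()]) sorted by
#'   `chrom`, `start`, strand.
#' @export
scan_genome <- function(genome, motifs = default_motifs()) {
  seqs <- as_named_sequences(genome)
  hits <- purrr::map(names(seqs), function(chr) {
    purrr::pmap(motifs, function(name, consensus, both_strands) {
      scan_sequence(seqs[[chr]], consensus, name = name,
                    both_strands = both_strands, chrom = chr)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(hits))
  if (nrow(out) == 0L) return(out)
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand, .data$motif)
}

# normalise the accepted genome representations to a named character vector
as_named_sequences <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    set <- Biostrings::readDNAStringSet(genome)
    return(as_named_sequences(set))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("`genome` must be a named character vector, DNAStringSet, or FASTA path",
       call. = FALSE)
}
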