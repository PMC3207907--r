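#' IUPAC nucleotide ambiguity codes
#'
#' Named list mapping each IUPAC code to the set of unambiguous bases it
#' stands for. `N` matches all four bases when it appears in a *motif*;
#' an `N` in the scanned *sequence* never matches (conservative calling on
#' masked genome).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement table covering IUPAC codes (used for consensus reverse complement)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Validate an IUPAC consensus and expand it to per-position base sets
#'
#' @param consensus A single non-empty string over the 15 IUPAC codes
#'   (case-insensitive).
#' @return A list with one character vector of allowed bases per position.
#' @examples
#' validate_iupac("N")   # list(c("A","C","G","T"))
#' validate_iupac("W")   # list(c("A","T"))
#' @export
validate_iupac <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || is.na(consensus) ||
      nchar(consensus) == 0L) {
    stop("`consensus` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0L) {
    # positions are 0-based here as everywhere else in the package
    stop(sprintf("invalid IUPAC symbol '%s' at position %d (0-based) in consensus '%s'",
                 chars[bad[1]], bad[1] - 1L, consensus), call. = FALSE)
  }
  unname(IUPAC_CODES[chars])
}

#' Reverse complement of a nucleotide sequence
#'
#' Strict Watson-Crick reverse complement over `{A,C,G,T,N}`; output is
#' uppercase. The empty string maps to itself.
#'
#' @param seq A single character string.
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("GACCACCCA")  # "TGGGTGGTC"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bad <- which(!chars %in% names(comp))
  if (length(bad) > 0L) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  paste(rev(unname(comp[chars])), collapse = "")
}

#' Reverse complement of an IUPAC consensus
#'
#' Complements ambiguity codes (e.g. `R` -> `Y`, `W` -> `W`) and reverses,
#' so that scanning the minus strand can reuse forward-axis matching.
#'
#' @param consensus IUPAC consensus string.
#' @return The reverse-complement consensus, uppercase.
#' @export
iupac_reverse_complement <- function(consensus) {
  validate_iupac(consensus)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}
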