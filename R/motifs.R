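#' Build a motif set
#'
#' A motif set is a tibble with one row per named IUPAC consensus. Consensus
#' strings are validated at construction; names must be unique and each
#' consensus at least 4 nt long.
#'
#' @param name Character vector of motif labels (e.g. `"SOX9"`).
#' @param consensus Character vector of IUPAC consensus strings.
#' @param both_strands Logical; scan the reverse strand too (recycled).
#' @return A tibble with columns `name`, `consensus`, `both_strands`.
#' @export
motif_set <- function(name, consensus, both_strands = TRUE) {
  stopifnot(length(name) == length(consensus))
  if (anyDuplicated(name)) {
    stop("motif names must be unique", call. = FALSE)
  }
  consensus <- toupper(consensus)
  for (i in seq_along(consensus)) {
    sets <- validate_iupac(consensus[i])
    if (length(sets) < 4L) {
      stop(sprintf("consensus for '%s' is shorter than 4 nt", name[i]),
           call. = FALSE)
    }
  }
  tibble::tibble(
    name = as.character(name),
    consensus = consensus,
    both_strands = rep_len(as.logical(both_strands), length(name))
  )
}

#' Default motif set: SOX9, GLI, TCF
#'
#' Editable defaults for the chondrocyte enhancer screen. The consensus
#' strings follow the literature conventions for each factor: the SOX9
#' heptamer (COL2C1-type site class first defined in the Col2a1 intron-1
#' enhancer), the GLI1/2/3 9-mer, and the TCF/LEF core. They are defaults,
#' not constants: pass any [motif_set()] or a YAML file via [read_motifs()]
#' to scan something else.
#'
#' @return A tibble as produced by [motif_set()].
#' @examples
#' default_motifs()
#' @export
default_motifs <- function() {
  motif_set(
    name = c("SOX9", "GLI", "TCF"),
    consensus = c("WWCAAWG", "GACCACCCA", "CTTTGWW"),
    both_strands = TRUE
  )
}

#' Read a motif set from a YAML config file
#'
#' The file holds a list of entries with fields `name`, `consensus` and
#' (optionally) `both_strands`:
#' ```yaml
#' motifs:
#'   - name: SOX9
#'     consensus: WWCAAWG
#'     both_strands: true
#' ```
#'
#' @param path Path to a YAML file.
#' @return A validated motif-set tibble.
#' @export
read_motifs <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$motifs)) cfg$motifs else cfg
  if (length(entries) == 0L) stop("no motif entries in ", path, call. = FALSE)
  motif_set(
    name = purrr::map_chr(entries, ~ as.character(.x$name)),
    consensus = purrr::map_chr(entries, ~ as.character(.x$consensus)),
    both_strands = purrr::map_lgl(entries, ~ isTRUE(.x$both_strands %||% TRUE))
  )
}

#' Write a motif set to a YAML config file
#'
#' @param motifs A motif-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  entries <- purrr::pmap(motifs, function(name, consensus, both_strands) {
    list(name = name, consensus = consensus, both_strands = both_strands)
  })
  yaml::write_yaml(list(motifs = entries), path)
  invisible(path)
}
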