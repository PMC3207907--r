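#' Convert TSS-relative boundary coordinates to a forward-axis interval
#'
#' Regulatory elements are conventionally reported by promoter-relative
#' boundary positions (negative upstream of the transcription start site).
#' Internally the package works in 0-based half-open coordinates, so a pair
#' of boundaries like (-4286, -3646) maps to the half-open interval
#' `[tss - 4286, tss - 3646)` of width 640 nt.
#'
#' @param from,to TSS-relative boundary coordinates, `from < to` (e.g.
#'   `-4286` and `-3646` for an element wholly upstream).
#' @param tss Forward-axis 0-based coordinate of the transcription start
#'   site (default 0: the interval is returned TSS-relative).
#' @return A one-row tibble: `start`, `end` (0-based half-open), `width`.
#' @examples
#' tss_relative_interval(-4286, -3646)  # width 640
#' @export
tss_relative_interval <- function(from, to, tss = 0L) {
  stopifnot(is.numeric(from), is.numeric(to), length(from) == 1L,
            length(to) == 1L)
  if (from >= to) stop("`from` must be less than `to`", call. = FALSE)
  tibble::tibble(start = tss + from, end = tss + to, width = to - from)
}

#' Convert 0-based half-open intervals to 1-based inclusive (biological)
#'
#' @param x Tibble with `start`, `end` columns (0-based half-open).
#' @return `x` with `start` shifted to 1-based inclusive convention.
#' @export
to_one_based <- function(x) {
  dplyr::mutate(x, start = .data$start + 1L)
}
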