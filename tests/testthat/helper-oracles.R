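# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (window-by-window loops, exact integer enumeration) and
# share no code with the package internals.

iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# brute-force scan: test every window against the per-position base sets,
# forward and (optionally) reverse complement
oracle_scan <- function(seq, consensus, both_strands = TRUE) {
  seq <- toupper(seq)
  sets <- iupac_table[strsplit(toupper(consensus), "")[[1]]]
  L <- length(sets)
  n <- nchar(seq)
  out <- data.frame(start = integer(), strand = character())
  if (n < L) return(out)
  for (i in 0:(n - L)) {
    win <- substr(seq, i + 1, i + L)
    wc <- strsplit(win, "")[[1]]
    if (all(vapply(seq_len(L), function(p) wc[p] %in% sets[[p]], TRUE))) {
      out <- rbind(out, data.frame(start = i, strand = "+"))
    }
    if (both_strands) {
      rc <- strsplit(oracle_revcomp(win), "")[[1]]
      if (all(vapply(seq_len(L), function(p) rc[p] %in% sets[[p]], TRUE))) {
        out <- rbind(out, data.frame(start = i, strand = "-"))
      }
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_iupac_motif <- function(len) {
  # bias toward informative codes so matches are rare but non-trivial
  codes <- c(rep(c("A", "C", "G", "T"), 4), "R", "Y", "S", "W", "K", "M", "N")
  paste(sample(codes, len, replace = TRUE), collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exact one-tailed Fisher by enumerating every table at fixed margins;
# choose() is exact for the totals used (<= 40)
oracle_fisher_tail <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k_tot <- a + c; N <- n1 + n2
  denom <- choose(N, k_tot)
  p <- 0
  for (a2 in max(0, k_tot - n2):min(n1, k_tot)) {
    if (a2 >= a) p <- p + choose(n1, a2) * choose(n2, k_tot - a2) / denom
  }
  p
}

# expected number of background (sox9, gli) hit pairs with inner gap in
# [0, max_spacing] on an i.i.d. sequence of length L at the given GC;
# windows of a pair are disjoint, so expectations multiply
oracle_expected_pairs <- function(L, sox9, gli, gc, max_spacing = 100) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  match_prob <- function(consensus) {
    sets <- iupac_table[strsplit(toupper(consensus), "")[[1]]]
    prod(vapply(sets, function(s) sum(base_p[s]), 0))
  }
  both_prob <- function(consensus) {
    match_prob(consensus) + match_prob(oracle_revcomp_iupac(consensus))
  }
  pS <- both_prob(sox9); pG <- both_prob(gli)
  wS <- nchar(sox9); wG <- nchar(gli)
  count_placements <- function(w1, w2) {
    total <- 0
    for (i in 0:(L - w1)) {
      j_lo <- i + w1; j_hi <- min(i + w1 + max_spacing, L - w2)
      if (j_hi >= j_lo) total <- total + (j_hi - j_lo + 1)
    }
    total
  }
  count_placements(wS, wG) * pS * pG + count_placements(wG, wS) * pG * pS
}

oracle_revcomp_iupac <- function(consensus) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(consensus), "")[[1]]]), collapse = "")
}

# small MAF fixture built in code
maf_text <- function(rows, score = "0.0") {
  c("##maf version=1", "", paste0("a score=", score),
    vapply(rows, identity, ""))
}

write_temp_maf <- function(rows) {
  path <- withr::local_tempfile(fileext = ".maf",
                                .local_envir = parent.frame())
  writeLines(maf_text(rows), path)
  path
}
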