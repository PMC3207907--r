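ref_row <- "s mouse.chr1 10 10 + 1000 ACGTACGTAC"
hum_row <- "s human.chr7 20 10 + 2000 ACGTACGTAC"

test_that("read_maf parses blocks, species prefixes, and strand conversion", {
  path <- write_temp_maf(c(ref_row, hum_row))
  maf <- read_maf(path)
  expect_equal(nrow(maf), 2L)
  expect_equal(maf$species, c("mouse", "human"))
  expect_equal(maf$chrom, c("chr1", "chr7"))
  expect_equal(maf$start, c(10L, 20L))
  expect_equal(maf$end, c(20L, 30L))
  expect_equal(maf$is_ref, c(TRUE, FALSE))

  # '-' strand coordinates converted to the forward axis
  path2 <- write_temp_maf(c(ref_row, "s human.chr7 20 10 - 2000 ACGTACGTAC"))
  maf2 <- read_maf(path2)
  expect_equal(maf2$start[2], 2000L - 20L - 10L)
})

test_that("read_maf returns an empty tibble for an empty file", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(character(), path)
  expect_equal(nrow(read_maf(path)), 0L)
})

test_that("read_maf rejects ragged and malformed rows with a line number", {
  path <- write_temp_maf(c(ref_row, "s human.chr7 20 7 + 2000 ACGTACG"))
  expect_error(read_maf(path), "ragged|line")
  path2 <- write_temp_maf(c("s mouse.chr1 10 10 ACGT"))
  expect_error(read_maf(path2), "line")
  path3 <- write_temp_maf(c(ref_row, "s human.chr7 20 9 + 2000 ACGTACGTAC"))
  expect_error(read_maf(path3), "non-gap")
})

test_that("MAF round-trip preserves coordinates and row texts", {
  path <- write_temp_maf(c("s mouse.chr1 10 8 + 1000 AC-GTACGT",
                           "s human.chr7 1970 9 - 2000 ACTGTACGT"))
  maf <- read_maf(path)
  out <- withr::local_tempfile(fileext = ".maf")
  write_maf(maf, out)
  back <- read_maf(out)
  expect_equal(back$start, maf$start)
  expect_equal(back$end, maf$end)
  expect_equal(back$text, maf$text)
  expect_equal(back$species, maf$species)
})

test_that("reference intervals map to alignment columns through gaps", {
  # reference row "AC-GT" anchored at 0: bases A,C,G,T at columns 0,1,3,4
  expect_equal(ref_interval_to_columns("AC-GT", 0L, 2L, 4L), c(3L, 4L))
  expect_equal(ref_interval_to_columns("AC-GT", 0L, 0L, 2L), c(0L, 1L))
  expect_error(ref_interval_to_columns("AC-GT", 0L, 2L, 6L), "outside")
  # anchored blocks
  expect_equal(ref_interval_to_columns("AC-GT", 100L, 102L, 104L), c(3L, 4L))
})

block_from_rows <- function(...) {
  path <- write_temp_maf(c(...))
  read_maf(path)
}

test_that("perfect conservation requires identity, no gaps, partner present", {
  b <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                       "s human.chr1 0 7 + 100 ATCAATG")
  expect_true(is_perfectly_conserved(b, 0L, 7L, "human"))
  # one mismatch
  b2 <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                        "s human.chr1 0 7 + 100 ATCAATC")
  expect_false(is_perfectly_conserved(b2, 0L, 7L, "human"))
  expect_true(is_perfectly_conserved(b2, 0L, 6L, "human"))
  # a gap column breaks conservation (an indel destroys the site)
  b3 <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                        "s human.chr1 0 6 + 100 ATC-ATG")
  expect_false(is_perfectly_conserved(b3, 0L, 7L, "human"))
  # partner species absent -> FALSE, not an error
  b4 <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                        "s canine.chr1 0 7 + 100 ATCAATG")
  expect_false(is_perfectly_conserved(b4, 0L, 7L, "human"))
  # case-insensitive
  b5 <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                        "s human.chr1 0 7 + 100 atcaatg")
  expect_true(is_perfectly_conserved(b5, 0L, 7L, "human"))
})

panel6 <- c("mouse", "human", "chimpanzee", "canine", "bovine", "opossum")

test_that("conservation percentage counts identical columns across the panel", {
  ref <- "ACGTACGTAC"
  rows <- c(sprintf("s mouse.chr1 0 10 + 100 %s", ref),
            sprintf("s %s.chr1 0 10 + 100 %s",
                    c("human", "chimpanzee", "canine", "bovine"), ref),
            "s opossum.chr1 0 10 + 100 ACGTACGTAG")  # one mismatched column
  b <- block_from_rows(rows)
  rec <- conservation_percentage(b, 0L, 10L, panel6)
  expect_equal(rec$pct_identical, 90)
  expect_equal(rec$n_columns, 10L)
  expect_setequal(rec$species_present[[1]], panel6)
})

test_that("vacuous conservation flags reference-only windows", {
  b <- block_from_rows("s mouse.chr1 0 10 + 100 ACGTACGTAC")
  rec <- conservation_percentage(b, 0L, 10L, panel6)
  expect_equal(rec$pct_identical, 100)
  expect_equal(rec$species_present[[1]], "mouse")
  # all-gap partner row: no panel coverage, zero identical columns
  b2 <- block_from_rows("s mouse.chr1 0 10 + 100 ACGTACGTAC",
                        "s human.chr1 0 0 + 100 ----------")
  rec2 <- conservation_percentage(b2, 0L, 10L, panel6)
  expect_equal(rec2$species_present[[1]], "mouse")
  expect_error(conservation_percentage(b, 0L, 0L, panel6), "zero-length")
})

test_that("conservation percentage is invariant to non-reference row order", {
  rows_a <- c("s mouse.chr1 0 8 + 100 ACGTACGT",
              "s human.chr1 0 8 + 100 ACGTACGA",
              "s bovine.chr1 0 8 + 100 ACCTACGT")
  rows_b <- rows_a[c(1, 3, 2)]
  ra <- conservation_percentage(block_from_rows(rows_a), 0L, 8L, panel6)
  rb <- conservation_percentage(block_from_rows(rows_b), 0L, 8L, panel6)
  expect_equal(ra$pct_identical, rb$pct_identical)
  expect_setequal(ra$species_present[[1]], rb$species_present[[1]])
})

test_that("perfect conservation implies 100% over the ref+partner panel", {
  set.seed(21)
  for (i in 1:10) {
    s <- random_dna(12)
    b <- block_from_rows(sprintf("s mouse.chr1 0 12 + 100 %s", s),
                         sprintf("s human.chr1 0 12 + 100 %s", s))
    expect_true(is_perfectly_conserved(b, 2L, 9L, "human"))
    rec <- conservation_percentage(b, 2L, 9L, c("mouse", "human"))
    expect_equal(rec$pct_identical, 100)
  }
})

test_that("annotate_conservation filters and drops block-spanning hits", {
  maf <- block_from_rows("s mouse.chr1 0 7 + 100 ATCAATG",
                         "s human.chr1 0 7 + 100 ATCAATG")
  hits <- scan_sequence("ATCAATGCC", "WWCAAWG", name = "SOX9", chrom = "chr1")
  ann <- suppressMessages(annotate_conservation(hits, maf))
  expect_true(ann$conserved[1])
  # a hit outside the block's span is dropped with a message
  hits_out <- hits
  hits_out$start <- 50L; hits_out$end <- 57L
  expect_message(
    out <- annotate_conservation(hits_out, maf),
    "not fully contained"
  )
  expect_equal(nrow(out), 0L)
})
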