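write_bed12 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BED12 gene models parse blocks into exons", {
  path <- write_bed12(
    "chr1\t100\t200\tgeneA\t0\t+\t100\t200\t0\t2\t20,30,\t0,70,"
  )
  g <- read_gene_models(path)
  expect_equal(g$gene_id, "geneA")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  ex <- g$exons[[1]]
  expect_equal(ex$start, c(100L, 170L))
  expect_equal(ex$end, c(120L, 200L))
})

test_that("GTF transcripts of one gene collapse to exon union and widest span", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t150\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t121\t180\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t2";')
  ), path)
  g <- read_gene_models(path, format = "gtf")
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 100L)  # 0-based
  expect_equal(g$end, 400L)
  ex <- g$exons[[1]]
  expect_equal(ex$start, c(100L, 300L))  # overlapping exons merged
  expect_equal(ex$end, c(180L, 400L))
})

one_gene <- function() {
  tibble::tibble(
    gene_id = "A", chrom = "chr1", strand = "+", start = 100L, end = 200L,
    exons = list(tibble::tibble(start = 100L, end = 120L))
  )
}

test_that("region mask partitions the chromosome into the three classes", {
  mask <- build_region_mask(one_gene(), c(chr1 = 300L))
  expect_equal(mask$class[mask$start == 0], "intergenic")
  expect_equal(sum(mask$end - mask$start), 300L)
  expect_equal(mask$start[mask$class == "exonic"], 100L)
  expect_equal(mask$end[mask$class == "exonic"], 120L)
  expect_equal(mask$start[mask$class == "intronic"], 120L)
  expect_equal(mask$end[mask$class == "intronic"], 200L)
  expect_equal(sort(mask$start[mask$class == "intergenic"]), c(0L, 200L))
  # intervals tile without overlap
  m <- mask[order(mask$start), ]
  expect_true(all(m$start[-1] == m$end[-nrow(m)]))
})

test_that("mask handles no genes, overlapping genes, and bad input", {
  empty <- build_region_mask(one_gene()[0, ], c(chr1 = 500L))
  expect_equal(empty$class, "intergenic")
  expect_equal(empty$end - empty$start, 500L)

  # exon of gene B overlaps intron of gene A: exonic takes precedence
  two <- dplyr::bind_rows(one_gene(), tibble::tibble(
    gene_id = "B", chrom = "chr1", strand = "+", start = 150L, end = 250L,
    exons = list(tibble::tibble(start = 150L, end = 180L))
  ))
  mask <- build_region_mask(two, c(chr1 = 300L))
  expect_equal(sum(mask$end - mask$start), 300L)
  cls_at <- function(pos) mask$class[mask$start <= pos & pos < mask$end]
  expect_equal(cls_at(160), "exonic")
  expect_equal(cls_at(130), "intronic")

  expect_error(build_region_mask(one_gene(), c(chr1 = 150L)), "beyond")
  expect_error(build_region_mask(one_gene(), c(chr2 = 300L)),
               "no chromosome length")
})

test_that("property: mask intervals sum to chromosome length on random genes", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    len <- 1000L
    starts <- sort(sample(0:800, n))
    genes <- tibble::tibble(
      gene_id = paste0("g", seq_len(n)), chrom = "chr1", strand = "+",
      start = starts, end = pmin(starts + sample(50:200, n, replace = TRUE),
                                 len),
      exons = purrr::map2(starts, pmin(starts + 50L, len),
                          ~ tibble::tibble(start = .x, end = .y))
    )
    mask <- build_region_mask(genes, c(chr1 = len))
    expect_equal(sum(mask$end - mask$start), len)
    m <- mask[order(mask$start), ]
    expect_true(all(m$start[-1] == m$end[-nrow(m)]))
  }
})

test_that("hits overlapping exons are removed from non-coding space", {
  mask <- build_region_mask(one_gene(), c(chr1 = 300L))
  hits <- tibble::tibble(chrom = "chr1",
                         start = c(50L, 110L, 115L, 130L, 250L),
                         end = c(57L, 117L, 122L, 137L, 257L))
  kept <- filter_noncoding(hits, mask)
  expect_equal(kept$start, c(50L, 130L, 250L))  # any exon overlap excluded
})

test_that("gene assignment: containment, nearest, ties, flank limit", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), chrom = "chr1", strand = "+",
    start = c(1000L, 5000L), end = c(2000L, 6000L),
    exons = list(tibble::tibble(start = 1000L, end = 1100L),
                 tibble::tibble(start = 5000L, end = 5100L))
  )
  assign1 <- function(s, e, flank = 50000L) {
    assign_to_gene(tibble::tibble(chrom = "chr1", start = s, end = e),
                   genes, max_flank = flank)$genes[[1]]
  }
  expect_equal(assign1(1500L, 1510L), "A")            # inside intron of A
  expect_equal(assign1(2999L, 3010L), "A")            # nearer to A
  expect_equal(assign1(3500L, 3500L + 0L), c("A", "B"))  # equidistant tie
  expect_equal(assign1(2999L, 3010L, flank = 100L), character())  # beyond flank
  expect_equal(assign1(10L, 20L), "A")
})

test_that("gene assignment is independent of gene input order", {
  set.seed(32)
  genes <- tibble::tibble(
    gene_id = c("A", "B", "C"), chrom = "chr1", strand = "+",
    start = c(100L, 400L, 900L), end = c(200L, 600L, 950L),
    exons = list(tibble::tibble(start = integer(), end = integer()),
                 tibble::tibble(start = integer(), end = integer()),
                 tibble::tibble(start = integer(), end = integer()))
  )
  iv <- tibble::tibble(chrom = "chr1", start = sample(0:1000, 20),
                       end = NA_integer_)
  iv$end <- iv$start + 10L
  a1 <- assign_to_gene(iv, genes)
  a2 <- assign_to_gene(iv, genes[c(3, 1, 2), ])
  expect_equal(a1$genes, a2$genes)
})

test_that("chrom.sizes files read as named lengths", {
  path <- withr::local_tempfile(fileext = ".sizes")
  writeLines(c("chr1\t1000", "chr2\t500"), path)
  cs <- read_chrom_sizes(path)
  expect_equal(cs, c(chr1 = 1000L, chr2 = 500L))
})
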