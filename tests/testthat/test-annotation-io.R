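test_that("GTF CDS features assemble into strand-aware transcripts", {
  tx <- read_annotation(two_exon_gtf("+"), dialect = "gtf", genome_id = "G")
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$cds_exons[[1]]$start, c(1L, 200L))
  expect_equal(tx$cds_exons[[1]]$end, c(99L, 301L))
  expect_equal(tx$cds_nt, 201L)
  expect_equal(tx$protein_length, 66L)  # 201/3 - 1 with the stop codon included

  no_stop <- read_annotation(two_exon_gtf("+"), genome_id = "G", stop_included = FALSE)
  expect_equal(no_stop$protein_length, 67L)

  minus <- read_annotation(two_exon_gtf("-"), genome_id = "G")
  expect_equal(minus$cds_exons[[1]]$start, c(200L, 1L))  # 5'->3' order
  expect_equal(minus$cds_exons[[1]]$end, c(301L, 99L))
})

test_that("a mirrored minus-strand gene has the same exon-length sequence", {
  plus <- read_annotation(two_exon_gtf("+"), genome_id = "G")
  # mirror around position 400: exon (s, e) -> (400 - e, 400 - s)
  mirrored <- write_gtf_fixture(tibble::tibble(
    chrom = "chr1", start = 400L - c(99L, 301L), end = 400L - c(1L, 200L),
    strand = "-", transcript_id = "tx1", protein_id = "p1"
  ))
  minus <- read_annotation(mirrored, genome_id = "G")
  len <- function(tx) tx$cds_exons[[1]]$end - tx$cds_exons[[1]]$start + 1L
  expect_equal(len(minus), len(plus))
  expect_equal(minus$protein_length, plus$protein_length)
})

test_that("parsing is line-order independent", {
  path <- write_gtf_fixture(tibble::tibble(
    chrom = "chr1", start = c(1L, 200L, 500L), end = c(99L, 301L, 601L),
    strand = "+", transcript_id = "tx1", protein_id = "p1"
  ))
  shuffled <- tempfile(fileext = ".gtf")
  writeLines(rev(readLines(path)), shuffled)
  expect_equal(read_annotation(path, genome_id = "G"),
               read_annotation(shuffled, genome_id = "G"))
})

test_that("degenerate annotation inputs are reported, not fatal", {
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_warning(tx <- read_annotation(empty, genome_id = "G"), "empty")
  expect_equal(nrow(tx), 0L)

  # CDS total 200 nt: not a multiple of 3 -> dropped with a warning
  bad <- write_gtf_fixture(tibble::tibble(
    chrom = "chr1", start = c(1L, 200L), end = c(99L, 300L),
    strand = "+", transcript_id = "txbad", protein_id = "pbad"
  ))
  expect_warning(tx <- read_annotation(bad, genome_id = "G"), "multiple of 3")
  expect_equal(nrow(tx), 0L)

  trunc <- tempfile(fileext = ".gtf")
  writeLines(c(readLines(two_exon_gtf()), "chr1\tonly\tthree"), trunc)
  expect_error(read_annotation(trunc, genome_id = "G"), "line 3")
})

test_that("GFF3 CDS features are parsed via Parent/protein_id attributes", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tfix\tCDS\t1\t99\t.\t+\t0\tID=cds1;Parent=transcript:tx1;protein_id=p1",
    "chr1\tfix\tCDS\t200\t301\t.\t+\t0\tID=cds2;Parent=transcript:tx1;protein_id=p1"
  ), path)
  tx <- read_annotation(path, dialect = "gff3", genome_id = "G")
  expect_equal(tx$transcript_id, "tx1")
  expect_equal(tx$protein_id, "p1")
  expect_equal(tx$protein_length, 66L)
})

test_that("domain tables are parsed, deduplicated and range-checked", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("P1\td.58.1\t10\t50", "P1\td.58.1\t10\t50", "P1\tb.1.1\t60\t150"), path)
  expect_warning(dom <- read_domains(path, protein_lengths = c(P1 = 100L)),
                 "out of protein range")
  expect_equal(nrow(dom), 1L)  # duplicate collapsed, out-of-range row dropped
  expect_equal(dom$domain_id, "d.58.1")
  expect_equal(dom$start, 10L)
  expect_equal(dom$end, 50L)

  bad <- tempfile(fileext = ".tsv")
  writeLines("P1\td.58.1\tten\t50", bad)
  expect_error(read_domains(bad), "row 1")
})

test_that("disorder regions mode parses and merges touching regions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("P1\t20\t40", "P1\t41\t55", "P2\t5\t9"), path)
  dis <- read_disorder(path, mode = "regions")
  expect_equal(dis$start[dis$protein_id == "P1"], 20L)  # touching regions merged
  expect_equal(dis$end[dis$protein_id == "P1"], 55L)
  expect_equal(dis$source, rep("consensus", 2))
})

test_that("per-predictor disorder applies the 75% consensus rule", {
  track <- function(on) {
    x <- rep(0L, 20L)
    x[on] <- 1L
    paste(x, collapse = "")
  }
  path <- tempfile(fileext = ".tsv")
  # residues 5-10 called by 6 of 8 predictors (exactly 75%): one region
  rows <- c(
    sprintf("P1\tpred%d\t%s", 1:6, track(5:10)),
    sprintf("P1\tpred%d\t%s", 7:8, track(integer(0)))
  )
  writeLines(rows, path)
  dis <- read_disorder(path, mode = "per_predictor", protein_lengths = c(P1 = 20L))
  expect_equal(dis$start, 5L)
  expect_equal(dis$end, 10L)

  # 5 of 8 (62.5%) is below threshold: no region
  rows5 <- c(
    sprintf("P1\tpred%d\t%s", 1:5, track(5:10)),
    sprintf("P1\tpred%d\t%s", 6:8, track(integer(0)))
  )
  writeLines(rows5, path)
  dis5 <- read_disorder(path, mode = "per_predictor")
  expect_equal(nrow(dis5), 0L)

  writeLines(c(sprintf("P1\tpred1\t%s", track(5:10)), "P1\tpred2\t0101"), path)
  expect_error(read_disorder(path, mode = "per_predictor"), "ragged")

  writeLines(sprintf("P1\tpred%d\t%s", 1:8, track(5:10)), path)
  expect_error(read_disorder(path, mode = "per_predictor",
                             protein_lengths = c(P1 = 25L)),
               "protein length")
})

test_that("genome summary tables round-trip field for field", {
  summary <- tibble::tibble(
    genome_id = c("G1", "G2"), class = c("domain", "disorder"),
    n_proteins = c(120L, 98L), n_boundaries = c(640L, 500L),
    observed = c(150L, 40L), expected = c(100, 41.2345678912),
    ratio = c(1.5, 40 / 41.2345678912),
    chi2 = c(27.7777777777778, 0.123456789), p_value = c(1.3e-7, 0.73),
    significant = c(TRUE, FALSE)
  )
  path <- tempfile(fileext = ".tsv")
  write_genome_summary(summary, path)
  back <- read_genome_summary(path)
  expect_equal(as.data.frame(back), as.data.frame(summary), tolerance = 1e-10)

  write_genome_summary(summary[0, ], path)
  expect_equal(nrow(read_genome_summary(path)), 0L)

  expect_error(write_genome_summary(summary[, -3], path), "missing column")
})
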