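test_that("boundary windows hold six residues per interior interval, unioned and clipped", {
  expect_equal(build_boundary_windows(tibble::tibble(start = 10L, end = 50L), 100L),
               c(9L, 10L, 11L, 49L, 50L, 51L))
  expect_equal(build_boundary_windows(tibble::tibble(start = 1L, end = 100L), 100L),
               c(1L, 2L, 99L, 100L))
  w <- build_boundary_windows(tibble::tibble(start = c(10L, 21L), end = c(20L, 30L)), 100L)
  expect_equal(w, c(9L, 10L, 11L, 19L, 20L, 21L, 22L, 29L, 30L, 31L))
  expect_length(w, 10L)  # shared residues counted once
  expect_equal(build_boundary_windows(tibble::tibble(start = integer(), end = integer()), 50L),
               integer(0))
  expect_error(build_boundary_windows(tibble::tibble(start = 0L, end = 10L), 100L),
               "out of range")
  expect_error(build_boundary_windows(tibble::tibble(start = 5L, end = 101L), 100L),
               "out of range")
})

test_that("window set size is at most six per interval with equality iff no clipping/overlap", {
  set.seed(31)
  for (rep in 1:50) {
    L <- sample(20:120, 1)
    k <- sample(1:4, 1)
    s <- sort(sample.int(L, k))
    e <- pmin(L, s + sample(0:30, k, replace = TRUE))
    ivl <- tibble::tibble(start = s, end = e)
    w <- build_boundary_windows(ivl, L)
    expect_lte(length(w), 6L * k)
    raw <- c(s - 1L, s, s + 1L, e - 1L, e, e + 1L)
    no_clip_no_overlap <- all(raw >= 1L & raw <= L) && !anyDuplicated(raw)
    expect_equal(length(w) == 6L * k, no_clip_no_overlap)
  }
})

test_that("consensus calls require at least the threshold fraction of predictors", {
  m6 <- rbind(matrix(1L, 6, 3), matrix(0L, 2, 3))
  expect_equal(consensus_call(m6), c(1L, 1L, 1L))       # 6/8 = 75% inclusive
  m5 <- rbind(matrix(1L, 5, 3), matrix(0L, 3, 3))
  expect_equal(consensus_call(m5), c(0L, 0L, 0L))       # 62.5% below threshold
  single <- matrix(c(1L, 0L, 1L), 1)
  expect_equal(consensus_call(single, threshold = 1), c(1L, 0L, 1L))
  expect_error(consensus_call(list(c(1L, 0L), c(1L, 0L, 1L))), "ragged")
})

test_that("observed counts respect multiset junctions", {
  w <- c(9L, 10L, 11L, 49L, 50L, 51L)
  expect_equal(count_observed(c(33L, 67L), w), 0L)
  expect_equal(count_observed(c(10L, 50L), w), 2L)
  expect_equal(count_observed(c(11L, 11L), w), 2L)
  expect_equal(count_observed(integer(0), w), 0L)
})

test_that("expected counts equal boundaries times window fraction", {
  expect_equal(expected_aligned(3, 6, 100), 0.18)
  expect_equal(expected_aligned(0, 6, 100), 0)
  expect_equal(expected_aligned(5, 80, 80), 5)
})

test_that("expected counts agree with exhaustive junction enumeration", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(5:30, 1)
    k <- sample(0:3, 1)
    n_ivl <- sample(1:2, 1)
    s <- sort(sample.int(L, n_ivl))
    e <- pmin(L, s + sample(0:5, n_ivl, replace = TRUE))
    w <- build_boundary_windows(tibble::tibble(start = s, end = e), L)
    expect_equal(expected_aligned(k, length(w), L),
                 enumerate_expected(k, w, L), tolerance = 1e-9)
  }
})

test_that("filters drop single-exon proteins and sparse genomes", {
  dom <- tibble::tibble(domain_id = "d1", start = 5L, end = 20L)
  rec <- make_records(
    protein_id = c("a", "b", "c", "d"),
    genome_id = c("G1", "G1", "G2", "G2"),
    length = 50L,
    junctions = list(10L, integer(0), 10L, 25L),
    domains = list(dom, dom, dom, dom)
  )
  out <- apply_filters(rec, min_multiexon_proteins = 0)
  expect_equal(out$records$protein_id, c("a", "c", "d"))  # single-exon "b" dropped
  expect_equal(nrow(out$exclusions), 0L)

  out2 <- apply_filters(rec, min_multiexon_proteins = 2)
  expect_equal(out2$exclusions$genome_id, "G1")  # only one multi-exon domain protein
  expect_true(all(out2$records$genome_id == "G2"))
})

test_that("genome aggregation sums eligible proteins and flags undefined ratios", {
  counts <- tibble::tibble(
    protein_id = c("a", "b", "c"), genome_id = "G1", class = "domain",
    n_cds_exons = 2L, length = 100L,
    n_intervals = c(1L, 1L, 0L), n_window_residues = c(6L, 6L, 0L),
    n_boundaries = c(1L, 1L, 1L),
    observed = c(1L, 0L, 1L), expected = c(0.5, 0.5, 0)
  )
  s <- summarize_genome_alignment(counts)
  expect_equal(s$n_proteins, 2L)  # the domainless protein contributes nothing
  expect_equal(s$observed, 1L)
  expect_equal(s$expected, 1.0)
  expect_equal(s$ratio, 1.0)

  zero <- counts
  zero$expected <- 0
  zero$n_intervals <- 1L
  warns <- character(0)
  sz <- withCallingHandlers(
    summarize_genome_alignment(zero),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  expect_true(any(grepl("undefined", warns)))
  expect_true(is.na(sz$ratio))
})

test_that("both-ends counting doubles the boundary events of junction mode", {
  dom <- tibble::tibble(domain_id = "d1", start = 10L, end = 30L)
  rec <- make_records("a", "G1", 100L, junctions = list(c(20L, 40L)),
                      domains = list(dom))
  pj <- protein_alignment_counts(rec, "domain", boundary_mode = "junction")
  pb <- protein_alignment_counts(rec, "domain", boundary_mode = "both_ends")
  expect_equal(pj$n_boundaries, 2L)
  expect_equal(pb$n_boundaries, 4L)
  expect_equal(pb$expected, 2 * pj$expected)
})
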