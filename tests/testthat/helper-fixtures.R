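# Build a GTF file from a table of CDS features (one row per exon).
write_gtf_fixture <- function(exons, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\tfixture\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "%s_g"; transcript_id "%s"; protein_id "%s";',
    exons$chrom, exons$start, exons$end, exons$strand,
    exons$transcript_id, exons$transcript_id, exons$protein_id
  )
  writeLines(lines, path)
  path
}

# Two-exon plus-strand transcript used across parser tests: CDS 1-99 and
# 200-301 (201 nt total).
two_exon_gtf <- function(strand = "+", path = tempfile(fileext = ".gtf")) {
  write_gtf_fixture(tibble::tibble(
    chrom = "chr1", start = c(1L, 200L), end = c(99L, 301L),
    strand = strand, transcript_id = "tx1", protein_id = "p1"
  ), path)
}

# Hand-assembled protein records tibble for stats tests that do not need the
# parser path.
make_records <- function(protein_id, genome_id, length, junctions,
                         domains = NULL, disorder = NULL, n_cds_exons = NULL) {
  n <- length(protein_id)
  empty_dom <- tibble::tibble(domain_id = character(), start = integer(), end = integer())
  empty_dis <- tibble::tibble(start = integer(), end = integer())
  if (is.null(domains)) domains <- rep(list(empty_dom), n)
  if (is.null(disorder)) disorder <- rep(list(empty_dis), n)
  if (is.null(n_cds_exons)) n_cds_exons <- lengths(junctions) + 1L
  tibble::tibble(
    protein_id = protein_id,
    transcript_id = paste0(protein_id, "_t"),
    genome_id = genome_id,
    length = as.integer(length),
    n_cds_exons = as.integer(n_cds_exons),
    junctions = junctions,
    junction_offsets = lapply(junctions, function(j) 3L * j),
    domains = domains,
    disorder = disorder,
    n_domains = vapply(domains, nrow, integer(1)),
    n_disorder = vapply(disorder, nrow, integer(1)),
    architecture = vapply(domains, boundalign::architecture_string, character(1))
  )
}

# Exhaustive-enumeration oracle: exact mean window-hit count over every
# placement (with replacement) of k junctions on residues 1..L.
enumerate_expected <- function(k, window_set, L) {
  if (k == 0L) return(0)
  grids <- rep(list(seq_len(L)), k)
  placements <- as.matrix(expand.grid(grids))
  mean(rowSums(matrix(placements %in% window_set, nrow = nrow(placements))))
}

# Pure-R reference for the bootstrap partition test (independent of the
# compiled kernel).
ref_bootstrap_p <- function(counts, labels, n_trials) {
  df <- merge(as.data.frame(counts), as.data.frame(labels), by = "protein_id")
  per_genome <- split(df, df$genome_id)
  ratio <- function(g, idx) sum(g$observed[idx]) / sum(g$expected[idx])
  actual <- sum(vapply(per_genome, function(g) {
    new <- g$label == "new"
    ratio(g, new) > ratio(g, !new)
  }, logical(1)))
  trial_counts <- vapply(seq_len(n_trials), function(t) {
    sum(vapply(per_genome, function(g) {
      k <- sum(g$label == "new")
      idx <- seq_len(nrow(g)) %in% sample.int(nrow(g), k)
      ratio(g, idx) > ratio(g, !idx)
    }, logical(1)))
  }, numeric(1))
  mean(trial_counts >= actual)
}

# Per-protein (observed, expected) counts for the domain class straight from
# a fast-path bundle, restricted to eligible proteins.
eligible_domain_counts <- function(bundle) {
  rec <- boundalign::bundle_protein_records(bundle)
  rec <- rec[rec$n_cds_exons >= 2L, ]
  pc <- boundalign::protein_alignment_counts(rec, "domain")
  pc[pc$n_intervals > 0L, ]
}
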