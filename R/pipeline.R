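#' Run the full boundary-alignment analysis over a set of genomes
#'
#' Orchestrates every stage: read annotations and tables, map junctions to
#' protein residues, apply the multi-exon and sparse-genome filters, count
#' observed and expected window hits for both boundary classes, aggregate
#' per genome with chi-square significance, classify proteins as new/old,
#' and run the bootstrap partition test and the domain-disorder ratio
#' correlation. A genome whose inputs fail to load is skipped with a logged
#' reason; the run continues.
#'
#' @param genomes A data frame with one row per genome and columns
#'   `genome_id`, `annotation` (GTF/GFF3 path), `domains` (TSV path),
#'   `disorder` (TSV path), and optionally `labels` (TSV path, `NA` to use
#'   the built-in presence/absence novelty rule).
#' @param out_dir Optional output directory; when given, writes
#'   `genome_summary.tsv`, `new_old_summary.tsv`, `bootstrap.json`,
#'   `correlation.json`, `exclusions.tsv` and `log.txt`.
#' @param dialect Annotation dialect, `"gtf"` or `"gff3"`.
#' @param disorder_mode `"per_predictor"` (default) or `"regions"`.
#' @param consensus_threshold Disorder consensus fraction, default 0.75.
#' @param boundary_mode `"junction"` or `"both_ends"`, see
#'   [protein_alignment_counts()].
#' @param alpha Per-genome significance level, default 0.01.
#' @param min_multiexon_proteins Genome-exclusion threshold, default 200.
#' @param min_new_proteins New/old sparse-genome threshold, default 10.
#' @param n_trials Bootstrap trials, default 50000.
#' @param seed Seed for the bootstrap RNG.
#' @param stop_included Stop-codon policy for [read_annotation()].
#' @return A list: `summary` (per-genome, per-class tibble), `new_old`
#'   (per-genome new/old ratios), `bootstrap` (`bootstrap_partition` or
#'   `NULL`), `correlation` (tibble or `NULL`), `exclusions`, `log`
#'   (character vector of decisions).
#' @export
run_pipeline <- function(genomes, out_dir = NULL,
                         dialect = c("gtf", "gff3"),
                         disorder_mode = c("per_predictor", "regions"),
                         consensus_threshold = 0.75,
                         boundary_mode = c("junction", "both_ends"),
                         alpha = 0.01,
                         min_multiexon_proteins = 200,
                         min_new_proteins = 10,
                         n_trials = 50000,
                         seed = NULL,
                         stop_included = TRUE) {
  dialect <- match.arg(dialect)
  disorder_mode <- match.arg(disorder_mode)
  boundary_mode <- match.arg(boundary_mode)
  genomes <- tibble::as_tibble(genomes)
  stopifnot(all(c("genome_id", "annotation", "domains", "disorder") %in% names(genomes)))

  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  note("run: %d genome(s), boundary_mode=%s, consensus=%.2f, alpha=%.3g, min_multiexon=%d, min_new=%d, n_trials=%d, seed=%s",
       nrow(genomes), boundary_mode, consensus_threshold, alpha,
       as.integer(min_multiexon_proteins), as.integer(min_new_proteins),
       as.integer(n_trials), if (is.null(seed)) "NULL" else as.character(seed))

  records_all <- list()
  for (i in seq_len(nrow(genomes))) {
    gid <- genomes$genome_id[i]
    rec <- tryCatch({
      tx <- read_annotation(genomes$annotation[i], dialect = dialect,
                            genome_id = gid, stop_included = stop_included)
      lens <- setNames(tx$protein_length, tx$protein_id)
      dom <- read_domains(genomes$domains[i], protein_lengths = lens)
      dis <- read_disorder(genomes$disorder[i], mode = disorder_mode,
                           protein_lengths = lens,
                           threshold = consensus_threshold)
      build_protein_records(tx, dom, dis, unknown_ids = "drop")
    }, error = function(e) {
      note("genome %s skipped: %s", gid, conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) {
      note("genome %s: %d protein(s) mapped", gid, nrow(rec))
      records_all[[gid]] <- rec
    }
  }
  if (length(records_all) == 0L) stop("no genome could be loaded", call. = FALSE)
  records <- purrr::list_rbind(records_all)

  filt <- apply_filters(records, min_multiexon_proteins = min_multiexon_proteins)
  for (j in seq_len(nrow(filt$exclusions))) {
    note("genome %s excluded: %s", filt$exclusions$genome_id[j],
         filt$exclusions$reason[j])
  }
  records <- filt$records

  counts_dom <- protein_alignment_counts(records, "domain", boundary_mode)
  counts_dis <- protein_alignment_counts(records, "disorder", boundary_mode)
  summary <- summarize_genome_alignment(dplyr::bind_rows(counts_dom, counts_dis),
                                        alpha = alpha)

  correlation <- NULL
  wide <- tidyr::pivot_wider(summary[, c("genome_id", "class", "ratio")],
                             names_from = "class", values_from = "ratio")
  if (all(c("domain", "disorder") %in% names(wide)) && nrow(wide) >= 3L) {
    correlation <- pearson_ratio_correlation(wide$domain, wide$disorder)
    note("domain vs disorder ratio correlation: R=%.3f (p=%.3g, n=%d)",
         correlation$estimate, correlation$p_value, correlation$n)
  }

  # new/old comparison on the domain class
  new_old <- NULL
  bootstrap <- NULL
  labels <- tryCatch({
    if ("labels" %in% names(genomes) && any(!is.na(genomes$labels))) {
      lab_files <- genomes[!is.na(genomes$labels), c("genome_id", "labels")]
      lab <- purrr::map(lab_files$labels, read_novelty_labels) |> purrr::list_rbind()
      # labels may cover proteins the multi-exon filter removed
      lab <- lab[lab$protein_id %in% records$protein_id, , drop = FALSE]
      classify_new_old(records, labels = lab)
    } else {
      classify_new_old(records)
    }
  }, error = function(e) {
    note("new/old classification failed: %s", conditionMessage(e))
    NULL
  })
  if (!is.null(labels) && nrow(labels) > 0L) {
    spars <- tryCatch(exclude_sparse_genomes(labels, min_new_proteins = min_new_proteins),
                      error = function(e) {
                        note("new/old analysis dropped: %s", conditionMessage(e))
                        NULL
                      })
    if (!is.null(spars)) {
      dropped <- spars$report$genome_id[!spars$report$retained]
      if (length(dropped) > 0L) {
        note("genome(s) excluded from new/old analysis (too few new proteins): %s",
             paste(dropped, collapse = ", "))
      }
      eligible <- counts_dom[counts_dom$n_intervals > 0L, , drop = FALSE]
      bootstrap <- tryCatch(
        bootstrap_new_old(eligible, spars$labels[, c("protein_id", "label")],
                          n_trials = n_trials, seed = seed),
        error = function(e) {
          note("bootstrap failed: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(bootstrap)) {
        new_old <- tidy(bootstrap)
        note("bootstrap: new ratio > old ratio in %d/%d genomes, p=%.4g",
             bootstrap$actual_count, bootstrap$n_genomes, bootstrap$p_value)
      }
    }
  }

  result <- list(summary = summary, new_old = new_old, bootstrap = bootstrap,
                 correlation = correlation, exclusions = filt$exclusions,
                 log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_summary(summary, file.path(out_dir, "genome_summary.tsv"))
    if (!is.null(new_old)) {
      readr::write_tsv(new_old, file.path(out_dir, "new_old_summary.tsv"))
    }
    if (!is.null(bootstrap)) {
      jsonlite::write_json(glance(bootstrap), file.path(out_dir, "bootstrap.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
    if (!is.null(correlation)) {
      jsonlite::write_json(correlation, file.path(out_dir, "correlation.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
    readr::write_tsv(filt$exclusions, file.path(out_dir, "exclusions.tsv"))
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  result
}

#' Genome file table for a written synthetic bundle
#'
#' Convenience: lists the per-genome files of a directory produced by
#' [write_bundle()] in the shape [run_pipeline()] expects.
#'
#' @param bundle_dir Directory written by [write_bundle()].
#' @return Tibble `genome_id`, `annotation`, `domains`, `disorder`,
#'   `labels`.
#' @export
bundle_file_table <- function(bundle_dir) {
  gtfs <- sort(list.files(bundle_dir, pattern = "\\.gtf$", full.names = TRUE))
  if (length(gtfs) == 0L) stop("no GTF files in ", bundle_dir, call. = FALSE)
  gid <- sub("\\.gtf$", "", basename(gtfs))
  tibble::tibble(
    genome_id = gid,
    annotation = gtfs,
    domains = file.path(bundle_dir, paste0(gid, "_domains.tsv")),
    disorder = file.path(bundle_dir, paste0(gid, "_disorder.tsv")),
    labels = file.path(bundle_dir, paste0(gid, "_labels.tsv"))
  )
}
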