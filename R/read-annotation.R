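#' Read protein-coding transcript structures from a GTF/GFF3 annotation
#'
#' Extracts the CDS features of every protein-coding transcript and assembles
#' one record per transcript, with CDS exons ordered 5'->3' (descending genomic
#' coordinate on the minus strand). Transcripts whose total CDS length is not a
#' multiple of three (annotated frameshifts, partial CDS) are dropped with a
#' warning: codon-phase bookkeeping is undefined for them.
#'
#' Genomic coordinates are 1-based inclusive, as in both GTF and GFF3.
#'
#' @param path Path to a GTF or GFF3 file. Only `CDS` features are used; they
#'   must carry `transcript_id` and `protein_id` attributes (GFF3: `Parent`
#'   and `protein_id`).
#' @param dialect `"gtf"` or `"gff3"`.
#' @param genome_id Genome identifier attached to every transcript. Defaults
#'   to the file name without extension.
#' @param stop_included If `TRUE` (default), the final codon of the CDS is
#'   taken to be the stop codon, so `protein_length = total_cds_nt / 3 - 1`.
#'   Set `FALSE` for annotations whose CDS excludes the stop codon
#'   (`protein_length = total_cds_nt / 3`).
#'
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `protein_id`, `genome_id`, `chrom`, `strand`, `n_cds_exons`, `cds_nt`,
#'   `protein_length`, and a list-column `cds_exons` of tibbles
#'   (`start`, `end`) in 5'->3' transcript order.
#' @export
read_annotation <- function(path, dialect = c("gtf", "gff3"), genome_id = NULL,
                            stop_included = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gtf|gff3?|gff)$", "", basename(path), ignore.case = TRUE)
  }

  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    warning("annotation file is empty: ", path, call. = FALSE)
    return(empty_transcripts())
  }
  nfields <- lengths(strsplit(lines[body_idx], "\t", fixed = TRUE))
  bad <- body_idx[nfields < 8L]
  if (length(bad) > 0L) {
    stop("unparseable annotation line ", bad[1L], " in ", path,
         " (", nfields[match(bad[1L], body_idx)], " tab-separated fields, expected >= 8)",
         call. = FALSE)
  }

  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  df <- df[!is.na(df$type) & df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no CDS features in ", path, call. = FALSE)
    return(empty_transcripts())
  }

  if (dialect == "gtf") {
    tx <- as.character(df$transcript_id %||% rep(NA_character_, nrow(df)))
  } else {
    parent <- df$Parent
    tx <- vapply(as.list(parent), function(p) {
      if (length(p) == 0L) NA_character_ else sub("^transcript:", "", p[[1L]])
    }, character(1))
  }
  prot <- if ("protein_id" %in% names(df)) as.character(df$protein_id) else rep(NA_character_, nrow(df))

  no_prot <- is.na(prot) | !nzchar(prot)
  if (any(no_prot)) {
    skipped <- unique(tx[no_prot])
    warning(length(skipped), " transcript(s) without protein_id skipped: ",
            paste(head(skipped, 5L), collapse = ", "), call. = FALSE)
    keep <- !tx %in% skipped
    df <- df[keep, , drop = FALSE]
    tx <- tx[keep]
    prot <- prot[keep]
  }
  if (nrow(df) == 0L) {
    return(empty_transcripts())
  }

  cds <- tibble::tibble(
    transcript_id = tx,
    protein_id = prot,
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = as.integer(df$start),
    end = as.integer(df$end)
  )

  out <- cds |>
    dplyr::group_by(.data$transcript_id, .data$protein_id, .data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    tidyr::nest(cds_exons = c("start", "end")) |>
    dplyr::ungroup()

  exons_5to3 <- purrr::map2(out$cds_exons, out$strand, function(ex, s) {
    if (s == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
  })
  overlapping <- purrr::map_lgl(out$cds_exons, function(ex) {
    nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])
  })
  if (any(overlapping)) {
    warning(sum(overlapping), " transcript(s) with overlapping CDS exons dropped: ",
            paste(head(out$transcript_id[overlapping], 5L), collapse = ", "),
            call. = FALSE)
  }
  out$cds_exons <- exons_5to3
  out <- out[!overlapping, , drop = FALSE]

  out$n_cds_exons <- purrr::map_int(out$cds_exons, nrow)
  out$cds_nt <- purrr::map_int(out$cds_exons, ~ sum(.x$end - .x$start + 1L))

  not_mod3 <- out$cds_nt %% 3L != 0L
  if (any(not_mod3)) {
    warning(sum(not_mod3), " transcript(s) with CDS length not a multiple of 3 dropped: ",
            paste(head(out$transcript_id[not_mod3], 5L), collapse = ", "),
            call. = FALSE)
    out <- out[!not_mod3, , drop = FALSE]
  }
  out$protein_length <- out$cds_nt %/% 3L - if (stop_included) 1L else 0L
  too_short <- out$protein_length < 1L
  if (any(too_short)) {
    warning(sum(too_short), " transcript(s) with zero-length protein dropped", call. = FALSE)
    out <- out[!too_short, , drop = FALSE]
  }

  out$genome_id <- genome_id
  dplyr::select(out, "transcript_id", "protein_id", "genome_id", "chrom",
                "strand", "n_cds_exons", "cds_nt", "protein_length", "cds_exons")
}

empty_transcripts <- function() {
  tibble::tibble(
    transcript_id = character(), protein_id = character(),
    genome_id = character(), chrom = character(), strand = character(),
    n_cds_exons = integer(), cds_nt = integer(), protein_length = integer(),
    cds_exons = list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
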