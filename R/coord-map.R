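#' Map a splice junction from spliced-CDS nucleotide position to protein residue
#'
#' A junction is addressed by the 1-based index, along the spliced CDS, of the
#' last coding nucleotide of the upstream exon. It maps to the residue whose
#' codon contains that nucleotide: `ceiling(index / 3)`. A phase-0 junction
#' (index divisible by 3) therefore maps to the residue completed by the
#' upstream exon; phase-1/2 junctions map to the residue encoded by the split
#' codon.
#'
#' @param cds_nt_index Integer vector of 1-based nucleotide indices along the
#'   spliced CDS.
#' @param total_cds_nt Total spliced CDS length in nucleotides; every index
#'   must satisfy `1 <= index < total_cds_nt`.
#' @return Integer vector of 1-based residue indices.
#' @export
junction_to_residue <- function(cds_nt_index, total_cds_nt) {
  idx <- as.integer(cds_nt_index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx >= total_cds_nt)) {
    stop("cds_nt_index must lie in [1, total_cds_nt - 1]", call. = FALSE)
  }
  (idx + 2L) %/% 3L
}

#' Build per-protein records from transcripts and annotations
#'
#' Combines transcript CDS structures with domain and disorder assignments
#' into one record per protein: protein length, the residues of all internal
#' splice junctions (one per junction, `n_cds_exons - 1` of them), the
#' attached domain and disorder intervals, and the N->C domain architecture
#' string. Junctions that map beyond the protein length (possible only when a
#' junction lies inside the stop codon) are discarded with a warning.
#'
#' @param transcripts Tibble from [read_annotation()] (or
#'   [generate_bundle()]).
#' @param domains Optional tibble `protein_id`, `domain_id`, `start`, `end`.
#' @param disorder Optional tibble `protein_id`, `start`, `end`.
#' @param unknown_ids What to do when an annotation row references a protein
#'   absent from `transcripts`: `"error"` (default) or `"drop"` with a
#'   warning.
#' @return A tibble with one row per protein: identifiers, `length`,
#'   `n_cds_exons`, list-columns `junctions` (residues) and
#'   `junction_offsets` (spliced-CDS nucleotide indices), `domains`,
#'   `disorder`, counts `n_domains`/`n_disorder`, and `architecture`.
#' @export
build_protein_records <- function(transcripts, domains = NULL, disorder = NULL,
                                  unknown_ids = c("error", "drop")) {
  unknown_ids <- match.arg(unknown_ids)
  stopifnot(is.data.frame(transcripts))

  known <- transcripts$protein_id
  domains <- check_annotation_ids(domains, known, "domain", unknown_ids)
  disorder <- check_annotation_ids(disorder, known, "disorder", unknown_ids)

  offs <- purrr::map(transcripts$cds_exons, function(ex) {
    lens <- ex$end - ex$start + 1L
    n <- length(lens)
    if (n < 2L) integer(0) else cumsum(lens)[-n]
  })
  resid <- purrr::map2(offs, transcripts$cds_nt,
                       function(o, tot) if (length(o) == 0L) integer(0) else junction_to_residue(o, tot))

  lens <- transcripts$protein_length
  n_beyond <- sum(purrr::map2_int(resid, lens, ~ sum(.x > .y)))
  if (n_beyond > 0L) {
    warning(n_beyond, " junction(s) mapping beyond the protein length ",
            "(inside the stop codon) discarded", call. = FALSE)
    keep <- purrr::map2(resid, lens, ~ .x <= .y)
    resid <- purrr::map2(resid, keep, ~ .x[.y])
    offs <- purrr::map2(offs, keep, ~ .x[.y])
  }

  dom_split <- split_by_protein(domains, known)
  dis_split <- split_by_protein(disorder, known)

  tibble::tibble(
    protein_id = transcripts$protein_id,
    transcript_id = transcripts$transcript_id,
    genome_id = transcripts$genome_id,
    length = as.integer(lens),
    n_cds_exons = transcripts$n_cds_exons,
    junctions = resid,
    junction_offsets = offs,
    domains = dom_split,
    disorder = dis_split,
    n_domains = purrr::map_int(dom_split, nrow),
    n_disorder = purrr::map_int(dis_split, nrow),
    architecture = purrr::map_chr(dom_split, architecture_string)
  )
}

check_annotation_ids <- function(ann, known, what, unknown_ids) {
  if (is.null(ann) || nrow(ann) == 0L) return(ann)
  missing <- !ann$protein_id %in% known
  if (any(missing)) {
    ids <- unique(ann$protein_id[missing])
    msg <- paste0(length(ids), " ", what, " protein id(s) absent from transcripts: ",
                  paste(head(ids, 5L), collapse = ", "))
    if (unknown_ids == "error") stop(msg, call. = FALSE)
    warning(msg, "; rows dropped", call. = FALSE)
    ann <- ann[!missing, , drop = FALSE]
  }
  ann
}

split_by_protein <- function(ann, ids) {
  empty <- if (is.null(ann)) {
    tibble::tibble(start = integer(), end = integer())
  } else {
    ann[0L, setdiff(names(ann), "protein_id"), drop = FALSE]
  }
  if (is.null(ann) || nrow(ann) == 0L) {
    return(rep(list(empty), length(ids)))
  }
  keep_cols <- setdiff(names(ann), "protein_id")
  by_id <- split(ann[, keep_cols, drop = FALSE], ann$protein_id)
  out <- by_id[ids]
  out[vapply(out, is.null, logical(1))] <- list(empty)
  names(out) <- NULL
  lapply(out, tibble::as_tibble)
}
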