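#' Domain architecture string of a protein
#'
#' The architecture is the ordered N->C comma-joined sequence of domain
#' identifiers. Overlapping assignments are resolved deterministically by
#' keeping the longer one (ties: the one with the smaller start), so that
#' every protein has a single reproducible architecture token.
#'
#' @param domains Tibble with columns `domain_id`, `start`, `end` for one
#'   protein; may be empty.
#' @return A string, empty (`""`) when there are no domains.
#' @export
architecture_string <- function(domains) {
  if (is.null(domains) || nrow(domains) == 0L) return("")
  len <- domains$end - domains$start + 1L
  ord <- order(-len, domains$start)
  kept <- integer(0)
  for (i in ord) {
    overlaps <- any(domains$start[i] <= domains$end[kept] &
                      domains$end[i] >= domains$start[kept])
    if (!overlaps) kept <- c(kept, i)
  }
  kept <- kept[order(domains$start[kept])]
  paste(domains$domain_id[kept], collapse = ",")
}

#' Classify proteins as carrying novel ('new') or shared ('old') architectures
#'
#' With a label table, those labels win verbatim. Otherwise a built-in
#' presence/absence rule is applied: a domain-containing protein is 'new'
#' when its architecture occurs in exactly one genome of the clade (its
#' own), and 'old' when the architecture is also seen in another genome.
#' Proteins without domains have no architecture and are excluded from the
#' new/old analysis.
#'
#' @param records Tibble from [build_protein_records()], covering all
#'   genomes of the clade.
#' @param clade Optional character vector of genome ids defining the clade;
#'   defaults to every genome present in `records`.
#' @param labels Optional tibble `protein_id`, `label` (e.g. from
#'   [read_novelty_labels()]); referencing unknown proteins is an error.
#' @return Tibble `protein_id`, `genome_id`, `architecture`, `label`.
#' @export
classify_new_old <- function(records, clade = NULL, labels = NULL) {
  if (is.null(clade)) clade <- unique(records$genome_id)
  dc <- records[records$genome_id %in% clade & records$n_domains > 0L, , drop = FALSE]

  if (!is.null(labels)) {
    unknown <- setdiff(labels$protein_id, records$protein_id)
    if (length(unknown) > 0L) {
      stop("label file references unknown protein id(s): ",
           paste(head(unknown, 10L), collapse = ", "), call. = FALSE)
    }
    out <- dplyr::inner_join(
      dplyr::select(dc, "protein_id", "genome_id", "architecture"),
      labels, by = "protein_id"
    )
    return(out)
  }

  if (length(clade) == 1L) {
    warning("clade contains a single genome: every architecture is unique ",
            "and every domain-containing protein is labelled 'new'",
            call. = FALSE)
  }
  n_genomes_with <- dc |>
    dplyr::distinct(.data$architecture, .data$genome_id) |>
    dplyr::count(.data$architecture, name = "n_genomes")
  out <- dc |>
    dplyr::select("protein_id", "genome_id", "architecture") |>
    dplyr::left_join(n_genomes_with, by = "architecture")
  out$label <- ifelse(out$n_genomes == 1L, "new", "old")
  dplyr::select(out, "protein_id", "genome_id", "architecture", "label")
}

#' Exclude genomes with too few novel-architecture proteins
#'
#' Genomes with very few 'new' proteins cannot support a stable new-vs-old
#' ratio comparison and are dropped from that analysis.
#'
#' @param labels Tibble from [classify_new_old()] (needs `genome_id`,
#'   `label`).
#' @param min_new_proteins Minimum number of 'new' proteins per genome,
#'   default 10.
#' @return A list: `labels` (restricted to retained genomes) and `report`
#'   (tibble `genome_id`, `n_new`, `retained`).
#' @export
exclude_sparse_genomes <- function(labels, min_new_proteins = 10) {
  report <- labels |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_new = sum(.data$label == "new"), .groups = "drop")
  report$retained <- report$n_new >= min_new_proteins
  if (!any(report$retained)) {
    stop("no genome has at least ", min_new_proteins,
         " proteins with novel architectures", call. = FALSE)
  }
  list(
    labels = labels[labels$genome_id %in% report$genome_id[report$retained], , drop = FALSE],
    report = report
  )
}
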