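#' Consensus disorder call across predictor tracks
#'
#' A residue is called disordered when at least `threshold` of the predictor
#' tracks call it (default 75%, the D2P2-style consensus rule).
#'
#' @param tracks Matrix of 0/1 calls (rows = predictors, columns = residues)
#'   or a list of equal-length 0/1 vectors.
#' @param threshold Minimum fraction of predictors, default 0.75. The
#'   comparison is inclusive: 6 of 8 predictors meet a 0.75 threshold.
#' @return Integer 0/1 vector, one entry per residue.
#' @export
consensus_call <- function(tracks, threshold = 0.75) {
  if (is.list(tracks) && !is.matrix(tracks)) {
    if (length(tracks) == 0L) stop("at least one track required", call. = FALSE)
    if (length(unique(lengths(tracks))) != 1L) {
      stop("ragged track lengths", call. = FALSE)
    }
    tracks <- do.call(rbind, lapply(tracks, as.integer))
  }
  tracks <- as.matrix(tracks)
  if (nrow(tracks) < 1L) stop("at least one track required", call. = FALSE)
  # small slack keeps exact-fraction cases (6/8 at 0.75) inclusive under
  # floating-point thresholds
  as.integer(colSums(tracks != 0) >= threshold * nrow(tracks) - 1e-9)
}

#' Boundary windows around domain or disorder intervals
#'
#' For each interval, the window covers the start and end residues plus one
#' residue on either side of each: six residues per interior interval.
#' Windows from all intervals are unioned (shared residues counted once) and
#' clipped to `[1, protein_length]`.
#'
#' @param intervals Data frame with integer columns `start`, `end`
#'   (1-based inclusive residues), or a 2-column matrix.
#' @param protein_length Protein length in residues.
#' @return Sorted integer vector of distinct window residues.
#' @export
build_boundary_windows <- function(intervals, protein_length) {
  if (is.matrix(intervals)) {
    intervals <- tibble::tibble(start = intervals[, 1L], end = intervals[, 2L])
  }
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer(0))
  s <- as.integer(intervals$start)
  e <- as.integer(intervals$end)
  if (any(s < 1L) || any(e > protein_length) || any(s > e)) {
    stop("interval out of range [1, ", protein_length, "]", call. = FALSE)
  }
  window_residue_set(s, e, protein_length)
}

# validation-free core, shared with the synthetic generator's hot loop
window_residue_set <- function(s, e, protein_length) {
  w <- c(s - 1L, s, s + 1L, e - 1L, e, e + 1L)
  sort(unique(w[w >= 1L & w <= protein_length]))
}

#' Observed number of junctions inside boundary windows
#'
#' Counts junction entries (as a multiset: repeated residues count
#' repeatedly) whose residue lies in the window set.
#'
#' @param junction_residues Integer vector of junction residues (multiset).
#' @param window_set Integer vector of window residues.
#' @return Integer count.
#' @export
count_observed <- function(junction_residues, window_set) {
  sum(junction_residues %in% window_set)
}

#' Expected number of junctions inside boundary windows under uniform placement
#'
#' Under the null, each junction is placed uniformly over the protein's
#' residues, so the expected window-hit count is the number of junctions
#' times the window fraction of the protein.
#'
#' @param n_boundaries Number of junctions.
#' @param n_window_residues Size of the window residue set.
#' @param protein_length Protein length in residues (> 0).
#' @return Real expected count, `n_boundaries * n_window_residues /
#'   protein_length`.
#' @export
expected_aligned <- function(n_boundaries, n_window_residues, protein_length) {
  stopifnot(all(protein_length > 0),
            all(n_window_residues >= 0), all(n_window_residues <= protein_length))
  n_boundaries * n_window_residues / protein_length
}

#' Per-protein observed and expected boundary-alignment counts
#'
#' For each protein record, builds the boundary windows of the requested
#' class (domain or disorder intervals), counts the internal splice junctions
#' falling inside them, and computes the uniform-placement expectation.
#'
#' @param records Tibble from [build_protein_records()].
#' @param class `"domain"` or `"disorder"`: which intervals define windows.
#' @param boundary_mode `"junction"` (default): each internal splice junction
#'   is one boundary event at the residue of the last nucleotide of the
#'   upstream exon. `"both_ends"`: each junction contributes two events — the
#'   end of the upstream exon and the start of the downstream exon —
#'   `2 * (n_cds_exons - 1)` in total.
#' @return Tibble with one row per protein: `protein_id`, `genome_id`,
#'   `class`, `n_cds_exons`, `length`, `n_intervals`, `n_window_residues`,
#'   `n_boundaries`, `observed`, `expected`.
#' @export
protein_alignment_counts <- function(records, class = c("domain", "disorder"),
                                     boundary_mode = c("junction", "both_ends")) {
  class <- match.arg(class)
  boundary_mode <- match.arg(boundary_mode)
  ivls <- if (class == "domain") records$domains else records$disorder

  windows <- purrr::map2(ivls, records$length, build_boundary_windows)
  boundaries <- if (boundary_mode == "junction") {
    records$junctions
  } else {
    purrr::map2(records$junction_offsets, records$length, function(o, L) {
      if (length(o) == 0L) return(integer(0))
      r <- c((o + 2L) %/% 3L, (o + 3L) %/% 3L)  # end of exon i, start of exon i+1
      r[r <= L]
    })
  }

  n_window <- lengths(windows)
  n_b <- lengths(boundaries)
  tibble::tibble(
    protein_id = records$protein_id,
    genome_id = records$genome_id,
    class = class,
    n_cds_exons = records$n_cds_exons,
    length = records$length,
    n_intervals = purrr::map_int(ivls, nrow),
    n_window_residues = as.integer(n_window),
    n_boundaries = as.integer(n_b),
    observed = purrr::map2_int(boundaries, windows, count_observed),
    expected = expected_aligned(n_b, n_window, records$length)
  )
}

#' Multi-exon and sparse-genome filters
#'
#' Drops proteins encoded by a single CDS exon (they have no internal splice
#' junction) and excludes genomes whose number of multi-exon,
#' domain-containing proteins falls below a threshold — genomes with so few
#' multi-exon transcripts carry no signal for the analysis.
#'
#' @param records Tibble from [build_protein_records()].
#' @param min_multiexon_proteins Minimum count of multi-exon,
#'   domain-containing proteins for a genome to be retained (default 200;
#'   set 0 to disable).
#' @return A list: `records` (filtered tibble) and `exclusions` (tibble
#'   `genome_id`, `n_multiexon_domain`, `reason`).
#' @export
apply_filters <- function(records, min_multiexon_proteins = 200) {
  multi <- records[records$n_cds_exons >= 2L, , drop = FALSE]
  per_genome <- multi |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_multiexon_domain = sum(.data$n_domains > 0L), .groups = "drop")
  excluded <- per_genome[per_genome$n_multiexon_domain < min_multiexon_proteins, , drop = FALSE]
  excluded$reason <- sprintf("fewer than %d multi-exon domain-containing proteins",
                             min_multiexon_proteins)
  list(
    records = multi[!multi$genome_id %in% excluded$genome_id, , drop = FALSE],
    exclusions = excluded
  )
}

#' Aggregate alignment counts over a genome's eligible proteins
#'
#' Sums the per-protein observed and expected counts over the proteins with
#' at least one interval of the class (a protein with no domain contributes
#' nothing to the domain-class sums), and attaches the observed/expected
#' ratio and a two-cell chi-square goodness-of-fit test per genome.
#'
#' @param protein_counts Tibble from [protein_alignment_counts()], possibly
#'   covering several genomes and classes (row-bind them first).
#' @param alpha Significance level for the `significant` flag, default 0.01.
#' @param eligibility `"own_class"` (default): a genome's sum for a class
#'   runs over proteins with at least one interval of that class.
#'   `"domain"`: both classes are summed over domain-containing proteins (a
#'   sensitivity analysis).
#' @return Tibble with one row per genome and class: `genome_id`, `class`,
#'   `n_proteins`, `n_boundaries`, `observed`, `expected`, `ratio`, `chi2`,
#'   `p_value`, `significant`. The ratio is `NA` (flagged by a warning) when
#'   the pooled expected count is zero.
#' @export
summarize_genome_alignment <- function(protein_counts, alpha = 0.01,
                                       eligibility = c("own_class", "domain")) {
  eligibility <- match.arg(eligibility)
  eligible <- if (eligibility == "own_class") {
    protein_counts[protein_counts$n_intervals > 0L, , drop = FALSE]
  } else {
    dc <- protein_counts$protein_id[protein_counts$class == "domain" &
                                      protein_counts$n_intervals > 0L]
    protein_counts[protein_counts$protein_id %in% dc, , drop = FALSE]
  }
  out <- eligible |>
    dplyr::group_by(.data$genome_id, .data$class) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_boundaries = sum(.data$n_boundaries),
      observed = sum(.data$observed),
      expected = sum(.data$expected),
      .groups = "drop"
    )
  if (any(out$expected <= 0)) {
    warning("genome(s) with zero pooled expected count: ratio undefined",
            call. = FALSE)
  }
  out$ratio <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  chi <- chi_square_obs_exp(out$observed, out$expected, out$n_boundaries)
  out$chi2 <- chi$chi2
  out$p_value <- chi$p_value
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
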