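#' Read a protein domain assignment table
#'
#' Parses a SUPERFAMILY-style TSV of structural domain assignments: one row
#' per assignment with protein identifier, domain identifier and 1-based
#' inclusive residue coordinates. A header row naming the columns is optional.
#' Duplicate rows are collapsed to one assignment.
#'
#' @param path Path to a TSV with columns `protein_id`, `domain_id`, `start`,
#'   `end`.
#' @param protein_lengths Optional named integer vector (or data frame with
#'   columns `protein_id`, `protein_length`) of protein lengths. Assignments
#'   whose coordinates fall outside `[1, protein_length]` are dropped with a
#'   warning.
#' @return A tibble `protein_id`, `domain_id`, `start`, `end`.
#' @export
read_domains <- function(path, protein_lengths = NULL) {
  df <- read_coord_tsv(path, c("protein_id", "domain_id", "start", "end"),
                       int_cols = c("start", "end"))
  df <- dplyr::distinct(df)
  bad <- df$start < 1L | df$end < df$start
  df <- drop_rows(df, bad, "domain assignment(s) with invalid coordinates")
  df <- drop_out_of_range(df, protein_lengths, "domain assignment(s)")
  df
}

#' Read protein disorder annotations
#'
#' Two input shapes are supported. In `regions` mode the file holds consensus
#' disordered regions directly (`protein_id`, `start`, `end`). In
#' `per_predictor` mode the file holds one binary residue track per predictor
#' per protein (`protein_id`, `predictor`, `calls` with `calls` a 0/1 string,
#' one character per residue); tracks are collapsed by [consensus_call()] — a
#' residue is disordered when at least `threshold` of the predictors call it —
#' and run-length encoded into maximal regions.
#'
#' @param path Path to the TSV.
#' @param mode `"regions"` or `"per_predictor"`.
#' @param protein_lengths As in [read_domains()]. In `per_predictor` mode a
#'   track whose length disagrees with the known protein length is an error.
#' @param threshold Consensus fraction, default 0.75.
#' @return A tibble `protein_id`, `start`, `end`, `source`, regions per
#'   protein non-overlapping and maximal.
#' @export
read_disorder <- function(path, mode = c("regions", "per_predictor"),
                          protein_lengths = NULL, threshold = 0.75) {
  mode <- match.arg(mode)
  if (mode == "regions") {
    df <- read_coord_tsv(path, c("protein_id", "start", "end"),
                         int_cols = c("start", "end"))
    df <- dplyr::distinct(df)
    bad <- df$start < 1L | df$end < df$start
    df <- drop_rows(df, bad, "disorder region(s) with invalid coordinates")
    df <- drop_out_of_range(df, protein_lengths, "disorder region(s)")
    df <- merge_touching_regions(df)
    df$source <- "consensus"
    return(df)
  }

  df <- read_coord_tsv(path, c("protein_id", "predictor", "calls"), int_cols = character())
  lens <- length_lookup(protein_lengths)
  out <- df |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_map(function(g, key) {
      pid <- key$protein_id[[1L]]
      tracks <- lapply(g$calls, function(s) as.integer(strsplit(s, "")[[1L]]))
      n <- lengths(tracks)
      if (length(unique(n)) != 1L) {
        stop("ragged predictor tracks for protein ", pid, call. = FALSE)
      }
      if (!is.null(lens) && pid %in% names(lens) && n[1L] != lens[[pid]]) {
        stop("predictor track length ", n[1L], " != protein length ",
             lens[[pid]], " for protein ", pid, call. = FALSE)
      }
      cons <- consensus_call(do.call(rbind, tracks), threshold = threshold)
      reg <- regions_from_track(cons)
      if (nrow(reg) == 0L) return(NULL)
      tibble::tibble(protein_id = pid, start = reg$start, end = reg$end)
    }) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(protein_id = character(), start = integer(), end = integer())
  }
  out$source <- "consensus"
  out
}

#' Read a new/old protein label table
#'
#' @param path TSV with columns `protein_id`, `label` (`new` or `old`);
#'   header optional.
#' @return A tibble `protein_id`, `label`.
#' @export
read_novelty_labels <- function(path) {
  df <- read_coord_tsv(path, c("protein_id", "label"), int_cols = character())
  bad <- !df$label %in% c("new", "old")
  if (any(bad)) {
    stop("invalid novelty label(s): ", paste(unique(df$label[bad]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::distinct(df)
}

#' Write and re-read the per-genome alignment summary table
#'
#' The summary TSV holds one row per genome and boundary class with the pooled
#' observed and expected window-hit counts, their ratio, and the chi-square
#' significance. `read_genome_summary()` round-trips the table field for
#' field.
#'
#' @param summaries Tibble as produced by [summarize_genome_alignment()].
#' @param path Output path.
#' @return `write_genome_summary()` returns `path` invisibly;
#'   `read_genome_summary()` returns the tibble.
#' @export
write_genome_summary <- function(summaries, path) {
  cols <- c("genome_id", "class", "n_proteins", "n_boundaries", "observed",
            "expected", "ratio", "chi2", "p_value", "significant")
  missing <- setdiff(cols, names(summaries))
  if (length(missing) > 0L) {
    stop("summary table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(summaries[, cols], path)
  invisible(path)
}

#' @rdname write_genome_summary
#' @export
read_genome_summary <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    genome_id = "c", class = "c", n_proteins = "i",
                    n_boundaries = "i", observed = "i", expected = "d",
                    ratio = "d", chi2 = "d", p_value = "d", significant = "l"
                  ))
}

# --- internal helpers -------------------------------------------------------

read_coord_tsv <- function(path, col_names, int_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- length(first) > 0L &&
    identical(strsplit(first, "\t", fixed = TRUE)[[1L]][1L], col_names[1L])
  df <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else col_names,
    col_types = readr::cols(.default = "c"),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0L) {
    stop(path, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, col_names, drop = FALSE]
  for (col in int_cols) {
    raw <- df[[col]]
    ok <- grepl("^[0-9]+$", raw)
    if (any(!ok)) {
      row <- which(!ok)[1L] + has_header
      stop("non-integer value '", raw[!ok][1L], "' in column ", col,
           " at row ", row, " of ", path, call. = FALSE)
    }
    df[[col]] <- as.integer(raw)
  }
  df
}

length_lookup <- function(protein_lengths) {
  if (is.null(protein_lengths)) return(NULL)
  if (is.data.frame(protein_lengths)) {
    len_col <- intersect(c("protein_length", "length"), names(protein_lengths))[1L]
    if (is.na(len_col) || !"protein_id" %in% names(protein_lengths)) {
      stop("protein_lengths data frame needs columns protein_id and protein_length",
           call. = FALSE)
    }
    return(setNames(as.integer(protein_lengths[[len_col]]),
                    protein_lengths$protein_id))
  }
  setNames(as.integer(protein_lengths), names(protein_lengths))
}

drop_rows <- function(df, bad, what) {
  if (any(bad)) {
    warning(sum(bad), " ", what, " dropped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df
}

drop_out_of_range <- function(df, protein_lengths, what) {
  lens <- length_lookup(protein_lengths)
  if (is.null(lens) || nrow(df) == 0L) return(df)
  known <- df$protein_id %in% names(lens)
  bad <- known & df$end > unname(lens[df$protein_id])
  drop_rows(df, bad, paste(what, "out of protein range"))
}

# collapse overlapping or touching regions per protein into maximal regions
merge_touching_regions <- function(df) {
  if (nrow(df) == 0L) return(df)
  df |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      grp <- cumsum(c(TRUE, g$start[-1L] > cummax(g$end)[-nrow(g)] + 1L))
      tibble::tibble(
        start = as.integer(tapply(g$start, grp, min)),
        end = as.integer(tapply(g$end, grp, max))
      )
    }) |>
    dplyr::ungroup()
}

regions_from_track <- function(track) {
  r <- rle(as.integer(track) != 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}
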