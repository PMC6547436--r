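#' Two-cell chi-square test of observed vs expected window hits
#'
#' Goodness-of-fit with one degree of freedom on the two cells (inside a
#' window, outside a window) of the pooled counts:
#' `chi2 = (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E)`, with the p-value
#' from the upper tail of chi-square(1). Vectorised over genomes.
#'
#' @param observed Observed window-hit count(s).
#' @param expected Expected count(s) under uniform placement; the test is
#'   undefined (`NA`, with a warning) when `expected <= 0` or
#'   `expected >= n_boundaries`.
#' @param n_boundaries Total junction count(s).
#' @return A tibble with columns `chi2` and `p_value`.
#' @export
chi_square_obs_exp <- function(observed, expected, n_boundaries) {
  o <- as.numeric(observed)
  e <- as.numeric(expected)
  n <- as.numeric(n_boundaries)
  bad <- is.na(e) | e <= 0 | e >= n | o > n
  if (any(bad)) {
    warning(sum(bad), " test(s) undefined (expected count at or beyond the ",
            "cell bounds)", call. = FALSE)
  }
  d <- o - e
  chi2 <- ifelse(bad, NA_real_, d^2 / e + d^2 / (n - e))
  tibble::tibble(chi2 = chi2, p_value = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Pearson correlation between two per-genome ratio vectors
#'
#' @param x,y Paired numeric vectors (same genomes, same order), `n >= 3`.
#' @return A tibble `estimate` (Pearson R), `p_value` (two-sided t test),
#'   `n`. `NA` with a warning if either vector has zero variance.
#' @export
pearson_ratio_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired genomes", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bootstrap partition test: is domain-exon alignment stronger in new proteins?
#'
#' For each genome, the actually observed quantity is whether the
#' observed/expected ratio over its 'new' proteins exceeds the ratio over its
#' 'old' proteins; `actual_count` is the number of genomes where it does. In
#' each bootstrap trial every genome's eligible proteins are repartitioned
#' uniformly at random into pseudo-new/pseudo-old sets of the original sizes
#' and the count of genomes with pseudo-new ratio strictly greater than
#' pseudo-old is recorded. The p-value is the proportion of trials whose
#' count is at least `actual_count`. Ties (equal ratios) do not count as
#' greater.
#'
#' @param protein_counts Tibble from [protein_alignment_counts()]
#'   (class `"domain"`), one row per eligible protein (use proteins with
#'   `n_intervals > 0`).
#' @param labels Tibble `protein_id`, `label` (`new`/`old`), e.g. from
#'   [classify_new_old()].
#' @param n_trials Number of bootstrap trials, default 50000.
#' @param seed Optional integer seed for reproducibility.
#' @param add_one If `TRUE`, use the add-one permutation-style estimator
#'   `(count + 1) / (n_trials + 1)` instead of the plain proportion.
#' @return An object of class `bootstrap_partition` with elements
#'   `n_trials`, `actual_count`, `n_genomes`, `trial_counts`, `p_value`,
#'   `genomes` (per-genome new/old ratios), `excluded_genomes`. Has
#'   [tidy()], [glance()], [autoplot()] and print methods.
#' @export
bootstrap_new_old <- function(protein_counts, labels, n_trials = 50000,
                              seed = NULL, add_one = FALSE) {
  df <- dplyr::inner_join(protein_counts, labels, by = "protein_id")
  if (nrow(df) == 0L) stop("no labelled proteins in protein_counts", call. = FALSE)
  if (!all(df$label %in% c("new", "old"))) {
    stop("labels must be 'new' or 'old'", call. = FALSE)
  }

  per_genome <- split(df, df$genome_id)
  usable <- vapply(per_genome, function(g) {
    any(g$label == "new") && any(g$label == "old")
  }, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " genome(s) without both new and old proteins excluded: ",
            paste(head(names(per_genome)[!usable], 5L), collapse = ", "),
            call. = FALSE)
  }
  per_genome <- per_genome[usable]
  if (length(per_genome) == 0L) {
    stop("no genome has both new and old proteins", call. = FALSE)
  }

  genome_tbl <- purrr::imap(per_genome, function(g, gid) {
    new <- g$label == "new"
    tibble::tibble(
      genome_id = gid,
      n_proteins = nrow(g),
      n_new = sum(new),
      observed_new = sum(g$observed[new]),
      expected_new = sum(g$expected[new]),
      observed_old = sum(g$observed[!new]),
      expected_old = sum(g$expected[!new])
    )
  }) |> purrr::list_rbind()
  genome_tbl$ratio_new <- genome_tbl$observed_new / genome_tbl$expected_new
  genome_tbl$ratio_old <- genome_tbl$observed_old / genome_tbl$expected_old
  genome_tbl$new_greater <- is.finite(genome_tbl$ratio_new) &
    is.finite(genome_tbl$ratio_old) &
    genome_tbl$ratio_new > genome_tbl$ratio_old
  actual_count <- sum(genome_tbl$new_greater)

  if (!is.null(seed)) set.seed(seed)
  obs_list <- lapply(per_genome, function(g) as.numeric(g$observed))
  exp_list <- lapply(per_genome, function(g) as.numeric(g$expected))
  k_new <- genome_tbl$n_new
  trial_counts <- bootstrap_trial_counts(obs_list, exp_list,
                                         as.integer(k_new), as.integer(n_trials))

  hits <- sum(trial_counts >= actual_count)
  p_value <- if (add_one) (hits + 1) / (n_trials + 1) else hits / n_trials

  structure(
    list(
      n_trials = as.integer(n_trials),
      actual_count = actual_count,
      n_genomes = nrow(genome_tbl),
      trial_counts = trial_counts,
      p_value = p_value,
      add_one = add_one,
      genomes = genome_tbl,
      excluded_genomes = names(usable)[!usable]
    ),
    class = "bootstrap_partition"
  )
}

#' @export
print.bootstrap_partition <- function(x, ...) {
  cat("Bootstrap partition test (new vs old proteins)\n")
  cat(sprintf("  genomes: %d (new ratio > old ratio in %d)\n",
              x$n_genomes, x$actual_count))
  cat(sprintf("  trials:  %d%s\n", x$n_trials,
              if (x$add_one) " (add-one estimator)" else ""))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' @rdname bootstrap_new_old
#' @param x A `bootstrap_partition` object.
#' @param ... Unused.
#' @export
tidy.bootstrap_partition <- function(x, ...) {
  dplyr::select(x$genomes, "genome_id", "n_proteins", "n_new",
                "ratio_new", "ratio_old", "new_greater")
}

#' @rdname bootstrap_new_old
#' @export
glance.bootstrap_partition <- function(x, ...) {
  tibble::tibble(
    n_genomes = x$n_genomes,
    actual_count = x$actual_count,
    n_trials = x$n_trials,
    p_value = x$p_value,
    add_one = x$add_one
  )
}

#' @rdname bootstrap_new_old
#' @param object A `bootstrap_partition` object.
#' @export
autoplot.bootstrap_partition <- function(object, ...) {
  df <- tibble::tibble(count = object$trial_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$actual_count,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = "genomes with pseudo-new ratio > pseudo-old ratio (per trial)",
      y = "trials",
      title = sprintf("Bootstrap partition test: p = %.4g", object$p_value)
    ) +
    ggplot2::theme_minimal()
}
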