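#' Scatter plot of per-genome domain vs disorder alignment ratios
#'
#' One point per genome: observed/expected ratio for domain-boundary windows
#' on the x axis, disorder-boundary windows on the y axis, coloured by which
#' of the two per-genome chi-square tests are significant. Dotted lines mark
#' observed = expected.
#'
#' @param summary Tibble from [summarize_genome_alignment()] holding both
#'   classes.
#' @return A ggplot object.
#' @export
plot_genome_ratios <- function(summary) {
  wide <- summary |>
    dplyr::select("genome_id", "class", "ratio", "significant") |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("ratio", "significant"))
  stopifnot(all(c("ratio_domain", "ratio_disorder") %in% names(wide)))
  wide$signif <- dplyr::case_when(
    wide$significant_domain & wide$significant_disorder ~ "both",
    wide$significant_domain ~ "domain only",
    wide$significant_disorder ~ "disorder only",
    .default = "neither"
  )
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$ratio_domain,
                                     y = .data$ratio_disorder,
                                     colour = .data$signif)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed/expected (domain boundaries)",
                  y = "observed/expected (disorder boundaries)",
                  colour = "significant (chi-square)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of new-protein vs old-protein alignment ratios per genome
#'
#' One point per genome: the domain-boundary observed/expected ratio over
#' 'old' proteins (x) against 'new' proteins (y), with the y = x identity
#' line. Points above the line are genomes where alignment is stronger in
#' recently evolved proteins.
#'
#' @param new_old Tibble from `tidy()` on a [bootstrap_new_old()] result
#'   (columns `ratio_old`, `ratio_new`).
#' @return A ggplot object.
#' @export
plot_new_old_ratios <- function(new_old) {
  stopifnot(all(c("ratio_old", "ratio_new") %in% names(new_old)))
  ggplot2::ggplot(new_old, ggplot2::aes(x = .data$ratio_old,
                                        y = .data$ratio_new)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "observed/expected (old proteins)",
                  y = "observed/expected (new proteins)") +
    ggplot2::theme_minimal()
}
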