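test_that("two-cell chi-square matches its closed form", {
  r <- chi_square_obs_exp(150, 100, 1000)
  expect_equal(r$chi2, 2500 / 100 + 2500 / 900, tolerance = 1e-12)
  expect_equal(r$chi2, 27.7777778, tolerance = 1e-7)

  r0 <- chi_square_obs_exp(0, 5, 10)
  expect_equal(r0$chi2, 10)

  rnull <- chi_square_obs_exp(100, 100, 1000)
  expect_equal(rnull$chi2, 0)
  expect_equal(rnull$p_value, 1)

  expect_warning(rna <- chi_square_obs_exp(5, 0, 10), "undefined")
  expect_true(is.na(rna$chi2))
  expect_warning(chi_square_obs_exp(5, 10, 10), "undefined")
})

test_that("chi-square agrees with a generic goodness-of-fit oracle on random triples", {
  set.seed(123)
  n <- sample(10:10000, 1000, replace = TRUE)
  e <- runif(1000, 0.02, 0.98) * n
  o <- pmin(n, rbinom(1000, n, e / n))
  ours <- chi_square_obs_exp(o, e, n)
  for (i in seq_len(1000)) {
    oracle <- suppressWarnings(
      stats::chisq.test(c(o[i], n[i] - o[i]), p = c(e[i] / n[i], 1 - e[i] / n[i]))
    )
    expect_equal(ours$chi2[i], unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value[i], oracle$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson ratio correlation matches the direct formula", {
  expect_equal(pearson_ratio_correlation(1:10, 1:10)$estimate, 1)
  expect_equal(pearson_ratio_correlation(1:10, -(1:10))$estimate, -1)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_ratio_correlation(x, y)$estimate, manual, tolerance = 1e-12)

  expect_warning(flat <- pearson_ratio_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(flat$estimate))
  expect_error(pearson_ratio_correlation(c(1, 2), c(1, 2)), "at least 3")
})

make_bootstrap_data <- function(n_genomes = 6, n_proteins = 40, seed = 99,
                                shift_new = 0) {
  set.seed(seed)
  counts <- purrr::map(seq_len(n_genomes), function(g) {
    tibble::tibble(
      protein_id = sprintf("G%d_p%03d", g, seq_len(n_proteins)),
      genome_id = sprintf("G%d", g),
      observed = rbinom(n_proteins, 6, 0.3),
      expected = runif(n_proteins, 0.5, 2.5)
    )
  }) |> purrr::list_rbind()
  labels <- counts |>
    dplyr::group_by(genome_id) |>
    dplyr::mutate(label = ifelse(dplyr::row_number() <= 8, "new", "old")) |>
    dplyr::ungroup()
  labels$observed <- labels$observed + ifelse(labels$label == "new", shift_new, 0L)
  list(counts = labels[, c("protein_id", "genome_id", "observed", "expected")],
       labels = labels[, c("protein_id", "label")])
}

test_that("bootstrap partition test is seed-reproducible and consistent across seeds", {
  d <- make_bootstrap_data()
  b1 <- bootstrap_new_old(d$counts, d$labels, n_trials = 2000, seed = 5)
  b2 <- bootstrap_new_old(d$counts, d$labels, n_trials = 2000, seed = 5)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$trial_counts, b2$trial_counts)

  b3 <- bootstrap_new_old(d$counts, d$labels, n_trials = 2000, seed = 6)
  se <- sqrt(b1$p_value * (1 - b1$p_value) / 2000)
  expect_lt(abs(b3$p_value - b1$p_value), 3 * se + 3 * se)
})

test_that("bootstrap p-value agrees with a pure-R reference implementation", {
  d <- make_bootstrap_data(n_genomes = 4, n_proteins = 20)
  b <- bootstrap_new_old(d$counts, d$labels, n_trials = 4000, seed = 11)
  set.seed(12)
  p_ref <- ref_bootstrap_p(d$counts, d$labels, 4000)
  se <- sqrt(max(b$p_value * (1 - b$p_value), p_ref * (1 - p_ref)) / 4000)
  expect_lt(abs(b$p_value - p_ref), 4 * se + 1e-3)
  expect_equal(b$actual_count,
               sum(tidy(b)$new_greater))
})

test_that("degenerate bootstrap inputs behave as documented", {
  # new ratios forced to the floor: actual_count = 0 so every trial >= 0
  d <- make_bootstrap_data(shift_new = 0)
  floor_counts <- d$counts
  lab <- dplyr::inner_join(d$counts, d$labels, by = "protein_id")
  floor_counts$observed[lab$label == "new"] <- 0L
  b <- bootstrap_new_old(floor_counts, d$labels, n_trials = 500, seed = 1)
  expect_equal(b$actual_count, 0L)
  expect_equal(b$p_value, 1)

  # a genome with no 'new' proteins is excluded with a warning
  one_sided <- d$labels
  one_sided$label[grepl("^G1_", one_sided$protein_id)] <- "old"
  expect_warning(b2 <- bootstrap_new_old(d$counts, one_sided,
                                         n_trials = 200, seed = 1),
                 "excluded")
  expect_equal(b2$n_genomes, 5L)

  all_old <- d$labels
  all_old$label <- "old"
  expect_error(suppressWarnings(
    bootstrap_new_old(d$counts, all_old, n_trials = 100, seed = 1)
  ), "no genome")
})

test_that("bootstrap result methods expose tidy, glance and a plot", {
  d <- make_bootstrap_data()
  b <- bootstrap_new_old(d$counts, d$labels, n_trials = 300, seed = 2)
  td <- tidy(b)
  expect_equal(nrow(td), b$n_genomes)
  expect_true(all(c("genome_id", "ratio_new", "ratio_old", "new_greater") %in% names(td)))
  gl <- glance(b)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$p_value, b$p_value)
  expect_s3_class(autoplot(b), "ggplot")
  expect_output(print(b), "Bootstrap partition test")
})
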