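#' Configuration for the synthetic multi-genome generator
#'
#' Bundles every distribution and enrichment parameter of the generator. The
#' generator emulates multi-exon protein-coding transcripts with domain and
#' disorder annotations and a tunable planted enrichment of splice junctions
#' at boundary windows, so the whole pipeline — file I/O, coordinate mapping,
#' counting, significance — can be exercised with known ground truth.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_genomes,n_proteins Number of genomes and proteins per genome.
#' @param length_median,length_sigma Log-normal protein length (median in
#'   residues, log-scale sigma); lengths are clamped to at least 30.
#' @param exon_mean Mean of the Poisson part of the exon count:
#'   `n_exons = 1 + Poisson(exon_mean)`.
#' @param domain_probs Probabilities of a protein carrying 0, 1, 2 or 3
#'   domains.
#' @param domain_len_range Uniform integer range of domain lengths
#'   (residues); lengths are shrunk proportionally when they would not fit.
#' @param n_architectures,n_domain_ids Size of the shared architecture pool
#'   and of the domain identifier pool. Pool architectures are reused across
#'   genomes (each genome carries every pool architecture at least once when
#'   sizes allow), so presence/absence novelty classification is exact.
#' @param disorder_prob Probability that an inter-domain segment long enough
#'   to host one receives a disorder region.
#' @param disorder_len_range Uniform integer range of disorder region lengths.
#' @param n_predictors,predictor_error Number of simulated disorder
#'   predictors and the per-residue probability that a predictor flips the
#'   consensus call.
#' @param theta_domain,theta_disorder Planted enrichment: with probability
#'   `theta_domain` a junction residue is drawn uniformly from the protein's
#'   domain boundary-window set (then with probability `theta_disorder` from
#'   the disorder window set), otherwise uniformly over all residues.
#' @param frac_new Fraction of proteins given a planted-unique ('new')
#'   architecture containing a genome-private novel domain id.
#' @param theta_new Enrichment used for planted-new proteins (defaults to
#'   `theta_domain`).
#' @param intron_range Uniform integer range of intron lengths (nt) for the
#'   genomic realization; irrelevant to the statistics but required for
#'   valid GTF.
#' @param allow_overlap If `TRUE`, disorder regions are placed anywhere on
#'   the protein (possibly overlapping domains), emulating correlated domain
#'   and disorder boundaries; by default they are carved only outside
#'   domains so the two window classes stay distinguishable in truth.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genomes = 5L,
                             n_proteins = 500L,
                             length_median = 350,
                             length_sigma = 0.5,
                             exon_mean = 6,
                             domain_probs = c(0.15, 0.45, 0.30, 0.10),
                             domain_len_range = c(50L, 150L),
                             n_architectures = 30L,
                             n_domain_ids = 60L,
                             disorder_prob = 0.6,
                             disorder_len_range = c(10L, 40L),
                             n_predictors = 8L,
                             predictor_error = 0.05,
                             theta_domain = 0,
                             theta_disorder = 0,
                             frac_new = 0.05,
                             theta_new = NULL,
                             intron_range = c(50L, 2000L),
                             allow_overlap = FALSE) {
  if (is.null(theta_new)) theta_new <- theta_domain
  cfg <- list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    n_proteins = as.integer(n_proteins),
    length_median = length_median, length_sigma = length_sigma,
    exon_mean = exon_mean,
    domain_probs = domain_probs / sum(domain_probs),
    domain_len_range = as.integer(domain_len_range),
    n_architectures = as.integer(n_architectures),
    n_domain_ids = as.integer(n_domain_ids),
    disorder_prob = disorder_prob,
    disorder_len_range = as.integer(disorder_len_range),
    n_predictors = as.integer(n_predictors),
    predictor_error = predictor_error,
    theta_domain = theta_domain, theta_disorder = theta_disorder,
    frac_new = frac_new, theta_new = theta_new,
    intron_range = as.integer(intron_range),
    allow_overlap = isTRUE(allow_overlap)
  )
  probs <- c(cfg$domain_probs, cfg$theta_domain, cfg$theta_disorder,
             cfg$frac_new, cfg$theta_new, cfg$disorder_prob, cfg$predictor_error)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$theta_domain + cfg$theta_disorder <= 1,
            cfg$n_genomes >= 0, cfg$n_proteins >= 1,
            cfg$length_median >= 30, cfg$exon_mean >= 0,
            length(cfg$domain_probs) == 4L,
            cfg$n_predictors >= 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate a multi-genome synthetic bundle
#'
#' Seeds the RNG from `config$seed`, builds a shared architecture pool, and
#' generates every genome. With `genomic = TRUE` each transcript is realized
#' on its own toy chromosome (random intron lengths, random strand, a random
#' codon phase per junction) so the GTF parser path is exercised; with
#' `genomic = FALSE` only the protein-level truth is produced, which is much
#' faster for large calibration studies.
#'
#' @param config A [synthetic_config()].
#' @param genomic Realize genomic CDS coordinates (default `TRUE`).
#' @param predictor_tracks Generate per-predictor disorder tracks (default
#'   follows `genomic`). Consensus disorder regions are always produced.
#' @return A list of class `synthetic_bundle`: `config` and `genomes`, a
#'   named list with per-genome `transcripts`, `domains`, `disorder`,
#'   `tracks`, `labels` and `truth` tables.
#' @export
generate_bundle <- function(config, genomic = TRUE, predictor_tracks = genomic) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pool <- architecture_pool(config)
  genomes <- list()
  if (config$n_genomes > 0L) {
    ids <- sprintf("G%02d", seq_len(config$n_genomes))
    genomes <- lapply(ids, function(gid) {
      generate_genome(config, gid, architecture_pool = pool,
                      genomic = genomic, predictor_tracks = predictor_tracks)
    })
    names(genomes) <- ids
  }
  structure(list(config = config, genomes = genomes), class = "synthetic_bundle")
}

architecture_pool <- function(config) {
  ids <- sprintf("SF%03d", seq_len(config$n_domain_ids))
  kp <- config$domain_probs[2:4] / sum(config$domain_probs[2:4])
  lapply(seq_len(config$n_architectures), function(i) {
    k <- sample.int(3L, 1L, prob = kp)
    sample(ids, k)
  })
}

#' Generate one synthetic genome
#'
#' Normally called through [generate_bundle()], which seeds the RNG and
#' shares one architecture pool across genomes; called directly it draws its
#' own pool from the current RNG state.
#'
#' @inheritParams generate_bundle
#' @param genome_id Genome identifier.
#' @param architecture_pool Optional list of domain-id vectors shared across
#'   genomes.
#' @return A per-genome list as described in [generate_bundle()].
#' @export
generate_genome <- function(config, genome_id, architecture_pool = NULL,
                            genomic = TRUE, predictor_tracks = genomic) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(architecture_pool)) architecture_pool <- architecture_pool(config)
  n <- config$n_proteins
  pid <- sprintf("%s_P%05d", genome_id, seq_len(n))
  tid <- sprintf("%s_T%05d", genome_id, seq_len(n))

  L <- pmax(30L, as.integer(round(rlnorm(n, log(config$length_median),
                                         config$length_sigma))))
  n_ex <- pmin(1L + rpois(n, config$exon_mean), L)
  is_new <- runif(n) < config$frac_new

  # architecture assignment: planted-new proteins carry a genome-private
  # novel id; old domain-containing proteins draw from the shared pool, with
  # the first ones cycling through it so every pool architecture is present
  arch <- vector("list", n)
  k0 <- config$domain_probs[1L]
  old_dom <- which(!is_new & runif(n) >= k0)
  n_pool <- length(architecture_pool)
  pool_idx <- integer(length(old_dom))
  if (length(old_dom) > 0L) {
    n_cover <- min(n_pool, length(old_dom))
    pool_idx[seq_len(n_cover)] <- seq_len(n_cover)
    if (length(old_dom) > n_cover) {
      pool_idx[(n_cover + 1L):length(old_dom)] <-
        sample.int(n_pool, length(old_dom) - n_cover, replace = TRUE)
    }
  }
  arch[old_dom] <- architecture_pool[pool_idx]
  new_idx <- which(is_new)
  all_ids <- sprintf("SF%03d", seq_len(config$n_domain_ids))
  for (j in seq_along(new_idx)) {
    i <- new_idx[j]
    novel <- sprintf("NV_%s_%04d", genome_id, j)
    k_base <- sample.int(3L, 1L) - 1L   # 0..2 pool domains besides the novel one
    base <- if (k_base > 0L) sample(all_ids, k_base) else character(0)
    a <- c(base, novel)
    arch[[i]] <- sample(a, length(a))
  }

  domains_l <- vector("list", n)
  disorder_l <- vector("list", n)
  junc_res <- vector("list", n)
  junc_off <- vector("list", n)
  n_fallback <- integer(n)
  dlr <- config$domain_len_range
  xlr <- config$disorder_len_range

  for (i in seq_len(n)) {
    Li <- L[i]
    a <- arch[[i]]
    k <- length(a)
    dom <- NULL
    if (k > 0L) {
      lens <- sample(seq.int(dlr[1L], dlr[2L]), k, replace = TRUE)
      if (sum(lens) > Li - k) {
        lens <- pmax(10L, as.integer(floor(lens * (0.8 * Li) / sum(lens))))
      }
      gaps <- as.vector(stats::rmultinom(1L, Li - sum(lens), rep(1, k + 1L)))
      starts <- integer(k)
      pos <- 0L
      for (d in seq_len(k)) {
        starts[d] <- pos + gaps[d] + 1L
        pos <- starts[d] + lens[d] - 1L
      }
      dom <- list(domain_id = a, start = starts, end = starts + lens - 1L)
    }
    domains_l[i] <- list(dom)   # [[<- would drop the element when dom is NULL

    segs <- if (config$allow_overlap || is.null(dom)) {
      list(c(1L, Li))
    } else {
      free_segments(dom$start, dom$end, Li)
    }
    ds <- de <- integer(0)
    for (sg in segs) {
      seg_len <- sg[2L] - sg[1L] + 1L
      if (seg_len >= xlr[1L] && runif(1) < config$disorder_prob) {
        dl <- sample(seq.int(xlr[1L], min(xlr[2L], seg_len)), 1L)
        st <- sg[1L] + sample.int(seg_len - dl + 1L, 1L) - 1L
        ds <- c(ds, st); de <- c(de, st + dl - 1L)
      }
    }
    disorder_l[i] <- list(if (length(ds) > 0L) list(start = ds, end = de) else NULL)

    n_j <- n_ex[i] - 1L
    if (n_j > 0L) {
      dw <- if (is.null(dom)) integer(0) else window_residue_set(dom$start, dom$end, Li)
      xw <- if (length(ds) == 0L) integer(0) else window_residue_set(ds, de, Li)
      th_d <- if (is_new[i]) config$theta_new else config$theta_domain
      th_x <- config$theta_disorder
      u <- runif(n_j)
      r <- integer(n_j)
      want_dom <- u < th_d
      want_dis <- !want_dom & u < th_d + th_x
      hit_dom <- want_dom & length(dw) > 0L
      hit_dis <- want_dis & length(xw) > 0L
      n_fallback[i] <- sum(want_dom & !hit_dom) + sum(want_dis & !hit_dis)
      if (any(hit_dom)) r[hit_dom] <- dw[sample.int(length(dw), sum(hit_dom), replace = TRUE)]
      if (any(hit_dis)) r[hit_dis] <- xw[sample.int(length(xw), sum(hit_dis), replace = TRUE)]
      rest <- r == 0L
      if (any(rest)) r[rest] <- sample.int(Li, sum(rest), replace = TRUE)
      if (anyDuplicated(r)) {
        # at most 3 junctions (one per phase) can share a residue
        src <- rep("uni", n_j)
        src[hit_dom] <- "dom"
        src[hit_dis] <- "dis"
        r <- sort(cap_residue_multiplicity(r, Li, src, dw, xw))
        off <- integer(n_j)
        pos <- 1L
        for (res in unique(r)) {
          g <- sum(r == res)
          ph <- if (g == 1L) sample.int(3L, 1L) else sort(sample.int(3L, g))
          off[pos:(pos + g - 1L)] <- 3L * (res - 1L) + ph
          pos <- pos + g
        }
      } else {
        r <- sort(r)
        off <- 3L * (r - 1L) + sample.int(3L, n_j, replace = TRUE)
      }
      junc_res[[i]] <- r
      junc_off[[i]] <- off
    } else {
      junc_res[[i]] <- integer(0)
      junc_off[[i]] <- integer(0)
    }
  }

  domains <- bind_interval_list(domains_l, pid,
                                cols = c("domain_id", "start", "end"))
  disorder <- bind_interval_list(disorder_l, pid, cols = c("start", "end"))
  arch_str <- vapply(seq_len(n), function(i) {
    d <- domains_l[[i]]
    if (is.null(d)) "" else paste(d$domain_id[order(d$start)], collapse = ",")
  }, character(1))
  labels <- tibble::tibble(
    protein_id = pid[arch_str != ""],
    label = ifelse(is_new[arch_str != ""], "new", "old")
  )
  truth <- tibble::tibble(
    protein_id = pid, transcript_id = tid, genome_id = genome_id,
    length = L, n_cds_exons = n_ex,
    junctions = junc_res, junction_offsets = junc_off,
    is_new = is_new, architecture = arch_str,
    theta = ifelse(is_new, config$theta_new, config$theta_domain),
    n_fallback = n_fallback
  )

  transcripts <- if (genomic) realize_genomic(truth, config) else NULL
  tracks <- if (predictor_tracks) predictor_track_table(pid, L, disorder, config) else NULL

  list(genome_id = genome_id, transcripts = transcripts, domains = domains,
       disorder = disorder, tracks = tracks, labels = labels, truth = truth)
}

free_segments <- function(dstart, dend, L) {
  ord <- order(dstart)
  dstart <- dstart[ord]; dend <- dend[ord]
  segs <- list()
  prev <- 0L
  for (d in seq_along(dstart)) {
    if (dstart[d] > prev + 1L) segs[[length(segs) + 1L]] <- c(prev + 1L, dstart[d] - 1L)
    prev <- max(prev, dend[d])
  }
  if (prev < L) segs[[length(segs) + 1L]] <- c(prev + 1L, L)
  segs
}

# Redraw junctions beyond the third at a residue, from the same source
# distribution they were drawn from (domain windows, disorder windows or
# uniform), so planted enrichment is preserved. Falls back to uniform when a
# window set is saturated.
cap_residue_multiplicity <- function(r, L, src = NULL, dw = integer(0),
                                     xw = integer(0)) {
  if (is.null(src)) src <- rep("uni", length(r))
  for (iter in 1:50) {
    tab <- table(r)
    over <- as.integer(names(tab)[tab > 3L])
    if (length(over) == 0L) return(r)
    for (res in over) {
      idx <- which(r == res)
      for (j in idx[-seq_len(3L)]) {
        pool <- switch(src[j], dom = dw, dis = xw, seq_len(L))
        free <- setdiff(pool, as.integer(names(tab)[tab >= 3L]))
        if (length(free) == 0L) {
          src[j] <- "uni"
          free <- setdiff(seq_len(L), as.integer(names(tab)[tab >= 3L]))
        }
        r[j] <- free[sample.int(length(free), 1L)]
      }
    }
  }
  r
}

bind_interval_list <- function(lst, pid, cols) {
  keep <- !vapply(lst, is.null, logical(1))
  if (!any(keep)) {
    out <- tibble::tibble(protein_id = character())
    for (cl in cols) out[[cl]] <- if (cl == "domain_id") character() else integer()
    return(out)
  }
  reps <- vapply(lst[keep], function(x) length(x[[cols[1L]]]), integer(1))
  out <- tibble::tibble(protein_id = rep(pid[keep], reps))
  for (cl in cols) out[[cl]] <- unlist(lapply(lst[keep], `[[`, cl), use.names = FALSE)
  out
}

# Realize each transcript on its own toy chromosome. The CDS includes the
# stop codon (total nt = 3 * (length + 1)); junction offsets already encode a
# random phase per junction. On the minus strand the 5'->3' exon order runs
# from high to low genomic coordinates.
realize_genomic <- function(truth, config) {
  n <- nrow(truth)
  exon_list <- vector("list", n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ir <- config$intron_range
  for (i in seq_len(n)) {
    off <- truth$junction_offsets[[i]]
    total <- 3L * (truth$length[i] + 1L)
    lens <- diff(c(0L, off, total))
    n_j <- length(off)
    introns <- if (n_j > 0L) sample(seq.int(ir[1L], ir[2L]), n_j, replace = TRUE) else integer(0)
    txstart <- sample.int(1000000L, 1L)
    if (strand[i] == "+") {
      starts <- txstart + cumsum(c(0L, head(lens, -1L) + introns))
      ends <- starts + lens - 1L
    } else {
      rl <- rev(lens); ri <- rev(introns)
      sl <- txstart + cumsum(c(0L, head(rl, -1L) + ri))
      el <- sl + rl - 1L
      starts <- rev(sl); ends <- rev(el)
    }
    exon_list[[i]] <- tibble::tibble(start = as.integer(starts), end = as.integer(ends))
  }
  tibble::tibble(
    transcript_id = truth$transcript_id,
    protein_id = truth$protein_id,
    genome_id = truth$genome_id,
    chrom = paste0("chr_", truth$protein_id),
    strand = strand,
    n_cds_exons = truth$n_cds_exons,
    cds_nt = 3L * (truth$length + 1L),
    protein_length = truth$length,
    cds_exons = exon_list
  )
}

predictor_track_table <- function(pid, L, disorder, config) {
  n <- length(pid)
  ends <- cumsum(L)
  starts <- ends - L + 1L
  cons <- integer(ends[n])
  if (nrow(disorder) > 0L) {
    m <- match(disorder$protein_id, pid)
    for (j in seq_len(nrow(disorder))) {
      i <- m[j]
      cons[(starts[i] + disorder$start[j] - 1L):(starts[i] + disorder$end[j] - 1L)] <- 1L
    }
  }
  P <- config$n_predictors
  out <- vector("list", P)
  for (p in seq_len(P)) {
    flip <- rbinom(length(cons), 1L, config$predictor_error)
    calls <- as.integer(xor(cons, flip))
    chunks <- vapply(seq_len(n), function(i) {
      paste(calls[starts[i]:ends[i]], collapse = "")
    }, character(1))
    out[[p]] <- tibble::tibble(protein_id = pid,
                               predictor = sprintf("pred%02d", p),
                               calls = chunks)
  }
  dplyr::arrange(purrr::list_rbind(out), .data$protein_id, .data$predictor)
}

#' Protein records straight from a synthetic bundle
#'
#' Builds the same per-protein records that [read_annotation()] +
#' [build_protein_records()] would produce from the written files, directly
#' from the generator's in-memory truth — the fast path for large
#' calibration studies. Equality of the two paths on a written bundle is the
#' generator/parser round-trip check.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @return A tibble as returned by [build_protein_records()].
#' @export
bundle_protein_records <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  recs <- lapply(bundle$genomes, function(g) {
    truth <- g$truth
    dom_split <- split_by_protein(g$domains, truth$protein_id)
    dis_split <- split_by_protein(g$disorder, truth$protein_id)
    tibble::tibble(
      protein_id = truth$protein_id,
      transcript_id = truth$transcript_id,
      genome_id = truth$genome_id,
      length = truth$length,
      n_cds_exons = truth$n_cds_exons,
      junctions = truth$junctions,
      junction_offsets = truth$junction_offsets,
      domains = dom_split,
      disorder = dis_split,
      n_domains = purrr::map_int(dom_split, nrow),
      n_disorder = purrr::map_int(dis_split, nrow),
      architecture = truth$architecture
    )
  })
  purrr::list_rbind(recs)
}

#' Write a synthetic bundle to disk
#'
#' Writes, per genome, a GTF annotation, a domain TSV, a per-predictor
#' disorder TSV and a truth label TSV, plus a bundle-level `truth.json`
#' (planted enrichment values and per-protein junction residues) and a
#' `manifest.json` with record counts. The bundle must have been generated
#' with `genomic = TRUE` and `predictor_tracks = TRUE`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_genomes = length(bundle$genomes),
    config = unclass(bundle$config),
    genomes = list()
  )
  truth_out <- list(
    theta_domain = bundle$config$theta_domain,
    theta_disorder = bundle$config$theta_disorder,
    theta_new = bundle$config$theta_new,
    genomes = list()
  )
  for (gid in names(bundle$genomes)) {
    g <- bundle$genomes[[gid]]
    if (is.null(g$transcripts) || is.null(g$tracks)) {
      stop("bundle must be generated with genomic = TRUE and ",
           "predictor_tracks = TRUE to be written", call. = FALSE)
    }
    writeLines(gtf_lines(g$transcripts), file.path(out_dir, paste0(gid, ".gtf")))
    readr::write_tsv(g$domains, file.path(out_dir, paste0(gid, "_domains.tsv")))
    readr::write_tsv(g$tracks, file.path(out_dir, paste0(gid, "_disorder.tsv")))
    readr::write_tsv(g$labels, file.path(out_dir, paste0(gid, "_labels.tsv")))
    manifest$genomes[[gid]] <- list(
      n_transcripts = nrow(g$transcripts),
      n_domain_rows = nrow(g$domains),
      n_track_rows = nrow(g$tracks),
      n_label_rows = nrow(g$labels)
    )
    truth_out$genomes[[gid]] <- list(
      protein_id = g$truth$protein_id,
      length = g$truth$length,
      junctions = g$truth$junctions,
      is_new = g$truth$is_new,
      n_fallback = g$truth$n_fallback
    )
  }
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

gtf_lines <- function(transcripts) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$cds_exons[[i]]           # 5'->3' transcript order
    lens <- ex$end - ex$start + 1L
    cum_prev <- c(0L, cumsum(lens))[seq_len(nrow(ex))]
    frame <- (3L - cum_prev %% 3L) %% 3L
    ord <- order(ex$start)                     # genomic ascending in the file
    lines <- c(lines, sprintf(
      '%s\tboundalign_synth\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id "%s"; transcript_id "%s"; protein_id "%s";',
      transcripts$chrom[i], ex$start[ord], ex$end[ord], transcripts$strand[i],
      frame[ord], paste0(transcripts$transcript_id[i], "_g"),
      transcripts$transcript_id[i], transcripts$protein_id[i]
    ))
  }
  lines
}

#' Closed-form genome ratio under the planted-enrichment model
#'
#' When a fraction `theta` of junctions is drawn uniformly from the domain
#' boundary-window residue set and the rest uniformly over the protein, the
#' pooled observed/expected ratio over eligible proteins is
#' `(theta + (1 - theta) * wbar) / wbar`, where `wbar` is the
#' boundary-weighted mean window fraction. `planted_ratio_se()` gives the
#' Monte-Carlo standard error of the realized ratio from the same per-protein
#' quantities (sum of independent Bernoulli junction indicators).
#'
#' @param protein_counts Tibble from [protein_alignment_counts()] restricted
#'   to the eligible (domain-containing, multi-exon) proteins.
#' @param theta Planted enrichment in `[0, 1]`.
#' @return A single number: the predicted ratio, or its standard error.
#' @export
expected_planted_ratio <- function(protein_counts, theta) {
  w <- protein_counts$n_window_residues / protein_counts$length
  nb <- protein_counts$n_boundaries
  wbar <- sum(nb * w) / sum(nb)
  (theta + (1 - theta) * wbar) / wbar
}

#' @rdname expected_planted_ratio
#' @export
planted_ratio_se <- function(protein_counts, theta) {
  w <- protein_counts$n_window_residues / protein_counts$length
  nb <- protein_counts$n_boundaries
  p <- theta + (1 - theta) * w
  sqrt(sum(nb * p * (1 - p))) / sum(nb * w)
}
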