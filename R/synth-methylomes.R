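# Synthetic multi-sample methylomes.  Cytosines are laid out in dense local
# clumps (mimicking the uneven cytosine density of real genomes and giving
# the region-clustering step something to find).  Counts follow a
# hierarchical model: negative-binomial coverage, binomial methylated reads
# with logit-scale locus, stage, cultivar and replicate effects.

H_BASES <- c("A", "C", "T")

rtrinucleotide <- function(context, n) {
  switch(context,
    CG  = paste0("CG", sample(c("A", "C", "G", "T"), n, replace = TRUE)),
    CHG = paste0("C", sample(H_BASES, n, replace = TRUE), "G"),
    CHH = paste0("C", sample(H_BASES, n, replace = TRUE),
                 sample(H_BASES, n, replace = TRUE)))
}

place_sites <- function(config) {
  lens <- config$chrom_lengths
  sites <- list()
  cl <- 0L
  total <- 0L
  while (total < config$n_cytosines) {
    cl <- cl + 1L
    ci <- sample(seq_along(lens), 1, prob = lens)
    size <- 4L + stats::rpois(1, 4)
    size <- min(size, config$n_cytosines - total)
    center <- round(runif(1, 200, lens[[ci]] - 600))
    pos <- center + cumsum(sample(6:50, size, replace = TRUE))
    pos <- pos[pos <= lens[[ci]]]
    if (!length(pos)) next
    sites[[cl]] <- tibble(chrom = names(lens)[ci], pos = as.integer(pos),
                          cluster_id = cl)
    total <- total + length(pos)
  }
  out <- bind_rows(sites) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(match(.data$chrom, names(lens)), .data$pos)
  ctx <- sample(names(config$context_mix), nrow(out), replace = TRUE,
                prob = config$context_mix)
  out$context <- ctx
  tri <- character(nrow(out))
  for (cx in methylation_contexts) {
    idx <- which(ctx == cx)
    if (length(idx)) tri[idx] <- rtrinucleotide(cx, length(idx))
  }
  out$trinucleotide <- tri
  out
}

# pick whole clusters (weighted) until `quota` sites are marked
pick_cluster_sites <- function(sites, eligible_clusters, weights, quota) {
  chosen <- integer(0)
  marked <- integer(0)
  pool <- eligible_clusters
  w <- weights
  while (length(marked) < quota && length(pool)) {
    j <- sample.int(length(pool), 1, prob = w)
    cl <- pool[j]
    pool <- pool[-j]; w <- w[-j]
    idx <- which(sites$cluster_id == cl)
    take <- head(idx, quota - length(marked))
    marked <- c(marked, take)
    chosen <- c(chosen, cl)
  }
  list(rows = marked, clusters = chosen)
}

#' Build the sample metadata table for a synthetic study
#'
#' Samples are created stage by stage in canonical order with cultivars
#' cycled within stage (keeping cultivar and stage uncorrelated, so cultivar
#' effects act purely as confounding structure) and chilling-hour values
#' drawn from stage-typical ranges.
#'
#' @param config A [synth_config()].
#' @return A tibble with `sample_id`, `cultivar`, `experiment`,
#'   `chilling_hours` and `stage`.
#' @keywords internal
build_sample_meta <- function(config) {
  stages <- intersect(dormancy_stages, names(config$class_counts))
  rows <- purrr::map_dfr(stages, function(st) {
    n <- config$class_counts[[st]]
    tibble(stage = st,
           cultivar = paste0("cv", ((seq_len(n) - 1) %% config$n_cultivars) + 1))
  })
  ch_range <- list(paradormancy = c(0, 150), endodormancy = c(300, 800),
                   ecodormancy = c(900, 1400))
  rows |>
    mutate(sample_id = sprintf("S%02d", row_number()),
           experiment = paste0("E", ((match(.data$cultivar,
                                            paste0("cv", seq_len(config$n_cultivars))) - 1) %% 3) + 1),
           chilling_hours = purrr::map_dbl(.data$stage, function(s)
             round(runif(1, ch_range[[s]][1], ch_range[[s]][2])))) |>
    select("sample_id", "cultivar", "experiment", "chilling_hours", "stage")
}

#' Simulate per-sample cytosine methylation reports with planted signal
#'
#' Draws, for every sample and cytosine, a negative-binomial coverage and a
#' binomial methylated-read count with success probability
#' `plogis(logit(base) + locus jitter + stage effect + cultivar effect +
#' replicate noise)`.  Stage effects are planted on whole cytosine clumps
#' (so region features inherit the signal) sampled with configurable
#' enrichment towards TE and chromosome-4 QTL intervals; cultivar effects
#' are planted on a disjoint clump set, one cultivar per clump.  The planted
#' truth is returned alongside the data.
#'
#' @param config A [synth_config()].
#' @param annotation An `annotation_bundle` from [simulate_genome_annotation()];
#'   used to enrich informative loci in TEs/QTLs.  May be `NULL`, in which
#'   case loci are sampled uniformly.
#' @return A list of class `"methylome_sim"` with elements
#'   \describe{
#'     \item{reports}{named list of per-sample cytosine-report tibbles
#'       (`chrom`, `pos` (1-based), `strand`, `n_meth`, `n_unmeth`,
#'       `context`, `trinucleotide`);}
#'     \item{meta}{sample metadata tibble;}
#'     \item{truth}{list with `informative` (chrom, pos, per-stage logit
#'       offsets) and `confounder` (chrom, pos, cultivar) tibbles;}
#'     \item{sites}{the site table with cluster ids;}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
#' @examples
#' cfg <- synth_config(seed = 3, n_cytosines = 300,
#'                     class_counts = c(endodormancy = 4, ecodormancy = 4))
#' sim <- simulate_methylomes(cfg)
#' names(sim$reports)[1:2]
simulate_methylomes <- function(config, annotation = NULL) {
  validate_synth_config(config)
  seeded(config$seed + 1L, {
    sites <- place_sites(config)
    n_sites <- nrow(sites)
    meta <- build_sample_meta(config)
    n_samp <- nrow(meta)

    clusters <- unique(sites$cluster_id)
    w <- rep(1, length(clusters))
    if (!is.null(annotation)) {
      enriched <- GenomicRanges::GRanges(
        c(annotation$tes$chrom, annotation$qtls$chrom),
        IRanges::IRanges(start = c(annotation$tes$start, annotation$qtls$start) + 1,
                         end = c(annotation$tes$end, annotation$qtls$end)))
      centers <- sites |>
        group_by(.data$cluster_id) |>
        summarise(chrom = .data$chrom[1], pos = round(mean(.data$pos)))
      cgr <- GenomicRanges::GRanges(centers$chrom,
                                    IRanges::IRanges(centers$pos, width = 1))
      hit <- GenomicRanges::countOverlaps(cgr, enriched) > 0
      w <- ifelse(hit[match(clusters, centers$cluster_id)],
                  config$informative_te_enrichment, 1)
    }

    n_inf <- round(config$frac_informative * n_sites)
    inf <- pick_cluster_sites(sites, clusters, w, n_inf)
    remaining <- setdiff(clusters, inf$clusters)
    n_conf <- round(config$frac_confounder * n_sites)
    conf <- pick_cluster_sites(sites, remaining,
                               rep(1, length(remaining)), n_conf)

    # per-informative-clump permutation of (-1, 0, +1) * stage_effect
    patterns <- lapply(inf$clusters, function(cl) sample(c(-1, 0, 1)))
    names(patterns) <- as.character(inf$clusters)
    stage_off <- matrix(0, n_sites, 3,
                        dimnames = list(NULL, dormancy_stages))
    for (r in inf$rows) {
      p <- patterns[[as.character(sites$cluster_id[r])]]
      stage_off[r, ] <- p * config$stage_effect
    }
    conf_cultivar <- character(n_sites)
    cvs <- paste0("cv", seq_len(config$n_cultivars))
    cl_cv <- setNames(cvs[((seq_along(conf$clusters) - 1) %% length(cvs)) + 1],
                      as.character(conf$clusters))
    conf_cultivar[conf$rows] <- cl_cv[as.character(sites$cluster_id[conf$rows])]

    base_logit <- qlogis(config$base_level_by_context[sites$context]) +
      stats::rnorm(n_sites, 0, config$locus_noise_sd)

    reports <- vector("list", n_samp)
    names(reports) <- meta$sample_id
    for (j in seq_len(n_samp)) {
      lp <- base_logit + stage_off[, meta$stage[j]] +
        ifelse(conf_cultivar == meta$cultivar[j], config$cultivar_effect, 0) +
        stats::rnorm(n_sites, 0, config$sample_noise_sd)
      cov <- rnbinom(n_sites, size = config$coverage_dispersion,
                     mu = config$coverage_mean)
      nm <- rbinom(n_sites, cov, plogis(lp))
      reports[[j]] <- tibble(chrom = sites$chrom, pos = sites$pos,
                             strand = "+", n_meth = nm,
                             n_unmeth = cov - nm,
                             context = sites$context,
                             trinucleotide = sites$trinucleotide)
    }

    truth <- list(
      informative = tibble(chrom = sites$chrom[inf$rows],
                           pos = sites$pos[inf$rows],
                           cluster_id = sites$cluster_id[inf$rows]) |>
        mutate(offset_paradormancy = stage_off[inf$rows, "paradormancy"],
               offset_endodormancy = stage_off[inf$rows, "endodormancy"],
               offset_ecodormancy = stage_off[inf$rows, "ecodormancy"]),
      confounder = tibble(chrom = sites$chrom[conf$rows],
                          pos = sites$pos[conf$rows],
                          cluster_id = sites$cluster_id[conf$rows],
                          cultivar = conf_cultivar[conf$rows]))

    structure(list(reports = reports, meta = meta, truth = truth,
                   sites = sites, config = config),
              class = "methylome_sim")
  })
}

#' @export
print.methylome_sim <- function(x, ...) {
  cat("<methylome_sim>\n")
  cat(sprintf("  %d samples x %d cytosines; %d informative, %d confounder loci\n",
              length(x$reports), nrow(x$sites),
              nrow(x$truth$informative), nrow(x$truth$confounder)))
  invisible(x)
}
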