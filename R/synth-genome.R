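# Synthetic genome annotation: non-overlapping gene models with exons,
# a TE track drawn to a target genome fraction, and QTL windows for the
# four dormancy-related traits.  All internal coordinates are 0-based
# half-open; writers convert at the boundary.

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

TE_CLASSES <- c("LTR/Ty3" = 0.30, "LTR/Copia" = 0.25, "LTR/unknown" = 0.10,
                "DNA/MULE-MuDR" = 0.08, "DNA/hAT" = 0.07, "LINE/L1" = 0.08,
                "SINE" = 0.04, "Unknown" = 0.08)

QTL_TRAITS <- c("CR", "HR", "FD", "MD")

#' Simulate a genome annotation to accompany synthetic methylomes
#'
#' Generates non-overlapping gene models (with exons and strand), a
#' transposable-element track labelled with classes (LTR/Ty3 and LTR/Copia
#' dominating, as in stone-fruit genomes), and one QTL window per trait in
#' CR/HR/FD/MD (chilling requirement, heat requirement, flowering date,
#' maturity date) placed on chromosome 4 (or the last chromosome when fewer
#' exist).  TEs are drawn as an alternating walk of element and gap whose
#' expected coverage equals `config$te_fraction`.
#'
#' @param config A [synth_config()].
#' @return An `annotation_bundle`: a list of tibbles `genes`, `exons`, `tes`,
#'   `qtls` (all 0-based half-open) plus `chrom_lengths`.
#' @export
#' @examples
#' ann <- simulate_genome_annotation(synth_config(seed = 1))
#' head(ann$genes)
simulate_genome_annotation <- function(config) {
  validate_synth_config(config)
  min_span <- 1000 + 2 * 2000 + 200   # smallest gene plus both 2-kb flanks
  short <- config$chrom_lengths < min_span
  if (any(short))
    abort(sprintf("chromosome %s (%d bp) is too short for a gene plus 2-kb flanks (need >= %d bp)",
                  names(config$chrom_lengths)[short][1],
                  config$chrom_lengths[short][1], min_span))
  seeded(config$seed, {
    genes <- list(); exons <- list(); tes <- list()
    gi <- 0L; ti <- 0L
    for (ci in seq_along(config$chrom_lengths)) {
      chrom <- names(config$chrom_lengths)[ci]
      L <- config$chrom_lengths[[ci]]
      # gene walk
      pos <- 2000
      while (pos + 4000 + 2000 < L) {
        glen <- round(runif(1, 1000, 4000))
        gi <- gi + 1L
        gid <- sprintf("gene%04d", gi)
        strand <- sample(c("+", "-"), 1)
        genes[[length(genes) + 1]] <-
          tibble(chrom = chrom, start = pos, end = pos + glen,
                 strand = strand, gene_id = gid)
        n_ex <- sample(1:3, 1)
        cuts <- sort(round(runif(2 * (n_ex - 1), 0.1 * glen, 0.9 * glen)))
        bounds <- c(0, cuts, glen)
        for (e in seq_len(n_ex)) {
          s <- bounds[2 * e - 1]; en <- bounds[2 * e]
          if (en > s)
            exons[[length(exons) + 1]] <-
              tibble(chrom = chrom, start = pos + s, end = pos + en,
                     strand = strand,
                     gene_id = gid, exon_id = sprintf("%s.e%d", gid, e))
        }
        pos <- pos + glen + round(runif(1, 2000, 8000))
      }
      # TE layout: element lengths drawn to cover te_fraction * L bases
      # exactly, gaps apportioned over the remainder, so the realised
      # genome fraction matches the target up to rounding
      if (config$te_fraction > 0) {
        target <- round(config$te_fraction * L)
        tlens <- integer(0)
        while (sum(tlens) < target)
          tlens <- c(tlens, 200L + round(rexp(1, 1 / 1300)))
        excess <- sum(tlens) - target
        tlens[length(tlens)] <- tlens[length(tlens)] - excess
        if (tlens[length(tlens)] < 50 && length(tlens) > 1) {
          tlens[length(tlens) - 1] <- tlens[length(tlens) - 1] +
            tlens[length(tlens)]
          tlens <- tlens[-length(tlens)]
        }
        gaps <- rexp(length(tlens) + 1)
        gaps <- floor(gaps / sum(gaps) * (L - sum(tlens)))
        pos <- gaps[1]
        for (e in seq_along(tlens)) {
          ti <- ti + 1L
          tes[[length(tes) + 1]] <-
            tibble(chrom = chrom, start = pos, end = pos + tlens[e],
                   te_id = sprintf("te%05d", ti),
                   class = sample(names(TE_CLASSES), 1, prob = TE_CLASSES))
          pos <- pos + tlens[e] + gaps[e + 1]
        }
      }
    }
    qc <- min(4L, length(config$chrom_lengths))
    qchrom <- names(config$chrom_lengths)[qc]
    qlen <- config$chrom_lengths[[qc]]
    qtls <- purrr::map_dfr(QTL_TRAITS, function(tr) {
      w <- round(0.08 * qlen)
      s <- round(runif(1, 0, qlen - w))
      tibble(chrom = qchrom, start = s, end = s + w, trait = tr)
    })
    structure(list(genes = bind_rows(genes),
                   exons = bind_rows(exons),
                   tes = bind_rows(tes),
                   qtls = qtls,
                   chrom_lengths = config$chrom_lengths),
              class = "annotation_bundle")
  })
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("<annotation_bundle>\n")
  cat(sprintf("  %d chromosomes (%.2f Mb), %d genes, %d exons, %d TEs, %d QTLs\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(x$genes), nrow(x$exons), nrow(x$tes), nrow(x$qtls)))
  invisible(x)
}
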