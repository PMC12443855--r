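# Genomic annotation of selected features: strand-aware promoter and
# downstream windows, precedence-based context assignment
# (TE > promoter > gene body > downstream > intergenic), TE-class
# cross-tabulation, feature-set comparisons, megabase density windows and
# QTL colocalization.  Interval algebra goes through GenomicRanges.

tbl_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Derive promoter and downstream windows from gene models
#'
#' The promoter is the 2-kb window upstream of the transcription start
#' site, the downstream region the 2-kb window past the transcription
#' termination site, both strand-aware and clipped at chromosome bounds;
#' windows clipped to zero width are dropped.
#'
#' @param genes Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `gene_id`.
#' @param chrom_lengths Named vector of chromosome lengths for clipping.
#' @param width Window width in bp (default 2000).
#' @return Tibble with the same shape as `genes`.
#' @export
#' @examples
#' g <- tibble::tibble(chrom = "chr_1", start = 5000, end = 7000,
#'                     strand = "+", gene_id = "g1")
#' derive_promoters(g, c(chr_1 = 100000))
derive_promoters <- function(genes, chrom_lengths, width = 2000) {
  bad <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad)) abort(sprintf("unknown strand '%s'", bad[1]))
  out <- genes |>
    mutate(p_start = ifelse(.data$strand == "+",
                            .data$start - width, .data$end),
           p_end = ifelse(.data$strand == "+",
                          .data$start, .data$end + width)) |>
    mutate(p_start = pmax(.data$p_start, 0),
           p_end = pmin(.data$p_end,
                        unname(chrom_lengths[.data$chrom]))) |>
    filter(.data$p_end > .data$p_start)
  tibble(chrom = out$chrom, start = out$p_start, end = out$p_end,
         strand = out$strand, gene_id = out$gene_id)
}

#' @rdname derive_promoters
#' @export
derive_downstream <- function(genes, chrom_lengths, width = 2000) {
  flipped <- mutate(genes, strand = ifelse(.data$strand == "+", "-", "+"))
  out <- derive_promoters(flipped, chrom_lengths, width)
  mutate(out, strand = ifelse(.data$strand == "+", "-", "+"))
}

default_precedence <- c("TE", "promoter", "gene", "downstream", "intergenic")

#' Assign selected features to genomic contexts
#'
#' Overlap means sharing at least one base pair.  The primary context
#' follows a total precedence order (default TE > promoter > gene body >
#' downstream > intergenic), which makes the categories mutually exclusive;
#' `gene_relative_context` applies the same order without TE, so
#' TE-overlapping features also report where they sit relative to genes.
#' The TE class reported is that of the TE with the largest overlap (ties:
#' first by coordinate).
#'
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. the `features` element of a
#'   `methylation_matrix` subset to the selection.
#' @param bundle An `annotation_bundle`.
#' @param precedence Character permutation of
#'   `c("TE", "promoter", "gene", "downstream", "intergenic")`.
#' @return Tibble of class `"context_assignment"`: `feature_id`,
#'   `primary_context`, `gene_relative_context`, `te_overlap`, `te_class`.
#' @export
assign_context <- function(features, bundle,
                           precedence = default_precedence) {
  if (!setequal(precedence, default_precedence))
    abort("`precedence` must be a permutation of the five context kinds")
  unknown <- setdiff(unique(features$chrom), names(bundle$chrom_lengths))
  if (length(unknown))
    abort(sprintf("feature on unknown chromosome '%s'", unknown[1]))
  fgr <- tbl_to_gr(features)
  lens <- bundle$chrom_lengths
  promoters <- derive_promoters(bundle$genes, lens)
  downstream <- derive_downstream(bundle$genes, lens)
  olap <- function(track)
    if (nrow(track) == 0) rep(FALSE, length(fgr))
    else GenomicRanges::countOverlaps(fgr, tbl_to_gr(track)) > 0
  hit <- list(TE = olap(bundle$tes),
              promoter = olap(promoters),
              gene = olap(bundle$genes),
              downstream = olap(downstream))
  pick <- function(order_) {
    out <- rep("intergenic", length(fgr))
    for (kind in rev(setdiff(order_, "intergenic")))
      out[hit[[kind]]] <- kind
    out
  }
  primary <- pick(precedence)
  gene_rel <- pick(setdiff(precedence, "TE"))

  te_class <- rep(NA_character_, length(fgr))
  if (nrow(bundle$tes)) {
    tes <- arrange(bundle$tes, .data$chrom, .data$start, .data$end)
    tgr <- tbl_to_gr(tes)
    ov <- GenomicRanges::findOverlaps(fgr, tgr)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(fgr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(tgr)[S4Vectors::subjectHits(ov)]))
      o <- tibble(q = S4Vectors::queryHits(ov),
                  s = S4Vectors::subjectHits(ov), w = w) |>
        arrange(.data$q, dplyr::desc(.data$w), .data$s) |>
        distinct(.data$q, .keep_all = TRUE)
      te_class[o$q] <- tes$class[o$s]
    }
  }
  out <- tibble(feature_id = features$feature_id,
                primary_context = primary,
                gene_relative_context = gene_rel,
                te_overlap = !is.na(te_class),
                te_class = te_class)
  class(out) <- c("context_assignment", class(out))
  out
}

#' Cross-tabulate TE classes against gene-relative contexts
#'
#' Counts TE-overlapping features by (TE class, gene-relative context).
#' Marginals over either axis recount the TE-overlapping features.
#'
#' @param assignments A `context_assignment` tibble.
#' @return Tibble with `te_class`, `gene_relative_context`, `n`.
#' @export
te_context_crosstab <- function(assignments) {
  assignments |>
    filter(.data$te_overlap) |>
    count(.data$te_class, .data$gene_relative_context, name = "n") |>
    arrange(.data$te_class, .data$gene_relative_context)
}

#' Compare selected feature sets between models
#'
#' For sets of the same kind, membership is compared by feature id:
#' pairwise shared counts and per-set exclusive counts.  Across kinds,
#' positional colocalization is reported separately: a cytosine feature
#' colocalizes with a region feature when its position falls inside the
#' region span.
#'
#' @param sets Named list (>= 2) of feature tibbles with `feature_id`,
#'   `chrom`, `start`, `end`, `kind`.
#' @return List with `pairwise` (tibble: set_a, set_b, shared), `exclusive`
#'   (tibble: set, n_exclusive, n_total) and `colocalization` (tibble:
#'   cytosine_set, region_set, n_colocalized, ids list-column).
#' @export
compare_feature_sets <- function(sets) {
  if (length(sets) < 2) abort("need at least two named feature sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("feature sets must be named")
  for (nm in names(sets))
    if (anyDuplicated(sets[[nm]]$feature_id))
      abort(sprintf("duplicate feature ids within set '%s'", nm))
  nms <- names(sets)
  like_kind <- function(a, b)
    identical(sort(unique(a$kind)), sort(unique(b$kind)))
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    tibble(set_a = p[1], set_b = p[2],
           comparable = like_kind(a, b),
           shared = if (like_kind(a, b))
             length(intersect(a$feature_id, b$feature_id)) else NA_integer_)
  })
  exclusive <- purrr::map_dfr(nms, function(nm) {
    others <- unlist(lapply(sets[setdiff(nms, nm)], function(s)
      if (like_kind(sets[[nm]], s)) s$feature_id else character(0)))
    tibble(set = nm,
           n_total = nrow(sets[[nm]]),
           n_exclusive = length(setdiff(sets[[nm]]$feature_id, others)))
  })
  coloc <- list()
  for (a in nms) for (b in nms) {
    ca <- sets[[a]]; rb <- sets[[b]]
    if (!all(ca$kind == "cytosine") || !all(rb$kind == "region")) next
    if (nrow(ca) == 0 || nrow(rb) == 0) {
      coloc[[length(coloc) + 1]] <- tibble(cytosine_set = a, region_set = b,
                                           n_colocalized = 0L,
                                           ids = list(character(0)))
      next
    }
    ov <- GenomicRanges::findOverlaps(tbl_to_gr(ca), tbl_to_gr(rb),
                                      type = "within")
    ids <- unique(ca$feature_id[S4Vectors::queryHits(ov)])
    coloc[[length(coloc) + 1]] <- tibble(cytosine_set = a, region_set = b,
                                         n_colocalized = length(ids),
                                         ids = list(ids))
  }
  list(pairwise = pairwise, exclusive = exclusive,
       colocalization = bind_rows(coloc))
}

#' Feature density in fixed genomic windows
#'
#' Non-overlapping windows tile each chromosome from position 0; a feature
#' counts in the window containing its start, so regions crossing a window
#' boundary are not double-counted.
#'
#' @param features Tibble with `chrom`, `start`, `end`, `kind`.
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window size in bp (default 1 Mb).
#' @return Tibble with `chrom`, `window` (1-based index), `win_start`,
#'   `win_end`, `kind`, `n` — every window of every chromosome appears,
#'   zero-filled, for each feature kind present.
#' @export
density_windows <- function(features, chrom_lengths, window = 1e6) {
  win <- window   # avoid capture by the tibble column of the same name
  beyond <- features$start >= unname(chrom_lengths[features$chrom]) |
    is.na(chrom_lengths[features$chrom])
  if (any(beyond))
    abort(sprintf("feature start beyond chromosome end (%s)",
                  features$chrom[beyond][1]))
  kinds <- unique(features$kind) %||% character(0)
  if (length(kinds) == 0) kinds <- "feature"
  grid <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    nw <- ceiling(chrom_lengths[[ch]] / win)
    tibble(chrom = ch, window = seq_len(nw),
           win_start = (seq_len(nw) - 1) * win,
           win_end = pmin(seq_len(nw) * win, chrom_lengths[[ch]]))
  })
  grid <- tidyr::crossing(grid, kind = kinds)
  cnt <- features |>
    mutate(window = floor(.data$start / win) + 1L) |>
    count(.data$chrom, .data$window, .data$kind, name = "n")
  grid |>
    left_join(cnt, by = c("chrom", "window", "kind")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(.data$chrom, .data$window, .data$kind)
}

#' QTL colocalization of selected features
#'
#' A feature colocalizes with a QTL when they share at least one base pair;
#' a feature may hit several traits.
#'
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end`.
#' @param qtls Tibble with `chrom`, `start`, `end`, `trait`.
#' @return Tibble with one row per trait: `trait`, `n_features`, `ids`
#'   (list-column of feature ids).
#' @export
qtl_colocalization <- function(features, qtls) {
  traits <- unique(qtls$trait)
  purrr::map_dfr(traits, function(tr) {
    q <- qtls[qtls$trait == tr, ]
    ids <- character(0)
    if (nrow(features) && nrow(q)) {
      ov <- GenomicRanges::findOverlaps(tbl_to_gr(features), tbl_to_gr(q))
      ids <- unique(features$feature_id[S4Vectors::queryHits(ov)])
    }
    tibble(trait = tr, n_features = length(ids), ids = list(ids))
  })
}

#' Fraction of the genome covered by transposable elements
#'
#' Union (overlap-merged) TE bases divided by total genome length, so
#' duplicated or overlapping intervals are counted once.
#'
#' @param tes Tibble with `chrom`, `start`, `end`.
#' @param chrom_lengths Named chromosome lengths.
#' @return A single number in \[0, 1\].
#' @export
te_genome_fraction <- function(tes, chrom_lengths) {
  if (nrow(tes) == 0) return(0)
  covered <- sum(BiocGenerics::width(GenomicRanges::reduce(tbl_to_gr(tes))))
  covered / sum(chrom_lengths)
}
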