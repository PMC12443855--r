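# Feature construction: the coverage/presence filter, gap-based clustering
# of retained cytosines into region features, the samples x features
# methylation matrix, and the printed feature-identifier format.

#' Per-cytosine methylation level
#'
#' The fraction of methylated reads, `n_meth / (n_meth + n_unmeth)`.
#'
#' @param n_meth,n_unmeth Non-negative integer read counts (vectorised).
#' @return Numeric vector of levels in \[0, 1\].
#' @export
#' @examples
#' methylation_level(5, 3)   # 0.625
methylation_level <- function(n_meth, n_unmeth) {
  cov <- n_meth + n_unmeth
  if (any(cov < 1)) abort("methylation level undefined at zero coverage")
  n_meth / cov
}

#' Coverage/presence filter for cytosines
#'
#' A cytosine is retained iff it is observed with coverage
#' `n_meth + n_unmeth >= min_coverage` in *every* sample (strict
#' completeness; no imputation).  By default only CG-context cytosines are
#' considered; set `context = "all"` to admit all three contexts.
#'
#' @param reports Named list of cytosine-report tibbles (>= 2 samples).
#' @param min_coverage Minimum per-sample read coverage (default 4).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @return Tibble of retained coordinates (`chrom`, `pos`, `context`),
#'   sorted by (chrom, pos).
#' @export
filter_cytosines <- function(reports, min_coverage = 4, context = "CG") {
  if (length(reports) < 2) abort("need at least two samples to filter")
  keep_ctx <- if (identical(context, "all")) methylation_contexts else context
  per_sample <- lapply(reports, function(r)
    r[r$context %in% keep_ctx &
        (r$n_meth + r$n_unmeth) >= min_coverage,
      c("chrom", "pos", "context")])
  counts <- bind_rows(per_sample) |>
    count(.data$chrom, .data$pos, .data$context, name = "n_present")
  counts |>
    filter(.data$n_present == length(reports)) |>
    select("chrom", "pos", "context") |>
    arrange(.data$chrom, .data$pos)
}

#' Cluster retained cytosines into region features
#'
#' Greedy single-pass clustering per chromosome: a region is extended while
#' the next retained cytosine lies within `gap_max` bp of the previous
#' member, and closed otherwise.  Regions with fewer than `min_cytosines`
#' members are dropped.  Region widths therefore vary; they are not fixed
#' bins.
#'
#' @param coords Tibble of retained coordinates (from [filter_cytosines()]),
#'   sorted by (chrom, pos).
#' @param gap_max Maximum gap between consecutive member cytosines (bp).
#' @param min_cytosines Minimum number of member cytosines per region.
#' @return Tibble with one row per region: `chrom`, `first`, `last`
#'   (1-based member bounds), `n_cytosines` and a `positions` list-column.
#' @export
#' @examples
#' coords <- tibble::tibble(chrom = "chr_1",
#'                          pos = c(100L, 150L, 180L, 199L), context = "CG")
#' cluster_regions(coords)
cluster_regions <- function(coords, gap_max = 100, min_cytosines = 4) {
  if (nrow(coords) == 0)
    return(tibble(chrom = character(), first = integer(), last = integer(),
                  n_cytosines = integer(), positions = list()))
  coords <- arrange(coords, .data$chrom, .data$pos)
  coords |>
    group_by(.data$chrom) |>
    mutate(cluster = cumsum(c(TRUE, diff(.data$pos) > gap_max))) |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(first = min(.data$pos), last = max(.data$pos),
              n_cytosines = n(), positions = list(.data$pos),
              .groups = "drop") |>
    filter(.data$n_cytosines >= min_cytosines) |>
    arrange(.data$chrom, .data$first) |>
    select("chrom", "first", "last", "n_cytosines", "positions")
}

#' Format and parse printed feature identifiers
#'
#' Cytosine features print as `<chrom>_<pos>` and regions as
#' `<chrom>_<first>_<last>`, all positions 1-based (e.g. `chr_4_31092165`,
#' `chr_3_9331371_9331488`).  Because chromosome names may themselves
#' contain underscores, parsing requires the feature kind.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (cytosines) or first member position
#'   (regions).
#' @param last 1-based last member position (regions only).
#' @param kind `"cytosine"` or `"region"`.
#' @return `format_feature_id()`: a character vector;
#'   `parse_feature_id()`: a tibble with `chrom`, `pos`, `last`, `kind`.
#' @export
#' @examples
#' format_feature_id("chr_4", 31092165, kind = "cytosine")
#' parse_feature_id("chr_3_9331371_9331488", kind = "region")
format_feature_id <- function(chrom, pos, last = NULL,
                              kind = c("cytosine", "region")) {
  kind <- match.arg(kind)
  if (kind == "cytosine") paste(chrom, pos, sep = "_")
  else paste(chrom, pos, last, sep = "_")
}

#' @rdname format_feature_id
#' @param id Character vector of printed identifiers.
#' @export
parse_feature_id <- function(id, kind = c("cytosine", "region")) {
  kind <- match.arg(kind)
  parts <- strsplit(id, "_", fixed = TRUE)
  n_tail <- if (kind == "cytosine") 1L else 2L
  purrr::map_dfr(parts, function(p) {
    if (length(p) <= n_tail) abort(sprintf("cannot parse feature id"))
    tail_vals <- suppressWarnings(as.integer(p[(length(p) - n_tail + 1):length(p)]))
    if (anyNA(tail_vals)) abort("cannot parse feature id: non-numeric position")
    tibble(chrom = paste(p[1:(length(p) - n_tail)], collapse = "_"),
           pos = tail_vals[1],
           last = if (n_tail == 2) tail_vals[2] else NA_integer_,
           kind = kind)
  })
}

#' Build the samples x features methylation matrix
#'
#' For `kind = "cytosine"` every retained coordinate becomes one feature
#' whose value is its methylation level in each sample.  For
#' `kind = "region"` each region's value is the (by default unweighted)
#' mean of its member-cytosine levels; `weight_by_coverage = TRUE` weights
#' members by their read coverage instead.  The presence filter guarantees
#' a complete matrix.
#'
#' @param reports Named list of cytosine-report tibbles.
#' @param features Output of [filter_cytosines()] (`kind = "cytosine"`) or
#'   [cluster_regions()] (`kind = "region"`).
#' @param meta Sample metadata tibble covering every sample in `reports`.
#' @param kind `"cytosine"` or `"region"`.
#' @param weight_by_coverage Weight region members by coverage.
#' @return An object of class `"methylation_matrix"`: a list with `values`
#'   (samples x features numeric matrix), `features` (tibble with
#'   `feature_id`, `chrom`, `start`, `end` 0-based half-open, `kind`,
#'   `n_cytosines`) and `meta`.
#' @export
build_matrix <- function(reports, features, meta,
                         kind = c("cytosine", "region"),
                         weight_by_coverage = FALSE) {
  kind <- match.arg(kind)
  missing_meta <- setdiff(names(reports), meta$sample_id)
  if (length(missing_meta))
    abort(sprintf("no metadata for sample(s): %s",
                  paste(missing_meta, collapse = ", ")))
  meta <- meta[match(names(reports), meta$sample_id), ]

  if (kind == "cytosine") {
    feat <- tibble(
      feature_id = format_feature_id(features$chrom, features$pos,
                                     kind = "cytosine"),
      chrom = features$chrom, start = features$pos - 1L, end = features$pos,
      kind = "cytosine", n_cytosines = 1L)
    key <- paste(features$chrom, features$pos)
    vals <- vapply(reports, function(r) {
      i <- match(key, paste(r$chrom, r$pos))
      if (anyNA(i)) abort("retained coordinate missing from a sample report")
      methylation_level(r$n_meth[i], r$n_unmeth[i])
    }, numeric(nrow(features)))
  } else {
    feat <- tibble(
      feature_id = format_feature_id(features$chrom, features$first,
                                     features$last, kind = "region"),
      chrom = features$chrom, start = features$first - 1L,
      end = features$last,
      kind = "region", n_cytosines = features$n_cytosines)
    member_key <- purrr::map2(features$chrom, features$positions,
                              function(ch, p) paste(ch, p))
    vals <- vapply(reports, function(r) {
      rk <- paste(r$chrom, r$pos)
      vapply(member_key, function(k) {
        i <- match(k, rk)
        if (anyNA(i)) abort("region member missing from a sample report")
        lv <- methylation_level(r$n_meth[i], r$n_unmeth[i])
        if (weight_by_coverage) {
          w <- r$n_meth[i] + r$n_unmeth[i]
          sum(lv * w) / sum(w)
        } else mean(lv)
      }, 0)
    }, numeric(nrow(features)))
  }
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(feat))
  vals <- t(vals)   # samples x features
  dimnames(vals) <- list(names(reports), feat$feature_id)
  new_methylation_matrix(vals, feat, meta)
}

new_methylation_matrix <- function(values, features, meta) {
  stopifnot(nrow(values) == nrow(meta), ncol(values) == nrow(features),
            !anyNA(values), all(values >= 0 & values <= 1),
            !anyDuplicated(features$feature_id))
  structure(list(values = values, features = features, meta = meta),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d %s features\n",
              nrow(x$values), ncol(x$values), x$features$kind[1]))
  print(count(x$meta, .data$stage))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

#' Subset a methylation matrix by features or samples
#'
#' @param mm A `methylation_matrix`.
#' @param feature_ids Character vector of feature ids to keep (in the given
#'   order).
#' @return A `methylation_matrix`.
#' @export
subset_features <- function(mm, feature_ids) {
  i <- match(feature_ids, mm$features$feature_id)
  if (anyNA(i)) abort("unknown feature id(s) in subset")
  new_methylation_matrix(mm$values[, i, drop = FALSE],
                         mm$features[i, ], mm$meta)
}

#' @rdname subset_features
#' @param stages Stages to keep (samples of other stages are dropped).
#' @export
subset_stages <- function(mm, stages) {
  keep <- mm$meta$stage %in% stages
  if (!any(keep)) abort("no samples left after stage subset")
  new_methylation_matrix(mm$values[keep, , drop = FALSE], mm$features,
                         mm$meta[keep, ])
}

#' Persist a methylation matrix as TSV plus a sidecar BED
#'
#' The TSV has samples as rows and feature ids as column headers (first
#' column `sample_id`); the BED carries the feature coordinates.
#'
#' @param mm A `methylation_matrix`.
#' @param path Output TSV path; the BED is written next to it as
#'   `<path>.bed`.
#' @return Named list of paths, invisibly.
#' @export
write_matrix <- function(mm, path) {
  tbl <- bind_cols(tibble(sample_id = rownames(mm$values)),
                   as_tibble(mm$values))
  readr::write_tsv(tbl, path, progress = FALSE)
  bed <- file.path(paste0(path, ".bed"))
  write_bed(mutate(mm$features, name = .data$feature_id), bed)
  invisible(list(matrix = path, bed = bed))
}
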