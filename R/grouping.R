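# A light-weight measure of which labelling (stage or cultivar) the sample
# structure of a matrix follows: leave-one-out nearest-centroid accuracy.
# Raw methylation matrices with planted cultivar confounding group by
# cultivar; after consensus selection they group by stage.

#' Leave-one-out nearest-centroid grouping score
#'
#' For each sample, the centroids of all groups are computed with the
#' sample itself held out, and the sample scores 1 when its nearest
#' centroid (Euclidean) belongs to its own group.  The mean over samples
#' measures how strongly the matrix geometry follows the grouping: 1 means
#' perfectly grouped, 1/#groups is chance.
#'
#' @param mm A `methylation_matrix` or numeric matrix (samples x features).
#' @param groups Grouping vector, or the name of a metadata column
#'   (`"stage"`, `"cultivar"`) when `mm` is a `methylation_matrix`.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' m <- matrix(c(0, 0, 1, 1, 0.1, 0.1, 0.9, 0.9), 4)
#' grouping_score(m, c("a", "a", "b", "b"))
grouping_score <- function(mm, groups = "stage") {
  if (inherits(mm, "methylation_matrix")) {
    if (is.character(groups) && length(groups) == 1)
      groups <- mm$meta[[groups]]
    x <- mm$values
  } else x <- as.matrix(mm)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  lev <- unique(groups)
  sums <- rowsum(x, groups)            # per-group feature sums
  cnt <- as.integer(table(groups)[rownames(sums)])
  hits <- vapply(seq_len(nrow(x)), function(i) {
    cs <- sums
    cs[groups[i], ] <- cs[groups[i], ] - x[i, ]
    n <- ifelse(rownames(sums) == groups[i], cnt - 1L, cnt)
    if (any(n == 0)) return(NA)        # singleton group: undefined
    cen <- cs / n
    d2 <- rowSums(sweep(cen, 2, x[i, ])^2)
    names(which.min(d2)) == groups[i]
  }, NA)
  mean(hits, na.rm = TRUE)
}

#' Confounding-reversal summary for a selection
#'
#' Compares the nearest-centroid grouping score by stage and by cultivar on
#' the full matrix and on its consensus-selected submatrix.  On data whose
#' raw structure is dominated by cultivar, the expectation is
#' cultivar > stage before selection and stage > cultivar after.
#'
#' @param mm A labelled `methylation_matrix` with a `cultivar` metadata
#'   column.
#' @param selected Character vector of selected feature ids.
#' @return Tibble with columns `feature_set`, `by_stage`, `by_cultivar`.
#' @export
confound_reversal <- function(mm, selected) {
  sel <- subset_features(mm, selected)
  tibble(feature_set = c("full", "selected"),
         by_stage = c(grouping_score(mm, "stage"),
                      grouping_score(sel, "stage")),
         by_cultivar = c(grouping_score(mm, "cultivar"),
                         grouping_score(sel, "cultivar")))
}
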