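# Per-sample methylation-context composition: absolute levels (methylated
# reads over total reads, per context) and relative shares (what fraction
# of called methylated cytosines falls in each context).

#' Methylation-context composition of one sample
#'
#' Absolute level per context is the ratio of methylated to total reads over
#' all cytosines of that context.  The relative share is the fraction of
#' *called* methylated cytosines belonging to each context; because
#' cytosine reports carry counts rather than calls, a cytosine is called
#' methylated when it has at least `min_meth` methylated reads, a
#' methylation level of at least `min_level` and coverage of at least
#' `min_coverage` (defaults 1 / 0.1 / 4).  The call rule is a convention of
#' this package and is deliberately configurable.
#'
#' Contexts with zero total coverage get `NA` absolute level with a warning;
#' if no cytosine is called methylated the relative shares are `NA` with a
#' warning (never silently zero).
#'
#' @param records A cytosine-report tibble (see [read_cytosine_report()]).
#' @param min_meth,min_level,min_coverage Methylated-cytosine call rule.
#' @return A tibble of class `"context_composition"` with one row per
#'   context: `context`, `absolute_level`, `relative_share`, `n_sites`,
#'   `n_methylated`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 2, n_cytosines = 400,
#'                     class_counts = c(endodormancy = 2, ecodormancy = 2))
#' sim <- simulate_methylomes(cfg)
#' context_composition(sim$reports[[1]])
context_composition <- function(records, min_meth = 1, min_level = 0.1,
                                min_coverage = 4) {
  if (nrow(records) == 0) abort("empty record set")
  cov <- records$n_meth + records$n_unmeth
  called <- records$n_meth >= min_meth & cov >= min_coverage &
    records$n_meth / pmax(cov, 1) >= min_level
  out <- purrr::map_dfr(methylation_contexts, function(cx) {
    i <- records$context == cx
    tot <- sum(cov[i])
    tibble(context = cx,
           absolute_level = if (tot > 0) sum(records$n_meth[i]) / tot
                            else NA_real_,
           n_sites = sum(i),
           n_methylated = sum(called & i))
  })
  n_called <- sum(out$n_methylated)
  if (n_called > 0) {
    out$relative_share <- out$n_methylated / n_called
  } else {
    warn("no cytosine passed the methylated call rule; relative shares undefined")
    out$relative_share <- NA_real_
  }
  if (anyNA(out$absolute_level))
    warn(sprintf("zero coverage in context(s) %s; absolute level undefined",
                 paste(out$context[is.na(out$absolute_level)], collapse = ", ")))
  out <- out[, c("context", "absolute_level", "relative_share",
                 "n_sites", "n_methylated")]
  class(out) <- c("context_composition", class(out))
  out
}

#' Context composition for every sample of a study
#'
#' @param reports Named list of cytosine-report tibbles.
#' @param ... Passed to [context_composition()].
#' @return A tibble with a `sample_id` column prepended.
#' @export
context_composition_all <- function(reports, ...) {
  purrr::imap_dfr(reports, function(r, id)
    mutate(as_tibble(context_composition(r, ...)), sample_id = id,
           .before = 1))
}
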