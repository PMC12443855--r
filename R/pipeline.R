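# End-to-end orchestration: simulate (or load) -> filter/build -> select ->
# evaluate -> annotate, with every artifact written as plain TSV/BED/JSON
# and a manifest recording configuration, seeds and content hashes.

#' Run the full dormancy-classification pipeline
#'
#' Orchestrates every stage on either a synthetic study (give `sim_config`)
#' or existing files (give `reports_dir`, `meta`, and annotation paths).
#' All intermediate artifacts are persisted as plain text so each stage can
#' be inspected independently; a `manifest.json` records the configuration,
#' seeds, package versions and MD5 hashes of every output, which suffices
#' to reproduce the run.
#'
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param sim_config A [synth_config()] to simulate a study, or `NULL` to
#'   read real inputs.
#' @param reports_dir,meta,gff,te,qtl,chrom_sizes Input paths when
#'   `sim_config` is `NULL`.
#' @param scenario `"3stage"` or `"2stage"`.
#' @param kinds Feature kinds to build (`"cytosine"`, `"region"` or both).
#' @param context Contexts admitted by the presence filter (`"CG"` or
#'   `"all"`; synthetic runs default to `"all"`, file runs to `"CG"`).
#' @param min_coverage,gap_max,min_cytosines Filter/clustering parameters.
#' @param rf_config,xgb_config,scheme Model and cross-validation settings.
#' @return The `scenario_report`, invisibly, with the run directory in
#'   attribute `"out_dir"`.
#' @export
run_pipeline <- function(out_dir,
                         sim_config = NULL,
                         reports_dir = NULL, meta = NULL,
                         gff = NULL, te = NULL, qtl = NULL,
                         chrom_sizes = NULL,
                         scenario = c("3stage", "2stage"),
                         kinds = c("cytosine", "region"),
                         context = NULL,
                         min_coverage = 4, gap_max = 100, min_cytosines = 4,
                         rf_config = dormclass::rf_config(),
                         xgb_config = dormclass::xgb_config(),
                         scheme = NULL) {
  scenario <- match.arg(scenario)
  kinds <- match.arg(kinds, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- function(stage) message(sprintf("[%s] %s", Sys.time(), stage))

  if (!is.null(sim_config)) {
    stage_log("simulate")
    ann <- simulate_genome_annotation(sim_config)
    sim <- simulate_methylomes(sim_config, ann)
    write_annotation_bundle(ann, file.path(out_dir, "annotation"))
    write_methylome_sim(sim, file.path(out_dir, "data"))
    reports <- sim$reports
    meta_tbl <- sim$meta
    context <- context %||% "all"
  } else {
    stage_log("load")
    if (is.null(reports_dir) || !dir.exists(reports_dir))
      abort(sprintf("missing reports directory: %s", reports_dir %||% "<NULL>"))
    if (is.null(meta) || !file.exists(meta))
      abort(sprintf("missing metadata file: %s", meta %||% "<NULL>"))
    reports <- read_cytosine_reports(reports_dir)
    meta_tbl <- read_sample_meta(meta)
    ann <- if (!is.null(gff)) read_annotation(gff, te, qtl, chrom_sizes)
           else NULL
    context <- context %||% "CG"
  }

  stage_log("filter/build")
  retained <- filter_cytosines(reports, min_coverage, context)
  matrices <- list()
  if ("cytosine" %in% kinds)
    matrices$cytosine <- build_matrix(reports, retained, meta_tbl,
                                      kind = "cytosine")
  if ("region" %in% kinds) {
    regions <- cluster_regions(retained, gap_max, min_cytosines)
    if (nrow(regions) >= 2)
      matrices$region <- build_matrix(reports, regions, meta_tbl,
                                      kind = "region")
    else warn("fewer than two region features; region dataset skipped")
  }
  for (ds in names(matrices))
    write_matrix(matrices[[ds]],
                 file.path(out_dir, sprintf("matrix_%s.tsv", ds)))

  stage_log("select/evaluate")
  report <- run_scenario(matrices, scenario, scheme = scheme,
                         rf_config = rf_config, xgb_config = xgb_config)
  for (ds in names(report$selections)) {
    sel <- report$selections[[ds]]
    readr::write_tsv(sel$importance,
                     file.path(out_dir, sprintf("importances_%s.tsv", ds)),
                     progress = FALSE)
    readr::write_tsv(sel$ranks,
                     file.path(out_dir, sprintf("selected_%s.tsv", ds)),
                     progress = FALSE)
  }
  readr::write_tsv(report$benefit, file.path(out_dir, "benefit_tests.tsv"),
                   progress = FALSE)
  cv_summary <- purrr::map_dfr(names(report$reports), function(ds)
    purrr::map_dfr(names(report$reports[[ds]]), function(m)
      purrr::map_dfr(c("full", "selected"), function(fs) {
        r <- report$reports[[ds]][[m]][[fs]]
        mutate(glance(r), dataset = ds, model = m, feature_set = fs,
               .before = 1)
      })))
  readr::write_tsv(cv_summary, file.path(out_dir, "cv_summary.tsv"),
                   progress = FALSE)

  if (!is.null(sim_config) || !is.null(gff)) {
    stage_log("annotate")
    for (ds in names(report$selections)) {
      mm <- matrices[[ds]]
      sel_ids <- report$selections[[ds]]$selected
      feats <- mm$features[match(sel_ids, mm$features$feature_id), ]
      asg <- assign_context(feats, ann)
      readr::write_tsv(asg,
                       file.path(out_dir, sprintf("contexts_%s.tsv", ds)),
                       progress = FALSE)
      write_bed(mutate(feats, name = .data$feature_id),
                file.path(out_dir, sprintf("selected_%s.bed", ds)))
      qt <- qtl_colocalization(feats, ann$qtls) |>
        mutate(ids = vapply(.data$ids, paste, "", collapse = ","))
      readr::write_tsv(qt,
                       file.path(out_dir, sprintf("qtl_%s.tsv", ds)),
                       progress = FALSE)
    }
  }

  stage_log("manifest")
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    created = format(Sys.time()),
    scenario = scenario, kinds = kinds, context = context,
    filter = list(min_coverage = min_coverage, gap_max = gap_max,
                  min_cytosines = min_cytosines),
    seeds = list(sim = if (!is.null(sim_config)) sim_config$seed else NULL,
                 rf = rf_config$seed, xgb = xgb_config$seed,
                 cv = report$scheme$seed),
    versions = list(dormclass = as.character(utils::packageVersion("dormclass")),
                    randomForest = as.character(utils::packageVersion("randomForest")),
                    xgboost = as.character(utils::packageVersion("xgboost"))),
    hashes = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(report, "out_dir") <- out_dir
  invisible(report)
}
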