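# Readers and writers for the file dialects the pipeline speaks:
# Bismark-style cytosine reports (7-column TSV, 1-based), sample metadata
# TSV, BED6(+1 label) and GFF3 (via rtracklayer).  Internal coordinates are
# 0-based half-open everywhere; 1-based formats are converted exactly once
# at the boundary.

report_cols <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "trinucleotide")

#' Read a Bismark-dialect cytosine report
#'
#' Parses a 7-column tab-separated cytosine report (chromosome, 1-based
#' position, strand, methylated read count, unmethylated read count,
#' context, trinucleotide) and validates every record.  Input order is
#' preserved.
#'
#' @param path Path to the report file.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("chr_1\t100\t+\t5\t3\tCG\tCGA", f)
#' read_cytosine_report(f)
read_cytosine_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  x <- readr::read_tsv(path, col_names = report_cols,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         strand = readr::col_character(),
                         n_meth = readr::col_integer(),
                         n_unmeth = readr::col_integer(),
                         context = readr::col_character(),
                         trinucleotide = readr::col_character()),
                       progress = FALSE, lazy = FALSE)
  pb <- readr::problems(x)
  if (nrow(pb) > 0)
    abort(sprintf("malformed cytosine report %s: line %d (%s)",
                  path, pb$row[1], pb$expected[1]))
  bad <- which(!(x$context %in% methylation_contexts))
  if (length(bad))
    abort(sprintf("unknown context '%s' in %s, line %d",
                  x$context[bad[1]], path, bad[1]))
  bad <- which(!(x$strand %in% c("+", "-")))
  if (length(bad))
    abort(sprintf("bad strand '%s' in %s, line %d",
                  x$strand[bad[1]], path, bad[1]))
  bad <- which(x$pos < 1 | x$n_meth < 0 | x$n_unmeth < 0)
  if (length(bad))
    abort(sprintf("invalid position or counts in %s, line %d", path, bad[1]))
  x
}

#' Write a cytosine report
#'
#' @param records Tibble as returned by [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  stopifnot(all(report_cols %in% names(records)))
  readr::write_tsv(records[report_cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' A tab-separated table with header columns `sample_id`, `cultivar`,
#' `experiment`, `chilling_hours`, `stage`.  Stages must come from
#' [dormancy_stages] and sample ids must be unique.
#'
#' @param path File path.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @export
read_sample_meta <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cultivar = readr::col_character(),
    experiment = readr::col_character(),
    chilling_hours = readr::col_double(),
    stage = readr::col_character()), progress = FALSE)
  if (anyDuplicated(x$sample_id))
    abort(sprintf("duplicate sample_id in %s", path))
  bad <- setdiff(unique(x$stage), dormancy_stages)
  if (length(bad))
    abort(sprintf("unknown stage '%s' in %s", bad[1], path))
  if (any(x$chilling_hours < 0))
    abort(sprintf("negative chilling_hours in %s", path))
  x
}

#' @rdname read_sample_meta
#' @param meta Metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read and write BED6(+1) interval files
#'
#' Standard BED semantics: 0-based half-open coordinates.  An optional
#' seventh column carries a label (TE class or QTL trait).
#'
#' @param path File path.
#' @param label Name for the optional seventh column (`NULL` for plain BED6).
#' @return A tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   and, when present, the label column.
#' @export
read_bed <- function(path, label = NULL) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  ncol <- if (length(first)) length(strsplit(first, "\t")[[1]]) else 6L
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  types <- "ciicdc"
  if (ncol >= 7) {
    nms <- c(nms, label %||% "label")
    types <- paste0(types, "c")
  }
  x <- readr::read_tsv(path, col_names = nms, col_types = types,
                       progress = FALSE)
  if (any(x$end <= x$start))
    abort(sprintf("interval with end <= start in %s", path))
  x
}

#' @rdname read_bed
#' @param x Tibble with at least `chrom`, `start`, `end` (0-based half-open);
#'   `name`, `score`, `strand` and a label column are used when present.
#' @export
write_bed <- function(x, path, label = NULL) {
  col_or <- function(nm, default)
    if (nm %in% names(x)) x[[nm]] else default
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = col_or("name", "."),
                score = col_or("score", 0),
                strand = col_or("strand", "."))
  if (!is.null(label)) out[[label]] <- x[[label]]
  out <- arrange(out, .data$chrom, .data$start, .data$end, .data$name)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

annotation_to_gff_granges <- function(bundle) {
  g <- bundle$genes
  e <- bundle$exons
  gr <- GenomicRanges::GRanges(
    seqnames = c(g$chrom, e$chrom),
    ranges = IRanges::IRanges(start = c(g$start, e$start) + 1,
                              end = c(g$end, e$end)),
    strand = c(g$strand, e$strand))
  gr$source <- "dormclass"
  gr$type <- c(rep("gene", nrow(g)), rep("exon", nrow(e)))
  gr$ID <- c(g$gene_id, e$exon_id)
  gr$Parent <- c(rep(NA_character_, nrow(g)), e$gene_id)
  gr
}

#' Write a synthetic annotation bundle to disk
#'
#' Genes and exons go to `genes.gff3` (1-based, via rtracklayer), TEs and
#' QTLs to BED6+1 files with the class/trait in column 7, chromosome sizes
#' to `chrom.sizes`.
#'
#' @param bundle An `annotation_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(gff = file.path(dir, "genes.gff3"),
                te = file.path(dir, "te.bed"),
                qtl = file.path(dir, "qtl.bed"),
                sizes = file.path(dir, "chrom.sizes"))
  rtracklayer::export(annotation_to_gff_granges(bundle), paths$gff,
                      format = "gff3")
  write_bed(mutate(bundle$tes, name = .data$te_id), paths$te, label = "class")
  write_bed(mutate(bundle$qtls,
                   name = paste0("qtl_", .data$trait)), paths$qtl,
            label = "trait")
  readr::write_tsv(tibble(chrom = names(bundle$chrom_lengths),
                          length = unname(bundle$chrom_lengths)),
                   paths$sizes, col_names = FALSE, progress = FALSE)
  invisible(paths)
}

#' Read genome annotation files into an annotation bundle
#'
#' @param gff Path to a GFF3 file with `gene` and `exon` features (1-based
#'   inclusive; converted internally to 0-based half-open).
#' @param te Path to a BED6+1 file of TE intervals, class label in column 7.
#' @param qtl Path to a BED6+1 file of QTL intervals, trait in column 7.
#' @param chrom_sizes Optional path to a two-column chromosome-sizes file;
#'   when missing, chromosome lengths are taken as the right-most annotated
#'   coordinate per chromosome.
#' @return An `annotation_bundle`.
#' @export
read_annotation <- function(gff, te, qtl, chrom_sizes = NULL) {
  gr <- rtracklayer::import(gff, format = "gff3")
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr)))
    abort(sprintf("interval with end < start in %s", gff))
  as_tbl <- function(g) {
    tibble(chrom = as.character(GenomicRanges::seqnames(g)),
           start = BiocGenerics::start(g) - 1L,
           end = BiocGenerics::end(g),
           strand = as.character(BiocGenerics::strand(g)))
  }
  is_gene <- gr$type == "gene"
  is_exon <- gr$type == "exon"
  genes <- as_tbl(gr[is_gene]) |>
    mutate(gene_id = as.character(gr$ID[is_gene]))
  parents <- vapply(gr$Parent[is_exon], function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  exons <- as_tbl(gr[is_exon]) |>
    mutate(gene_id = parents,
           exon_id = as.character(gr$ID[is_exon]))
  tes <- read_bed(te, label = "class") |>
    rename(te_id = "name") |>
    select("chrom", "start", "end", "te_id", "class")
  qtls <- read_bed(qtl, label = "trait") |>
    select("chrom", "start", "end", "trait")
  if (!is.null(chrom_sizes)) {
    cs <- readr::read_tsv(chrom_sizes, col_names = c("chrom", "length"),
                          col_types = "ci", progress = FALSE)
    lens <- setNames(cs$length, cs$chrom)
  } else {
    all_iv <- bind_rows(genes[c("chrom", "end")], tes[c("chrom", "end")],
                        qtls[c("chrom", "end")])
    lens <- tapply(all_iv$end, all_iv$chrom, max)
    lens <- setNames(as.integer(lens), names(lens))
  }
  structure(list(genes = genes, exons = exons, tes = tes, qtls = qtls,
                 chrom_lengths = lens),
            class = "annotation_bundle")
}

#' Write a complete synthetic study to disk
#'
#' Produces one cytosine report per sample under `reports/`, a
#' `metadata.tsv`, and the planted truth tables.
#'
#' @param sim A `methylome_sim` from [simulate_methylomes()].
#' @param dir Output directory.
#' @return Named list of paths, invisibly.
#' @export
write_methylome_sim <- function(sim, dir) {
  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  report_paths <- vapply(names(sim$reports), function(s) {
    p <- file.path(rep_dir, paste0(s, ".CX_report.txt"))
    write_cytosine_report(sim$reports[[s]], p)
    p
  }, "")
  meta_path <- file.path(dir, "metadata.tsv")
  write_sample_meta(sim$meta, meta_path)
  inf_path <- file.path(dir, "truth_informative.tsv")
  conf_path <- file.path(dir, "truth_confounder.tsv")
  readr::write_tsv(sim$truth$informative, inf_path, progress = FALSE)
  readr::write_tsv(sim$truth$confounder, conf_path, progress = FALSE)
  invisible(list(reports = report_paths, meta = meta_path,
                 truth_informative = inf_path, truth_confounder = conf_path))
}

#' Read a directory of cytosine reports
#'
#' @param paths Named character vector (names become sample ids) or a
#'   directory containing `*.CX_report.txt` files, in which case sample ids
#'   are derived from file names.
#' @return Named list of report tibbles.
#' @export
read_cytosine_reports <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.CX_report\\.txt$",
                        full.names = TRUE)
    paths <- setNames(files, sub("\\.CX_report\\.txt$", "", basename(files)))
  }
  if (is.null(names(paths))) abort("report paths must be named by sample id")
  lapply(paths, read_cytosine_report)
}
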