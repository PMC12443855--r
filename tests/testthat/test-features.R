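test_that("methylation level is the methylated-read fraction", {
  expect_equal(methylation_level(5, 3), 0.625)
  expect_equal(methylation_level(0, 7), 0)
  expect_equal(methylation_level(4, 0), 1)
  expect_error(methylation_level(0, 0), "zero coverage")
})

make_reports <- function(cov_matrix, chrom = "chr_1", context = "CG") {
  # cov_matrix: cytosines x samples coverages; meth = half the reads
  pos <- seq_len(nrow(cov_matrix)) * 10L
  lapply(setNames(seq_len(ncol(cov_matrix)),
                  paste0("S", seq_len(ncol(cov_matrix)))), function(j) {
    cov <- cov_matrix[, j]
    tibble::tibble(chrom = chrom, pos = pos, strand = "+",
                   n_meth = as.integer(ceiling(cov / 2)),
                   n_unmeth = as.integer(floor(cov / 2)),
                   context = context, trinucleotide = "CGA")
  })
}

test_that("presence filter keeps only cytosines covered in every sample", {
  reps <- make_reports(rbind(c(4, 5, 4), c(4, 3, 9)))
  kept <- filter_cytosines(reps, min_coverage = 4)
  expect_equal(kept$pos, 10L)   # second site dropped: one sample at 3 reads
  expect_error(filter_cytosines(reps[1], 4), "two samples")
})

test_that("presence filter equals the exhaustive double loop on random input", {
  set.seed(99)
  for (trial in 1:5) {
    cov <- matrix(rpois(200 * 5, 5), 200, 5)
    reps <- make_reports(cov)
    kept <- filter_cytosines(reps, min_coverage = 4)
    oracle <- integer(0)
    for (i in 1:200) {
      ok <- TRUE
      for (j in 1:5) if (cov[i, j] < 4) ok <- FALSE
      if (ok) oracle <- c(oracle, i * 10L)
    }
    expect_identical(kept$pos, oracle)
  }
})

test_that("raising the coverage threshold never grows the retained set", {
  set.seed(7)
  reps <- make_reports(matrix(rpois(300 * 4, 6), 300, 4))
  sizes <- sapply(2:10, function(mc)
    nrow(filter_cytosines(reps, min_coverage = mc)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("region clustering follows the gap rule", {
  mk <- function(pos) tibble::tibble(chrom = "chr_1", pos = as.integer(pos),
                                     context = "CG")
  r1 <- cluster_regions(mk(c(100, 150, 180, 199)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$first, 100L)
  expect_equal(r1$last, 199L)
  expect_equal(r1$n_cytosines, 4L)
  # a 150-bp gap splits; the 2-member cluster is dropped
  r2 <- cluster_regions(mk(c(100, 150, 300, 360, 420, 480)))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$first, 300L)
  expect_equal(r2$last, 480L)
  expect_equal(nrow(cluster_regions(mk(integer(0)))), 0)
})

# independent naive clustering: explicit scan, one position at a time
naive_clusters <- function(pos, gap_max = 100, min_cyt = 4) {
  pos <- sort(pos)
  out <- list(); cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= gap_max) cur <- c(cur, p)
    else { out <- c(out, list(cur)); cur <- p }
  }
  out <- c(out, list(cur))
  Filter(function(cl) length(cl) >= min_cyt, out)
}

test_that("clustering equals a naive second implementation on random input", {
  set.seed(3)
  for (trial in 1:20) {
    pos <- sort(sample.int(20000, 500))
    got <- cluster_regions(tibble::tibble(chrom = "chr_1", pos = pos,
                                          context = "CG"))
    want <- naive_clusters(pos)
    expect_equal(nrow(got), length(want))
    expect_equal(got$first, vapply(want, min, 0L))
    expect_equal(got$last, vapply(want, max, 0L))
    expect_equal(got$positions, want)
    # post-hoc gap rule on every emitted region
    expect_true(all(vapply(got$positions, function(p)
      length(p) < 2 || max(diff(p)) <= 100, TRUE)))
  }
})

test_that("region widths vary rather than tiling fixed bins", {
  s <- small_sim()
  ret <- filter_cytosines(s$sim$reports, context = "all")
  reg <- cluster_regions(ret)
  widths <- reg$last - reg$first + 1
  expect_gt(length(unique(widths)), 3)
  expect_gt(max(widths), 100)   # clusters may exceed the gap parameter
})

test_that("matrix values are per-sample levels and region means", {
  reps <- list(
    A = tibble::tibble(chrom = "chr_1", pos = c(10L, 20L, 30L, 40L),
                       strand = "+", n_meth = c(1L, 2L, 3L, 4L),
                       n_unmeth = c(4L, 3L, 2L, 1L),
                       context = "CG", trinucleotide = "CGA"),
    B = tibble::tibble(chrom = "chr_1", pos = c(10L, 20L, 30L, 40L),
                       strand = "+", n_meth = c(5L, 5L, 5L, 5L),
                       n_unmeth = c(5L, 5L, 5L, 5L),
                       context = "CG", trinucleotide = "CGA"))
  meta <- tibble::tibble(sample_id = c("A", "B"), cultivar = "cv1",
                         experiment = "E1", chilling_hours = 0,
                         stage = c("endodormancy", "ecodormancy"))
  coords <- filter_cytosines(reps, min_coverage = 4)
  mm <- build_matrix(reps, coords, meta, kind = "cytosine")
  expect_equal(dim(mm), c(2, 4))
  expect_equal(unname(mm$values["A", ]), c(0.2, 0.4, 0.6, 0.8))
  reg <- cluster_regions(coords, gap_max = 100, min_cytosines = 4)
  mr <- build_matrix(reps, reg, meta, kind = "region")
  expect_equal(unname(mr$values["A", 1]), 0.5)   # mean of 0.2 0.4 0.6 0.8
  # with equal coverages the weighted mean equals the unweighted mean
  mw <- build_matrix(reps, reg, meta, kind = "region",
                     weight_by_coverage = TRUE)
  expect_equal(mw$values, mr$values)
  # missing metadata is an error
  expect_error(build_matrix(reps, coords, meta[1, ], kind = "cytosine"),
               "no metadata")
})

test_that("matrix shape contract holds on a synthetic run", {
  s <- small_sim()
  ret <- filter_cytosines(s$sim$reports, context = "all")
  mm <- build_matrix(s$sim$reports, ret, s$sim$meta, kind = "cytosine")
  expect_equal(nrow(mm$values), length(s$sim$reports))
  expect_equal(ncol(mm$values), nrow(ret))
  expect_true(all(mm$values >= 0 & mm$values <= 1))
  expect_false(anyNA(mm$values))
})

test_that("feature ids print and parse in the published format", {
  expect_equal(format_feature_id("chr_4", 31092165, kind = "cytosine"),
               "chr_4_31092165")
  expect_equal(format_feature_id("chr_3", 9331371, 9331488, kind = "region"),
               "chr_3_9331371_9331488")
  p <- parse_feature_id("chr_4_31092165", kind = "cytosine")
  expect_equal(p$chrom, "chr_4")
  expect_equal(p$pos, 31092165L)
  q <- parse_feature_id("chr_3_9331371_9331488", kind = "region")
  expect_equal(q$chrom, "chr_3")
  expect_equal(q$pos, 9331371L)
  expect_equal(q$last, 9331488L)
  # round trip on random coordinates
  set.seed(1)
  for (i in 1:20) {
    ch <- sample(c("chr_1", "scaffold_12"), 1)
    a <- sample.int(1e8, 1); b <- a + sample.int(500, 1)
    expect_equal(parse_feature_id(
      format_feature_id(ch, a, b, kind = "region"), "region")$last, b)
    expect_equal(parse_feature_id(
      format_feature_id(ch, a, kind = "cytosine"), "cytosine")$pos, a)
  }
})
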