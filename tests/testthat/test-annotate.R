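toy_genes <- tibble::tibble(
  chrom = c("chr_1", "chr_1"), start = c(5000, 5000), end = c(7000, 7000),
  strand = c("+", "-"), gene_id = c("g1", "g2"))
lens <- c(chr_1 = 100000L, chr_2 = 50000L)

test_that("promoters are strand-aware 2-kb windows, clipped at bounds", {
  p <- derive_promoters(toy_genes, lens)
  expect_equal(p$start[p$gene_id == "g1"], 3000)
  expect_equal(p$end[p$gene_id == "g1"], 5000)
  expect_equal(p$start[p$gene_id == "g2"], 7000)
  expect_equal(p$end[p$gene_id == "g2"], 9000)
  near0 <- tibble::tibble(chrom = "chr_1", start = 500, end = 1500,
                          strand = "+", gene_id = "g3")
  pc <- derive_promoters(near0, lens)
  expect_equal(pc$start, 0)
  expect_equal(pc$end, 500)
  expect_error(derive_promoters(dplyr::mutate(near0, strand = "?"), lens),
               "strand")
})

test_that("downstream windows mirror promoters on the 3' side", {
  d <- derive_downstream(toy_genes, lens)
  expect_equal(d$start[d$gene_id == "g1"], 7000)
  expect_equal(d$end[d$gene_id == "g1"], 9000)
  expect_equal(d$start[d$gene_id == "g2"], 3000)
  expect_equal(d$end[d$gene_id == "g2"], 5000)
  # a gene ending at the chromosome end has no downstream window
  at_end <- tibble::tibble(chrom = "chr_2", start = 49000, end = 50000,
                           strand = "+", gene_id = "g4")
  expect_equal(nrow(derive_downstream(at_end, lens)), 0)
})

toy_bundle <- structure(list(
  genes = toy_genes,
  exons = dplyr::mutate(toy_genes,
                        exon_id = paste0(gene_id, ".e1")),
  tes = tibble::tibble(chrom = "chr_1", start = c(4000, 4100),
                       end = c(4500, 4600),
                       te_id = c("te1", "te2"),
                       class = c("LTR/Copia", "LTR/Ty3")),
  qtls = tibble::tibble(chrom = "chr_1", start = 25000000 %/% 1000,
                        end = 26000000 %/% 1000, trait = "CR"),
  chrom_lengths = lens), class = "annotation_bundle")

test_that("context precedence resolves multi-overlaps deterministically", {
  feats <- tibble::tibble(
    feature_id = c("in_te_and_promoter", "in_gene", "nowhere"),
    chrom = "chr_1", start = c(4200, 6000, 90000),
    end = c(4201, 6001, 90001))
  a <- assign_context(feats, toy_bundle)
  expect_equal(a$primary_context,
               c("TE", "gene", "intergenic"))
  expect_equal(a$gene_relative_context,
               c("promoter", "gene", "intergenic"))
  expect_true(a$te_overlap[1])
  # largest-overlap TE wins; here both cover the point, tie broken by
  # coordinate order
  expect_equal(a$te_class[1], "LTR/Copia")
  expect_false(a$te_overlap[2])
  expect_true(is.na(a$te_class[3]))
  expect_error(assign_context(dplyr::mutate(feats, chrom = "chrX"),
                              toy_bundle), "unknown chromosome")
})

test_that("every feature gets exactly one primary context (partition)", {
  s <- small_sim()
  set.seed(5)
  feats <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:300),
    chrom = sample(names(s$cfg$chrom_lengths), 300, replace = TRUE),
    start = sample.int(190000, 300))
  feats$end <- feats$start + sample(c(1L, 50L, 200L), 300, replace = TRUE)
  a <- assign_context(feats, s$ann)
  expect_equal(nrow(a), 300)
  expect_true(all(a$primary_context %in%
                    c("TE", "promoter", "gene", "downstream", "intergenic")))
  expect_equal(sum(table(a$primary_context)), 300)
})

test_that("context assignment agrees with an all-pairs overlap oracle", {
  s <- small_sim()
  ann <- s$ann
  proms <- derive_promoters(ann$genes, ann$chrom_lengths)
  downs <- derive_downstream(ann$genes, ann$chrom_lengths)
  set.seed(8)
  feats <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:200),
    chrom = sample(names(ann$chrom_lengths), 200, replace = TRUE),
    start = sample.int(190000, 200))
  feats$end <- feats$start + sample(c(1L, 120L), 200, replace = TRUE)
  a <- assign_context(feats, ann)
  hit_te <- apply(naive_overlaps(feats, ann$tes), 1, any)
  hit_pr <- apply(naive_overlaps(feats, proms), 1, any)
  hit_gn <- apply(naive_overlaps(feats, ann$genes), 1, any)
  hit_dn <- apply(naive_overlaps(feats, downs), 1, any)
  oracle <- ifelse(hit_te, "TE",
            ifelse(hit_pr, "promoter",
            ifelse(hit_gn, "gene",
            ifelse(hit_dn, "downstream", "intergenic"))))
  expect_equal(a$primary_context, oracle)
  expect_equal(a$te_overlap, hit_te)
})

test_that("TE crosstab counts and marginals are consistent", {
  asg <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    primary_context = "TE",
    gene_relative_context = "promoter",
    te_overlap = TRUE,
    te_class = c("LTR/Copia", "LTR/Copia", "LTR/Ty3"))
  ct <- te_context_crosstab(asg)
  expect_equal(ct$n[ct$te_class == "LTR/Copia"], 2)
  expect_equal(ct$n[ct$te_class == "LTR/Ty3"], 1)
  expect_equal(sum(ct$n), sum(asg$te_overlap))
  expect_equal(nrow(te_context_crosstab(asg[0, ])), 0)
  # random marginal consistency
  set.seed(2)
  big <- tibble::tibble(
    feature_id = sprintf("f%d", 1:200),
    primary_context = "TE",
    gene_relative_context = sample(c("promoter", "gene", "downstream",
                                     "intergenic"), 200, TRUE),
    te_overlap = sample(c(TRUE, FALSE), 200, TRUE),
    te_class = sample(c("LTR/Copia", "LTR/Ty3", "Unknown"), 200, TRUE))
  big$te_class[!big$te_overlap] <- NA
  ct2 <- te_context_crosstab(big)
  expect_equal(sum(ct2$n), sum(big$te_overlap))
  by_class <- dplyr::count(dplyr::filter(big, te_overlap), te_class)
  got <- dplyr::count(ct2, te_class, wt = n)
  expect_equal(as.data.frame(got), as.data.frame(by_class))
})

test_that("feature-set comparison counts shared, exclusive and colocalized", {
  mkset <- function(ids, kind = "cytosine", start = seq_along(ids) * 100) {
    tibble::tibble(feature_id = ids, chrom = "chr_1", start = start,
                   end = start + ifelse(kind == "cytosine", 1L, 100L),
                   kind = kind)
  }
  cmp <- compare_feature_sets(list(m1 = mkset(c("a", "b")),
                                   m2 = mkset(c("b", "c"))))
  expect_equal(cmp$pairwise$shared, 1)
  expect_equal(cmp$exclusive$n_exclusive, c(1, 1))
  # positional colocalization: cytosine inside a region span
  cyt <- mkset("cy1", start = 150)
  reg <- tibble::tibble(feature_id = "rg1", chrom = "chr_1", start = 100,
                        end = 200, kind = "region")
  cmp2 <- compare_feature_sets(list(cyt = cyt, reg = reg))
  expect_equal(cmp2$colocalization$n_colocalized, 1)
  expect_equal(cmp2$colocalization$ids[[1]], "cy1")
  expect_error(compare_feature_sets(list(m1 = mkset(c("a", "a")),
                                         m2 = mkset("b"))), "duplicate")
})

test_that("set comparisons equal the set-algebra oracle on random sets", {
  set.seed(6)
  universe <- sprintf("f%03d", 1:60)
  for (i in 1:100) {
    a <- sample(universe, sample(5:30, 1))
    b <- sample(universe, sample(5:30, 1))
    mk <- function(ids) tibble::tibble(feature_id = ids, chrom = "chr_1",
                                       start = seq_along(ids), kind = "cytosine",
                                       end = seq_along(ids) + 1L)
    cmp <- compare_feature_sets(list(A = mk(a), B = mk(b)))
    expect_equal(cmp$pairwise$shared, length(intersect(a, b)))
    expect_equal(cmp$exclusive$n_exclusive,
                 c(length(setdiff(a, b)), length(setdiff(b, a))))
  }
})

test_that("density windows tile from zero and count by feature start", {
  feats <- tibble::tibble(feature_id = c("a", "b"), chrom = "chr_1",
                          start = c(5e5, 15e5), end = c(5e5 + 1, 15e5 + 1),
                          kind = "cytosine")
  dw <- density_windows(feats, c(chr_1 = 2e6), window = 1e6)
  expect_equal(dw$n, c(1L, 1L))
  empty <- density_windows(feats[0, ], c(chr_1 = 2e6))
  expect_true(all(empty$n == 0))
  expect_equal(nrow(empty), 2)
  expect_error(density_windows(dplyr::mutate(feats, start = 3e6),
                               c(chr_1 = 2e6)), "beyond")
  # floor-division oracle on random features
  set.seed(12)
  rf <- tibble::tibble(feature_id = sprintf("f%d", 1:300),
                       chrom = sample(c("chr_1", "chr_2"), 300, TRUE),
                       start = sample.int(3e6, 300) - 1L, kind = "region")
  rf$end <- rf$start + 100L
  rlens <- c(chr_1 = 3e6, chr_2 = 3e6)
  dw2 <- density_windows(rf, rlens)
  for (j in seq_len(nrow(dw2))) {
    expect_equal(dw2$n[j], sum(rf$chrom == dw2$chrom[j] &
                                 rf$start %/% 1e6 == dw2$window[j] - 1))
  }
})

test_that("QTL colocalization is 1-bp overlap, per trait, cross-chromosome safe", {
  qtls <- tibble::tibble(chrom = "chr_4", start = 25000000, end = 26000000,
                         trait = "CR")
  reg <- tibble::tibble(feature_id = "r1", chrom = "chr_4",
                        start = 25100000, end = 25200000)
  expect_equal(qtl_colocalization(reg, qtls)$n_features, 1)
  off <- dplyr::mutate(reg, chrom = "chr_1")
  expect_equal(qtl_colocalization(off, qtls)$n_features, 0)
  # brute-force oracle
  set.seed(9)
  feats <- random_intervals(80, c("chr_1", "chr_4"))
  feats$feature_id <- sprintf("f%d", 1:80)
  q <- random_intervals(6, c("chr_1", "chr_4"), max_len = 3000)
  q$trait <- sample(c("CR", "HR", "FD", "MD"), 6, TRUE)
  got <- qtl_colocalization(feats, q)
  hits <- naive_overlaps(feats, q)
  for (tr in unique(q$trait)) {
    want <- sum(apply(hits[, q$trait == tr, drop = FALSE], 1, any))
    expect_equal(got$n_features[got$trait == tr], want)
  }
})

test_that("TE genome fraction uses union semantics", {
  one <- tibble::tibble(chrom = "chr_1", start = 0, end = 50000)
  expect_equal(te_genome_fraction(one, c(chr_1 = 100000)), 0.5)
  dup <- dplyr::bind_rows(one, one)
  expect_equal(te_genome_fraction(dup, c(chr_1 = 100000)), 0.5)
  split2 <- tibble::tibble(chrom = "chr_1", start = c(0, 25000),
                           end = c(25000, 50000))
  expect_equal(te_genome_fraction(split2, c(chr_1 = 100000)), 0.5)
  # random merge-then-sum oracle via position flags
  set.seed(20)
  for (i in 1:20) {
    iv <- random_intervals(sample(3:25, 1), "chr_1", max_len = 500,
                           span = 5000)
    got <- te_genome_fraction(iv, c(chr_1 = 6000))
    covered <- logical(6000)
    for (j in seq_len(nrow(iv)))
      covered[(iv$start[j] + 1):iv$end[j]] <- TRUE
    expect_equal(got, sum(covered) / 6000)
  }
})

test_that("BED export writes published-style identifiers and round-trips", {
  feats <- tibble::tibble(
    feature_id = c("chr_4_31092165", "chr_3_9331371_9331488"),
    chrom = c("chr_4", "chr_3"),
    start = c(31092164, 9331370), end = c(31092165, 9331488))
  f <- withr::local_tempfile()
  write_bed(dplyr::mutate(feats, name = feature_id), f)
  lines <- readLines(f)
  expect_true("chr_4\t31092164\t31092165\tchr_4_31092165\t0\t." %in% lines)
  expect_true("chr_3\t9331370\t9331488\tchr_3_9331371_9331488\t0\t." %in% lines)
  back <- read_bed(f)
  f2 <- withr::local_tempfile()
  write_bed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
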