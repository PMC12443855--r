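test_that("stratified folds respect the study's class geometry", {
  labels <- rep(dormancy_stages, c(9, 36, 26))
  folds <- stratified_folds(labels, cv_scheme(3, n_repeats = 4, seed = 2))
  for (f in folds) {
    expect_setequal(unique(f), 1:3)
    tab <- table(f, labels)
    expect_true(all(tab[, "paradormancy"] == 3))   # 9 divides evenly
    expect_true(all(tab > 0))
  }
  # two-stage: 26/36 samples over 10 folds
  labels2 <- rep(c("ecodormancy", "endodormancy"), c(26, 36))
  f2 <- stratified_folds(labels2, cv_scheme(10, 2, seed = 3))[[1]]
  tab2 <- table(f2, labels2)
  expect_true(all(tab2[, "ecodormancy"] %in% 2:3))
  expect_true(all(tab2[, "endodormancy"] %in% 3:4))
})

test_that("folds partition and stratify for arbitrary label vectors", {
  set.seed(14)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    n_cl <- sample(2:4, 1)
    counts <- sample(k:(4 * k), n_cl, replace = TRUE)
    labels <- sample(rep(paste0("c", seq_len(n_cl)), counts))
    f <- stratified_folds(labels, cv_scheme(k, 1, seed = i))[[1]]
    expect_length(f, length(labels))
    expect_setequal(unique(f), seq_len(k))
    tab <- table(factor(f, levels = seq_len(k)), labels)
    expect_true(all(tab > 0))
    for (cl in colnames(tab))
      expect_lte(diff(range(tab[, cl])), 1)
  }
})

test_that("a class smaller than the fold count is named in the error", {
  expect_error(stratified_folds(rep(c("a", "b"), c(2, 9)), cv_scheme(3)),
               "'a' has 2")
})

test_that("confusion-matrix metrics handle clean and degenerate cases", {
  m <- metrics_from_confusion(matrix(c(5, 0, 0, 5), 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))))
  expect_equal(m$overall$accuracy, 1)
  expect_equal(m$overall$macro_f1, 1)
  # nothing predicted as class 1: precision falls back to 0 with a warning
  expect_warning(
    m2 <- metrics_from_confusion(matrix(c(0, 0, 5, 5), 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))),
    "precision undefined")
  expect_equal(m2$overall$accuracy, 0.5)
  expect_equal(m2$per_class$precision[1], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 3)), "square")
})

test_that("metrics equal a per-cell-loop oracle on random matrices", {
  set.seed(4)
  for (i in 1:500) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 4), k,
                 dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
    if (sum(cm) == 0) next
    m <- suppressWarnings(metrics_from_confusion(cm))
    tp <- numeric(k); fp <- numeric(k); fn <- numeric(k); correct <- 0
    for (a in 1:k) for (b in 1:k) {
      if (a == b) { tp[a] <- tp[a] + cm[a, b]; correct <- correct + cm[a, b] }
      else { fn[a] <- fn[a] + cm[a, b]; fp[b] <- fp[b] + cm[a, b] }
    }
    prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
    expect_equal(m$overall$accuracy, correct / sum(cm), tolerance = 1e-12)
    expect_equal(m$per_class$precision, prec, tolerance = 1e-12)
    expect_equal(m$per_class$recall, rec, tolerance = 1e-12)
    expect_equal(m$overall$macro_f1, mean(f1), tolerance = 1e-12)
  }
})

test_that("cross-validation is perfect on separable data", {
  # axis-aligned boundary with a wide margin: learnable out-of-fold
  set.seed(8)
  x <- cbind(f1 = c(runif(24, 0, 0.35), runif(24, 0.65, 1)),
             matrix(runif(48 * 4), 48, 4,
                    dimnames = list(NULL, paste0("f", 2:5))))
  rownames(x) <- sprintf("s%02d", 1:48)
  y <- ifelse(x[, "f1"] > 0.5, "endodormancy", "ecodormancy")
  mm <- dormclass:::new_methylation_matrix(
    x,
    tibble::tibble(feature_id = colnames(x), chrom = "chr_1",
                   start = 1:5, end = 2:6, kind = "cytosine",
                   n_cytosines = 1L),
    tibble::tibble(sample_id = rownames(x), cultivar = "cv1",
                   experiment = "E1", chilling_hours = 0, stage = y))
  r <- cross_validate(mm, "rf", cv_scheme(3, 2, seed = 5),
                      rf_config(n_trees = 100, seed = 1))
  expect_equal(mean(r$metrics$accuracy), 1)
  expect_equal(mean(r$auc$macro_auc), 1)
  # accuracy equals confusion trace over total, overall and per fold
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion), 1)
})

test_that("permuted labels score near the majority-class rate", {
  toy <- separable_toy(n = 40, p = 10, seed = 3)
  accs <- sapply(1:8, function(s) {
    set.seed(s)
    y <- sample(rep(c("endodormancy", "ecodormancy"), c(24, 16)))
    mm <- dormclass:::new_methylation_matrix(
      toy$x,
      tibble::tibble(feature_id = colnames(toy$x), chrom = "chr_1",
                     start = 1:10, end = 2:11, kind = "cytosine",
                     n_cytosines = 1L),
      tibble::tibble(sample_id = rownames(toy$x), cultivar = "cv1",
                     experiment = "E1", chilling_hours = 0, stage = y))
    r <- cross_validate(mm, "rf", cv_scheme(4, 1, seed = s),
                        rf_config(n_trees = 60, seed = s))
    mean(r$metrics$accuracy)
  })
  expect_lt(abs(mean(accs) - 0.6), 0.15)
})

test_that("the paired benefit test matches its closed form", {
  d <- c(0.1, 0.12, 0.09, 0.11)
  base <- rep(0.5, 4)
  out <- selection_benefit_test(base, base + d)
  t_manual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(out$t, t_manual)
  expect_equal(out$df, 3)
  # antisymmetry
  swapped <- selection_benefit_test(base + d, base)
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  # identical vectors: degenerate case, p = 1 by convention
  expect_warning(deg <- selection_benefit_test(base, base), "degenerate")
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  expect_error(selection_benefit_test(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("the benefit test refuses mismatched fold assignments", {
  toy <- separable_toy(n = 36, p = 4, seed = 2)
  mm <- dormclass:::new_methylation_matrix(
    toy$x,
    tibble::tibble(feature_id = colnames(toy$x), chrom = "chr_1",
                   start = 1:4, end = 2:5, kind = "cytosine",
                   n_cytosines = 1L),
    tibble::tibble(sample_id = rownames(toy$x), cultivar = "cv1",
                   experiment = "E1", chilling_hours = 0, stage = toy$y))
  r1 <- cross_validate(mm, "rf", cv_scheme(3, 1, seed = 1),
                       rf_config(n_trees = 30, seed = 1))
  r2 <- cross_validate(mm, "rf", cv_scheme(3, 1, seed = 2),
                       rf_config(n_trees = 30, seed = 1))
  expect_error(selection_benefit_test(r1, r2), "identical folds")
})

test_that("scenario evaluation produces one report per combination", {
  s <- small_sim()
  ret <- filter_cytosines(s$sim$reports, context = "all")
  mm <- build_matrix(s$sim$reports, ret, s$sim$meta, kind = "cytosine")
  rep3 <- run_scenario(list(cytosine = mm), "2stage",
                       models = c("rf", "xgb"),
                       scheme = cv_scheme(3, 1, seed = 4),
                       rf_config = rf_config(n_trees = 60, seed = 1),
                       xgb_config = toy_xgb(seed = 1))
  expect_named(rep3$reports, "cytosine")
  expect_named(rep3$reports$cytosine, c("rf", "xgb"))
  expect_equal(nrow(rep3$benefit), 2)
  # the 2-stage scenario drops paradormancy before anything else
  got_stages <- unique(rep3$reports$cytosine$rf$full$classes)
  expect_setequal(got_stages, c("endodormancy", "ecodormancy"))
  # identical folds underpin each paired comparison
  expect_identical(rep3$reports$cytosine$rf$full$folds,
                   rep3$reports$cytosine$rf$selected$folds)
})
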