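# Shared fixtures and independent brute-force oracles used across tests.

# small synthetic study, cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        seed = 42, n_cytosines = 600,
        chrom_lengths = setNames(rep(2e5L, 4), paste0("chr_", 1:4)),
        class_counts = c(paradormancy = 3L, endodormancy = 6L,
                         ecodormancy = 6L))
      ann <- simulate_genome_annotation(cfg)
      cache <<- list(cfg = cfg, ann = ann,
                     sim = simulate_methylomes(cfg, ann))
    }
    cache
  }
})

# a full-strength boosting config for small-p toys (the package defaults
# target p >> n matrices and are far too regularised for 6-column toys)
toy_xgb <- function(n_rounds = 20, max_depth = 3, seed = 1, ...) {
  xgb_config(n_rounds = n_rounds, max_depth = max_depth, seed = seed,
             learning_rate = 0.3, colsample_bytree = 1, reg_gamma = 0, ...)
}

# a small separable two-class matrix for model tests
separable_toy <- function(n = 40, p = 6, seed = 5) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- ifelse(x[, 1] + x[, 2] > 1, "endodormancy", "ecodormancy")
  list(x = x, y = y)
}

# brute-force interval overlap: >= 1 shared bp, 0-based half-open
naive_overlaps <- function(a, b) {
  hits <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      hits[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
  hits
}

random_intervals <- function(n, chroms = c("chr_1", "chr_2"), max_len = 1000,
                             span = 10000) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = s, end = s + sample.int(max_len, n, replace = TRUE))
}

expect_tibble_identical <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
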