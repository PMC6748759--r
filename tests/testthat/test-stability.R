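test_that("scaled ranks map to [0,1] with average ranks for ties", {
  expect_equal(scaled_rank(c(10, 30, 20)), c(0, 1, 0.5))
  expect_equal(scaled_rank(c(5, 5)), c(0.5, 0.5))
  expect_equal(scaled_rank(c(1, 2, 2, 4)), c(0, 0.5, 0.5, 1))
  expect_equal(scaled_rank(c(3, NA, 1)), c(1, NA, 0))
  expect_error(scaled_rank(c(NA_real_, NA_real_)), "missing")
})

test_that("index orientation: best-in-all-features gene scores 1, worst 0", {
  ft <- make_feature_table(lambda = c(0.01, 0.3, 0.5, 0.9),
                           sigma2 = c(0.1, 1, 2, 5),
                           omega_star = c(0.0, 0.1, 0.3, 0.6),
                           f_stat = c(0.5, 2, 7, 40))
  res <- stability_index(ft)
  expect_equal(unname(res$index[1]), 1)
  expect_equal(unname(res$index[4]), 0)
  expect_true(all(res$index >= 0 & res$index <= 1))
  expect_identical(res$features_used,
                   c("lambda", "sigma2", "omega_star", "f_stat"))
})

test_that("index equals an independent spreadsheet-style recomputation", {
  set.seed(53)
  ft <- make_feature_table(lambda = runif(10), sigma2 = rexp(10),
                           omega_star = runif(10), f_stat = rexp(10, 0.2))
  res <- stability_index(ft)
  expect_equal(unname(res$index), brute_index(ft))
})

test_that("mean index is 0.5 without ties and is permutation-equivariant", {
  set.seed(59)
  ft <- make_feature_table(lambda = sample(seq(0.01, 0.99, length.out = 25)),
                           sigma2 = sample(seq(0.1, 5, length.out = 25)),
                           omega_star = sample(seq(0, 0.9, length.out = 25)),
                           f_stat = sample(seq(0.2, 30, length.out = 25)))
  res <- stability_index(ft)
  expect_equal(mean(res$index), 0.5)

  perm <- sample(25)
  ftp <- ft[perm, ]
  class(ftp) <- class(ft)
  resp <- stability_index(ftp)
  expect_equal(unname(resp$index), unname(res$index[perm]))
})

test_that("index depends on features only through their ranks", {
  set.seed(61)
  ft <- make_feature_table(lambda = runif(15), sigma2 = rexp(15),
                           omega_star = runif(15), f_stat = rexp(15))
  res <- stability_index(ft)
  ft2 <- ft
  ft2$lambda <- exp(5 * ft2$lambda)        # strictly monotone transforms
  ft2$sigma2 <- ft2$sigma2^3 + 1
  ft2$f_stat <- log1p(ft2$f_stat)
  res2 <- stability_index(ft2)
  expect_equal(res2$index, res$index)
})

test_that("genes with a missing feature get a missing index; invalid fits too", {
  ft <- make_feature_table(lambda = c(0.1, 0.2, NA, 0.4),
                           sigma2 = c(1, 2, 3, 4),
                           omega_star = c(0, 0.1, 0.2, 0.3))
  ft$valid[3] <- FALSE
  res <- stability_index(ft)
  expect_true(is.na(res$index[3]))
  expect_false(anyNA(res$index[-3]))
  expect_error(stability_index(ft[c(3, 3), ]), "valid")
})

test_that("3-feature mode engages when no F-statistic column exists", {
  ft <- make_feature_table(lambda = c(0.1, 0.5, 0.9),
                           sigma2 = c(0.5, 1, 2),
                           omega_star = c(0, 0.2, 0.4))
  res <- stability_index(ft)
  expect_identical(res$features_used, c("lambda", "sigma2", "omega_star"))
  expect_equal(res$index, c(g01 = 1, g02 = 0.5, g03 = 0))
})

test_that("SEG selection equals exhaustive enumeration of the two-part rule", {
  set.seed(67)
  g <- 20
  ft <- make_feature_table(lambda = sample(seq(0.02, 0.98, length.out = g)),
                           sigma2 = sample(seq(0.2, 6, length.out = g)),
                           omega_star = sample(seq(0, 0.8, length.out = g)),
                           f_stat = sample(seq(0.1, 25, length.out = g)))
  res <- stability_index(ft)
  got <- suppressWarnings(select_segs(res, 80, 60))

  # independent enumeration
  pct <- function(v) 100 * (rank(v) - 1) / (g - 1)
  idx_ok <- pct(res$index) > 80
  feat_ok <- rep(TRUE, g)
  for (cl in c("lambda", "sigma2", "omega_star", "f_stat"))
    feat_ok <- feat_ok & (pct(-ft[[cl]]) > 60)
  expect_setequal(got, ft$gene_id[idx_ok & feat_ok])
})

test_that("the all-best gene is selected; one at the 75th percentile is not", {
  set.seed(71)
  g <- 100
  lam <- sort(runif(g, 0.1, 0.9)); lam[1] <- 0.001
  sg <- sort(rexp(g)) + 0.5; sg[1] <- 0.01
  os <- sort(runif(g, 0.05, 0.8)); os[1] <- 0
  fs <- sort(rexp(g, 0.1)) + 0.1; fs[1] <- 0.001
  ft <- make_feature_table(lambda = lam, sigma2 = sg, omega_star = os,
                           f_stat = fs)
  res <- stability_index(ft)
  expect_true(ft$gene_id[1] %in% suppressWarnings(select_segs(res)))

  idx_rank_pct <- 100 * (rank(res$index) - 1) / (g - 1)
  at75 <- which.min(abs(idx_rank_pct - 75))
  expect_false(ft$gene_id[at75] %in% suppressWarnings(select_segs(res)))
})

test_that("raising selection thresholds never adds genes", {
  set.seed(73)
  ft <- make_feature_table(lambda = runif(40), sigma2 = rexp(40),
                           omega_star = runif(40), f_stat = rexp(40))
  res <- stability_index(ft)
  loose <- suppressWarnings(select_segs(res, 60, 40))
  tight <- suppressWarnings(select_segs(res, 80, 60))
  tighter <- suppressWarnings(select_segs(res, 90, 80))
  expect_true(all(tight %in% loose))
  expect_true(all(tighter %in% tight))
})

test_that("empty selections warn instead of erroring", {
  # anti-correlated features: no gene can be extreme in both at once
  ft <- make_feature_table(lambda = c(0.1, 0.2, 0.3),
                           sigma2 = c(3, 2, 1), omega_star = c(0.2, 0.1, 0))
  res <- stability_index(ft)
  expect_warning(out <- select_segs(res, 50, 90), "no genes")
  expect_length(out, 0)
})

test_that("gene-list unions preserve first-seen order", {
  expect_identical(union_gene_lists(c("A", "B"), c("B", "C")),
                   c("A", "B", "C"))
  expect_identical(union_gene_lists(c("A", "B"), character(0)), c("A", "B"))
  expect_identical(union_gene_lists(c("A"), c("B"), c("C")),
                   c("A", "B", "C"))
  expect_identical(union_gene_lists(list(c("x", "y"), c("y", "z"))),
                   c("x", "y", "z"))
})

test_that("subsampling protocol validates inputs and is seed-reproducible", {
  sim <- simulate_seg_data(60, 200, 2, frac_stable = 0.5, seed = 79)
  expect_error(subsample_reproducibility(sim$matrix, fraction = 1.0),
               "strictly between")
  expect_error(subsample_reproducibility(sim$matrix, fraction = 0),
               "strictly between")
  expect_error(subsample_reproducibility(sim$matrix, reps = 1), "reps")

  r1 <- subsample_reproducibility(sim$matrix, fraction = 0.8, reps = 3,
                                  seed = 5)
  r2 <- subsample_reproducibility(sim$matrix, fraction = 0.8, reps = 3,
                                  seed = 5)
  expect_identical(r1$pairs$r, r2$pairs$r)
  expect_identical(r1$indices, r2$indices)
  expect_true(all(r1$pairs$r >= -1 & r1$pairs$r <= 1))
  expect_equal(nrow(r1$pairs), 3)
})

test_that("identical subsamples give perfectly correlated indices", {
  sim <- simulate_seg_data(50, 150, 2, frac_stable = 0.5, seed = 83)
  m <- sim$matrix
  sub <- segstab:::subset_seg_matrix(m, cells = 1:120)
  run_once <- function() {
    s <- log_transform(filter_genes_by_zeros(sub))
    stability_index(s)$index
  }
  expect_equal(cor(run_once(), run_once(), use = "complete.obs"), 1)
})

test_that("stability results serialize with ranks, index and SEG flags", {
  set.seed(89)
  ft <- make_feature_table(lambda = runif(12), sigma2 = rexp(12),
                           omega_star = runif(12), f_stat = rexp(12))
  res <- stability_index(ft)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stability(res, path, index_pct = 50, feature_pct = 20)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 12L)
  expect_true(all(c("gene_id", "rank_lambda", "index", "is_seg") %in%
                    names(tab)))
  expect_identical(sum(tab$is_seg),
                   length(suppressWarnings(select_segs(res, 50, 20))))
})
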