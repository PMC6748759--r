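test_that("pair counts match enumeration on the worked examples", {
  pc <- pair_counts(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unlist(pc[c("a", "b", "c", "d")]),
               c(a = 2, b = 0, c = 0, d = 4))
  pc2 <- pair_counts(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(unlist(pc2[c("a", "b", "c", "d")]),
               c(a = 0, b = 2, c = 2, d = 2))
  pc1 <- pair_counts(1, 1)
  expect_equal(unlist(pc1[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 0, d = 0))
  expect_error(pair_counts(c(1, 2), c(1, 2, 3)), "different numbers")
})

test_that("contingency fast path equals brute-force pair enumeration", {
  set.seed(97)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    truth <- random_partition(n, sample(2:6, 1))
    clus <- random_partition(n, sample(2:6, 1))
    pc <- pair_counts(truth, clus)
    bf <- brute_pair_counts(truth, clus)
    expect_identical(unlist(pc[c("a", "b", "c", "d")], use.names = FALSE),
                     as.numeric(unlist(bf)))
    expect_equal(pc$a + pc$b + pc$c + pc$d, choose(n, 2))
  }
})

test_that("ARI, Jaccard and FM evaluate their printed formulas exactly", {
  mk <- function(a, b, c, d) structure(list(a = a, b = b, c = c, d = d,
                                            n_cells = NA),
                                       class = "seg_pair_counts")
  expect_equal(ari(mk(2, 0, 0, 4)), 1)
  expect_equal(ari(mk(0, 2, 2, 2)), -0.5)
  expect_equal(jaccard_index(mk(2, 0, 0, 4)), 1)
  expect_equal(jaccard_index(mk(0, 2, 2, 2)), 0)
  expect_equal(jaccard_index(mk(1, 1, 1, 3)), 1 / 3)
  expect_equal(fowlkes_mallows(mk(2, 0, 0, 4)), 1)
  expect_equal(fowlkes_mallows(mk(0, 2, 2, 2)), 0)
  expect_equal(fowlkes_mallows(mk(1, 1, 1, 3)), 0.5)
  # degenerate denominators
  expect_equal(ari(mk(3, 0, 0, 0)), 1)
  expect_equal(jaccard_index(mk(0, 0, 0, 6)), 0)
  expect_equal(fowlkes_mallows(mk(0, 0, 0, 6)), 0)
})

test_that("purity scores cluster-wise best-class overlap", {
  expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(purity(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.5)
  expect_equal(purity(c(1, 1, 1, 2), c(1, 1, 1, 1)), 0.75)
})

test_that("all four metrics are label-renaming invariant and 1 iff identical", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(10:80, 1)
    truth <- random_partition(n, 4)
    clus <- random_partition(n, 4)
    score <- function(tr, cl)
      c(ari(pair_counts(tr, cl)), jaccard_index(pair_counts(tr, cl)),
        fowlkes_mallows(pair_counts(tr, cl)), purity(tr, cl))
    renamed_truth <- letters[truth]
    renamed_clus <- 10 - clus
    expect_equal(score(renamed_truth, renamed_clus), score(truth, clus))
    # identical up to relabeling -> all four equal 1
    expect_equal(score(truth, letters[truth]), rep(1, 4))
  }
})

test_that("purity never decreases when a cluster is split", {
  set.seed(107)
  for (i in 1:10) {
    truth <- random_partition(40, 3)
    clus <- random_partition(40, 3)
    p0 <- purity(truth, clus)
    split <- clus
    members <- which(clus == 1)
    if (length(members) >= 2) {
      split[sample(members, floor(length(members) / 2))] <- 99
      expect_gte(purity(truth, split), p0 - 1e-12)
    }
  }
})

test_that("marker genes recover classes while stable genes do not", {
  # well-separated regime: markers are cleanly expressed (little gamma
  # mass or dropout) with large class shifts
  sim <- simulate_seg_data(80, 240, 3, frac_stable = 0.5, seed = 109,
                           config = sim_control(shift_sd = 3,
                                                variable_lambda = c(0.02, 0.1),
                                                variable_dropout = c(0.02, 0.1),
                                                variable_sigma = c(0.4, 0.8),
                                                variable_mu = c(6, 9)))
  m <- log_transform(sim$matrix)
  truth <- sim$truth
  stable <- truth$gene_id[truth$stable_flag]
  shifts <- as.matrix(truth[, grep("^shift_", names(truth))])
  spread <- apply(shifts, 1, function(s) max(s) - min(s))
  markers <- truth$gene_id[order(-spread)][1:20]

  ev_mark <- evaluate_gene_list(m, markers, sim$annotation, reps = 5,
                                seed = 11)
  ev_stab <- evaluate_gene_list(m, stable[1:20], sim$annotation, reps = 5,
                                seed = 11)
  expect_gte(ev_mark$mean["ari"], 0.9)
  expect_lte(ev_stab$mean["ari"], 0.2)
  expect_true(all(ev_mark$runs$purity >= ev_stab$mean["purity"] - 0.05))
})

test_that("evaluation handles reps = 1, absent genes and determinism", {
  sim <- simulate_seg_data(40, 120, 2, frac_stable = 0.5, seed = 113)
  m <- log_transform(sim$matrix)
  genes <- sim$truth$gene_id[1:10]
  ev1 <- evaluate_gene_list(m, genes, sim$annotation, reps = 1, seed = 3)
  expect_equal(unname(ev1$sd), rep(0, 4))
  expect_equal(nrow(ev1$runs), 1)

  expect_error(evaluate_gene_list(m, c("nope1", "nope2"), sim$annotation,
                                  list_name = "ghost list"),
               "ghost list")

  ev_a <- evaluate_gene_list(m, genes, sim$annotation, reps = 3, seed = 7)
  ev_b <- evaluate_gene_list(m, genes, sim$annotation, reps = 3, seed = 7)
  expect_identical(ev_a$runs, ev_b$runs)
})

test_that("size-matched subsets are reproducible draws without replacement", {
  genes <- sprintf("g%d", 1:30)
  subs <- size_matched_subset(genes, 10, reps = 5, seed = 5)
  expect_length(subs, 5)
  for (s in subs) {
    expect_length(s, 10)
    expect_false(anyDuplicated(s) > 0)
    expect_true(all(s %in% genes))
  }
  expect_identical(subs, size_matched_subset(genes, 10, reps = 5, seed = 5))

  full <- size_matched_subset(genes, 30, reps = 2, seed = 1)
  expect_identical(full[[1]], genes)
  expect_identical(full[[2]], genes)

  expect_error(size_matched_subset(genes, 31), "exceeds")

  pairs3 <- size_matched_subset(c("a", "b", "c"), 2, reps = 20, seed = 2)
  expect_true(all(vapply(pairs3, function(p)
    paste(p, collapse = "") %in% c("ab", "ac", "bc"), logical(1))))
})
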