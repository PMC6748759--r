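#' Pair-classification counts between two partitions
#'
#' Classifies all `N(N-1)/2` unordered cell pairs by whether they share a
#' class in the reference partition and a cluster in the candidate
#' partition: `a` = same class & same cluster, `b` = different class & same
#' cluster, `c` = same class & different cluster, `d` = different class &
#' different cluster. Computed via the contingency table (exactly equal to
#' pair enumeration).
#'
#' @param truth Reference labels (vector or factor), one per cell.
#' @param clustering Candidate labels, same cells in the same order.
#' @return A list of class `"seg_pair_counts"` with `a`, `b`, `c`, `d` and
#'   `n_cells`.
#' @export
#' @examples
#' pair_counts(c(1, 1, 2, 2), c(1, 2, 1, 2))  # a=0, b=2, c=2, d=2
pair_counts <- function(truth, clustering) {
  if (length(truth) != length(clustering))
    stop("partitions cover different numbers of cells (", length(truth),
         " vs ", length(clustering), ")")
  n <- length(truth)
  tab <- table(truth, clustering)
  a <- sum(choose(tab, 2))
  same_cluster <- sum(choose(colSums(tab), 2))
  same_class <- sum(choose(rowSums(tab), 2))
  b <- same_cluster - a
  c_ <- same_class - a
  d <- choose(n, 2) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d, n_cells = n),
            class = "seg_pair_counts")
}

#' @export
print.seg_pair_counts <- function(x, ...) {
  cat(sprintf("Pair counts over %d cells: a=%g b=%g c=%g d=%g\n",
              x$n_cells, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Adjusted Rand index from pair counts
#'
#' `ARI = 2(ad - bc) / [(a+b)(b+d) + (a+c)(c+d)]`. When the denominator is
#' zero the value is 1 if `b = c = 0` (partitions agree perfectly) and 0
#' otherwise.
#'
#' @param pc A [pair_counts()] result.
#' @return Numeric scalar, at most 1.
#' @export
ari <- function(pc) {
  stopifnot(inherits(pc, "seg_pair_counts"))
  denom <- (pc$a + pc$b) * (pc$b + pc$d) + (pc$a + pc$c) * (pc$c + pc$d)
  if (denom == 0) return(if (pc$b == 0 && pc$c == 0) 1 else 0)
  2 * (pc$a * pc$d - pc$b * pc$c) / denom
}

#' Jaccard index from pair counts
#'
#' `a / (a + b + c)`; 0 when `a + b + c = 0` (no co-assigned pairs at all).
#'
#' @inheritParams ari
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_index <- function(pc) {
  stopifnot(inherits(pc, "seg_pair_counts"))
  s <- pc$a + pc$b + pc$c
  if (s == 0) return(0)
  pc$a / s
}

#' Fowlkes-Mallows index from pair counts
#'
#' `sqrt([a/(a+b)] [a/(a+c)])`; 0 in the degenerate cases `a + b = 0` or
#' `a + c = 0`.
#'
#' @inheritParams ari
#' @return Numeric scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(pc) {
  stopifnot(inherits(pc, "seg_pair_counts"))
  if (pc$a + pc$b == 0 || pc$a + pc$c == 0) return(0)
  sqrt((pc$a / (pc$a + pc$b)) * (pc$a / (pc$a + pc$c)))
}

#' Purity of a clustering against reference classes
#'
#' For each cluster, the size of its best-matching reference class; summed
#' over clusters and divided by the number of cells.
#'
#' @inheritParams pair_counts
#' @return Numeric scalar in `(0, 1]`.
#' @export
purity <- function(truth, clustering) {
  if (length(truth) != length(clustering))
    stop("partitions cover different numbers of cells")
  tab <- table(clustering, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

score_partition <- function(truth, clustering) {
  pc <- pair_counts(truth, clustering)
  c(ari = ari(pc), purity = purity(truth, clustering),
    fm = fowlkes_mallows(pc), jaccard = jaccard_index(pc))
}

#' Evaluate the expression stability of a gene list by clustering
#'
#' Restricts the matrix to the list's genes, runs k-means over cells with
#' as many clusters as there are predefined classes, and scores each run
#' against the predefined labels with ARI, Purity, Fowlkes-Mallows and
#' Jaccard. Because k-means is stochastic the procedure is repeated and
#' summarized as mean and sd per metric. In this framework LOW concordance
#' is the desired outcome for a stable list: genes that carry no cell-type
#' signal cannot reconstruct the classes.
#'
#' @param m A log-transformed `seg_matrix`.
#' @param genes Character vector of gene identifiers (the list to
#'   evaluate); at least 2 must be present in the matrix.
#' @param truth A [cell_annotation()] (or factor aligned to the cells).
#' @param reps Number of k-means repetitions. Default 10.
#' @param seed Master seed; per-repetition sub-seeds derive from it.
#' @param nstart Random restarts within each k-means run (best inertia
#'   kept). Default 10.
#' @param list_name Name used in error messages.
#' @return Object of class `"seg_concordance"`: data frame `runs` (one row
#'   per repetition with the four metrics), matrices `mean` and `sd`, and
#'   the gene count used.
#' @export
evaluate_gene_list <- function(m, genes, truth, reps = 10, seed = 1,
                               nstart = 10, list_name = "gene list") {
  stopifnot(inherits(m, "seg_matrix"))
  if (!is_log_transformed(m))
    stop("matrix must be log-transformed before clustering")
  present <- intersect(genes, gene_ids(m))
  if (length(present) == 0)
    stop("none of the genes in '", list_name, "' are present in the matrix")
  if (length(present) < 2)
    stop("'", list_name, "' has fewer than 2 genes present in the matrix")
  fac <- if (inherits(truth, "seg_annotation")) align_annotation(m, truth)
         else {
           if (length(truth) != ncol(m))
             stop("truth labels length does not match the number of cells")
           droplevels(as.factor(truth))
         }
  k <- nlevels(fac)
  if (k < 2) stop("need at least 2 predefined classes")
  sub <- t(unclass(m)[present, , drop = FALSE])  # cells x genes
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  runs <- matrix(NA_real_, reps, 4,
                 dimnames = list(NULL, c("ari", "purity", "fm", "jaccard")))
  for (r in seq_len(reps)) {
    set.seed(run_seeds[r])
    km <- stats::kmeans(sub, centers = k, nstart = nstart, iter.max = 50)
    runs[r, ] <- score_partition(fac, km$cluster)
  }
  runs_df <- data.frame(rep = seq_len(reps), runs)
  structure(list(runs = runs_df,
                 mean = colMeans(runs),
                 sd = if (reps > 1) apply(runs, 2, stats::sd) else
                   stats::setNames(rep(0, 4), colnames(runs)),
                 n_genes = length(present), k = k, reps = reps,
                 list_name = list_name),
            class = "seg_concordance")
}

#' @export
print.seg_concordance <- function(x, ...) {
  cat("Clustering concordance for '", x$list_name, "' (", x$n_genes,
      " genes, k = ", x$k, ", ", x$reps, " runs)\n", sep = "")
  cat("  values x100, mean ± sd; lower = more stable list\n")
  for (metric in names(x$mean))
    cat(sprintf("  %-8s %5.1f ± %.1f\n", toupper(metric),
                100 * x$mean[metric], 100 * x$sd[metric]))
  invisible(x)
}

#' Size-matched random subsets of a gene list
#'
#' Draws `reps` uniform random subsets of `target_size` genes without
#' replacement, reproducibly from `seed`. Used to control for gene-list
#' length when comparing the clustering concordance of lists of different
#' sizes.
#'
#' @param genes Character vector to subsample.
#' @param target_size Subset size, at most `length(genes)`.
#' @param reps Number of subsets. Default 10.
#' @param seed Integer seed.
#' @return List of `reps` character vectors (original order preserved
#'   within each subset).
#' @export
size_matched_subset <- function(genes, target_size, reps = 10, seed = 1) {
  if (target_size > length(genes))
    stop("target_size (", target_size, ") exceeds the list length (",
         length(genes), ")")
  if (target_size < 1) stop("target_size must be positive")
  set.seed(seed)
  lapply(seq_len(reps), function(i)
    genes[sort(sample.int(length(genes), target_size))])
}
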