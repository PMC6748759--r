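#' Scaled ranks in [0, 1]
#'
#' Ranks a vector in increasing order (average ranks for ties) and rescales
#' to `[0, 1]` by `(rank - 1) / (n_valid - 1)`. Missing entries are excluded
#' from the ranking and returned as `NA`. `Inf` is allowed and ranks last.
#'
#' @param v Numeric vector, at least 2 non-missing entries.
#' @return Numeric vector of the same length with values in `[0, 1]`.
#' @export
#' @examples
#' scaled_rank(c(10, 30, 20))  # 0, 1, 0.5
#' scaled_rank(c(5, 5))        # ties -> 0.5, 0.5
scaled_rank <- function(v) {
  ok <- !is.na(v)
  nv <- sum(ok)
  if (nv == 0) stop("all values missing")
  if (nv < 2) stop("need at least 2 non-missing values to rank")
  out <- rep(NA_real_, length(v))
  out[ok] <- (rank(v[ok], ties.method = "average") - 1) / (nv - 1)
  out
}

seg_feature_cols <- c(lambda = "lambda", sigma2 = "sigma2",
                      omega_star = "omega_star", f_stat = "f_stat")

#' Fit the per-gene expression stability index
#'
#' The central estimator of the package. Each stability feature — the
#' mixture's Gamma mass `lambda`, the Gaussian variance `sigma2`, the
#' regularized zero proportion `omega_star`, and (when cell classes are
#' known) the ANOVA `f_stat` — is ranked across genes in increasing order
#' and the ranks rescaled to `[0, 1]`; a gene's stability index is the mean
#' of `1 - scaled rank` over the features used, so the index lies in
#' `[0, 1]` with larger values indicating more stable expression. Genes
#' with any missing used feature receive a missing index.
#'
#' The method for `seg_matrix` runs [compute_features()] first; the method
#' for `seg_features` aggregates an existing feature table. When no labels
#' are available the index averages the 3 label-free features.
#'
#' @param x A `seg_features` table or a log-transformed `seg_matrix`.
#' @param ... Passed on between methods.
#' @return An object of class `"seg_stability"`: list with `gene_ids`,
#'   `scaled_ranks` (genes x features matrix), `index`, `features_used`,
#'   and the `features` table.
#' @export
#' @examples
#' ft <- data.frame(gene_id = c("a", "b", "c"),
#'                  lambda = c(0.1, 0.5, 0.9), sigma2 = c(1, 2, 3),
#'                  mu = 5:7, omega = c(0, .1, .2),
#'                  omega_star = c(0, .05, .2), valid = TRUE)
#' class(ft) <- c("seg_features", "data.frame")
#' stability_index(ft)$index
stability_index <- function(x, ...) UseMethod("stability_index")

#' @rdname stability_index
#' @param labels Optional [cell_annotation()] for the F-statistic feature.
#' @param control An [em_control()].
#' @export
stability_index.seg_matrix <- function(x, labels = NULL,
                                       control = em_control(), ...) {
  stability_index(compute_features(x, labels = labels, control = control))
}

#' @rdname stability_index
#' @export
stability_index.seg_features <- function(x, ...) {
  feats <- seg_feature_cols[seg_feature_cols %in% names(x)]
  if (!"f_stat" %in% names(x)) feats <- setdiff(feats, "f_stat")
  valid <- x$valid & !is.na(x$lambda)
  if (sum(valid) < 2)
    stop("need at least 2 genes with a valid mixture fit")
  g <- nrow(x)
  sr <- matrix(NA_real_, g, length(feats),
               dimnames = list(x$gene_id, feats))
  for (f in feats) {
    col <- x[[f]]
    col[!valid] <- NA
    sr[, f] <- scaled_rank(col)
  }
  index <- rowMeans(1 - sr)
  structure(list(gene_ids = x$gene_id, scaled_ranks = sr, index = index,
                 features_used = unname(feats), features = x),
            class = "seg_stability")
}

#' @export
print.seg_stability <- function(x, ...) {
  cat("Gene expression stability index\n")
  cat("  ", length(x$gene_ids), " genes; features used: ",
      paste(x$features_used, collapse = ", "), "\n", sep = "")
  ok <- !is.na(x$index)
  cat(sprintf("  index: %d valid genes, mean %.3f, range [%.3f, %.3f]\n",
              sum(ok), mean(x$index[ok]), min(x$index[ok]),
              max(x$index[ok])))
  invisible(x)
}

#' @export
summary.seg_stability <- function(object, ...) {
  ok <- !is.na(object$index)
  cat("Stability index over", length(object$gene_ids), "genes (",
      sum(!ok), "invalid )\n")
  print(summary(object$index[ok]))
  cat("\nTop 10 most stable genes:\n")
  top <- order(object$index, decreasing = TRUE)[1:min(10, sum(ok))]
  print(data.frame(gene_id = object$gene_ids[top],
                   index = round(object$index[top], 4)))
  invisible(object)
}

#' @export
coef.seg_stability <- function(object, ...) {
  stats::setNames(object$index, object$gene_ids)
}

#' @export
as.data.frame.seg_stability <- function(x, ...) {
  out <- data.frame(gene_id = x$gene_ids,
                    as.data.frame(x$scaled_ranks, row.names = NULL),
                    index = x$index, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[seq_along(x$features_used) + 1] <-
    paste0("rank_", x$features_used)
  out
}

#' @export
plot.seg_stability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$index, breaks = 30, main = "Stability index",
                 xlab = "index (1 = most stable)", col = "grey80")
  if (!is.null(x$features$omega)) {
    graphics::plot(x$features$mu, x$features$omega,
                   xlab = "Gaussian mean (log2)", ylab = "zero fraction",
                   main = "Dropout vs expression", pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.5))
  }
  invisible(x)
}

#' Select stably expressed genes by percentile thresholds
#'
#' A gene is a SEG when its stability-index rank percentile strictly
#' exceeds `index_pct` (genes ranked by increasing index, so a high index
#' gives a high percentile) and, for every feature used, its reversed rank
#' percentile strictly exceeds `feature_pct` (features ranked decreasingly,
#' so a small feature value gives a high percentile). Percentiles are
#' `100 * (rank - 1) / (G - 1)` with average ranks for ties.
#'
#' @param res A `seg_stability` object.
#' @param index_pct Index rank percentile threshold, default 80.
#' @param feature_pct Per-feature reversed rank percentile threshold,
#'   default 60.
#' @return Character vector of selected gene identifiers (possibly empty,
#'   with a warning).
#' @export
select_segs <- function(res, index_pct = 80, feature_pct = 60) {
  stopifnot(inherits(res, "seg_stability"))
  ok <- !is.na(res$index)
  gv <- sum(ok)
  if (gv < 2) stop("fewer than 2 genes with a valid index")
  idx_pct <- rep(NA_real_, length(res$index))
  idx_pct[ok] <- 100 * (rank(res$index[ok], ties.method = "average") - 1) /
    (gv - 1)
  keep <- !is.na(idx_pct) & idx_pct > index_pct
  ## reversed feature percentile: small value -> high percentile.
  ## scaled ranks are increasing, so 100 * (1 - scaled rank) is exactly the
  ## decreasing-order rank percentile (average ties commute).
  for (f in res$features_used) {
    fp <- 100 * (1 - res$scaled_ranks[, f])
    keep <- keep & !is.na(fp) & fp > feature_pct
  }
  sel <- res$gene_ids[keep]
  if (length(sel) == 0)
    warning("no genes pass the SEG selection thresholds (index_pct = ",
            index_pct, ", feature_pct = ", feature_pct, ")")
  sel
}

#' Union of gene lists preserving first-seen order
#'
#' Used, e.g., to merge the SEG lists identified from two datasets of the
#' same organism into a single list.
#'
#' @param ... Two or more character vectors (or a single list of them).
#' @return Character vector: the set union, first occurrence order.
#' @export
union_gene_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  unique(unlist(lists, use.names = FALSE))
}

#' Subsampling reproducibility of the stability index
#'
#' Repeatedly samples a fraction of cells without replacement, re-runs the
#' full pipeline (zero filter, features, index) on each subsample, and
#' reports the Pearson correlation of the index vectors over the gene
#' intersection of every pair of replicates. High correlations mean the
#' gene ranking is a property of the data, not of the particular cells
#' profiled.
#'
#' @param m A raw-scale `seg_matrix` (it is filtered and log-transformed
#'   inside each replicate; a pre-log matrix is also accepted and then used
#'   as is).
#' @param labels Optional [cell_annotation()]; when given, the F-statistic
#'   participates in each replicate's index.
#' @param fraction Fraction of cells per subsample, in (0, 1). Default 0.8.
#' @param reps Number of subsamples, >= 2. Default 10.
#' @param seed Integer seed controlling all subsampling.
#' @param max_zero_fraction Gene filter threshold applied inside each
#'   replicate. Default 0.8.
#' @param control An [em_control()].
#' @return Object of class `"seg_reproducibility"`: data frame `pairs`
#'   (`rep_i`, `rep_j`, `r`, `n_genes`), plus `mean_r`, `sd_r`.
#' @export
subsample_reproducibility <- function(m, labels = NULL, fraction = 0.8,
                                      reps = 10, seed = 1,
                                      max_zero_fraction = 0.8,
                                      control = em_control()) {
  stopifnot(inherits(m, "seg_matrix"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (reps < 2) stop("reps must be >= 2")
  n <- ncol(m)
  size <- floor(fraction * n)
  if (size < 2) stop("subsample would contain fewer than 2 cells")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  indices <- vector("list", reps)
  results <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    cells <- sort(sample.int(n, size))
    indices[[r]] <- cells
    sub <- subset_seg_matrix(m, cells = cells)
    sub <- filter_genes_by_zeros(sub, max_zero_fraction)
    if (!is_log_transformed(sub)) sub <- log_transform(sub)
    res <- stability_index(sub, labels = labels, control = control)
    results[[r]] <- stats::setNames(res$index, res$gene_ids)
  }
  pairs <- utils::combn(reps, 2)
  out <- data.frame(rep_i = pairs[1, ], rep_j = pairs[2, ],
                    r = NA_real_, n_genes = NA_integer_)
  for (k in seq_len(ncol(pairs))) {
    a <- results[[pairs[1, k]]]
    b <- results[[pairs[2, k]]]
    common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
    if (length(common) < 10)
      stop("gene intersection between replicates ", pairs[1, k], " and ",
           pairs[2, k], " has fewer than 10 genes")
    out$r[k] <- stats::cor(a[common], b[common])
    out$n_genes[k] <- length(common)
  }
  structure(list(pairs = out, mean_r = mean(out$r),
                 sd_r = stats::sd(out$r), fraction = fraction, reps = reps,
                 seed = seed, indices = indices),
            class = "seg_reproducibility")
}

#' @export
print.seg_reproducibility <- function(x, ...) {
  cat("Stability-index subsampling reproducibility\n")
  cat(sprintf("  %d replicates at %.0f%% of cells: mean pairwise r = %.4f (sd %.4f)\n",
              x$reps, 100 * x$fraction, x$mean_r, x$sd_r))
  invisible(x)
}

#' Write a stability result as TSV
#'
#' One row per gene: scaled feature ranks, index and SEG membership under
#' the given thresholds.
#'
#' @param res A `seg_stability` object.
#' @param path Output path.
#' @param index_pct,feature_pct Selection thresholds for the `is_seg`
#'   column (see [select_segs()]).
#' @return `path`, invisibly.
#' @export
write_stability <- function(res, path, index_pct = 80, feature_pct = 60) {
  df <- as.data.frame(res)
  segs <- suppressWarnings(select_segs(res, index_pct, feature_pct))
  df$is_seg <- df$gene_id %in% segs
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
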