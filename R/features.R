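#' Per-gene zero fraction
#'
#' Fraction of cells in which a gene's quantification is exactly zero
#' (dropout, stochastic expression, or true absence).
#'
#' @param m A `seg_matrix`.
#' @return Named numeric vector `omega` in `[0, 1]`, one entry per gene.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 2, 0, 5), 1, 4), "g1",
#'                        paste0("c", 1:4))
#' compute_zero_fraction(m)
compute_zero_fraction <- function(m) {
  stopifnot(inherits(m, "seg_matrix"))
  if (nrow(m) == 0 || ncol(m) == 0) stop("matrix is empty")
  rowMeans(unclass(m) == 0)
}

#' Min-max scale a vector to [0, 1]
#'
#' `(v - min v) / (max v - min v)`; a constant vector maps to all zeros
#' (convention). Missing values are carried through; non-finite values are
#' an error.
#'
#' @param v Numeric vector, length >= 1.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_scale <- function(v) {
  if (length(v) < 1) stop("empty input")
  ok <- !is.na(v)
  if (any(!is.finite(v[ok]))) stop("non-finite values in input")
  if (!any(ok)) stop("all values missing")
  rng <- range(v[ok])
  out <- rep(NA_real_, length(v))
  out[ok] <- if (rng[1] == rng[2]) 0 else (v[ok] - rng[1]) / diff(rng)
  out
}

#' Regularized zero proportion
#'
#' Down-weights the zero fraction of lowly expressed genes:
#' \eqn{\omega^* = \omega \cdot \mathrm{minmax}(\mu)}, where \eqn{\mu} is
#' the fitted Gaussian mean and minmax scaling is across genes. Because
#' dropout preferentially produces zeros in genes with low expression, the
#' raw zero fraction \eqn{\omega} overstates the instability of such genes;
#' multiplying by the scaled mean corrects that bias.
#'
#' @param omega Per-gene zero fractions in `[0, 1]`.
#' @param mu Per-gene Gaussian means (may contain `NA` for genes whose
#'   mixture fit failed; those genes get `NA`).
#' @return Numeric vector `omega_star`, elementwise
#'   `omega * minmax_scale(mu)`.
#' @export
regularize_zero_proportion <- function(omega, mu) {
  if (length(omega) != length(mu))
    stop("omega and mu lengths differ (", length(omega), " vs ",
         length(mu), ")")
  if (any(omega < 0 | omega > 1, na.rm = TRUE))
    stop("omega must lie in [0, 1]")
  omega * minmax_scale(mu)
}

#' One-way ANOVA F-statistic for a gene across cell classes
#'
#' Between-class mean square over within-class mean square, computed on the
#' log-transformed values of all cells (zeros included: class-specific
#' dropout is genuine instability). Degenerate cases follow fixed
#' conventions: no variation at all gives 0 (maximally stable by this
#' feature); zero within-class variance with non-zero between-class
#' variance gives `Inf` (ranked most unstable).
#'
#' @param values Numeric vector of one gene's expression over cells.
#' @param labels Factor (or coercible) of class labels, same length.
#'   Classes with fewer than 2 cells are dropped.
#' @return The F-statistic (possibly `Inf`), or `NA` if fewer than 2 usable
#'   classes remain.
#' @export
f_statistic <- function(values, labels) {
  labels <- as.factor(labels)
  if (length(values) != length(labels))
    stop("values and labels lengths differ")
  keep <- labels %in% names(which(table(labels) >= 2))
  values <- values[keep]
  labels <- droplevels(labels[keep])
  k <- nlevels(labels)
  n <- length(values)
  if (k < 2 || n <= k) return(NA_real_)
  gm <- mean(values)
  means <- tapply(values, labels, mean)
  sizes <- tabulate(labels)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[as.integer(labels)])^2)
  if (ssw <= 0) {
    if (ssb <= 0) return(0)
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Compute per-gene stability features
#'
#' For each gene of a log-transformed, zero-filtered matrix, fits the
#' Gamma-Gaussian mixture to the gene's strictly positive values and
#' extracts the mixing proportion `lambda` and the Gaussian `mu` and
#' `sigma2`; computes the zero fraction `omega` over all cells, the
#' regularized zero proportion `omega_star` across the genes with a valid
#' fit, and (when `labels` are supplied) the one-way ANOVA `f_stat` across
#' predefined cell classes. Genes with too few positive values or a failed
#' fit are flagged `valid = FALSE` and carry `NA` features; they never
#' abort the table.
#'
#' @param m A log-transformed `seg_matrix` (see [log_transform()] and
#'   [filter_genes_by_zeros()]).
#' @param labels Optional [cell_annotation()] (or factor aligned to the
#'   cells) enabling the F-statistic feature.
#' @param control An [em_control()].
#' @return A data frame of class `"seg_features"` with columns `gene_id`,
#'   `lambda`, `sigma2`, `mu`, `omega`, `omega_star`, `valid`, and `f_stat`
#'   when labels were given.
#' @export
compute_features <- function(m, labels = NULL, control = em_control()) {
  stopifnot(inherits(m, "seg_matrix"))
  if (!is_log_transformed(m))
    stop("matrix must be log-transformed first (see log_transform())")
  v <- unclass(m)
  g <- nrow(v)
  lambda <- sigma2 <- mu <- rep(NA_real_, g)
  valid <- logical(g)
  for (i in seq_len(g)) {
    pos <- v[i, ]
    pos <- pos[pos > 0]
    fit <- tryCatch(fit_gamma_gaussian(pos, control), error = function(e) NULL)
    if (!is.null(fit)) {
      lambda[i] <- fit$lambda
      mu[i] <- fit$mu
      sigma2[i] <- fit$sigma2
      valid[i] <- TRUE
    }
  }
  omega <- compute_zero_fraction(m)
  omega_star <- rep(NA_real_, g)
  if (any(valid))
    omega_star[valid] <- regularize_zero_proportion(omega[valid], mu[valid])
  out <- data.frame(gene_id = gene_ids(m), lambda = lambda, sigma2 = sigma2,
                    mu = mu, omega = omega, omega_star = omega_star,
                    valid = valid, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(labels)) {
    fac <- if (inherits(labels, "seg_annotation")) align_annotation(m, labels)
           else {
             if (length(labels) != ncol(m))
               stop("labels length does not match the number of cells")
             droplevels(as.factor(labels))
           }
    out$f_stat <- apply(v, 1, f_statistic, labels = fac)
  }
  attr(out, "n_cells") <- ncol(m)
  class(out) <- c("seg_features", "data.frame")
  out
}

#' Write / read a feature table as TSV
#'
#' @param ft A `seg_features` data frame.
#' @param path Output path.
#' @return `path` (write) / the table (read), invisibly for write.
#' @export
write_features <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("seg_features", "data.frame")
  out
}
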