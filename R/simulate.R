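#' Control parameters for the synthetic-data generator
#'
#' Ranges from which per-gene ground-truth parameters are drawn. Stable
#' genes have a small Gamma mass, high Gaussian mean, tight variance, low
#' dropout and zero class shifts; variable genes span a wider, noisier
#' regime with class-specific mean shifts on the expressed component.
#' Units are log2 expression throughout.
#'
#' @param stable_lambda,variable_lambda Ranges for the Gamma mixing
#'   proportion (stable genes must stay at or below 0.2).
#' @param stable_mu,variable_mu Ranges for the Gaussian mean.
#' @param stable_sigma,variable_sigma Ranges for the Gaussian sd.
#' @param stable_dropout,variable_dropout Ranges for the per-gene baseline
#'   dropout probability.
#' @param gamma_shape,gamma_rate Ranges for the low-end Gamma component.
#' @param shift_sd Sd of the per-class additive mean shifts of variable
#'   genes (log2 units).
#' @param dropout_mid,dropout_scale Midpoint and scale of the logistic
#'   coupling of dropout to the mean: dropout = base *
#'   plogis(-(mu - mid)/scale), so lowly expressed genes drop out more.
#' @return A list of class `"sim_control"`.
#' @export
sim_control <- function(stable_lambda = c(0.01, 0.15),
                        variable_lambda = c(0.20, 0.60),
                        stable_mu = c(6, 10), variable_mu = c(2, 8),
                        stable_sigma = c(0.4, 0.9),
                        variable_sigma = c(0.8, 2.0),
                        stable_dropout = c(0.05, 0.20),
                        variable_dropout = c(0.20, 0.60),
                        gamma_shape = c(1.5, 3), gamma_rate = c(1.5, 3),
                        shift_sd = 1.5, dropout_mid = 6,
                        dropout_scale = 1.5) {
  if (stable_lambda[2] > 0.2)
    stop("stable genes must have lambda_true <= 0.2")
  structure(list(stable_lambda = stable_lambda,
                 variable_lambda = variable_lambda,
                 stable_mu = stable_mu, variable_mu = variable_mu,
                 stable_sigma = stable_sigma,
                 variable_sigma = variable_sigma,
                 stable_dropout = stable_dropout,
                 variable_dropout = variable_dropout,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 shift_sd = shift_sd, dropout_mid = dropout_mid,
                 dropout_scale = dropout_scale),
            class = "sim_control")
}

## Realized dropout probability of a gene: baseline modulated by a logistic
## decrease in the Gaussian mean (low expression -> more dropout).
dropout_probability <- function(dropout_base, mu, config) {
  dropout_base * stats::plogis(-(mu - config$dropout_mid) /
                                 config$dropout_scale)
}

#' Generate a synthetic expression matrix with known per-gene truth
#'
#' Each gene's log2 expression follows the two-component generative model:
#' with the gene's dropout probability a cell reports 0; otherwise the
#' log-value is drawn from a Gamma (low/"off") component with probability
#' `lambda_true`, or from a Gaussian expressed component whose mean is
#' shifted per cell class for variable genes. Values are back-transformed
#' to the raw scale by `2^v - 1` so that `log2(x + 1)` recovers the drawn
#' value exactly. The dropout probability decreases logistically with the
#' gene's Gaussian mean, emulating the empirical coupling of zero fraction
#' to expression level; negative Gaussian draws (rare, low-mean genes) are
#' clamped to 0 and so appear as additional zeros.
#'
#' @param n_genes,n_cells,n_classes Dimensions of the dataset (all
#'   positive). Defaults: 1000 genes, 1000 cells, 4 classes.
#' @param frac_stable Fraction of genes that are stable (no class shifts,
#'   `lambda_true <= 0.2`); `ceiling(frac_stable * n_genes)` genes.
#'   Default 0.2.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param config A [sim_control()].
#' @return Object of class `"seg_simulation"`: `matrix` (raw-scale
#'   `seg_matrix`), `annotation` ([cell_annotation()]), and `truth` (data
#'   frame with one row per gene: `gene_id`, `stable_flag`, `lambda_true`,
#'   `alpha_true`, `beta_true`, `mu_true`, `sigma_true`, `dropout_base`,
#'   `dropout_prob`, and `shift_<class>` columns).
#' @export
#' @examples
#' sim <- simulate_seg_data(50, 100, 2, 0.5, seed = 7)
#' sim$matrix
simulate_seg_data <- function(n_genes = 1000, n_cells = 1000, n_classes = 4,
                              frac_stable = 0.2, seed = 1,
                              config = sim_control()) {
  if (n_genes < 1 || n_cells < 1 || n_classes < 1)
    stop("n_genes, n_cells and n_classes must be positive")
  if (frac_stable < 0 || frac_stable > 1)
    stop("frac_stable must lie in [0, 1]")
  stopifnot(inherits(config, "sim_control"))
  set.seed(seed)
  n_stable <- ceiling(frac_stable * n_genes)
  stable <- seq_len(n_genes) <= n_stable
  runif_range <- function(n, r) stats::runif(n, r[1], r[2])
  lambda <- ifelse(stable,
                   runif_range(n_genes, config$stable_lambda),
                   runif_range(n_genes, config$variable_lambda))
  mu <- ifelse(stable,
               runif_range(n_genes, config$stable_mu),
               runif_range(n_genes, config$variable_mu))
  sigma <- ifelse(stable,
                  runif_range(n_genes, config$stable_sigma),
                  runif_range(n_genes, config$variable_sigma))
  dropout_base <- ifelse(stable,
                         runif_range(n_genes, config$stable_dropout),
                         runif_range(n_genes, config$variable_dropout))
  alpha <- runif_range(n_genes, config$gamma_shape)
  beta <- runif_range(n_genes, config$gamma_rate)
  shifts <- matrix(0, n_genes, n_classes)
  if (any(!stable) && n_classes > 1)
    shifts[!stable, ] <- stats::rnorm(sum(!stable) * n_classes, 0,
                                      config$shift_sd)
  dropout <- dropout_probability(dropout_base, mu, config)
  classes <- sample.int(n_classes, n_cells, replace = TRUE)
  vals <- matrix(0, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    keep <- stats::runif(n_cells) >= dropout[g]
    nk <- sum(keep)
    if (nk == 0) next
    from_gamma <- stats::runif(nk) < lambda[g]
    v <- numeric(nk)
    v[from_gamma] <- stats::rgamma(sum(from_gamma), alpha[g], beta[g])
    ng <- sum(!from_gamma)
    if (ng > 0)
      v[!from_gamma] <- stats::rnorm(ng,
                                     mu[g] + shifts[g, classes[keep][!from_gamma]],
                                     sigma[g])
    v <- pmax(v, 0)
    vals[g, keep] <- 2^v - 1
  }
  gids <- sprintf("gene%04d", seq_len(n_genes))
  cids <- sprintf("cell%04d", seq_len(n_cells))
  truth <- data.frame(gene_id = gids, stable_flag = stable,
                      lambda_true = lambda, alpha_true = alpha,
                      beta_true = beta, mu_true = mu, sigma_true = sigma,
                      dropout_base = dropout_base, dropout_prob = dropout,
                      stringsAsFactors = FALSE)
  shift_df <- as.data.frame(shifts)
  names(shift_df) <- sprintf("shift_class%d", seq_len(n_classes))
  truth <- cbind(truth, shift_df)
  structure(list(matrix = expression_matrix(vals, gids, cids, units = "CPM",
                                            log_transformed = FALSE),
                 annotation = cell_annotation(cids,
                                              sprintf("class%d", classes)),
                 truth = truth, seed = seed, config = config),
            class = "seg_simulation")
}

#' @export
print.seg_simulation <- function(x, ...) {
  cat("Synthetic single-cell dataset (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$matrix), " genes x ", ncol(x$matrix), " cells, ",
      nlevels(x$annotation$class_label), " classes; ",
      sum(x$truth$stable_flag), " stable genes\n", sep = "")
  invisible(x)
}

#' Export / import the ground-truth table of a simulation
#'
#' @param ds A `seg_simulation`.
#' @return The truth data frame (one row per gene).
#' @export
truth_table <- function(ds) {
  stopifnot(inherits(ds, "seg_simulation"))
  if (nrow(ds$truth) == 0) stop("empty simulation: no truth records")
  ds$truth
}

#' @rdname truth_table
#' @param truth A truth data frame.
#' @param path TSV path.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  for (j in seq_along(out))   # 17 significant digits: doubles round-trip
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
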