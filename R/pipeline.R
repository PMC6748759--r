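#' Configuration for an end-to-end stability run
#'
#' @param matrix_path Expression matrix file (dense TSV/CSV or MTX).
#' @param format `"dense"` or `"mtx"`.
#' @param gene_file,cell_file MTX identifier sidecars.
#' @param labels_path Optional cell-annotation TSV enabling the
#'   F-statistic.
#' @param out_dir Output directory (created if absent).
#' @param max_zero_fraction Gene filter threshold. Default 0.8.
#' @param index_pct,feature_pct SEG selection thresholds. Defaults 80, 60.
#' @param reps Repetitions for the optional evaluation step. Default 10.
#' @param seed Master seed recorded in every output header. Default 1.
#' @param evaluate Logical; run the clustering concordance evaluation of
#'   the selected SEG list (requires labels). Default `FALSE`.
#' @param control An [em_control()].
#' @return A list of class `"seg_config"`.
#' @export
seg_config <- function(matrix_path, format = c("dense", "mtx"),
                       gene_file = NULL, cell_file = NULL,
                       labels_path = NULL, out_dir = "segstab_out",
                       max_zero_fraction = 0.8, index_pct = 80,
                       feature_pct = 60, reps = 10, seed = 1,
                       evaluate = FALSE, control = em_control()) {
  format <- match.arg(format)
  stopifnot(max_zero_fraction >= 0, max_zero_fraction <= 1,
            index_pct >= 0, index_pct <= 100,
            feature_pct >= 0, feature_pct <= 100, reps >= 1)
  structure(list(matrix_path = matrix_path, format = format,
                 gene_file = gene_file, cell_file = cell_file,
                 labels_path = labels_path, out_dir = out_dir,
                 max_zero_fraction = max_zero_fraction,
                 index_pct = index_pct, feature_pct = feature_pct,
                 reps = reps, seed = as.integer(seed), evaluate = evaluate,
                 control = control),
            class = "seg_config")
}

#' Read a flat key=value run-configuration file
#'
#' One `key = value` pair per line, keys as in [seg_config()]; `#` starts a
#' comment. Values given as arguments override file values.
#'
#' @param path Configuration file.
#' @param ... Overrides passed to [seg_config()].
#' @return A `seg_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) p[2]),
                          vapply(kv, function(p) p[1], ""))
  num <- c("max_zero_fraction", "index_pct", "feature_pct", "reps", "seed")
  for (k in intersect(num, names(vals))) vals[[k]] <- as.numeric(vals[[k]])
  if ("evaluate" %in% names(vals))
    vals$evaluate <- tolower(vals$evaluate) %in% c("true", "1", "yes")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(seg_config, vals)
}

#' Run the full stability pipeline
#'
#' Reads (or takes) an expression matrix, applies the zero filter and the
#' log2(x + 1) transform, computes stability features and the stability
#' index, selects SEGs by the percentile rule, optionally evaluates the
#' selected list by clustering concordance, and writes all result tables
#' plus a run log to `cfg$out_dir`. Every stochastic step consumes a seed
#' derived from `cfg$seed`, so identical configurations give identical
#' outputs.
#'
#' @param cfg A [seg_config()].
#' @param matrix Optional in-memory `seg_matrix` (raw scale), bypassing
#'   `cfg$matrix_path`.
#' @param labels Optional in-memory [cell_annotation()], bypassing
#'   `cfg$labels_path`.
#' @return Invisibly, a list with the `seg_stability` object, the selected
#'   `segs`, the optional `evaluation`, and the output file `paths`.
#' @export
run_pipeline <- function(cfg, matrix = NULL, labels = NULL) {
  stopifnot(inherits(cfg, "seg_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[segstab] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("run seed: %d", cfg$seed)
  m <- stage("read", {
    if (!is.null(matrix)) matrix
    else read_expression(cfg$matrix_path, cfg$format,
                         gene_file = cfg$gene_file,
                         cell_file = cfg$cell_file)
  })
  say("input: %d genes x %d cells", nrow(m), ncol(m))
  ann <- stage("labels", {
    if (!is.null(labels)) labels
    else if (!is.null(cfg$labels_path)) read_cell_annotation(cfg$labels_path)
    else NULL
  })
  if (is.null(ann) && cfg$evaluate)
    stop("pipeline stage 'labels' failed: evaluation requested but no ",
         "cell labels were provided", call. = FALSE)
  m <- stage("filter", filter_genes_by_zeros(m, cfg$max_zero_fraction))
  say("after >%.0f%%-zeros filter: %d genes", 100 * cfg$max_zero_fraction,
      nrow(m))
  m <- stage("log_transform",
             if (is_log_transformed(m)) m else log_transform(m))
  res <- stage("stability_index",
               stability_index(m, labels = ann, control = cfg$control))
  say("features used: %s", paste(res$features_used, collapse = ", "))
  if (is.null(ann)) say("no labels: running in 3-feature mode (no F-statistic)")
  segs <- stage("select_segs",
                suppressWarnings(select_segs(res, cfg$index_pct,
                                             cfg$feature_pct)))
  say("selected %d SEGs (index_pct > %g, feature_pct > %g)",
      length(segs), cfg$index_pct, cfg$feature_pct)
  evaluation <- NULL
  if (cfg$evaluate && length(segs) >= 2)
    evaluation <- stage("evaluate",
                        evaluate_gene_list(m, segs, ann, reps = cfg$reps,
                                           seed = cfg$seed,
                                           list_name = "selected SEGs"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(features = file.path(cfg$out_dir, "features.tsv"),
                stability = file.path(cfg$out_dir, "stability.tsv"),
                segs = file.path(cfg$out_dir, "segs.txt"),
                log = file.path(cfg$out_dir, "run_log.txt"))
  if (!is.null(evaluation))
    paths$evaluation <- file.path(cfg$out_dir, "evaluation.tsv")
  stage("write", {
    write_features(res$features, paths$features)
    write_stability(res, paths$stability, cfg$index_pct, cfg$feature_pct)
    write_gene_list(segs, paths$segs)
    if (!is.null(evaluation)) {
      ev <- rbind(evaluation$runs,
                  data.frame(rep = NA, t(evaluation$mean)))
      utils::write.table(ev, paths$evaluation, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "mean")
    }
  })
  writeLines(c(sprintf("segstab %s",
                       as.character(utils::packageVersion("segstab"))),
               sprintf("R %s", getRversion()), log_lines), paths$log)
  say("outputs written to %s", cfg$out_dir)
  invisible(list(stability = res, segs = segs, evaluation = evaluation,
                 paths = paths))
}
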