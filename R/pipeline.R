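# stage seed offsets: derived from the global seed by a fixed counter so
# adding a stage never perturbs earlier stages' randomness
.stage_seeds <- function(seed)
  list(synth = seed, impute = seed + 1L, cv = seed + 2L, tune = seed + 3L,
       gsea = seed + 4L)

.known_keys <- list(
  top = c("matrix", "metadata", "gmt", "expression", "out_dir", "seed",
          "dialect", "preprocess", "model", "tuning", "cv", "contrasts",
          "quadrant", "gsea"),
  preprocess = c("drop_threshold", "low_threshold", "k", "width", "shift"),
  model = c("ncomp", "keepX"),
  tuning = c("keepX_grid", "ncomp_max"),
  cv = c("folds", "repeats", "distance"),
  contrast = c("name", "type", "a", "b", "test", "correction"),
  quadrant = c("x", "y", "fc_threshold", "sig_threshold"),
  gsea = c("nperm", "min_size", "max_size", "exponent", "metric", "filter",
           "filter_on"))

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an in-memory list; fills defaults,
#' resolves relative paths against the config file location, and rejects
#' contradictions (unknown keys, both a fixed model and a tuning grid,
#' missing inputs).
#'
#' @param config Path to a YAML or JSON config file, or a list.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    base_dir <- dirname(normalizePath(config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or file path",
                             call. = FALSE)
  .check_keys(config, .known_keys$top, "top level")
  if (is.null(config$matrix) || is.null(config$metadata))
    stop("config needs 'matrix' and 'metadata' inputs", call. = FALSE)
  if (!is.null(config$model) && !is.null(config$tuning))
    stop("set either 'model' (fixed ncomp/keepX) or 'tuning' (grid), not both",
         call. = FALSE)
  resolve <- function(p) {
    if (is.null(p) || inherits(p, "intensity_matrix") || is.data.frame(p) ||
        is.list(p) || file.exists(p)) return(p)
    file.path(base_dir, p)
  }
  for (key in c("matrix", "metadata", "gmt", "expression"))
    config[[key]] <- resolve(config[[key]])
  for (key in c("matrix", "metadata", "gmt", "expression")) {
    v <- config[[key]]
    if (is.character(v) && !file.exists(v))
      stop("input file not found: ", v, call. = FALSE)
  }
  .check_keys(config$preprocess, .known_keys$preprocess, "preprocess")
  .check_keys(config$model, .known_keys$model, "model")
  .check_keys(config$tuning, .known_keys$tuning, "tuning")
  .check_keys(config$cv, .known_keys$cv, "cv")
  .check_keys(config$quadrant, .known_keys$quadrant, "quadrant")
  .check_keys(config$gsea, .known_keys$gsea, "gsea")
  if (!is.null(config$contrasts))
    for (i in seq_along(config$contrasts))
      .check_keys(config$contrasts[[i]], .known_keys$contrast,
                  sprintf("contrasts[%d]", i))
  defaults <- list(seed = 1L, dialect = "generic_wide", out_dir = NULL,
                   preprocess = list(), cv = list(), gsea = list())
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  cvd <- list(folds = 5L, repeats = 10L, distance = "max_dist")
  for (nm in names(cvd))
    if (is.null(config$cv[[nm]])) config$cv[[nm]] <- cvd[[nm]]
  if (is.null(config$model) && is.null(config$tuning))
    config$tuning <- list()
  if (!is.null(config$tuning)) {
    if (is.null(config$tuning$keepX_grid))
      config$tuning$keepX_grid <- c(5L, 10L, 20L, 50L)
    if (is.null(config$tuning$ncomp_max)) config$tuning$ncomp_max <- 2L
  }
  gd <- list(nperm = 1000L, min_size = 10L, max_size = 500L, exponent = 1,
             metric = "signed_logp", filter = NULL, filter_on = "q")
  for (nm in names(gd))
    if (is.null(config$gsea[[nm]])) config$gsea[[nm]] <- gd[[nm]]
  structure(config, class = c("pipeline_config", "list"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (missingness-stratified imputation) ->
#' keepX/ncomp tuning (unless a fixed model is configured) -> sPLS-DA fit ->
#' repeated cross-validation -> differential tables per configured contrast
#' -> GSEA per contrast (if a gene-set collection is configured, else
#' recorded as skipped) -> dual-contrast quadrant analysis (if configured).
#' A single global seed determines every stochastic stage through fixed
#' per-stage offsets, so two runs with the same config are identical. When
#' `out_dir` is set, every stage table is written as TSV and the run report
#' as JSON.
#'
#' @param config A [validate_config()]-acceptable config: list or file path.
#'   Inputs may be file paths or in-memory objects (`intensity_matrix`,
#'   metadata data.frame, `gene_set_collection`).
#' @return A list of class `pipeline_result`: `report` (per-stage counts,
#'   tuning choice, CV metrics, differential and enrichment summaries, wall
#'   time), plus the stage objects (`preprocessed`, `tuning`, `model`, `cv`,
#'   `differential`, `enrichment`, `quadrants`, `heatmap`).
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  config <- validate_config(config)
  seeds <- .stage_seeds(as.integer(config$seed))

  im <- if (inherits(config$matrix, "intensity_matrix")) config$matrix
        else read_intensity_table(config$matrix, config$dialect)
  meta <- if (is.data.frame(config$metadata))
    align_metadata(config$metadata, im)
  else read_sample_metadata(config$metadata, im)
  groups <- meta$group
  tb <- table(groups)
  if (length(tb) < 2L || any(tb < 2L))
    stop("pipeline: need >= 2 groups with >= 2 samples each", call. = FALSE)
  gmt <- if (is.null(config$gmt)) NULL
         else if (inherits(config$gmt, "gene_set_collection")) config$gmt
         else read_gmt(config$gmt)

  pp_args <- config$preprocess
  pp_args$seed <- seeds$impute
  pc <- do.call(preprocess_config, pp_args)
  pp <- preprocess(im, pc)
  xmat <- t(pp$matrix$values)   # samples x proteins for the model

  tuning <- NULL
  if (!is.null(config$tuning)) {
    grid <- pmin(config$tuning$keepX_grid, ncol(xmat))
    tuning <- tune_splsda(xmat, groups, keepX_grid = grid,
                          ncomp_max = config$tuning$ncomp_max,
                          folds = config$cv$folds,
                          repeats = config$cv$repeats,
                          distance = config$cv$distance, seed = seeds$tune)
    ncomp <- tuning$ncomp
    keepX <- tuning$keepX
  } else {
    ncomp <- config$model$ncomp
    keepX <- config$model$keepX
  }
  model <- splsda(xmat, groups, ncomp = ncomp, keepX = keepX)
  cv <- cv_splsda(xmat, groups, ncomp = ncomp, keepX = keepX,
                  folds = config$cv$folds, repeats = config$cv$repeats,
                  distance = config$cv$distance, seed = seeds$cv)

  contrasts <- config$contrasts
  if (is.null(contrasts))
    contrasts <- list(list(type = "multi_group"))
  diff_tables <- list()
  for (cs in contrasts) {
    spec <- contrast_spec(cs$type, a = cs$a, b = cs$b, name = cs$name)
    test <- if (is.null(cs$test)) "anova" else cs$test
    corr <- if (is.null(cs$correction)) "bh" else cs$correction
    diff_tables[[spec$name]] <-
      differential_table(pp$matrix, groups, spec, test = test,
                         correction = corr)
  }

  enr <- list()
  gsea_status <- if (is.null(gmt)) "skipped (no gene sets configured)" else "run"
  if (!is.null(gmt)) {
    for (nm in names(diff_tables)) {
      tab <- diff_tables[[nm]]
      if (all(is.na(tab$log2_fc))) next  # multi-group: no signed metric
      rl <- ranked_list(tab, metric = config$gsea$metric,
                        filter = config$gsea$filter,
                        filter_on = config$gsea$filter_on)
      enr[[nm]] <- gsea(rl, gmt, nperm = config$gsea$nperm,
                        min_size = config$gsea$min_size,
                        max_size = config$gsea$max_size,
                        exponent = config$gsea$exponent, seed = seeds$gsea)
    }
  }

  quad <- NULL
  if (!is.null(config$quadrant)) {
    qx <- diff_tables[[config$quadrant$x]]
    qy <- diff_tables[[config$quadrant$y]]
    if (is.null(qx) || is.null(qy))
      stop("quadrant stage: contrasts '", config$quadrant$x, "'/'",
           config$quadrant$y, "' not found", call. = FALSE)
    fct <- if (is.null(config$quadrant$fc_threshold)) 1
           else config$quadrant$fc_threshold
    sct <- if (is.null(config$quadrant$sig_threshold)) 0.05
           else config$quadrant$sig_threshold
    quad <- dual_contrast(qx, qy, fc_threshold = fct, sig_threshold = sct)
  }
  heat <- scaled_group_heatmap(
    pp$matrix$values[selected_proteins(model), , drop = FALSE], groups)

  report <- list(
    package_version = as.character(utils::packageVersion("proteodisc")),
    seed = as.integer(config$seed),
    stage_seeds = seeds,
    n_samples = ncol(im$values),
    groups = as.list(tb),
    preprocess = pp$report[c("n_proteins_in", "n_dropped_missingness",
                             "n_dropped_zero_variance", "n_retained",
                             "strata_counts", "n_cells_imputed_knn",
                             "n_cells_imputed_downshift")],
    tuning = if (is.null(tuning)) "skipped (fixed model configured)"
             else list(ncomp = tuning$ncomp, keepX = tuning$keepX,
                       best_ber = tuning$best_ber),
    model = list(ncomp = ncomp, keepX = keepX,
                 n_selected = length(selected_proteins(model)),
                 explained_variance = as.list(model$explained_variance)),
    cv = list(error_rate = as.list(cv$error_rate), ber = as.list(cv$ber),
              auroc_mean = as.list(cv$auroc$mean),
              auroc_sd = as.list(cv$auroc$sd)),
    differential = lapply(diff_tables, function(tb)
      list(n_proteins = nrow(tb), n_significant = sum(tb$significant))),
    enrichment = if (is.null(gmt)) gsea_status else
      lapply(enr, function(e) list(n_sets = nrow(e),
                                   n_significant = sum(e$p_adjusted <= 0.05))),
    quadrants = if (is.null(quad)) "skipped (not configured)" else
      as.list(table(quad$quadrant)),
    wall_time_s = NA_real_)

  out <- structure(list(report = report, preprocessed = pp, tuning = tuning,
                        model = model, cv = cv, differential = diff_tables,
                        enrichment = enr, quadrants = quad, heatmap = heat),
                   class = "pipeline_result")
  out$report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  out
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  write_intensity_table(result$preprocessed$matrix,
                        file.path(od, "imputed_matrix.tsv"))
  if (!is.null(result$tuning))
    .write_tsv(result$tuning$grid, file.path(od, "tuning_curve.tsv"))
  ld <- data.frame(protein = rownames(result$model$loadings),
                   result$model$loadings, check.names = FALSE)
  .write_tsv(ld, file.path(od, "splsda_loadings.tsv"))
  sc <- data.frame(sample = rownames(result$model$scores),
                   group = as.character(result$model$y),
                   result$model$scores, check.names = FALSE)
  .write_tsv(sc, file.path(od, "splsda_scores.tsv"))
  for (nm in names(result$differential))
    .write_tsv(result$differential[[nm]],
               file.path(od, paste0("differential_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
  for (nm in names(result$enrichment))
    .write_tsv(result$enrichment[[nm]],
               file.path(od, paste0("gsea_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
  if (!is.null(result$quadrants))
    .write_tsv(result$quadrants, file.path(od, "quadrants.tsv"))
  hm <- data.frame(protein = rownames(result$heatmap$values),
                   result$heatmap$values, check.names = FALSE)
  .write_tsv(hm, file.path(od, "heatmap_scaled_means.tsv"))
  if (!is.null(result$heatmap$row_tree))
    jsonlite::write_json(
      list(row = result$heatmap$row_tree[c("order", "labels", "merge", "height")],
           column = if (is.null(result$heatmap$col_tree)) NULL
                    else result$heatmap$col_tree[c("order", "labels", "merge", "height")]),
      file.path(od, "heatmap_dendrograms.json"), auto_unbox = TRUE, digits = NA)
  rep_out <- result$report
  jsonlite::write_json(rep_out, file.path(od, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(od)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline_result\n")
  cat(sprintf("  samples: %d in %d group(s)\n", r$n_samples,
              length(r$groups)))
  cat(sprintf("  proteins retained: %d of %d\n", r$preprocess$n_retained,
              r$preprocess$n_proteins_in))
  cat(sprintf("  model: ncomp = %d, keepX = (%s), %d protein(s) selected\n",
              r$model$ncomp, paste(r$model$keepX, collapse = ", "),
              r$model$n_selected))
  cat(sprintf("  CV BER: %.3f +/- %.3f\n", r$cv$ber$mean, r$cv$ber$sd))
  invisible(x)
}
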