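#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the full analysis.
#' Defaults follow the conventional settings for this analysis: minimum
#' category size 10, 1000 permutation iterations, 95% confidence
#' intervals, and a flagging rule of 4 null standard deviations. The
#' configuration round-trips losslessly through its YAML file form
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param expression path to the paired expression table.
#' @param annotation path to the annotation file.
#' @param annotation_format `"gaf"` or `"two_column"`.
#' @param condition primary condition label to analyse.
#' @param compare_condition optional second condition label for the
#'   cross-condition comparison.
#' @param covariates optional path to a per-gene covariate table.
#' @param out_dir output directory for report tables and the manifest.
#' @param min_category_size minimum complete pairs per category
#'   (default 10).
#' @param n_iterations permutation iterations (default 1000).
#' @param seed global integer seed; per-stage substreams are derived
#'   from it so stages are independently reproducible.
#' @param ci_level confidence level (default 0.95).
#' @param flag_sd_k null standard deviations above the null mean for
#'   flagging predictive categories (default 4).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, annotation,
                            annotation_format = c("gaf", "two_column"),
                            condition, compare_condition = NULL,
                            covariates = NULL, out_dir = "gopredict_out",
                            min_category_size = 10L, n_iterations = 1000L,
                            seed = 1L, ci_level = 0.95, flag_sd_k = 4) {
  annotation_format <- match.arg(annotation_format)
  stopifnot(min_category_size >= 2L, n_iterations >= 1L,
            ci_level > 0, ci_level < 1, flag_sd_k >= 0)
  structure(list(
    expression = expression, annotation = annotation,
    annotation_format = annotation_format, condition = condition,
    compare_condition = compare_condition, covariates = covariates,
    out_dir = out_dir, min_category_size = as.integer(min_category_size),
    n_iterations = as.integer(n_iterations), seed = as.integer(seed),
    ci_level = ci_level, flag_sd_k = flag_sd_k
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x[vapply(x, is.null, logical(1))] <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Orchestrates every stage on real input files: read and validate,
#' assemble categories and fit per-category OLS, remove duplicate
#' categories, summarize per aspect with cross-aspect comparisons and
#' cumulative curves, build the size-matched permutation null per aspect
#' (observed-vs-null test, size correlation, predictive-category
#' flagging), screen covariates and fit the stability regression when a
#' covariate table is supplied, and compare conditions when a second
#' condition is configured. All report tables are written tab-delimited
#' to `config$out_dir` together with a JSON manifest recording the seed,
#' the configuration (and its file checksum), package version, and row
#' counts at every filtering step.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every intermediate object
#'   (`expression`, `annotation`, `categories`, `regressions` (deduped),
#'   `regressions_raw`, `overall`, `summaries`, `aspect_comparisons`,
#'   `curves`, `nulls`, `null_tests`, `flagged`, `covariate_screen`,
#'   `stability`, `comparison`, `manifest`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "gopredict",
                   version = as.character(utils::packageVersion("gopredict")),
                   seed = config$seed, counts = list(), files = list())

  expr <- read_expression(config$expression)
  annot <- read_annotations(config$annotation, config$annotation_format,
                            expression = expr)
  covariates <- if (!is.null(config$covariates)) {
    read_covariates(config$covariates)
  }
  manifest$counts$genes <- nrow(expr)
  manifest$counts$terms_annotated <- nrow(annot$terms)

  run_condition <- function(condition) {
    cats <- assemble_categories(expr, annot, condition,
                                min_size = config$min_category_size)
    reg_raw <- category_regressions(expr, cats, condition,
                                    ci_level = config$ci_level)
    reg <- deduplicate_categories(reg_raw, cats)
    list(categories = cats, raw = reg_raw, deduped = reg)
  }

  primary <- run_condition(config$condition)
  reg <- primary$deduped
  overall <- overall_regression(expr, config$condition,
                                ci_level = config$ci_level)
  manifest$counts$categories_min_size <- nrow(primary$raw)
  manifest$counts$categories_after_dedup <- nrow(reg)
  manifest$counts$duplicates_removed <-
    nrow(attr(reg, "removal_report"))
  per_aspect <- split(reg, reg$aspect)

  summaries <- do.call(rbind, lapply(names(per_aspect), function(a) {
    summarize_aspect(per_aspect[[a]]$r2, aspect = a)
  }))
  cmp_ready <- Filter(function(df) nrow(df) >= 2L, per_aspect)
  aspect_cmp <- if (length(cmp_ready) >= 2L) {
    compare_aspects(lapply(cmp_ready, `[[`, "r2"))
  }
  curves <- lapply(per_aspect, function(df) cumulative_curve(df$r2))

  nulls <- list()
  null_tests <- list()
  flagged <- list()
  for (a in names(per_aspect)) {
    sizes <- per_aspect[[a]]$n
    nl <- build_null(expr, sizes, condition = config$condition,
                     n_iterations = config$n_iterations,
                     seed = stage_seed(config$seed, paste0("null_", a)),
                     aspect = a)
    nulls[[a]] <- nl
    null_tests[[a]] <- data.frame(
      aspect = a,
      null_mean = nl$summary[["mean"]], null_sd = nl$summary[["sd"]],
      null_median = nl$summary[["median"]],
      null_skewness = sample_skewness(nl$draws$r2),
      mw_u = compare_observed_to_null(per_aspect[[a]]$r2, nl)$U,
      mw_p = compare_observed_to_null(per_aspect[[a]]$r2, nl)$p,
      size_rho = null_size_correlation(nl)$rho,
      size_rho_p = null_size_correlation(nl)$p,
      stringsAsFactors = FALSE)
    fl <- flag_predictive_categories(per_aspect[[a]], nl, k = config$flag_sd_k)
    fl$threshold <- rep(attr(fl, "threshold"), nrow(fl))
    flagged[[a]] <- fl
  }
  null_tests <- do.call(rbind, c(null_tests, list(make.row.names = FALSE)))
  flagged <- do.call(rbind, c(flagged, list(make.row.names = FALSE)))

  # covariate screens: size and abundance always run, the stability rates
  # only when a covariate table is supplied
  stability <- list()
  screen_rows <- list()
  gene_vals <- abundance_covariates(expr, config$condition)
  if (!is.null(covariates)) {
    gene_vals <- merge(gene_vals, as.data.frame(covariates),
                       by = "gene_id", all.x = TRUE)
  }
  cov_means <- category_covariate_means(primary$categories, gene_vals,
                                        min_size = config$min_category_size)
  for (a in names(per_aspect)) {
    df <- per_aspect[[a]]
    screen_rows[[paste0(a, ".size")]] <- screen_covariate(
      df$r2, df$n, sizes = df$n, covariate_name = "category_size",
      aspect = a)
    for (cv in unique(cov_means$covariate)) {
      cm <- cov_means[cov_means$covariate == cv, , drop = FALSE]
      m <- cm$mean[match(df$term_id, cm$term_id)]
      screen_rows[[paste0(a, ".", cv)]] <- screen_covariate(
        df$r2, m, sizes = NULL, covariate_name = cv, aspect = a)
    }
    if (!is.null(covariates) &&
        all(c("transcription_rate", "translation_rate", "mrna_half_life",
              "protein_half_life") %in% unique(cov_means$covariate))) {
      r2v <- stats::setNames(df$r2, df$term_id)
      stability[[a]] <- tryCatch(
        fit_stability_regression(
          r2v, cov_means[cov_means$term_id %in% df$term_id, , drop = FALSE],
          aspect = a),
        error = function(e) {
          message("stability regression skipped for ", a, ": ",
                  conditionMessage(e))
          NULL
        })
    }
  }
  screen <- format_covariate_screen(
    do.call(rbind, c(screen_rows, list(make.row.names = FALSE))))

  comparison <- NULL
  if (!is.null(config$compare_condition)) {
    secondary <- run_condition(config$compare_condition)
    comparison <- compare_conditions(reg, secondary$deduped,
                                     label_a = config$condition,
                                     label_b = config$compare_condition)
    manifest$counts$categories_compare_condition <- nrow(secondary$deduped)
    manifest$counts$shared_terms <- nrow(comparison$per_term)
  }

  # ---- write outputs ----
  out <- function(name) file.path(config$out_dir, name)
  files <- list()
  files$categories <- write_tsv(reg, out("category_regressions.tsv"))
  files$overall <- write_tsv(overall, out("overall_regression.tsv"))
  files$removed <- write_tsv(attr(reg, "removal_report"),
                             out("duplicates_removed.tsv"))
  files$summary <- write_tsv(summaries, out("aspect_summaries.tsv"))
  if (!is.null(aspect_cmp)) {
    files$aspect_comparisons <- write_tsv(aspect_cmp,
                                          out("aspect_comparisons.tsv"))
  }
  for (a in names(nulls)) {
    files[[paste0("null_", a)]] <-
      write_tsv(nulls[[a]]$draws, out(paste0("null_draws_", a, ".tsv")))
  }
  files$null_tests <- write_tsv(null_tests, out("null_tests.tsv"))
  files$flagged <- write_tsv(flagged, out("flagged_categories.tsv"))
  if (!is.null(screen)) {
    files$covariate_screen <- write_tsv(screen, out("covariate_screen.tsv"))
  }
  if (length(stability)) {
    stab_rows <- do.call(rbind, lapply(names(stability), function(a) {
      s <- stability[[a]]
      if (is.null(s)) return(NULL)
      data.frame(aspect = a, s$coefficients, model_r2 = s$r2,
                 f = s$f_statistic, df1 = s$df[["covariates"]],
                 df2 = s$df[["residual"]], model_p = unname(s$p),
                 n_categories = s$n_categories, stringsAsFactors = FALSE)
    }))
    if (!is.null(stab_rows)) {
      files$stability <- write_tsv(stab_rows, out("stability_regression.tsv"))
    }
  }
  if (!is.null(comparison) && nrow(comparison$per_term)) {
    files$comparison_terms <- write_tsv(comparison$per_term,
                                        out("comparison_terms.tsv"))
    files$comparison_summary <- write_tsv(comparison$by_aspect,
                                          out("comparison_summary.tsv"))
  }

  cfg_path <- out("pipeline_config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest$config <- unclass(config)
  manifest$config[vapply(manifest$config, is.null, logical(1))] <- NULL
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$files <- lapply(files, function(p) {
    list(path = basename(p), rows = length(readLines(p)) - 1L)
  })
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    expression = expr, annotation = annot, categories = primary$categories,
    regressions = reg, regressions_raw = primary$raw, overall = overall,
    summaries = summaries, aspect_comparisons = aspect_cmp, curves = curves,
    nulls = nulls, null_tests = null_tests, flagged = flagged,
    covariate_screen = screen, stability = stability,
    comparison = comparison, manifest = manifest
  ))
}

#' Generate a synthetic study and analyse it end to end
#'
#' Writes a synthetic dataset ([generate_expression()],
#' [generate_covariates()]) under `out_dir/inputs`, runs [run_full()] on
#' the written files, and adds a ground-truth recovery report: for every
#' non-duplicate category, the estimated R-squared and slope next to
#' their generating values, whether the truth falls inside the estimated
#' 95% intervals (slope CI from the fit; R-squared CI via
#' [r2_confint()]), and the recovered covariate-coupling correlations
#' next to their configured targets.
#'
#' @param syn_config a [synthetic_config()].
#' @param out_dir output directory.
#' @param compare_condition optional second condition label (must be in
#'   `syn_config$conditions`).
#' @param ... further arguments passed to [pipeline_config()]
#'   (`n_iterations`, `flag_sd_k`, ...).
#' @return invisibly, the [run_full()] bundle plus `dataset`,
#'   `recovery` (per-category data frame) and `coupling_recovery`.
#' @export
run_synthetic <- function(syn_config, out_dir, compare_condition = NULL, ...) {
  stopifnot(inherits(syn_config, "synthetic_config"))
  dataset <- generate_expression(syn_config)
  input_dir <- file.path(out_dir, "inputs")
  covs <- generate_covariates(dataset)
  paths <- write_synthetic_dataset(dataset, input_dir, covariates = covs)
  config <- pipeline_config(
    expression = paths[["expression"]], annotation = paths[["annotation_gaf"]],
    annotation_format = "gaf", condition = syn_config$conditions[1L],
    compare_condition = compare_condition, covariates = paths[["covariates"]],
    out_dir = out_dir, seed = syn_config$seed,
    min_category_size = syn_config$min_category_size, ...)
  bundle <- run_full(config)

  truth <- dataset$truth[is.na(dataset$truth$duplicate_of), , drop = FALSE]
  est <- bundle$regressions
  m <- match(truth$term_id, est$term_id)
  present <- !is.na(m)
  rec <- cbind(truth[present, c("term_id", "aspect", "size", "target_r2",
                                "true_r2", "true_slope")],
               est[m[present], c("n", "r2", "slope", "slope_ci_low",
                                 "slope_ci_high")])
  rec$slope_in_ci <- rec$true_slope >= rec$slope_ci_low &
    rec$true_slope <= rec$slope_ci_high
  r2ci <- t(mapply(function(r2, n, s) r2_confint(r2, n, sign(s)),
                   rec$r2, rec$n, rec$slope))
  rec$r2_ci_low <- r2ci[, 1L]
  rec$r2_ci_high <- r2ci[, 2L]
  rec$r2_in_ci <- rec$true_r2 >= rec$r2_ci_low & rec$true_r2 <= rec$r2_ci_high
  rownames(rec) <- NULL

  # recovered covariate coupling: Spearman(category-mean covariate, true R2)
  cov_means <- category_covariate_means(
    dataset$annotation$members[rec$term_id], as.data.frame(covs),
    min_size = 2L)
  coupling <- do.call(rbind, lapply(COVARIATE_COLUMNS, function(cv) {
    cm <- cov_means[cov_means$covariate == cv, , drop = FALSE]
    sp <- spearman_rank(rec$true_r2[match(cm$term_id, rec$term_id)], cm$mean)
    data.frame(covariate = cv,
               target = unname(syn_config$covariate_coupling[cv]),
               recovered_rho = sp$rho, p = sp$p, n = sp$n,
               stringsAsFactors = FALSE)
  }))

  write_tsv(rec, file.path(out_dir, "recovery.tsv"))
  write_tsv(coupling, file.path(out_dir, "coupling_recovery.tsv"))
  invisible(c(bundle, list(dataset = dataset, recovery = rec,
                           coupling_recovery = coupling)))
}
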