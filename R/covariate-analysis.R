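#' Per-category covariate means
#'
#' Arithmetic mean of each per-gene covariate over a category's members,
#' excluding genes lacking that covariate pairwise. A category whose
#' member count with the covariate falls below `min_size` is excluded for
#' that covariate (mirroring the re-application of the category minimum
#' after merging with an external stability dataset).
#'
#' @param memberships named list term_id -> member genes (e.g. from
#'   [assemble_categories()]).
#' @param gene_values data frame with a `gene_id` column and one or more
#'   numeric per-gene columns (a [covariate_table()], or per-gene
#'   abundances bound by the caller).
#' @param min_size minimum members-with-value per category (default 10).
#' @return long data frame: `term_id`, `covariate`, `n_genes` (members
#'   carrying the value), `mean` (`NA` when excluded), `included`.
#' @export
category_covariate_means <- function(memberships, gene_values, min_size = 10L) {
  gene_values <- as.data.frame(gene_values)
  stopifnot("gene_id" %in% names(gene_values))
  covs <- setdiff(names(gene_values), "gene_id")
  if (!length(covs)) stop("gene_values has no covariate columns")
  rownames(gene_values) <- gene_values$gene_id
  rows <- list()
  for (term in names(memberships)) {
    g <- intersect(memberships[[term]], gene_values$gene_id)
    for (cv in covs) {
      v <- gene_values[g, cv]
      v <- v[!is.na(v)]
      ok <- length(v) >= min_size
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = term, covariate = cv, n_genes = length(v),
        mean = if (ok) mean(v) else NA_real_, included = ok,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene abundance columns for the covariate screen
#'
#' Convenience: the per-gene mean transcript and protein log-abundances
#' of one condition, shaped like a covariate table, so category mean
#' abundance can be screened with the same machinery as the stability
#' covariates.
#'
#' @param expr an [expression_table()].
#' @param condition condition label.
#' @return data frame: `gene_id`, `mean_transcript_expression`,
#'   `mean_protein_expression`.
#' @export
abundance_covariates <- function(expr, condition) {
  p <- condition_pairs(expr, condition)
  data.frame(gene_id = p$gene_id,
             mean_transcript_expression = p$transcript,
             mean_protein_expression = p$protein,
             stringsAsFactors = FALSE)
}

#' Spearman screen of category R-squared against a covariate
#'
#' Spearman rank correlation (average-rank ties, t-approximation
#' p-value) between per-category R-squared and a per-category covariate,
#' for all categories and -- when `sizes` is given -- separately for the
#' strata below and at-or-above `size_threshold` members (default 20;
#' the boundary value falls in the upper stratum).
#'
#' @param r2 numeric vector of per-category R-squared.
#' @param covariate numeric vector of per-category covariate values,
#'   aligned with `r2`; `NA`s excluded pairwise.
#' @param sizes optional integer vector of category sizes (enables the
#'   strata).
#' @param covariate_name,aspect labels carried into the result.
#' @param size_threshold stratum boundary (default 20).
#' @return data frame of class `covariate_screen`: `aspect`, `covariate`,
#'   `stratum` (`all`, `lt20`, `ge20`), `spearman_rho`, `p`,
#'   `n_categories`. Strata with fewer than 3 usable categories report
#'   `NA` correlations.
#' @export
screen_covariate <- function(r2, covariate, sizes = NULL,
                             covariate_name = "covariate",
                             aspect = NA_character_, size_threshold = 20L) {
  stopifnot(length(r2) == length(covariate))
  strata <- list(all = rep(TRUE, length(r2)))
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == length(r2))
    strata[[paste0("lt", size_threshold)]] <- sizes < size_threshold
    strata[[paste0("ge", size_threshold)]] <- sizes >= size_threshold
  }
  rows <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    sp <- spearman_rank(r2[idx], covariate[idx])
    data.frame(aspect = aspect, covariate = covariate_name, stratum = s,
               spearman_rho = sp$rho, p = sp$p, n_categories = sp$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("covariate_screen", "data.frame")
  out
}

#' Multiple regression of category R-squared on stability covariates
#'
#' Ordinary least squares (with intercept) of per-category R-squared on
#' the four category-mean stability covariates: transcription rate,
#' translation rate, mRNA half-life and protein half-life, all on their
#' raw scales. Categories missing any covariate are dropped (complete
#' cases).
#'
#' @param r2 named numeric vector: per-category R-squared, names =
#'   term_id.
#' @param covariate_means long data frame from
#'   [category_covariate_means()] containing the four stability
#'   covariates.
#' @param aspect label carried into the result.
#' @return list of class `stability_regression`: `aspect`,
#'   `coefficients` (term, estimate, std_error, t_value, p), `r2`
#'   (model), `f_statistic`, `df` (c(covariates, residual)), `p`
#'   (model F-test), `n_categories`.
#' @export
fit_stability_regression <- function(r2, covariate_means,
                                     aspect = NA_character_) {
  rate_covs <- c("transcription_rate", "translation_rate",
                 "mrna_half_life", "protein_half_life")
  cm <- covariate_means[covariate_means$covariate %in% rate_covs, , drop = FALSE]
  wide <- stats::reshape(
    cm[, c("term_id", "covariate", "mean")], direction = "wide",
    idvar = "term_id", timevar = "covariate")
  names(wide) <- sub("^mean\\.", "", names(wide))
  missing_cov <- setdiff(rate_covs, names(wide))
  if (length(missing_cov)) {
    stop("covariate_means lacks: ", paste(missing_cov, collapse = ", "))
  }
  wide$r2 <- unname(r2[wide$term_id])
  wide <- wide[stats::complete.cases(wide[, c("r2", rate_covs)]), , drop = FALSE]
  n <- nrow(wide)
  if (n < 6L) stop("need >= 6 categories with all four covariates, have ", n)
  fit <- stats::lm(stats::reformulate(rate_covs, response = "r2"), data = wide)
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(
    term = rownames(co), estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"], t_value = co[, "t value"],
    p = co[, "Pr(>|t|)"], stringsAsFactors = FALSE, row.names = NULL)
  fs <- sm$fstatistic
  structure(list(
    aspect = aspect, coefficients = coefs, r2 = sm$r.squared,
    f_statistic = unname(fs["value"]),
    df = c(covariates = unname(fs["numdf"]), residual = unname(fs["dendf"])),
    p = stats::pf(fs["value"], fs["numdf"], fs["dendf"], lower.tail = FALSE),
    n_categories = n, model = fit
  ), class = "stability_regression")
}

#' @export
print.stability_regression <- function(x, ...) {
  cat("<stability_regression>",
      if (!is.na(x$aspect)) paste0(" [", x$aspect, "]"), "\n", sep = "")
  print(x$coefficients, digits = 3)
  cat(sprintf("R2 = %.2f, F(%d, %d) = %.2f, p = %.3g  (n = %d categories)\n",
              x$r2, x$df[["covariates"]], x$df[["residual"]],
              x$f_statistic, x$p, x$n_categories))
  invisible(x)
}

#' Format a covariate screen with significance markers
#'
#' Adds the conventional `*` (p < 0.05) / `**` (p < 0.01) markers to a
#' [screen_covariate()] table for report output.
#'
#' @param screen a `covariate_screen` data frame (rows from one or more
#'   [screen_covariate()] calls).
#' @return data frame with an additional `signif` column.
#' @export
format_covariate_screen <- function(screen) {
  screen$signif <- ifelse(is.na(screen$p), "",
                          ifelse(screen$p < 0.01, "**",
                                 ifelse(screen$p < 0.05, "*", "")))
  screen
}
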