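#' Assemble GO categories from paired expression
#'
#' Restricts each term's membership to genes with a complete
#' transcript/protein pair in `condition` and keeps only terms with at
#' least `min_size` such members (the conventional minimum for a
#' per-category regression).
#'
#' @param expr an [expression_table()].
#' @param annot an [annotation_map()].
#' @param condition condition label to analyse.
#' @param min_size minimum number of complete pairs per category
#'   (default 10).
#' @return named list (term_id -> character vector of member genes) with
#'   attributes `terms` (the matching metadata rows) and `n_before`
#'   (term count before the size filter).
#' @export
assemble_categories <- function(expr, annot, condition, min_size = 10L) {
  stopifnot(inherits(expr, "expression_table"), inherits(annot, "annotation_map"))
  pairs <- condition_pairs(expr, condition)
  members <- lapply(annot$members, function(g) g[g %in% pairs$gene_id])
  keep <- lengths(members) >= min_size
  if (!any(keep)) {
    stop("no category has >= ", min_size, " complete pairs in '", condition,
         "' (", nrow(annot$terms), " terms, largest overlap ",
         max(lengths(members)), ")")
  }
  out <- members[keep]
  attr(out, "terms") <- annot$terms[keep, , drop = FALSE]
  attr(out, "n_before") <- nrow(annot$terms)
  out
}

#' Ordinary least squares fit for one category
#'
#' Regresses protein log-expression on transcript log-expression
#' (protein is the response throughout this package: the question is how
#' well transcripts predict proteins). Reports the coefficient of
#' determination, the two-sided t-test p-value for the slope (identical
#' to the one-predictor model F-test), and t-based confidence intervals
#' on `n - 2` degrees of freedom.
#'
#' @param pairs data frame with numeric columns `transcript`, `protein`
#'   (e.g. from [condition_pairs()], subset to a category's members).
#' @param term_id,name,aspect metadata copied into the result row.
#' @param ci_level confidence level for the slope/intercept intervals
#'   (default 0.95).
#' @return one-row data frame: `term_id`, `name`, `aspect`, `n`, `r2`,
#'   `p`, `slope`, `slope_ci_low`, `slope_ci_high`, `intercept`,
#'   `intercept_ci_low`, `intercept_ci_high`.
#' @export
fit_category_ols <- function(pairs, term_id = "ALL", name = term_id,
                             aspect = NA_character_, ci_level = 0.95) {
  pairs <- pairs[stats::complete.cases(pairs[, c("transcript", "protein")]), ,
                 drop = FALSE]
  n <- nrow(pairs)
  if (n < 3L) stop("category '", term_id, "': need >= 3 complete pairs, have ", n)
  if (stats::var(pairs$transcript) == 0) {
    stop("category '", term_id, "': degenerate fit, transcript values are all identical")
  }
  fit <- stats::lm(protein ~ transcript, data = pairs)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = ci_level)
  co <- sm$coefficients
  data.frame(
    term_id = term_id, name = name, aspect = aspect, n = n,
    r2 = sm$r.squared, p = co["transcript", "Pr(>|t|)"],
    slope = co["transcript", "Estimate"],
    slope_ci_low = ci["transcript", 1L], slope_ci_high = ci["transcript", 2L],
    intercept = co["(Intercept)", "Estimate"],
    intercept_ci_low = ci["(Intercept)", 1L],
    intercept_ci_high = ci["(Intercept)", 2L],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-category OLS regressions
#'
#' Applies [fit_category_ols()] to every assembled category and returns
#' the results ordered by descending R-squared (the "complete ordered
#' list" convention).
#'
#' @param expr an [expression_table()].
#' @param categories output of [assemble_categories()].
#' @param condition condition label.
#' @param ci_level confidence level (default 0.95).
#' @return data frame of class `category_regressions`, one row per
#'   category, columns as in [fit_category_ols()].
#' @export
category_regressions <- function(expr, categories, condition, ci_level = 0.95) {
  pairs <- condition_pairs(expr, condition)
  rownames(pairs) <- pairs$gene_id
  terms <- attr(categories, "terms")
  rows <- lapply(seq_along(categories), function(i) {
    fit_category_ols(pairs[categories[[i]], , drop = FALSE],
                     term_id = names(categories)[i],
                     name = terms$name[i], aspect = terms$aspect[i],
                     ci_level = ci_level)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("category_regressions", "data.frame")
  out
}

#' Genome-wide regression over every complete pair
#'
#' Single OLS of protein on transcript over all complete pairs in the
#' condition; the benchmark against which categorical predictivity is
#' judged.
#'
#' @inheritParams category_regressions
#' @return one-row data frame as in [fit_category_ols()], with
#'   `term_id = "ALL"`.
#' @export
overall_regression <- function(expr, condition, ci_level = 0.95) {
  pairs <- condition_pairs(expr, condition)
  fit_category_ols(pairs, term_id = "ALL", name = "all transcript/protein pairs",
                   aspect = NA_character_, ci_level = ci_level)
}

#' Remove duplicate categories
#'
#' GO terms whose member sets are exactly identical to another term's (and
#' therefore share its R-squared) carry no independent information; within
#' each group of identical member sets exactly one representative is
#' retained -- the term earliest in case-insensitive lexicographic order
#' of term name (ties broken by term id). Terms sharing merely most of
#' their members are all retained. Idempotent.
#'
#' @param results a [category_regressions()] data frame.
#' @param memberships named list term_id -> member genes (e.g. the
#'   [assemble_categories()] output the results were fitted from).
#' @return `results` restricted to representatives, with attribute
#'   `removal_report`: data frame `removed_term_id`, `retained_term_id`.
#' @export
deduplicate_categories <- function(results, memberships) {
  if (nrow(results) == 0L) {
    attr(results, "removal_report") <- data.frame(
      removed_term_id = character(), retained_term_id = character(),
      stringsAsFactors = FALSE)
    return(results)
  }
  key <- vapply(memberships[results$term_id],
                function(g) paste(sort(g), collapse = "\r"), character(1))
  keep <- logical(nrow(results))
  removed <- retained <- character(0)
  for (grp in split(seq_len(nrow(results)), key)) {
    ord <- grp[order(tolower(results$name[grp]), results$term_id[grp])]
    keep[ord[1L]] <- TRUE
    if (length(ord) > 1L) {
      removed <- c(removed, results$term_id[ord[-1L]])
      retained <- c(retained, rep(results$term_id[ord[1L]], length(ord) - 1L))
    }
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_report") <- data.frame(
    removed_term_id = removed, retained_term_id = retained,
    stringsAsFactors = FALSE)
  class(out) <- class(results)
  out
}

#' Write a per-category regression table
#'
#' Tab-delimited, ordered by descending R-squared, with exactly the
#' conventional column set (category, n, R2, p, slope and CI, intercept
#' and CI).
#'
#' @param results a [category_regressions()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regression_table <- function(results, path) {
  out <- results[order(-results$r2, results$term_id), , drop = FALSE]
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
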