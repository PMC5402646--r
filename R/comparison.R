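#' Compare category predictivity between two conditions
#'
#' For the GO terms present in both sets of regression results (both
#' having passed their own minimum-size filter and duplicate removal),
#' computes per aspect: each term's R-squared rank in each condition
#' (rank 1 = highest R-squared, average ranks on ties, ranks taken over
#' the shared terms only), the absolute rank change and its scaled score
#' `|rank change| / n_terms_in_aspect * 100`, whether the two 95% slope
#' confidence intervals overlap (closed intervals: touching endpoints
#' count as overlapping), and the aspect-level Spearman correlation of
#' R-squared between the conditions.
#'
#' Symmetric: swapping the two inputs leaves scores, overlap flags and
#' correlations unchanged.
#'
#' @param results_a,results_b [category_regressions()] data frames for
#'   the two conditions.
#' @param label_a,label_b condition labels used in messages.
#' @return object of class `condition_comparison`: list with `per_term`
#'   (aspect, term_id, name, r2_a, r2_b, rank_a, rank_b,
#'   abs_rank_change, scaled_score, slope_ci_overlap) and `by_aspect`
#'   (aspect, n_shared, spearman_rho, p, n_ci_overlap). Aspects with
#'   fewer than 3 shared terms are dropped with a notice; an empty
#'   intersection returns an empty comparison with a notice.
#' @export
compare_conditions <- function(results_a, results_b,
                               label_a = "condition_a",
                               label_b = "condition_b") {
  shared <- intersect(results_a$term_id, results_b$term_id)
  empty <- function() {
    structure(list(
      per_term = data.frame(aspect = character(), term_id = character(),
                            name = character(), r2_a = numeric(),
                            r2_b = numeric(), rank_a = numeric(),
                            rank_b = numeric(), abs_rank_change = numeric(),
                            scaled_score = numeric(),
                            slope_ci_overlap = logical(),
                            stringsAsFactors = FALSE),
      by_aspect = data.frame(aspect = character(), n_shared = integer(),
                             spearman_rho = numeric(), p = numeric(),
                             n_ci_overlap = integer(),
                             stringsAsFactors = FALSE),
      labels = c(label_a, label_b)
    ), class = "condition_comparison")
  }
  if (!length(shared)) {
    message("compare_conditions: no shared terms between ", label_a,
            " and ", label_b)
    return(empty())
  }
  a <- results_a[match(shared, results_a$term_id), , drop = FALSE]
  b <- results_b[match(shared, results_b$term_id), , drop = FALSE]
  per_term <- list()
  by_aspect <- list()
  for (asp in unique(a$aspect)) {
    idx <- which(a$aspect == asp)
    if (length(idx) < 3L) {
      message("compare_conditions: aspect '", asp, "' has only ",
              length(idx), " shared term(s); skipped (need >= 3)")
      next
    }
    nt <- length(idx)
    rank_a <- rank(-a$r2[idx], ties.method = "average")
    rank_b <- rank(-b$r2[idx], ties.method = "average")
    drank <- abs(rank_a - rank_b)
    overlap <- a$slope_ci_low[idx] <= b$slope_ci_high[idx] &
      b$slope_ci_low[idx] <= a$slope_ci_high[idx]
    per_term[[asp]] <- data.frame(
      aspect = asp, term_id = a$term_id[idx], name = a$name[idx],
      r2_a = a$r2[idx], r2_b = b$r2[idx], rank_a = rank_a, rank_b = rank_b,
      abs_rank_change = drank, scaled_score = drank / nt * 100,
      slope_ci_overlap = overlap, stringsAsFactors = FALSE)
    sp <- spearman_rank(a$r2[idx], b$r2[idx])
    by_aspect[[asp]] <- data.frame(
      aspect = asp, n_shared = nt, spearman_rho = sp$rho, p = sp$p,
      n_ci_overlap = sum(overlap), stringsAsFactors = FALSE)
  }
  if (!length(per_term)) return(empty())
  out <- structure(list(
    per_term = do.call(rbind, c(per_term, list(make.row.names = FALSE))),
    by_aspect = do.call(rbind, c(by_aspect, list(make.row.names = FALSE))),
    labels = c(label_a, label_b)
  ), class = "condition_comparison")
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> ", x$labels[1L], " vs ", x$labels[2L], ": ",
      nrow(x$per_term), " shared terms\n", sep = "")
  print(x$by_aspect, digits = 3)
  invisible(x)
}

#' Terms with the most discordant predictivity ranks
#'
#' The `k` shared terms with the largest scaled rank-change score,
#' descending; ties broken by term name (then term id) so the output is
#' deterministic. `k` larger than the number of terms returns all terms.
#'
#' @param comparison a [compare_conditions()] result.
#' @param k number of terms to return.
#' @return rows of `comparison$per_term`, ordered.
#' @export
top_discordant_terms <- function(comparison, k) {
  stopifnot(inherits(comparison, "condition_comparison"))
  pt <- comparison$per_term
  if (!nrow(pt)) stop("empty comparison")
  ord <- order(-pt$scaled_score, tolower(pt$name), pt$term_id)
  out <- pt[ord[seq_len(min(k, nrow(pt)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
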