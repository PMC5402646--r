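#' Size-matched permutation null for categorical R-squared
#'
#' Builds the null distribution of per-category R-squared under broken
#' gene identity: per iteration, one pseudo-category per observed
#' category; its size is drawn with replacement from the observed size
#' list, then that many transcript values and -- independently -- that
#' many protein values are drawn without replacement from the full pools,
#' paired in draw order, and the OLS R-squared recorded together with the
#' size. The default 1000 iterations over `length(observed_sizes)`
#' categories gives `1000 * length(observed_sizes)` draws.
#'
#' @param expr an [expression_table()], or a data frame with numeric
#'   `transcript` and `protein` columns to use directly as pools.
#' @param observed_sizes integer vector of observed category sizes (all
#'   >= 2); its length sets the number of pseudo-categories per iteration.
#' @param condition condition label (required when `expr` is an
#'   expression table).
#' @param n_iterations number of iterations (default 1000).
#' @param seed integer seed recorded in the result.
#' @param aspect optional aspect label carried through to reports.
#' @return object of class `null_distribution`: list with `aspect`,
#'   `draws` (data frame `iteration`, `size`, `r2`), `n_iterations`,
#'   `seed`, `observed_sizes` and `summary` (mean, sd, median, min, max
#'   of r2).
#' @export
build_null <- function(expr, observed_sizes, condition = NULL,
                       n_iterations = 1000L, seed = 1L,
                       aspect = NA_character_) {
  if (inherits(expr, "expression_table")) {
    if (is.null(condition)) stop("condition is required with an expression table")
    pools <- condition_pairs(expr, condition)
  } else {
    pools <- as.data.frame(expr)
    stopifnot(all(c("transcript", "protein") %in% names(pools)))
  }
  observed_sizes <- as.integer(observed_sizes)
  if (length(observed_sizes) == 0L) stop("observed_sizes must be nonempty")
  if (any(observed_sizes < 2L)) stop("all observed sizes must be >= 2")
  pool_t <- pools$transcript[is.finite(pools$transcript)]
  pool_p <- pools$protein[is.finite(pools$protein)]
  if (max(observed_sizes) > min(length(pool_t), length(pool_p))) {
    stop("expression pool (", min(length(pool_t), length(pool_p)),
         ") smaller than the largest observed size (", max(observed_sizes), ")")
  }
  n_cat <- length(observed_sizes)
  total <- n_iterations * n_cat
  with_seed(seed, {
    sizes <- observed_sizes[sample.int(length(observed_sizes), total,
                                       replace = TRUE)]
    r2 <- vapply(sizes, function(m) {
      xt <- pool_t[sample.int(length(pool_t), m)]
      yp <- pool_p[sample.int(length(pool_p), m)]
      stats::cor(xt, yp)^2
    }, numeric(1))
    draws <- data.frame(iteration = rep(seq_len(n_iterations), each = n_cat),
                        size = sizes, r2 = r2)
    structure(list(
      aspect = aspect, draws = draws, n_iterations = as.integer(n_iterations),
      seed = as.integer(seed), observed_sizes = observed_sizes,
      summary = c(mean = mean(r2), sd = stats::sd(r2),
                  median = stats::median(r2), min = min(r2), max = max(r2))
    ), class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  s <- x$summary
  cat("<null_distribution>", if (!is.na(x$aspect)) paste0(" [", x$aspect, "]"),
      " ", nrow(x$draws), " draws (", x$n_iterations, " iterations x ",
      length(x$observed_sizes), " categories), seed ", x$seed, "\n",
      sprintf("  r2: mean %.3f +/- %.3f, median %.3f, range %.3f-%.3f\n",
              s["mean"], s["sd"], s["median"], s["min"], s["max"]),
      sep = "")
  invisible(x)
}

#' Compare observed categorical R-squared against the permutation null
#'
#' Two-sided Mann--Whitney test of the observed per-category R-squared
#' values against the null draws; `U` is computed with the observed
#' sample as sample 1 (see [mann_whitney()]).
#'
#' @param observed_r2 numeric vector of observed per-category R-squared.
#' @param null a [build_null()] result.
#' @return list with `U`, `p`, `direction` (+1 when the observed median
#'   exceeds the null median), `n_observed`, `n_null`.
#' @export
compare_observed_to_null <- function(observed_r2, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!length(observed_r2)) stop("observed_r2 must be nonempty")
  mw <- mann_whitney(observed_r2, null$draws$r2)
  list(U = mw$U, p = mw$p, direction = mw$direction,
       n_observed = mw$n1, n_null = mw$n2)
}

#' Correlation of null R-squared with pseudo-category size
#'
#' The expected strong negative association between R-squared and
#' category size under random pairing: the null R-squared at size n is
#' Beta(1/2, (n-2)/2)-distributed, which decreases stochastically in n.
#'
#' @param null a [build_null()] result with at least 3 draws over at
#'   least 2 distinct sizes.
#' @return list with `rho`, `p`, `n` (see [spearman_rank()]); `rho = NA`
#'   with a note when all draws share one size.
#' @export
null_size_correlation <- function(null) {
  stopifnot(inherits(null, "null_distribution"))
  sp <- spearman_rank(null$draws$r2, null$draws$size)
  if (is.na(sp$rho)) {
    message("null_size_correlation: undefined (", sp$note, ")")
  }
  sp
}

#' Flag categories more predictive than the permutation null
#'
#' Flags every observed category whose R-squared exceeds the null mean by
#' more than `k` null standard deviations (default 4, the conventional
#' rule for calling a category's transcript predictivity real rather than
#' a small-sample artefact).
#'
#' @param results a [category_regressions()] data frame.
#' @param null a [build_null()] result.
#' @param k number of null standard deviations above the null mean
#'   (default 4).
#' @return the flagged rows of `results` (possibly zero rows), with the
#'   numeric `threshold` attached as an attribute.
#' @export
flag_predictive_categories <- function(results, null, k = 4) {
  stopifnot(inherits(null, "null_distribution"))
  threshold <- unname(null$summary["mean"] + k * null$summary["sd"])
  out <- results[!is.na(results$r2) & results$r2 > threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
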