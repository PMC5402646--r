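#' Descriptive summary of per-category R-squared for one aspect
#'
#' Mean, sample standard deviation (n - 1 divisor), median, range,
#' Shapiro--Wilk normality test and adjusted Fisher--Pearson skewness
#' ([sample_skewness()]). Intended to be run after duplicate-category
#' removal.
#'
#' @param r2 numeric vector of per-category R-squared values.
#' @param aspect optional aspect label carried into the result.
#' @return one-row data frame: `aspect`, `n_categories`, `mean`, `sd`,
#'   `median`, `min`, `max`, `shapiro_w`, `shapiro_p`, `skewness`.
#'   Shapiro--Wilk is `NA` below 3 values; a notice is emitted below 8
#'   values, where the test has little power.
#' @export
summarize_aspect <- function(r2, aspect = NA_character_) {
  r2 <- r2[is.finite(r2)]
  n <- length(r2)
  if (n == 0L) stop("no R-squared values to summarize")
  if (n < 8L) {
    message("summarize_aspect: only ", n,
            " values; normality diagnostics are unreliable below 8")
  }
  sw <- if (n >= 3L && n <= 5000L && stats::sd(r2) > 0) {
    stats::shapiro.test(r2)
  } else list(statistic = NA_real_, p.value = NA_real_)
  data.frame(
    aspect = aspect, n_categories = n, mean = mean(r2), sd = stats::sd(r2),
    median = stats::median(r2), min = min(r2), max = max(r2),
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    skewness = sample_skewness(r2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pairwise Mann--Whitney comparison of aspects
#'
#' All pairwise two-sided Mann--Whitney tests between the per-aspect
#' R-squared distributions. `U` is oriented with the first-named aspect
#' of each pair as sample 1.
#'
#' @param r2_by_aspect named list of numeric vectors (one per aspect,
#'   each with at least 2 values).
#' @return data frame: `aspect_a`, `aspect_b`, `U`, `p`, `direction`
#'   (sign of `median(a) - median(b)`), `n_a`, `n_b`.
#' @export
compare_aspects <- function(r2_by_aspect) {
  stopifnot(is.list(r2_by_aspect), length(r2_by_aspect) >= 2L,
            !is.null(names(r2_by_aspect)))
  if (any(lengths(r2_by_aspect) < 2L)) {
    stop("each aspect needs at least 2 values")
  }
  pairs <- utils::combn(names(r2_by_aspect), 2L)
  rows <- apply(pairs, 2L, function(ab) {
    mw <- mann_whitney(r2_by_aspect[[ab[1L]]], r2_by_aspect[[ab[2L]]])
    data.frame(aspect_a = ab[1L], aspect_b = ab[2L], U = mw$U, p = mw$p,
               direction = mw$direction, n_a = mw$n1, n_b = mw$n2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned cumulative percentage curve of R-squared values
#'
#' Bins values on \[0, 1\] (default bin width 0.05), accumulates counts
#' into cumulative percentages, and optionally Gaussian-smooths the
#' binned density before accumulation (for a representative plotted
#' line; the smoothing kernel is renormalized at the edges so the curve
#' still terminates at 100). The unsmoothed curve is monotone
#' nondecreasing and ends at exactly 100.
#'
#' @param values numeric vector in \[0, 1\].
#' @param bin_width bin width (default 0.05).
#' @param smooth also compute a Gaussian-smoothed curve (default TRUE).
#' @param bandwidth kernel standard deviation in bin units (default 1);
#'   affects only the smoothed curve, never any statistic.
#' @return data frame of class `cumulative_curve`: `bin_low`, `bin_high`,
#'   `count`, `cum_pct` and (when `smooth`) `cum_pct_smooth`.
#' @export
cumulative_curve <- function(values, bin_width = 0.05, smooth = TRUE,
                             bandwidth = 1) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no values")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- as.vector(table(cut(values, breaks, include.lowest = TRUE,
                                right = TRUE)))
  out <- data.frame(
    bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
    count = counts, cum_pct = cumsum(counts) / length(values) * 100
  )
  if (smooth) {
    nb <- length(counts)
    sm <- vapply(seq_len(nb), function(i) {
      w <- stats::dnorm(seq_len(nb) - i, sd = bandwidth)
      sum(w * counts) / sum(w) * nb # renormalized at edges, mass preserved
    }, numeric(1))
    sm <- sm / sum(sm) * length(values)
    out$cum_pct_smooth <- cumsum(sm) / length(values) * 100
  }
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Plot cumulative R-squared curves
#'
#' Base-graphics rendering of one or more [cumulative_curve()] results
#' (observed and permutation-null curves are conventionally overlaid,
#' one colour per aspect with the null in a lighter shade).
#'
#' @param x a `cumulative_curve`, or a named list of them.
#' @param col line colour(s), recycled.
#' @param smooth draw the smoothed curve when available (default TRUE).
#' @param ... passed to [graphics::matplot()].
#' @return `NULL`, invisibly.
#' @export
plot.cumulative_curve <- function(x, col = NULL, smooth = TRUE, ...) {
  curves <- if (inherits(x, "cumulative_curve")) list(x) else x
  col <- col %||% seq_along(curves)
  ys <- vapply(curves, function(cv) {
    if (smooth && "cum_pct_smooth" %in% names(cv)) cv$cum_pct_smooth else cv$cum_pct
  }, numeric(nrow(curves[[1L]])))
  graphics::matplot(curves[[1L]]$bin_high, ys, type = "l", lty = 1, col = col,
                    xlab = expression(R^2), ylab = "cumulative %",
                    ylim = c(0, 100), ...)
  if (!is.null(names(curves))) {
    graphics::legend("bottomright", legend = names(curves), col = col, lty = 1)
  }
  invisible(NULL)
}
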