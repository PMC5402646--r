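#' Adjusted Fisher--Pearson sample skewness
#'
#' Computes the adjusted Fisher--Pearson standardized moment coefficient
#' \eqn{G_1 = \frac{\sqrt{n(n-1)}}{n-2}\, m_3 / m_2^{3/2}}, where \eqn{m_k}
#' are central sample moments with divisor \eqn{n}. This is the default
#' skewness estimator of most statistics packages and is used for all
#' distribution diagnostics in this package.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return A single numeric value; `NA` if fewer than 3 finite values or
#'   zero variance.
#' @examples
#' sample_skewness(c(1, 2, 3))        # 0: symmetric
#' sample_skewness(c(1, 2, 3, 4, 100)) # strongly right-skewed
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Mann--Whitney U test with documented orientation
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) test. `U` is computed with
#' `x` as sample 1: the number of (x, y) pairs with x > y, counting ties as
#' one half. The p-value uses exact enumeration when both samples are small
#' (`min(n1, n2) <` `exact_below`) and tie-free, and the tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_below exact p-values are used when `min(n1, n2)` is below
#'   this and there are no ties (default 20).
#' @return list with `U`, `p`, `n1`, `n2`, `direction` (sign of
#'   `median(x) - median(y)`) and `method`.
#' @examples
#' mann_whitney(1:3, 4:6)$U # 0: every y exceeds every x
#' @export
mann_whitney <- function(x, y, exact_below = 20L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  # exact enumeration only when both samples are small enough for the exact
  # U distribution to be tractable
  use_exact <- !ties && min(n1, n2) < exact_below && max(n1, n2) <= 100L
  if (stats::var(c(x, y)) == 0) {
    p <- 1
    method <- "degenerate (all values tied)"
  } else if (use_exact) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    )
    method <- "normal approximation, tie-corrected"
  }
  list(
    U = unname(U), p = p, n1 = n1, n2 = n2,
    direction = sign(stats::median(x) - stats::median(y)),
    method = method
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average-rank tie handling; the p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which remains defined in the presence of ties (the exact distribution
#' does not).
#'
#' @param x,y numeric vectors; pairs with a missing member are dropped.
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (with a message in
#'   `note`) when either variable is constant after pairwise deletion.
#' @export
spearman_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                note = "undefined: fewer than 3 pairs or a constant variable"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, note = NA_character_)
}

#' Confidence interval for a coefficient of determination
#'
#' Approximate CI for a population R-squared, via the Fisher z transform of
#' the signed correlation \eqn{r = s\sqrt{R^2}} (s the slope sign). The z
#' interval for \eqn{\rho} is back-transformed and squared; when the
#' interval for \eqn{\rho} straddles zero the lower R-squared bound is 0.
#'
#' @param r2 observed coefficient of determination in \[0, 1\].
#' @param n number of pairs (must exceed 3).
#' @param slope_sign sign of the fitted slope (+1/-1); only used to centre
#'   the transform, the returned interval is on the R-squared scale.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` on the R-squared scale.
#' @export
r2_confint <- function(r2, n, slope_sign = 1, level = 0.95) {
  stopifnot(r2 >= 0, r2 <= 1, n > 3)
  s <- if (slope_sign < 0) -1 else 1
  r <- s * sqrt(min(r2, 1 - 1e-12))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  lo <- tanh(z - q * se)
  hi <- tanh(z + q * se)
  if (lo <= 0 && hi >= 0) c(0, max(lo^2, hi^2)) else sort(c(lo^2, hi^2))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Stage offsets keep substreams distinct
# while staying below .Machine$integer.max.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

stage_seed <- function(seed, stage) {
  offsets <- c(
    expression = 11L, covariates = 29L, null_biological_process = 101L,
    null_molecular_function = 103L, null_cellular_component = 107L,
    permute = 113L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage)
  (as.integer(seed) + off) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical aspect vocabulary -------------------------------------------------

ASPECTS <- c("biological_process", "molecular_function", "cellular_component")
ASPECT_CODES <- c(
  P = "biological_process",
  F = "molecular_function",
  C = "cellular_component"
)

aspect_from_code <- function(code) {
  out <- ASPECT_CODES[as.character(code)]
  if (anyNA(out)) {
    bad <- unique(code[is.na(out)])
    stop("unknown GO aspect code(s): ", paste(bad, collapse = ", "),
         " (expected P, F or C)")
  }
  unname(out)
}

aspect_to_code <- function(aspect) {
  m <- match(aspect, ASPECT_CODES)
  if (anyNA(m)) stop("unknown aspect label(s): ",
                     paste(unique(aspect[is.na(m)]), collapse = ", "))
  names(ASPECT_CODES)[m]
}

check_aspect <- function(aspect) {
  bad <- setdiff(unique(aspect), ASPECTS)
  if (length(bad)) {
    stop("unknown aspect label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ASPECTS, collapse = ", "), ")")
  }
  invisible(aspect)
}
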