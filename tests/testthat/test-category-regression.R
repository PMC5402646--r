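test_that("a noiseless line is recovered exactly", {
  pairs <- data.frame(transcript = seq(1, 3, length.out = 10))
  pairs$protein <- 2 * pairs$transcript + 1
  fit <- suppressWarnings(fit_category_ols(pairs, term_id = "GO:X"))
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
})

test_that("OLS output matches the normal-equations oracle to 1e-8", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(8:40, 1)
    x <- rnorm(n, 2, 1)
    y <- 0.6 * x + rnorm(n, 3, 0.8)
    fit <- fit_category_ols(data.frame(transcript = x, protein = y))
    oracle <- ols_normal_equations(x, y)
    expect_equal(fit$slope, unname(oracle$slope), tolerance = 1e-8)
    expect_equal(fit$intercept, unname(oracle$intercept), tolerance = 1e-8)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-8)
    expect_equal(fit$p, unname(oracle$p_slope), tolerance = 1e-8)
    expect_equal(c(fit$slope_ci_low, fit$slope_ci_high), oracle$ci_slope,
                 tolerance = 1e-8)
    expect_equal(c(fit$intercept_ci_low, fit$intercept_ci_high),
                 oracle$ci_intercept, tolerance = 1e-8)
    # r2 equals the squared Pearson correlation
    expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("degenerate fits are refused with the term named", {
  expect_error(fit_category_ols(data.frame(transcript = c(1, 2), protein = c(1, 2))),
               ">= 3")
  expect_error(
    fit_category_ols(data.frame(transcript = rep(1, 5), protein = rnorm(5)),
                     term_id = "GO:BAD"),
    "GO:BAD.*degenerate")
})

test_that("minimum-size filter is a hard threshold at min_size", {
  expr <- tiny_expression()
  ann <- tiny_annotation() # GO:1 n=10, GO:2 n=15, GO:3 n=9
  cats <- assemble_categories(expr, ann, "test", min_size = 10)
  expect_setequal(names(cats), c("GO:1", "GO:2")) # 9-pair term excluded
  expect_error(assemble_categories(expr, ann, "test", min_size = 50),
               "no category")
})

test_that("a 120-term map with 100 terms of size >= 10 yields exactly 100 categories", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:200)
  expr <- expression_table(genes, data.frame(c_transcript = rnorm(200),
                                             c_protein = rnorm(200)))
  sizes <- c(rep(12L, 100), rep(7L, 20))
  members <- lapply(seq_along(sizes), function(i) sample(genes, sizes[i]))
  ids <- sprintf("GO:T%03d", seq_along(sizes))
  names(members) <- ids
  ann <- annotation_map(
    data.frame(term_id = ids, name = ids,
               aspect = rep(ASPECTS_FOR_TESTS <- c("biological_process",
                                                   "molecular_function",
                                                   "cellular_component"),
                            length.out = length(ids))),
    members)
  cats <- assemble_categories(expr, ann, "c", min_size = 10)
  expect_length(cats, 100L)
})

test_that("duplicate categories collapse to one representative, idempotently", {
  expr <- tiny_expression()
  genes <- sprintf("BG%03d", 1:15)
  members <- list("GO:B" = genes, "GO:A" = genes,
                  "GO:C" = c(sprintf("BG%03d", 1:9), "LIN01"))
  ann <- annotation_map(
    data.frame(term_id = c("GO:B", "GO:A", "GO:C"),
               name = c("zeta set", "alpha set", "near duplicate"),
               aspect = "biological_process"),
    members)
  cats <- assemble_categories(expr, ann, "test", min_size = 10)
  reg <- category_regressions(expr, cats, "test")
  dd <- deduplicate_categories(reg, cats)
  rep_report <- attr(dd, "removal_report")
  # identical member sets: representative is earliest by name -> "alpha set"
  expect_true("GO:A" %in% dd$term_id)
  expect_false("GO:B" %in% dd$term_id)
  expect_equal(rep_report$removed_term_id, "GO:B")
  expect_equal(rep_report$retained_term_id, "GO:A")
  # 9/10 shared members is not a duplicate
  expect_true("GO:C" %in% dd$term_id)
  # idempotence
  dd2 <- deduplicate_categories(dd, cats)
  expect_equal(as.data.frame(dd2), as.data.frame(dd), ignore_attr = TRUE)
  expect_equal(nrow(attr(dd2, "removal_report")), 0L)
})

test_that("results are invariant to member ordering", {
  expr <- tiny_expression()
  pairs <- condition_pairs(expr, "test")
  rownames(pairs) <- pairs$gene_id
  g <- sprintf("BG%03d", 1:12)
  f1 <- fit_category_ols(pairs[g, ])
  f2 <- fit_category_ols(pairs[rev(g), ])
  expect_equal(f1[, -(1:3)], f2[, -(1:3)], tolerance = 1e-12)
})

test_that("overall regression: noiseless line gives 1; permuted proteins give the null", {
  genes <- sprintf("g%02d", 1:60)
  x <- seq(0, 3, length.out = 60)
  expr <- expression_table(genes, data.frame(c_transcript = x,
                                             c_protein = 0.5 * x + 4))
  expect_equal(suppressWarnings(overall_regression(expr, "c"))$r2, 1.0,
               tolerance = 1e-12)

  # permuted pairing: mean R2 over seeds near 1/(n-1)
  set.seed(55)
  n <- 60
  r2s <- replicate(2000, {
    xs <- rnorm(n)
    cor(xs, sample(0.5 * xs + rnorm(n, 0, 0.1)))^2
  })
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * sd(r2s) / sqrt(length(r2s)))
})

test_that("estimated slopes cover the generating truth at the nominal rate", {
  # CI coverage over many small synthetic categories
  set.seed(77)
  n_cat <- 200
  covered <- logical(n_cat)
  for (i in seq_len(n_cat)) {
    n <- sample(10:40, 1)
    x <- rnorm(n, 2, 1)
    true_slope <- runif(1, 0.2, 1)
    y <- true_slope * x + rnorm(n, 3, 0.7)
    fit <- fit_category_ols(data.frame(transcript = x, protein = y))
    covered[i] <- true_slope >= fit$slope_ci_low & true_slope <= fit$slope_ci_high
  }
  expect_gte(mean(covered), 0.90)
})
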