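fake_results <- function(r2, slope_lo, slope_hi, aspect = "biological_process",
                         ids = sprintf("GO:%d", seq_along(r2)),
                         names_ = paste("term", seq_along(r2))) {
  data.frame(term_id = ids, name = names_, aspect = aspect,
             n = 12L, r2 = r2, p = 0.05, slope = (slope_lo + slope_hi) / 2,
             slope_ci_low = slope_lo, slope_ci_high = slope_hi,
             intercept = 4, intercept_ci_low = 3.5, intercept_ci_high = 4.5,
             stringsAsFactors = FALSE)
}

test_that("identical conditions give perfect concordance", {
  a <- fake_results(c(0.5, 0.4, 0.3, 0.2), rep(0.1, 4), rep(0.9, 4))
  cmp <- compare_conditions(a, a)
  expect_true(all(cmp$per_term$slope_ci_overlap))
  expect_true(all(cmp$per_term$scaled_score == 0))
  expect_equal(cmp$by_aspect$spearman_rho, 1)
})

test_that("reversed ranks over 4 terms score {75, 25, 25, 75}", {
  a <- fake_results(c(0.8, 0.6, 0.4, 0.2), rep(0.1, 4), rep(0.9, 4))
  b <- fake_results(c(0.2, 0.4, 0.6, 0.8), rep(0.1, 4), rep(0.9, 4))
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$per_term$scaled_score, c(75, 25, 25, 75))
  expect_equal(cmp$by_aspect$spearman_rho, -1)
})

test_that("slope CI overlap uses closed intervals and is symmetric", {
  a <- fake_results(c(0.5, 0.4, 0.3), c(0.10, 0.10, 0.10), c(0.30, 0.30, 0.30))
  b <- fake_results(c(0.45, 0.35, 0.25), c(0.30, 0.31, 0.05), c(0.50, 0.50, 0.09))
  cmp <- compare_conditions(a, b)
  # touching at 0.30 counts as overlap; disjoint does not; nested does
  expect_equal(cmp$per_term$slope_ci_overlap, c(TRUE, FALSE, FALSE))
  sym <- compare_conditions(b, a)
  expect_equal(sym$per_term$slope_ci_overlap, cmp$per_term$slope_ci_overlap)
  expect_equal(sym$per_term$scaled_score, cmp$per_term$scaled_score)
  expect_equal(sym$by_aspect$spearman_rho, cmp$by_aspect$spearman_rho)
})

test_that("ranks are computed over shared terms only, per aspect, with average ties", {
  a <- rbind(fake_results(c(0.9, 0.5, 0.5, 0.1), rep(0, 4), rep(1, 4)),
             fake_results(0.7, 0, 1, aspect = "molecular_function",
                          ids = "GO:MF1", names_ = "mf only"))
  b <- fake_results(c(0.1, 0.5, 0.5, 0.9), rep(0, 4), rep(1, 4))
  cmp <- suppressMessages(compare_conditions(a, b))
  # the MF-only term is absent from the shared universe
  expect_false("GO:MF1" %in% cmp$per_term$term_id)
  expect_equal(sort(cmp$per_term$rank_a), sort(cmp$per_term$rank_b))
  expect_equal(cmp$per_term$rank_a, c(1, 2.5, 2.5, 4))
  # scaled score bounded by (n-1)/n * 100
  expect_true(all(cmp$per_term$scaled_score <= (4 - 1) / 4 * 100))
})

test_that("top discordant terms order by score with name tie-breaks and clamp k", {
  a <- fake_results(c(0.8, 0.6, 0.4, 0.2), rep(0, 4), rep(1, 4),
                    names_ = c("delta", "beta", "alpha", "gamma"))
  b <- fake_results(c(0.2, 0.4, 0.6, 0.8), rep(0, 4), rep(1, 4),
                    names_ = c("delta", "beta", "alpha", "gamma"))
  cmp <- compare_conditions(a, b)
  top <- top_discordant_terms(cmp, 2)
  expect_equal(top$scaled_score, c(75, 75))
  expect_equal(top$name, c("delta", "gamma")) # alphabetical among ties
  expect_equal(nrow(top_discordant_terms(cmp, 99)), 4L)
  # all-zero scores still return k terms
  same <- compare_conditions(a, a)
  expect_equal(nrow(top_discordant_terms(same, 3)), 3L)
  expect_true(all(top_discordant_terms(same, 3)$scaled_score == 0))
})

test_that("disjoint results produce an empty comparison with a notice", {
  a <- fake_results(c(0.5, 0.4, 0.3), rep(0, 3), rep(1, 3),
                    ids = c("GO:A1", "GO:A2", "GO:A3"))
  b <- fake_results(c(0.5, 0.4, 0.3), rep(0, 3), rep(1, 3),
                    ids = c("GO:B1", "GO:B2", "GO:B3"))
  expect_message(cmp <- compare_conditions(a, b), "no shared")
  expect_equal(nrow(cmp$per_term), 0L)
})

test_that("shared generating truth yields higher concordance than independent draws", {
  cfg <- synthetic_config(
    n_genes = 600L, conditions = c("human_ACC", "chimp_ACC"),
    categories_per_aspect = c(biological_process = 12L,
                              molecular_function = 0L,
                              cellular_component = 0L),
    category_sizes = rep(c(10L, 14L, 20L, 30L), 3),
    category_r2 = rep(c(0.6, 0.35, 0.15, 0.05), 3),
    duplicate_terms = c(biological_process = 0L, molecular_function = 0L,
                        cellular_component = 0L),
    seed = 202L)
  rho_shared <- numeric(5)
  rho_indep <- numeric(5)
  for (i in 1:5) {
    cfg$seed <- 202L + i
    ds <- generate_expression(cfg)
    fit_cond <- function(cond) {
      cats <- assemble_categories(ds$expression, ds$annotation, cond)
      category_regressions(ds$expression, cats, cond)
    }
    ra <- fit_cond("human_ACC")
    rb <- fit_cond("chimp_ACC")
    rho_shared[i] <- compare_conditions(ra, rb)$by_aspect$spearman_rho
    # independent: same structure, fresh dataset for the second condition
    cfg2 <- cfg
    cfg2$seed <- 900L + i
    ds2 <- generate_expression(cfg2)
    cats2 <- assemble_categories(ds2$expression, ds2$annotation, "chimp_ACC")
    rb2 <- category_regressions(ds2$expression, cats2, "chimp_ACC")
    rho_indep[i] <- compare_conditions(ra, rb2)$by_aspect$spearman_rho
  }
  expect_gt(mean(rho_shared), mean(rho_indep))
  expect_gt(mean(rho_shared), 0.4)
})
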