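test_that("generation is deterministic: same seed and config give byte-identical files", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  cfg <- small_config(seed = 7L)
  write_synthetic_dataset(generate_expression(cfg), d1)
  write_synthetic_dataset(generate_expression(cfg), d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # and a different seed changes the expression draws
  d3 <- file.path(tempdir(), "det3")
  write_synthetic_dataset(generate_expression(small_config(seed = 8L)), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "expression.tsv"))),
    unname(tools::md5sum(file.path(d3, "expression.tsv")))))
})

test_that("config validation rejects invalid targets and infeasible sizing", {
  expect_error(small_config(category_r2 = c(0.5, 0.2, 0.05, 0.4, 0.1, 1.2)),
               "0, 1")
  expect_error(small_config(covariate_coupling = c(mrna_half_life = -1.5)),
               "-1, 1")
  expect_error(synthetic_config(n_genes = 50L,
                                categories_per_aspect = c(biological_process = 6L,
                                                          molecular_function = 0L,
                                                          cellular_component = 0L),
                                category_sizes = rep(12L, 6),
                                category_r2 = rep(0.2, 6),
                                duplicate_terms = c(biological_process = 0L,
                                                    molecular_function = 0L,
                                                    cellular_component = 0L)) |>
                 generate_expression(),
               "sizing")
})

test_that("a noiseless category yields an estimated R2 of 1", {
  cfg <- small_config(category_r2 = c(1, 0.2, 0.05, 0.4, 0.1, 0.6),
                      overlap_fraction = 0)
  ds <- generate_expression(cfg)
  cats <- assemble_categories(ds$expression, ds$annotation,
                              cfg$conditions[1L])
  fit <- suppressWarnings(
    category_regressions(ds$expression, cats, cfg$conditions[1L]))
  expect_gt(fit$r2[fit$term_id == "GO:0000001"], 1 - 1e-6)
})

test_that("a zero-coupling category's R2 estimates follow the null mean 1/(n-1)", {
  # closed form: under independence the OLS R2 at size n is
  # Beta(1/2, (n-2)/2) with mean 1/(n-1); Monte Carlo over 10,000 draws
  n <- 10L
  set.seed(101)
  r2 <- replicate(10000, cor(rnorm(n), rnorm(n))^2)
  beta_mean <- 1 / (n - 1)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - beta_mean), 3 * se)

  # the generator reproduces this: a category with target R2 = 0
  cfg <- small_config(category_r2 = c(0, 0.2, 0.05, 0.4, 0.1, 0.6),
                      overlap_fraction = 0)
  r2_hat <- vapply(1:300, function(i) {
    cfg$seed <- i
    ds <- generate_expression(cfg)
    g <- ds$annotation$members[["GO:0000001"]]
    e <- as.data.frame(ds$expression)
    rownames(e) <- e$gene_id
    cor(e[g, 2], e[g, 3])^2
  }, numeric(1))
  expect_lt(abs(mean(r2_hat) - beta_mean),
            4 * sd(r2_hat) / sqrt(length(r2_hat)))
})

test_that("study-shaped defaults hit the configured genome-wide R2", {
  # default config targets global R2 = 0.07 in population; average the
  # estimate over several seeds to beat single-draw sampling error
  r2s <- vapply(1:5, function(s) {
    ds <- generate_expression(synthetic_config(seed = s))
    overall_regression(ds$expression, "human_ACC")$r2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.07), 0.03)
})

test_that("marginal distributions match the configured location and scale", {
  cfg <- synthetic_config(n_genes = 2000L, seed = 3L,
                          categories_per_aspect = c(biological_process = 3L,
                                                    molecular_function = 2L,
                                                    cellular_component = 1L),
                          category_sizes = c(10L, 12L, 15L, 10L, 14L, 10L),
                          category_r2 = c(0.5, 0.2, 0.05, 0.4, 0.1, 0.6),
                          duplicate_terms = c(biological_process = 0L,
                                              molecular_function = 0L,
                                              cellular_component = 0L))
  ds <- generate_expression(cfg)
  e <- as.data.frame(ds$expression)
  n <- nrow(e)
  # mean within ~4 standard errors; sd within a loose multiple of its se
  expect_lt(abs(mean(e$human_ACC_transcript) - 2), 4 / sqrt(n))
  expect_lt(abs(mean(e$human_ACC_protein) - 5), 4 / sqrt(n))
  expect_lt(abs(sd(e$human_ACC_transcript) - 1), 0.1)
  expect_lt(abs(sd(e$human_ACC_protein) - 1), 0.1)
})

test_that("ground truth reflects overlap dilution and duplicate fixtures", {
  cfg <- small_config(overlap_fraction = 0.3, seed = 11L)
  ds <- generate_expression(cfg)
  truth <- ds$truth
  gt <- ds$gene_truth
  rownames(gt) <- gt$gene_id
  # mixture identity: true R2 = (mean member sqrt(r2_home))^2, checked
  # against the recorded per-gene couplings
  for (tid in truth$term_id) {
    q <- mean(gt[ds$annotation$members[[tid]], "coupling_sqrt_r2"])
    expect_equal(truth$true_r2[truth$term_id == tid], q^2, tolerance = 1e-12)
  }
  # duplicate fixture: identical member set, recorded provenance
  dup <- truth[!is.na(truth$duplicate_of), ][1L, ]
  expect_setequal(ds$annotation$members[[dup$term_id]],
                  ds$annotation$members[[dup$duplicate_of]])
  # overlap exists: some gene belongs to > 1 category
  counts <- table(unlist(ds$annotation$members))
  expect_gt(max(counts), 1L)
})

test_that("covariates are positive, cover the configured fraction, and track coupling", {
  cfg <- small_config(seed = 21L, covariate_coverage = 0.6)
  ds <- generate_expression(cfg)
  covs <- generate_covariates(ds)
  expect_equal(nrow(covs), round(0.6 * cfg$n_genes))
  for (cl in setdiff(names(covs), "gene_id")) {
    expect_true(all(covs[[cl]] > 0))
  }
  expect_true(all(covs$gene_length >= 1 & covs$gene_length == round(covs$gene_length)))
})

test_that("covariate coupling is recovered on average across replicates", {
  # target Spearman -0.5 on mRNA half-life, 100 categories; the mean
  # recovered correlation over replicate draws must come within 0.15
  cfg <- synthetic_config(
    n_genes = 3000L,
    categories_per_aspect = c(biological_process = 100L,
                              molecular_function = 0L,
                              cellular_component = 0L),
    category_sizes = rep(12L, 100), category_r2 = seq(0.005, 0.6, length.out = 100),
    global_r2 = 0.07, overlap_fraction = 0,
    duplicate_terms = c(biological_process = 0L, molecular_function = 0L,
                        cellular_component = 0L),
    covariate_coupling = c(mrna_half_life = -0.5), covariate_coverage = 1,
    seed = 1L)
  rhos <- vapply(1:200, function(s) {
    cfg$seed <- s
    ds <- generate_expression(cfg)
    covs <- generate_covariates(ds)
    cm <- category_covariate_means(ds$annotation$members,
                                   as.data.frame(covs)[, c("gene_id", "mrna_half_life")],
                                   min_size = 2L)
    truth <- ds$truth
    spearman_brute(truth$true_r2[match(cm$term_id, truth$term_id)], cm$mean)
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.5)), 0.15)

  # and zero coupling stays near zero
  cfg$covariate_coupling <- c(mrna_half_life = 0)
  rho0 <- vapply(1:50, function(s) {
    cfg$seed <- s
    ds <- generate_expression(cfg)
    covs <- generate_covariates(ds)
    cm <- category_covariate_means(ds$annotation$members,
                                   as.data.frame(covs)[, c("gene_id", "mrna_half_life")],
                                   min_size = 2L)
    truth <- ds$truth
    spearman_brute(truth$true_r2[match(cm$term_id, truth$term_id)], cm$mean)
  }, numeric(1))
  expect_lt(abs(mean(rho0)), 0.1)
})
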