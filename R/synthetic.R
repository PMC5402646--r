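default_category_layout <- function() {
  # Study-shaped defaults: right-skewed per-aspect R^2 targets with maxima
  # near the strongest observed categories (~0.5 BP, ~0.47 MF, ~0.66 CC),
  # small categories carrying the strongest coupling (size and R^2
  # negatively associated), sizes >= 10.
  list(
    biological_process = list(
      sizes = c(10L, 11L, 12L, 13L, 15L, 17L, 19L, 22L, 25L, 29L, 34L, 40L, 47L, 55L),
      r2 = c(0.45, 0.32, 0.24, 0.18, 0.15, 0.13, 0.11, 0.10, 0.08, 0.07,
             0.06, 0.05, 0.04, 0.02)
    ),
    molecular_function = list(
      sizes = c(10L, 12L, 14L, 17L, 21L, 26L, 33L, 45L),
      r2 = c(0.42, 0.30, 0.20, 0.14, 0.10, 0.07, 0.05, 0.03)
    ),
    cellular_component = list(
      sizes = c(10L, 12L, 15L, 19L, 24L, 31L),
      r2 = c(0.60, 0.20, 0.10, 0.06, 0.03, 0.01)
    )
  )
}

#' Configuration for the synthetic paired-expression generator
#'
#' Describes a synthetic study: paired per-gene transcript/protein mean
#' log-expression in one or more conditions (species x region labels),
#' GO-like overlapping categories with known per-category predictivity,
#' and per-gene stability covariates with tunable coupling to category
#' predictivity.
#'
#' The generative model gives every gene a "home" group (one category, or
#' the background): transcript log-expression is
#' `N(transcript_mean, transcript_sd^2)` and protein log-expression is
#' `slope * transcript + intercept + noise` with
#' `slope = sqrt(r2_home) * protein_sd / transcript_sd` and noise variance
#' `protein_sd^2 * (1 - r2_home)`. All groups therefore share identical
#' marginals, and the population R-squared of *any* gene set -- including
#' overlapping categories and the whole table -- is the squared mean of
#' its members' `sqrt(r2_home)`. The background coupling is solved so the
#' genome-wide population R-squared equals `global_r2` exactly.
#'
#' @param n_genes number of gene pairs (default 815, a typical single
#'   region/species table size).
#' @param conditions character vector of condition labels.
#' @param categories_per_aspect named integer vector (three aspects).
#' @param category_sizes integer vector of member counts, concatenated in
#'   aspect order; default study-shaped layout.
#' @param category_r2 per-category target population R-squared in \[0, 1),
#'   aligned with `category_sizes`.
#' @param global_r2 target genome-wide population R-squared (default 0.07).
#' @param transcript_mean,transcript_sd,protein_mean,protein_sd log-scale
#'   location/scale of the two marginals.
#' @param overlap_fraction fraction of each category's members drawn from
#'   genes homed elsewhere (default 0.1), producing the overlapping
#'   membership typical of GO.
#' @param duplicate_terms named integer vector: per aspect, how many extra
#'   terms to emit whose member sets exactly duplicate an existing
#'   category (exercises the duplicate-removal rule).
#' @param covariate_coupling named numeric vector in \[-1, 1\]: target
#'   Spearman correlation between each category-mean covariate and the
#'   category's true R-squared.
#' @param covariate_coverage fraction of genes carried by the covariate
#'   table (default 471/815, the coverage of a typical merge with
#'   published stability measures).
#' @param min_category_size minimum category size the downstream analysis
#'   will use; defaults must not fall below it.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genes = 815L,
    conditions = "human_ACC",
    categories_per_aspect = NULL,
    category_sizes = NULL,
    category_r2 = NULL,
    global_r2 = 0.07,
    transcript_mean = 2, transcript_sd = 1,
    protein_mean = 5, protein_sd = 1,
    overlap_fraction = 0.1,
    duplicate_terms = c(biological_process = 3L, molecular_function = 1L,
                        cellular_component = 1L),
    covariate_coupling = c(gene_length = 0, transcription_rate = -0.3,
                           translation_rate = 0.3, mrna_half_life = -0.3,
                           protein_half_life = -0.2),
    covariate_coverage = 471 / 815,
    min_category_size = 10L,
    seed = 1L) {
  layout <- default_category_layout()
  if (is.null(categories_per_aspect)) {
    categories_per_aspect <-
      if (is.null(category_sizes)) vapply(layout, function(l) length(l$sizes), 1L)
      else stop("category_sizes given without categories_per_aspect")
  }
  categories_per_aspect <- categories_per_aspect[ASPECTS]
  names(categories_per_aspect) <- ASPECTS
  categories_per_aspect[is.na(categories_per_aspect)] <- 0L
  if (is.null(category_sizes)) {
    category_sizes <- unlist(lapply(layout, `[[`, "sizes"), use.names = FALSE)
    category_r2 <- category_r2 %||%
      unlist(lapply(layout, `[[`, "r2"), use.names = FALSE)
  }
  k <- sum(categories_per_aspect)
  if (length(category_sizes) != k) {
    stop("category_sizes must have length sum(categories_per_aspect) = ", k)
  }
  if (is.null(category_r2)) stop("category_r2 must be supplied")
  category_r2 <- rep_len(category_r2, k)
  if (any(category_sizes < 2L)) stop("all category sizes must be >= 2")
  if (any(category_r2 < 0 | category_r2 > 1)) {
    stop("all target R-squared values must lie in [0, 1]")
  }
  if (global_r2 < 0 || global_r2 >= 1) stop("global_r2 must lie in [0, 1)")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  if (any(abs(covariate_coupling) > 1)) {
    stop("covariate_coupling values must lie in [-1, 1]")
  }
  bad_cov <- setdiff(names(covariate_coupling), COVARIATE_COLUMNS)
  if (length(bad_cov)) stop("unknown covariate(s): ", paste(bad_cov, collapse = ", "))
  dup <- integer(3); names(dup) <- ASPECTS
  dup[names(duplicate_terms)] <- as.integer(duplicate_terms)
  if (any(dup > categories_per_aspect)) {
    stop("duplicate_terms cannot exceed categories_per_aspect")
  }
  if (covariate_coverage <= 0 || covariate_coverage > 1) {
    stop("covariate_coverage must lie in (0, 1]")
  }
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    stop("conditions must be a nonempty vector of unique labels")
  }
  structure(list(
    n_genes = as.integer(n_genes), conditions = as.character(conditions),
    categories_per_aspect = categories_per_aspect,
    category_sizes = as.integer(category_sizes), category_r2 = category_r2,
    global_r2 = global_r2,
    transcript_mean = transcript_mean, transcript_sd = transcript_sd,
    protein_mean = protein_mean, protein_sd = protein_sd,
    overlap_fraction = overlap_fraction, duplicate_terms = dup,
    covariate_coupling = covariate_coupling,
    covariate_coverage = covariate_coverage,
    min_category_size = as.integer(min_category_size),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_genes, " genes x ", length(x$conditions),
      " condition(s); ", sum(x$categories_per_aspect), " categories (+",
      sum(x$duplicate_terms), " duplicates); global R2 = ", x$global_r2,
      "; seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic paired expression dataset
#'
#' Draws the expression table, the annotation map (with overlapping
#' membership and optional duplicate terms) and a ground-truth record
#' holding every category's generating slope, intercept and population
#' R-squared (mixture-adjusted for overlap members). See
#' [synthetic_config()] for the generative model.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `expression`
#'   ([expression_table()]), `annotation` ([annotation_map()]), `truth`
#'   (data frame: term_id, aspect, size, target_r2, true_r2, true_slope,
#'   true_intercept, duplicate_of), `gene_truth` (per-gene home group and
#'   coupling) and `config`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- sum(config$categories_per_aspect)
  aspects <- rep(ASPECTS, times = config$categories_per_aspect)
  sizes <- config$category_sizes
  r2 <- config$category_r2
  core_sizes <- pmax(2L, ceiling((1 - config$overlap_fraction) * sizes))
  if (sum(core_sizes) > config$n_genes) {
    stop("sizing error: requested categories need ", sum(core_sizes),
         " core genes but only ", config$n_genes, " genes are available")
  }
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  with_seed(stage_seed(config$seed, "expression"), {
    # assign disjoint home blocks in shuffled gene order
    order_idx <- sample.int(n)
    q_gene <- numeric(n) # sqrt of home-group R2 per gene
    home <- rep(NA_character_, n)
    pos <- 1L
    core_members <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- order_idx[pos:(pos + core_sizes[j] - 1L)]
      pos <- pos + core_sizes[j]
      core_members[[j]] <- idx
      q_gene[idx] <- sqrt(r2[j])
      home[idx] <- sprintf("cat%03d", j)
    }
    bg <- order_idx[pos:n]
    n_bg <- length(bg)
    if (n_bg == 0L) stop("sizing error: no background genes left")
    # solve background coupling so the genome-wide population R2 is exact
    q_bg <- (sqrt(config$global_r2) * n - sum(q_gene)) / n_bg
    if (q_bg < 0 || q_bg >= 1) {
      stop("infeasible config: implied background coupling sqrt(R2) = ",
           signif(q_bg, 3), " outside [0, 1); adjust global_r2, category_r2 ",
           "or n_genes")
    }
    q_gene[bg] <- q_bg
    home[bg] <- "background"

    b_gene <- q_gene * config$protein_sd / config$transcript_sd
    a_gene <- config$protein_mean - b_gene * config$transcript_mean
    s_gene <- config$protein_sd * sqrt(1 - q_gene^2)

    vals <- list()
    for (cond in config$conditions) {
      x <- stats::rnorm(n, config$transcript_mean, config$transcript_sd)
      y <- a_gene + b_gene * x + stats::rnorm(n, 0, s_gene)
      vals[[paste0(cond, "_transcript")]] <- round(x, 6)
      vals[[paste0(cond, "_protein")]] <- round(y, 6)
    }
    expr <- expression_table(genes, as.data.frame(vals))

    # overlap members: fill each category up to its nominal size with genes
    # homed elsewhere
    members <- vector("list", k)
    for (j in seq_len(k)) {
      extra_n <- sizes[j] - core_sizes[j]
      pool <- setdiff(seq_len(n), core_members[[j]])
      extra <- if (extra_n > 0L) sample(pool, extra_n) else integer(0)
      members[[j]] <- genes[c(core_members[[j]], extra)]
    }

    # per-category population parameters of the realized (mixed) member set
    q_by_gene <- stats::setNames(q_gene, genes)
    true_q <- vapply(members, function(g) mean(q_by_gene[g]), numeric(1))
    true_slope <- true_q * config$protein_sd / config$transcript_sd
    true_r2 <- true_q^2
    true_intercept <- config$protein_mean - true_slope * config$transcript_mean

    term_id <- sprintf("GO:%07d", seq_len(k))
    term_name <- sprintf("synthetic %s category %03d",
                         gsub("_", " ", aspects), seq_len(k))
    truth <- data.frame(
      term_id = term_id, name = term_name, aspect = aspects, size = sizes,
      n_core = core_sizes, target_r2 = r2, true_r2 = true_r2,
      true_slope = true_slope, true_intercept = true_intercept,
      duplicate_of = NA_character_, stringsAsFactors = FALSE
    )
    names(members) <- term_id

    # duplicate-term fixtures: identical member sets under fresh term ids
    dup_rows <- list()
    d_id <- k
    for (a in ASPECTS) {
      nd <- config$duplicate_terms[[a]]
      if (nd == 0L) next
      src <- which(aspects == a)[seq_len(nd)]
      for (s in src) {
        d_id <- d_id + 1L
        tid <- sprintf("GO:%07d", d_id)
        members[[tid]] <- members[[term_id[s]]]
        dup_rows[[length(dup_rows) + 1L]] <- data.frame(
          term_id = tid,
          name = sprintf("synthetic %s duplicate of %s",
                         gsub("_", " ", a), term_id[s]),
          aspect = a, size = sizes[s], n_core = core_sizes[s],
          target_r2 = r2[s], true_r2 = true_r2[s], true_slope = true_slope[s],
          true_intercept = true_intercept[s], duplicate_of = term_id[s],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(dup_rows)) truth <- rbind(truth, do.call(rbind, dup_rows))

    annot <- annotation_map(truth[, c("term_id", "name", "aspect")], members)
    gene_truth <- data.frame(gene_id = genes, home = home,
                             coupling_sqrt_r2 = q_gene,
                             stringsAsFactors = FALSE)
    structure(list(expression = expr, annotation = annot, truth = truth,
                   gene_truth = gene_truth, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$expression), " genes, ",
      nrow(x$truth), " terms (", sum(!is.na(x$truth$duplicate_of)),
      " duplicates), conditions: ",
      paste(condition_labels(x$expression), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate per-gene stability covariates
#'
#' Draws gene length and the four synthesis/degradation covariates as
#' log-normal values whose category-level means track the categories' true
#' R-squared at the Spearman level requested by
#' `config$covariate_coupling`. Mechanism: each category receives a latent
#' normal score built from the normal scores of its true-R-squared rank
#' (weight `rho`) plus independent noise (weight `sqrt(1 - rho^2)`); genes
#' inherit their home category's latent value plus small gene-level noise,
#' and the covariate is a log-normal transform of the latent value.
#' Background genes draw independent latents. All rates and half-lives are
#' strictly positive by construction; gene lengths are integers >= 1.
#'
#' Only `round(covariate_coverage * n_genes)` genes appear in the table,
#' mimicking a merge with an external stability dataset that covers part
#' of the genome.
#'
#' @param dataset a `synthetic_dataset` from [generate_expression()].
#' @return a [covariate_table()] with all five covariate columns.
#' @export
generate_covariates <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  config <- dataset$config
  truth <- dataset$truth[is.na(dataset$truth$duplicate_of), , drop = FALSE]
  k <- nrow(truth)
  # log-scale baselines loosely matching published mammalian fibroblast
  # measurements (median transcription ~2 molecules/(cell*h), translation
  # ~40 molecules/(mRNA*h), mRNA half-life ~9 h, protein half-life ~46 h,
  # gene length ~24 kb)
  base <- c(gene_length = 24000, transcription_rate = 2,
            translation_rate = 40, mrna_half_life = 9, protein_half_life = 46)
  spread <- c(gene_length = 0.8, transcription_rate = 1.0,
              translation_rate = 1.0, mrna_half_life = 0.6,
              protein_half_life = 0.8)
  with_seed(stage_seed(config$seed, "covariates"), {
    s_cat <- stats::qnorm((rank(truth$true_r2, ties.method = "average") - 0.5) / k)
    home <- stats::setNames(dataset$gene_truth$home, dataset$gene_truth$gene_id)
    home_idx <- match(home, sprintf("cat%03d", seq_len(k))) # NA for background
    n <- config$n_genes
    vals <- list()
    for (cv in COVARIATE_COLUMNS) {
      rho <- config$covariate_coupling[cv]
      if (is.na(rho)) rho <- 0
      eta <- stats::rnorm(k)
      latent_cat <- rho * s_cat + sqrt(1 - rho^2) * eta
      latent <- ifelse(is.na(home_idx), stats::rnorm(n), latent_cat[home_idx]) +
        stats::rnorm(n, 0, 0.3)
      v <- exp(log(base[[cv]]) + spread[[cv]] * latent)
      if (cv == "gene_length") v <- pmax(1, round(v))
      vals[[cv]] <- round(v, 4)
    }
    keep <- sort(sample.int(n, round(config$covariate_coverage * n)))
    covariate_table(dataset$expression$gene_id[keep],
                    as.data.frame(vals)[keep, , drop = FALSE])
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression table (tab-delimited), the annotation map in both
#' GAF 2.2 and two-column form, the covariate table, the ground-truth
#' record (tab-delimited sidecar plus the config as YAML). File contents
#' are byte-identical across runs with the same config.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param covariates optional [covariate_table()]; generated via
#'   [generate_covariates()] when `NULL`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, covariates = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  covariates <- covariates %||% generate_covariates(dataset)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    annotation_gaf = file.path(dir, "annotation.gaf"),
    annotation_map = file.path(dir, "annotation_map.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "synthetic_config.yaml")
  )
  write_expression(dataset$expression, paths[["expression"]])
  write_annotations(dataset$annotation, paths[["annotation_gaf"]], "gaf")
  write_annotations(dataset$annotation, paths[["annotation_map"]], "two_column")
  write_covariates(covariates, paths[["covariates"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  cfg$categories_per_aspect <- as.list(cfg$categories_per_aspect)
  cfg$duplicate_terms <- as.list(cfg$duplicate_terms)
  cfg$covariate_coupling <- as.list(cfg$covariate_coupling)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
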