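# Small in-code fixtures shared across test files.

# tiny expression table: known collinear category + noise genes
tiny_expression <- function(n_extra = 20, seed = 42) {
  set.seed(seed)
  genes <- c(sprintf("LIN%02d", 1:10), sprintf("BG%03d", seq_len(n_extra)))
  x <- c(seq(1, 3, length.out = 10), rnorm(n_extra, 2, 1))
  y <- c(2 * x[1:10] + 1, rnorm(n_extra, 5, 1))
  expression_table(genes, data.frame(test_transcript = x, test_protein = y))
}

tiny_annotation <- function() {
  annotation_map(
    data.frame(
      term_id = c("GO:1", "GO:2", "GO:3"),
      name = c("collinear set", "background set", "small set"),
      aspect = c("molecular_function", "biological_process",
                 "cellular_component"),
      stringsAsFactors = FALSE),
    list("GO:1" = sprintf("LIN%02d", 1:10),
         "GO:2" = sprintf("BG%03d", 1:15),
         "GO:3" = sprintf("BG%03d", 1:9)))
}

# a quick study-shaped config scaled for unit tests; overrides win
small_config <- function(...) {
  defaults <- list(
    n_genes = 200L,
    categories_per_aspect = c(biological_process = 3L,
                              molecular_function = 2L,
                              cellular_component = 1L),
    category_sizes = c(10L, 12L, 15L, 10L, 14L, 10L),
    category_r2 = c(0.5, 0.2, 0.05, 0.4, 0.1, 0.6),
    global_r2 = 0.07,
    duplicate_terms = c(biological_process = 1L, molecular_function = 0L,
                        cellular_component = 0L))
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
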