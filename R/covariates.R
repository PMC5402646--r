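COVARIATE_COLUMNS <- c(
  "gene_length",        # bases
  "transcription_rate", # molecules/(cell*h)
  "translation_rate",   # molecules/(mRNA*h)
  "mrna_half_life",     # h
  "protein_half_life"   # h
)

#' Per-gene covariate table
#'
#' Holds gene length and molecular synthesis/degradation measures
#' (transcription rate in molecules/(cell*h), translation rate in
#' molecules/(mRNA*h), mRNA and protein half-lives in hours). Any subset
#' of the columns may be present; per-gene missing values are allowed and
#' are excluded pairwise downstream. Present values must be finite, rates
#' and half-lives strictly positive, lengths at least 1.
#'
#' @param genes character vector of unique gene identifiers.
#' @param values data frame with any subset of the columns `gene_length`,
#'   `transcription_rate`, `translation_rate`, `mrna_half_life`,
#'   `protein_half_life`.
#' @return object of class `covariate_table` (a data frame).
#' @export
covariate_table <- function(genes, values) {
  genes <- trimws(as.character(genes))
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in covariate table")
  values <- as.data.frame(values)
  unknown <- setdiff(names(values), COVARIATE_COLUMNS)
  if (length(unknown)) {
    stop("unrecognized covariate column(s): ", paste(unknown, collapse = ", "))
  }
  if (ncol(values) == 0L) stop("covariate table has no recognized columns")
  for (cl in names(values)) {
    v <- values[[cl]]
    if (!is.numeric(v)) stop("non-numeric covariate column: ", cl)
    if (any(!is.na(v) & !is.finite(v))) stop("non-finite values in ", cl)
    lower <- if (cl == "gene_length") 1 else 0
    if (any(v[!is.na(v)] < lower) ||
        (cl != "gene_length" && any(v[!is.na(v)] == 0))) {
      stop("covariate '", cl, "' must be ",
           if (cl == "gene_length") ">= 1" else "strictly positive")
    }
  }
  out <- cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE), values)
  rownames(out) <- NULL
  structure(out, class = c("covariate_table", "data.frame"))
}

#' Read a per-gene covariate table
#'
#' Tab-delimited with a header; a `gene_id` column (or first column) plus
#' any subset of `gene_length`, `transcription_rate`, `translation_rate`,
#' `mrna_half_life`, `protein_half_life`. Unrecognized columns are dropped
#' with a message. Zero or negative rates/half-lives are a hard error.
#'
#' @param path file path.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  id_column <- if ("gene_id" %in% names(raw)) "gene_id" else names(raw)[1L]
  keep <- intersect(names(raw), COVARIATE_COLUMNS)
  extra <- setdiff(names(raw), c(id_column, COVARIATE_COLUMNS))
  if (length(extra)) {
    message("read_covariates: ignoring unrecognized column(s): ",
            paste(extra, collapse = ", "))
  }
  if (!length(keep)) stop("no recognized covariate columns in ", path)
  absent <- setdiff(COVARIATE_COLUMNS, keep)
  if (length(absent)) {
    message("read_covariates: column(s) absent, dependent analyses will be ",
            "skipped: ", paste(absent, collapse = ", "))
  }
  covariate_table(raw[[id_column]], raw[, keep, drop = FALSE])
}

#' Write a per-gene covariate table
#' @param cov a [covariate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  stopifnot(inherits(cov, "covariate_table"))
  utils::write.table(as.data.frame(cov), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene lengths from a BED file
#'
#' Alternative gene-length source: reads a BED file (half-open, 0-based)
#' via \pkg{rtracklayer} and returns length = end - start per named
#' feature. Duplicate names keep the longest interval.
#'
#' @param path BED file path.
#' @return a [covariate_table()] with the single column `gene_length`.
#' @export
read_gene_lengths_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_lengths_bed() requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) stop("BED features must be named (column 4)")
  # GRanges width of an imported BED interval equals BED end - start
  best <- tapply(gr$width, nm, max)
  covariate_table(names(best), data.frame(gene_length = as.numeric(best)))
}
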