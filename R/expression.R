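#' Paired transcript/protein expression table
#'
#' The canonical in-memory container for paired per-gene mean
#' log-expression. One row per gene; for every condition label (a species
#' x brain-region combination such as `"human_ACC"`) the table carries a
#' `<condition>_transcript` and a `<condition>_protein` column of unitless
#' log abundances. Gene identifiers are unique and no retained row has a
#' missing value.
#'
#' @param genes character vector of unique gene identifiers.
#' @param values data frame (or matrix) of numeric columns named
#'   `<condition>_transcript` / `<condition>_protein`.
#' @return An object of class `expression_table` (a data frame with a
#'   `gene_id` column and a `conditions` attribute).
#' @seealso [read_expression()], [condition_pairs()]
#' @export
expression_table <- function(genes, values) {
  genes <- trimws(as.character(genes))
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  values <- as.data.frame(values)
  if (nrow(values) != length(genes)) stop("genes and values disagree in length")
  conds <- parse_condition_columns(names(values))
  for (cl in names(values)) {
    if (!is.numeric(values[[cl]])) {
      stop("non-numeric expression column: ", cl)
    }
  }
  out <- cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE), values)
  rownames(out) <- NULL
  structure(out, conditions = conds,
            class = c("expression_table", "data.frame"))
}

# Map column names to condition labels; every condition must contribute a
# transcript and a protein column.
parse_condition_columns <- function(nms) {
  tr <- grepl("_transcript$", nms)
  pr <- grepl("_protein$", nms)
  if (!all(tr | pr)) {
    stop("unrecognized expression columns (expected *_transcript / *_protein): ",
         paste(nms[!(tr | pr)], collapse = ", "))
  }
  ct <- sub("_transcript$", "", nms[tr])
  cp <- sub("_protein$", "", nms[pr])
  if (anyDuplicated(ct) || anyDuplicated(cp)) stop("duplicate condition columns")
  if (!setequal(ct, cp)) {
    stop("conditions without a complete transcript/protein column pair: ",
         paste(union(setdiff(ct, cp), setdiff(cp, ct)), collapse = ", "))
  }
  ct
}

#' Condition labels of an expression table
#' @param expr an [expression_table()].
#' @return character vector of condition labels.
#' @export
condition_labels <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  attr(expr, "conditions")
}

#' Complete transcript/protein pairs for one condition
#'
#' @param expr an [expression_table()].
#' @param condition one of [condition_labels()].
#' @return data frame with columns `gene_id`, `transcript`, `protein`;
#'   rows with a missing member of the pair are dropped.
#' @export
condition_pairs <- function(expr, condition) {
  stopifnot(inherits(expr, "expression_table"))
  if (!condition %in% condition_labels(expr)) {
    stop("unknown condition: ", condition, " (have: ",
         paste(condition_labels(expr), collapse = ", "), ")")
  }
  out <- data.frame(
    gene_id = expr$gene_id,
    transcript = expr[[paste0(condition, "_transcript")]],
    protein = expr[[paste0(condition, "_protein")]],
    stringsAsFactors = FALSE
  )
  out[stats::complete.cases(out), , drop = FALSE]
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> ", nrow(x), " genes, conditions: ",
      paste(condition_labels(x), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Read a paired expression table
#'
#' Reads tab-delimited text with a header: a gene identifier column
#' (default `gene_id`, first column otherwise) plus one
#' `<condition>_transcript` and one `<condition>_protein` column per
#' condition. Values are assumed to be log-transformed already; set
#' `log_transform = TRUE` for raw abundances, which applies
#' `log10(x + log_offset)`.
#'
#' Rows in which any retained expression value is missing are dropped (a
#' pair needs both molecules) and the count is reported via `message()`.
#' Duplicate gene identifiers and non-numeric expression values are hard
#' errors.
#'
#' @param path file path.
#' @param conditions optional character vector restricting which condition
#'   labels to load; default all found in the header.
#' @param id_column name of the gene identifier column.
#' @param log_transform apply `log10(x + log_offset)` to raw values
#'   (default `FALSE`: input is already log scale).
#' @param log_offset offset added before the log when `log_transform` is
#'   `TRUE` (default 1).
#' @return an [expression_table()].
#' @export
read_expression <- function(path, conditions = NULL, id_column = "gene_id",
                            log_transform = FALSE, log_offset = 1) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_column %in% names(raw)) id_column <- names(raw)[1L]
  genes <- trimws(as.character(raw[[id_column]]))
  vals <- raw[, setdiff(names(raw), id_column), drop = FALSE]
  found <- parse_condition_columns(names(vals))
  if (!is.null(conditions)) {
    missing_cond <- setdiff(conditions, found)
    if (length(missing_cond)) {
      stop("condition(s) absent from file: ", paste(missing_cond, collapse = ", "))
    }
    keep <- paste0(rep(conditions, each = 2L), c("_transcript", "_protein"))
    vals <- vals[, keep, drop = FALSE]
  }
  for (cl in names(vals)) {
    v <- vals[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "NA")
      stop("non-numeric expression in column '", cl, "' (e.g. row ",
           if (length(bad)) bad[1L] else "?", ")")
    }
  }
  complete <- stats::complete.cases(vals)
  dropped <- sum(!complete)
  if (dropped > 0L) {
    message("read_expression: dropped ", dropped,
            " row(s) with an incomplete transcript/protein pair")
  }
  expression_table(genes[complete], vals[complete, , drop = FALSE])
}

#' Write a paired expression table
#'
#' Tab-delimited, `gene_id` first, then the per-condition transcript and
#' protein columns. Inverse of [read_expression()].
#'
#' @param expr an [expression_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  utils::write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
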