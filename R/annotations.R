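#' Gene Ontology annotation map
#'
#' Term-level GO membership: one row of metadata per term (id, name,
#' aspect) plus the member gene set. Membership is taken as explicitly
#' provided; no propagation up the ontology graph is performed.
#'
#' @param terms data frame with columns `term_id`, `name`, `aspect`
#'   (`biological_process`, `molecular_function` or `cellular_component`).
#' @param members named list (names = `term_id`) of character vectors of
#'   member gene identifiers; duplicates within a term are collapsed.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(terms, members) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "name", "aspect") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term identifiers: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  }
  check_aspect(terms$aspect)
  if (!setequal(names(members), terms$term_id)) {
    stop("member list names must match term ids exactly")
  }
  members <- lapply(members[terms$term_id],
                    function(g) unique(trimws(as.character(g))))
  if (nrow(terms) == 0L) stop("empty annotation map")
  rownames(terms) <- NULL
  structure(list(terms = terms, members = members), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  tab <- table(factor(x$terms$aspect, levels = ASPECTS))
  cat("<annotation_map> ", nrow(x$terms), " terms (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "); ",
      length(unique(unlist(x$members, use.names = FALSE))),
      " distinct genes\n", sep = "")
  invisible(x)
}

#' Restrict an annotation map to a gene universe
#'
#' Drops member genes absent from `genes`; terms left with no members are
#' removed. The number of discarded gene-term links is attached as
#' attribute `n_dropped_links` and reported via `message()`.
#'
#' @param annot an [annotation_map()].
#' @param genes character vector of gene identifiers to keep.
#' @return a restricted `annotation_map`.
#' @export
restrict_annotation <- function(annot, genes) {
  stopifnot(inherits(annot, "annotation_map"))
  genes <- unique(trimws(as.character(genes)))
  before <- sum(lengths(annot$members))
  members <- lapply(annot$members, function(g) g[g %in% genes])
  keep <- lengths(members) > 0L
  dropped <- before - sum(lengths(members))
  if (dropped > 0L) {
    message("restrict_annotation: ignored ", dropped,
            " gene-term link(s) outside the expression table")
  }
  if (!any(keep)) stop("no annotated gene overlaps the expression table")
  out <- annotation_map(annot$terms[keep, , drop = FALSE], members[keep])
  attr(out, "n_dropped_links") <- dropped
  out
}

#' Read GO annotations
#'
#' Two formats are accepted:
#' \describe{
#'   \item{`gaf`}{GAF 2.x gene association files. Comment lines starting
#'     with `!` are skipped; columns 2 (gene id), 5 (GO id) and 9 (aspect
#'     code P/F/C) are used. GAF carries no term names, so names default to
#'     the term id unless `term_names` supplies them.}
#'   \item{`two_column`}{tab-delimited `gene_id`, `term_id`, with optional
#'     third (`aspect`, full label or P/F/C code) and fourth (`name`)
#'     columns; a header line is detected and skipped. When the file has no
#'     aspect column, `aspects` must map term ids to aspect labels.}
#' }
#' A term listed twice for the same gene yields a single membership (set
#' semantics). Unknown aspect codes and an empty resulting map are hard
#' errors.
#'
#' @param path file path.
#' @param format `"gaf"` or `"two_column"`.
#' @param expression optional [expression_table()]; when given, the map is
#'   restricted to its genes via [restrict_annotation()].
#' @param aspects named character vector term_id -> aspect, used when the
#'   two-column file lacks an aspect column.
#' @param term_names named character vector term_id -> human-readable name.
#' @return an [annotation_map()].
#' @export
read_annotations <- function(path, format = c("gaf", "two_column"),
                             expression = NULL, aspects = NULL,
                             term_names = NULL) {
  format <- match.arg(format)
  long <- if (format == "gaf") read_gaf_long(path) else
    read_two_column_long(path, aspects)
  if (nrow(long) == 0L) stop("empty annotation map: no usable rows in ", path)
  check_aspect(long$aspect)
  # aspect must be assigned exactly once per term
  asp <- tapply(long$aspect, long$term_id, function(a) unique(a))
  multi <- names(asp)[lengths(asp) > 1L]
  if (length(multi)) {
    stop("term(s) annotated with more than one aspect: ",
         paste(multi, collapse = ", "))
  }
  ids <- sort(unique(long$term_id))
  nm <- if (!is.null(term_names)) {
    unname(ifelse(is.na(term_names[ids]) | is.null(term_names[ids]),
                  ids, term_names[ids]))
  } else if (!is.null(long$name)) {
    vapply(ids, function(i) {
      n <- unique(long$name[long$term_id == i & !is.na(long$name)])
      if (length(n)) n[1L] else i
    }, character(1))
  } else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  terms <- data.frame(term_id = ids, name = nm,
                      aspect = vapply(asp[ids], `[`, character(1), 1L),
                      stringsAsFactors = FALSE)
  members <- split(long$gene_id, factor(long$term_id, levels = ids))
  out <- annotation_map(terms, members)
  if (!is.null(expression)) out <- restrict_annotation(out, expression$gene_id)
  out
}

read_gaf_long <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(), term_id = character(),
                      aspect = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short)) {
    stop("malformed GAF line(s) with fewer than 9 columns, e.g. line ", short[1L])
  }
  data.frame(
    gene_id = trimws(vapply(fields, `[`, character(1), 2L)),
    term_id = trimws(vapply(fields, `[`, character(1), 5L)),
    aspect = aspect_from_code(trimws(vapply(fields, `[`, character(1), 9L))),
    stringsAsFactors = FALSE
  )
}

read_two_column_long <- function(path, aspects) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "!",
                           colClasses = "character")
  # tolerate a header line
  if (nrow(raw) > 0L &&
      tolower(trimws(raw[1L, 1L])) %in% c("gene_id", "gene", "id")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (ncol(raw) < 2L) stop("two_column annotation file needs >= 2 columns")
  out <- data.frame(gene_id = trimws(raw[[1L]]), term_id = trimws(raw[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 3L) {
    a <- trimws(raw[[3L]])
    out$aspect <- ifelse(a %in% names(ASPECT_CODES), ASPECT_CODES[a], a)
  } else {
    if (is.null(aspects)) {
      stop("file has no aspect column; supply `aspects` (term_id -> aspect)")
    }
    out$aspect <- unname(aspects[out$term_id])
    if (anyNA(out$aspect)) {
      stop("aspect missing for term(s): ",
           paste(unique(out$term_id[is.na(out$aspect)]), collapse = ", "))
    }
  }
  if (ncol(raw) >= 4L) out$name <- trimws(raw[[4L]])
  out
}

#' Write an annotation map
#'
#' `format = "gaf"` emits a 17-column GAF 2.2 file (with a
#' `!gaf-version: 2.2` header; synthetic placeholder values in the columns
#' this package does not use). `format = "two_column"` emits
#' `gene_id<TAB>term_id<TAB>aspect<TAB>name` with a header line.
#'
#' @param annot an [annotation_map()].
#' @param path output path.
#' @param format `"gaf"` or `"two_column"`.
#' @param taxon NCBI taxon string used in the GAF taxon column.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path, format = c("gaf", "two_column"),
                              taxon = "taxon:9606") {
  stopifnot(inherits(annot, "annotation_map"))
  format <- match.arg(format)
  idx <- rep(seq_len(nrow(annot$terms)), lengths(annot$members))
  genes <- unlist(annot$members, use.names = FALSE)
  terms <- annot$terms[idx, , drop = FALSE]
  if (format == "two_column") {
    df <- data.frame(gene_id = genes, term_id = terms$term_id,
                     aspect = terms$aspect, name = terms$name,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rows <- data.frame(
      db = "SYNTH", db_object_id = genes, symbol = genes, qualifier = "enables",
      go_id = terms$term_id, reference = "SYNTH:0000001", evidence = "IEA",
      with_from = "", aspect = aspect_to_code(terms$aspect), name = "",
      synonym = "", type = "protein", taxon = taxon, date = "20260101",
      assigned_by = "SYNTH", extension = "", product_id = "",
      stringsAsFactors = FALSE
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("!gaf-version: 2.2", "!generated-by: gopredict"), con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
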