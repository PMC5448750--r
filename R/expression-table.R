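#' Expression-density table
#'
#' Container for a gene x age matrix of expression densities, as extracted
#' from a developmental in situ hybridization atlas. Densities are
#' dimensionless fractions (expressing pixels over pixels intersecting the
#' region) and must be non-negative; absent measurements are held as `NA`.
#'
#' @param values numeric matrix, genes in rows, ages in columns. `NA`
#'   encodes a missing measurement.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param age_labels character vector of unique, ordered developmental-stage
#'   labels; defaults to `colnames(values)`. Order is taken as given
#'   (embryonic stages are expected before postnatal ones but labels are not
#'   lexically sortable, so no reordering is attempted).
#'
#' @return An object of class `ExpressionTable`: a list with elements
#'   `values` (matrix with `gene_ids`/`age_labels` as dimnames), `gene_ids`,
#'   `age_labels` and `missing_mask` (logical matrix, `TRUE` where absent).
#' @export
expression_table <- function(values, gene_ids = rownames(values),
                             age_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(age_labels))
    stop("gene_ids and age_labels are required (or supply dimnames)")
  gene_ids <- as.character(gene_ids)
  age_labels <- as.character(age_labels)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(age_labels))
    stop("matrix dimensions do not match gene/age label counts")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(age_labels))
    stop("duplicate age label(s)")
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression density for gene '%s' at age '%s'",
                 gene_ids[neg[1, 1]], age_labels[neg[1, 2]]))
  dimnames(values) <- list(gene_ids, age_labels)
  structure(
    list(values = values, gene_ids = gene_ids, age_labels = age_labels,
         missing_mask = is.na(values)),
    class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d ages (%s)\n",
              length(x$gene_ids), length(x$age_labels),
              paste(x$age_labels, collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.ExpressionTable <- function(x) dim(x$values)

#' Developmental stages of the source atlas
#'
#' The seven ages at which the developing-brain atlas was sampled: four
#' embryonic and three postnatal stages.
#' @export
DEV_AGES <- c("E11.5", "E13.5", "E15.5", "E18.5", "P4", "P14", "P28")

#' Read an expression-density table from a delimited file
#'
#' Expects a header row whose first column names the gene identifier and
#' whose remaining columns are age labels. Cells reading `NaN`, `nan` or
#' blank are treated as missing data (both encodings occur in atlas
#' exports). Duplicate gene identifiers and negative densities are hard
#' errors.
#'
#' @param path file path.
#' @param sep field delimiter; by default inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @param quiet suppress the row/column count message.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, sep = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NaN", "nan", "NA", ""),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  if (ncol(df) < 3)
    stop("expected one id column plus at least two age columns")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric values beyond the recognised missing encodings")
  rownames(vals) <- ids
  tab <- expression_table(vals, ids, colnames(df)[-1])
  if (!quiet)
    message(sprintf("read %d genes x %d ages from %s",
                    nrow(vals), ncol(vals), path))
  tab
}

#' Drop genes with no expression value at any age
#'
#' Genes whose measurements are missing at every age carry no temporal
#' information and are removed before normalization. Retained genes keep
#' their input order. Idempotent.
#'
#' @param t an [expression_table()].
#' @return list with `table` (the filtered `ExpressionTable`) and `removed`
#'   (character vector of dropped gene ids, possibly empty).
#' @export
filter_all_missing <- function(t) {
  stopifnot(inherits(t, "ExpressionTable"))
  all_na <- rowSums(!t$missing_mask) == 0
  keep <- t$values[!all_na, , drop = FALSE]
  list(table = expression_table(keep, t$gene_ids[!all_na], t$age_labels),
       removed = t$gene_ids[all_na])
}

#' Write a tabular result to disk
#'
#' Dispatches on the object class: `ExpressionTable` / `NormalizedTable`
#' matrices go to delimited text (missing cells written as `NaN`, so they
#' round-trip through [read_expression_table()]); data frames go to
#' delimited text; everything else is serialized as JSON. All writers emit
#' UTF-8, newline-terminated files.
#'
#' @param obj object to serialize.
#' @param path output path.
#' @param format one of `"tsv"`, `"csv"`, `"json"`; default inferred from
#'   the extension.
#' @export
write_table <- function(obj, path,
                        format = c("auto", "tsv", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, TRUE)) "csv"
      else if (grepl("\\.json$", path, TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- if (inherits(obj, c("ExpressionTable", "NormalizedTable"))) {
    data.frame(gene_id = obj$gene_ids,
               as.data.frame(obj$values, check.names = FALSE),
               check.names = FALSE)
  } else if (is.matrix(obj)) {
    as.data.frame(obj, check.names = FALSE)
  } else {
    as.data.frame(obj, check.names = FALSE)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NaN",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
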