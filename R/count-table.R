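# Count tables are plain base matrices, samples in rows, taxa in columns,
# with dimnames; per-sample depth is the row sum. Kept deliberately
# unclassed so they compose with vegan/picante/glmnet without coercion.

#' Validate a samples-by-taxa count table
#'
#' @param counts Integer matrix, samples in rows, taxa in columns, with
#'   row and column names.
#' @return The validated matrix (storage mode coerced to integer-valued
#'   numeric), invisibly classed as a plain matrix.
#' @export
as_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated taxon ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"
  counts
}

#' Per-sample sequencing depth
#'
#' @param counts Count table (see [as_count_table()]).
#' @return Named numeric vector of row sums.
#' @export
sample_depths <- function(counts) rowSums(counts)

#' Read / write count tables and metadata as TSV
#'
#' `write_count_tsv()` stores samples in rows with a leading `sample_id`
#' column; `read_count_tsv()` inverts it.
#'
#' @param counts Count table.
#' @param path File path.
#' @return `read_count_tsv()` returns a validated count matrix.
#' @export
write_count_tsv <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_count_table(m)
}

#' Write a count table as BIOM-format JSON
#'
#' Uses the BIOM v1 (JSON) representation via the biomformat package;
#' note BIOM stores taxa ("observations") in rows, so the table is
#' transposed on the way out and back.
#'
#' @param counts Count table (samples x taxa).
#' @param path File path.
#' @return `read_count_biom()` returns a validated samples-by-taxa matrix.
#' @export
write_count_biom <- function(counts, path) {
  b <- biomformat::make_biom(t(counts))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' @rdname write_count_biom
#' @export
read_count_biom <- function(path) {
  b <- biomformat::read_biom(path)
  m <- t(as(biomformat::biom_data(b), "matrix"))
  as_count_table(m)
}

#' @rdname write_count_tsv
#' @param meta Metadata data.frame with a `sample_id` column.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
}
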