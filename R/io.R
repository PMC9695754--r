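sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression table
#'
#' Reads a TSV/CSV with a header row of gene ids and a first column of
#' sample ids (or the transpose, with `orientation = "genes_by_samples"`).
#' Duplicate ids and non-numeric cells are rejected with the offending
#' coordinates.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @param orientation `"samples_by_genes"` (default) or
#'   `"genes_by_samples"`.
#' @return Numeric matrix samples x genes with dimnames.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids))
    stop(sprintf("duplicated row id(s): %s",
                 paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  if (anyDuplicated(col_ids))
    stop(sprintf("duplicated column id(s): %s",
                 paste(unique(col_ids[duplicated(col_ids)]), collapse = ", ")))
  M <- matrix(NA_real_, nrow(df), length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at data row %d (line %d), column '%s'",
                   bad[1L], bad[1L] + 1L, col_ids[j]))
    if (anyNA(v))
      stop(sprintf("missing value at data row %d, column '%s'",
                   which(is.na(v))[1L], col_ids[j]))
    M[, j] <- v
  }
  if (orientation == "genes_by_samples") M <- t(M)
  M
}

#' Read a modulator table
#'
#' TSV/CSV with first column sample id and one named column per
#' characteristic; missing values are rejected.
#'
#' @param path file path.
#' @return A [modulator_table()].
#' @export
read_modulator_table <- function(path) {
  M <- read_expression_table(path)
  modulator_table(M)
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a per-sample edge list
#'
#' Long-format TSV with columns sample, regulator, target, coefficient,
#' effect; full `%.17g` precision so a round trip is exact.
#'
#' @param edges data.frame from [edge_records()].
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  out <- edges
  for (cl in c("coefficient", "effect"))
    if (cl %in% names(out)) out[[cl]] <- sprintf("%.17g", out[[cl]])
  write_table_tsv(out, path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c("coefficient", "effect", "beta"))
    if (cl %in% names(df)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Write / read a numeric matrix with row ids (loadings, similarity)
#'
#' @param M numeric matrix with rownames.
#' @param path output path.
#' @param id_column name for the id column.
#' @export
write_matrix_tsv <- function(M, path, id_column = "id") {
  df <- data.frame(rownames(M),
                   apply(M, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(M))
  write_table_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  read_expression_table(path)
}
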