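#' Read a tab-separated table with a header row
#'
#' All pipeline tables are UTF-8 TSV with a header; decimal separator is
#' always a dot.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a tab-separated table with a header row
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# matrix -> data.frame with an id column first
mat_to_df <- function(m, id_name) {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  rownames(df) <- NULL
  df
}

df_to_mat <- function(df, id_col = 1) {
  m <- as.matrix(df[, -id_col, drop = FALSE])
  rownames(m) <- as.character(df[[id_col]])
  m
}
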