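#' Read and write genus count tables as TSV
#'
#' Count tables are plain numeric matrices, rows = samples, columns = genera,
#' stored as tab-separated text with sample ids in the first column
#' (`sample_id` header).
#'
#' @param path file path.
#' @return `read_count_tsv()` returns the counts matrix.
#' @export
read_count_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("count TSV must have a leading `sample_id` column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  assert_count_table(m, "counts")
  m
}

#' @param counts samples x taxa matrix with dimnames.
#' @rdname read_count_tsv
#' @export
write_count_tsv <- function(counts, path) {
  assert_count_table(counts, "counts")
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' @param path file path to a TSV with at least a `sample_id` column.
#' @return a data frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata TSV must have a `sample_id` column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in metadata")
  df
}
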