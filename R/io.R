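#' Read an OTU table from TSV
#'
#' On-disk convention: taxa as rows, samples as columns, first column the
#' OTU identifier (matching tree tip labels); lines starting with `#` are
#' provenance comments. Returned in the in-memory convention used
#' throughout the package: samples x OTUs.
#'
#' @param path TSV file.
#' @return Numeric matrix, samples x OTUs, with dimnames.
#' @export
read_otu_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  t(m)
}

#' Write an OTU table to TSV (taxa x samples)
#'
#' @param x Samples x OTUs matrix.
#' @param path Output file.
#' @param id_column Name of the OTU id column (default `"otu_id"`).
#' @param header Optional provenance comment lines (written with `#`).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, id_column = "otu_id", header = NULL) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  tx <- t(x)
  df <- data.frame(id = rownames(tx), tx, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples-x-fields TSV (outcome or covariates)
#'
#' First column is the sample identifier; remaining columns are numeric
#' fields. `#` lines are skipped.
#'
#' @param path TSV file.
#' @return data.frame with rownames set to the sample ids.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- as.character(tab[[1]])
  tab[, -1, drop = FALSE]
}

#' Write a samples-x-fields TSV
#'
#' @param df data.frame (rownames = sample ids) or named vector.
#' @param path Output file.
#' @param id_column Name for the id column.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path, id_column = "sample_id",
                               header = NULL) {
  if (is.null(dim(df))) df <- data.frame(value = df)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  out <- data.frame(id = rownames(df), df, check.names = FALSE)
  names(out)[1] <- id_column
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a counts matrix (samples x OTUs) with a sample table by id; errors
# list the offending ids. Detects a transposed count table by checking
# whether the sample ids match the OTU axis instead.
align_samples <- function(counts, sample_ids) {
  have <- rownames(counts)
  if (is.null(have)) {
    if (nrow(counts) != length(sample_ids)) {
      stop("count table has no sample names and a different sample count ",
           "than the outcome/covariate table")
    }
    rownames(counts) <- sample_ids
    return(counts)
  }
  missing <- setdiff(sample_ids, have)
  if (length(missing)) {
    if (all(sample_ids %in% colnames(counts))) {
      stop("sample ids match the OTU axis of the count table; the table ",
           "appears transposed (expected taxa as rows, samples as columns ",
           "on disk)")
    }
    stop("samples absent from the count table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  counts[sample_ids, , drop = FALSE]
}
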