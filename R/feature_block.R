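#' Construct a feature block
#'
#' A feature block is a named sample-by-feature numeric matrix carrying the
#' data-combination label it contributes to (e.g. `"Diet"`, `"16S_B"`,
#' `"MGm_B1"`, `"LC-MS"`, `"GRS"`). Missingness is represented block-wise:
#' samples absent from a block are simply not rows of it.
#'
#' @param values numeric matrix, samples as rows (rownames = sample ids),
#'   features as columns (unique colnames).
#' @param label character scalar, the block label.
#' @return an object of class `feature_block`.
#' @export
feature_block <- function(values, label) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("feature block '%s' needs sample rownames and feature colnames", label)
  if (anyDuplicated(colnames(values)))
    stopf("duplicate feature names in block '%s'", label)
  structure(list(label = label, values = values), class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block '%s': %d samples x %d features>\n",
              x$label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$values)

block_samples <- function(block) rownames(block$values)

#' Write / read a feature block as TSV
#'
#' Samples as rows; first column `sample_id`, then one column per feature.
#'
#' @param block a [feature_block()].
#' @param path file path.
#' @return `path` (writer) or a `feature_block` (reader), invisibly for the writer.
#' @export
write_feature_block_tsv <- function(block, path) {
  df <- data.frame(sample_id = rownames(block$values), block$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_block_tsv
#' @param label block label to attach on read.
#' @export
read_feature_block_tsv <- function(path, label) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  feature_block(m, label)
}
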