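#' Attach population labels from a sample-label TSV
#'
#' Reads a two-column tab-separated file (`sample_id<TAB>label`, no header)
#' and attaches the labels to a genotype matrix. Labels are matched
#' case-insensitively against the vocabulary `wild`, `vinifera`, `hybrid`
#' and stored in lowercase. Samples absent from the file are labelled
#' `"unknown"`; file entries naming samples absent from the matrix trigger a
#' warning and are ignored.
#'
#' @param path Path to the label TSV.
#' @param x A [geno_matrix].
#' @return `x` with its `labels` field populated.
#' @export
read_labels <- function(path, x) {
  stopifnot(inherits(x, "geno_matrix"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  labels <- rep("unknown", n_samples(x))
  if (file.size(path) > 0L) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(tab) < 2L) {
      stop("label file must have two tab-separated columns", call. = FALSE)
    }
    lab <- tolower(tab[[2]])
    bad <- setdiff(unique(lab), setdiff(label_vocabulary, "unknown"))
    if (length(bad)) {
      stop("label(s) outside vocabulary {wild, vinifera, hybrid}: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx <- match(tab[[1]], x$samples)
    if (anyNA(idx)) {
      warning("label file names sample(s) absent from the matrix: ",
              paste(tab[[1]][is.na(idx)], collapse = ", "), call. = FALSE)
    }
    labels[idx[!is.na(idx)]] <- lab[!is.na(idx)]
  }
  x$labels <- labels
  x
}

#' Write the sample-label TSV for a genotype matrix
#'
#' @param x A [geno_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  utils::write.table(
    data.frame(sample = x$samples, label = x$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
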