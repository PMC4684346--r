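#' Construct a paired feature/response dataset
#'
#' Light container pairing a samples x features matrix with a samples x
#' responses matrix, row-aligned by sample identifier.
#'
#' @param x numeric feature matrix with row names as sample IDs.
#' @param y numeric response matrix with matching row names.
#' @return an object of class `"cmrf_data"`.
#' @export
new_cmrf_data <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("'x' and 'y' must have the same rows")
  if (nrow(x) < 2) stop("need at least two samples")
  if (ncol(x) < 1 || ncol(y) < 1) stop("need at least one feature and one response")
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (is.null(rownames(y))) rownames(y) <- rownames(x)
  if (!identical(rownames(x), rownames(y))) stop("row names of 'x' and 'y' differ")
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("response_", seq_len(ncol(y)))
  structure(list(x = x, y = y, sample_ids = rownames(x),
                 feature_names = colnames(x), response_names = colnames(y)),
            class = "cmrf_data")
}

#' @export
print.cmrf_data <- function(x, ...) {
  cat("Dataset:", nrow(x$x), "samples,", ncol(x$x), "features,",
      ncol(x$y), "responses\n")
  invisible(x)
}

# read one delimited matrix: header row, leading sample-ID column, numeric
# cells elsewhere; a non-numeric cell that is not the missing token is fatal
# and named by row/column.
.read_matrix <- function(path, sep, na_token) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  if (ncol(raw) < 2) stop(path, ": expected a sample-ID column plus data")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop(path, ": duplicated sample IDs")
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1,
              dimnames = list(ids, colnames(raw)[-1]))
  for (j in 2:ncol(raw)) {
    cell <- raw[[j]]
    is_na <- cell %in% na_token | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !is_na)
    if (length(bad))
      stop(path, ": non-numeric value '", cell[bad[1]], "' at row ",
           bad[1], " (sample ", ids[bad[1]], "), column '",
           colnames(raw)[j], "'")
    val[is_na] <- NA_real_
    m[, j - 1] <- val
  }
  m
}

#' Read a paired feature/response dataset from delimited text
#'
#' Reads two delimited matrices (header row, leading sample-ID column),
#' aligns them on the intersection of sample IDs — always by ID, never by
#' position — preserving the feature file's order, and by default drops
#' samples with any missing response. Counts of dropped samples are
#' reported via `message()`.
#'
#' @param features_path,responses_path paths to the two files.
#' @param sep field delimiter (default `","`; use `"\t"` for TSV).
#' @param na_token string(s) treated as missing (default `"NA"`).
#' @param complete_cases drop samples with missing responses
#'   (default `TRUE`).
#' @return a `"cmrf_data"` object.
#' @export
read_dataset <- function(features_path, responses_path, sep = ",",
                         na_token = "NA", complete_cases = TRUE) {
  xm <- .read_matrix(features_path, sep, na_token)
  ym <- .read_matrix(responses_path, sep, na_token)
  common <- intersect(rownames(xm), rownames(ym))
  if (!length(common))
    stop("no overlapping sample IDs between '", features_path, "' and '",
         responses_path, "'")
  dropped_x <- nrow(xm) - length(common)
  dropped_y <- nrow(ym) - length(common)
  if (dropped_x + dropped_y > 0)
    message("dropped ", dropped_x, " feature-only and ", dropped_y,
            " response-only samples; ", length(common), " remain")
  # keep the feature file's row order
  common <- rownames(xm)[rownames(xm) %in% common]
  ds <- new_cmrf_data(xm[common, , drop = FALSE], ym[common, , drop = FALSE])
  if (complete_cases) ds <- complete_case_filter(ds)
  ds
}

#' Restrict a dataset to samples with complete responses
#'
#' Keeps only samples with a non-missing value for every response in
#' `responses` (all responses by default); the input is untouched.
#'
#' @param data a `"cmrf_data"` object.
#' @param responses indices or names of the responses that must be
#'   observed; default all.
#' @return a filtered `"cmrf_data"`; an empty result is an error.
#' @export
complete_case_filter <- function(data, responses = NULL) {
  stopifnot(inherits(data, "cmrf_data"))
  ysub <- if (is.null(responses)) data$y
          else data$y[, responses, drop = FALSE]
  keep <- rowSums(is.na(ysub)) == 0
  if (!any(keep)) stop("no samples with complete responses remain")
  dropped <- sum(!keep)
  if (dropped > 0)
    message("dropped ", dropped, " samples with missing responses")
  new_cmrf_data(data$x[keep, , drop = FALSE], data$y[keep, , drop = FALSE])
}

#' Write a dataset back to delimited text
#'
#' Inverse of [read_dataset()]: writes the feature and response matrices
#' with a leading `sample_id` column, at 17 significant digits so that a
#' read/write round trip reproduces the values exactly.
#'
#' @param data a `"cmrf_data"` object.
#' @param features_path,responses_path output paths.
#' @param sep field delimiter.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(data, features_path, responses_path, sep = ",") {
  stopifnot(inherits(data, "cmrf_data"))
  wr <- function(m, path) {
    fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    fm[is.na(m)] <- "NA"
    df <- data.frame(sample_id = rownames(m), fm, stringsAsFactors = FALSE,
                     check.names = FALSE)
    colnames(df) <- c("sample_id", colnames(m))
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  wr(data$x, features_path)
  wr(data$y, responses_path)
  invisible(c(features_path, responses_path))
}
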