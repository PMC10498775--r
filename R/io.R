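# Delimited-text input/output for response matrices and result tables.

#' Read a dichotomous response matrix from CSV
#'
#' Expects a comma-delimited file with a header row of item ids and one
#' row per person, the first column holding person ids.  Cells must be 0,
#' 1, or one of the configured missing codes (the 6 = not reached / 9 = no
#' response convention of large-scale assessments is the default).
#' Cleaning policies:
#' * `"drop"` (default): any person whose row contains a missing code is
#'   removed entirely;
#' * `"keep"`: missing-coded cells become `NA` and are simply skipped in
#'   the likelihood.
#'
#' @param path file path.
#' @param missing_codes numeric codes treated as missing (default `c(6, 9)`).
#' @param exclusion `"drop"` or `"keep"`.
#' @return integer matrix with person ids as rownames and item ids as
#'   colnames; `NA` marks missing cells (under `"keep"`).
#' @export
read_response_matrix <- function(path, missing_codes = c(6, 9),
                                 exclusion = c("drop", "keep")) {
  exclusion <- match.arg(exclusion)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a person-id column plus item columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("person ids are not unique")
  X <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(X), nrow(X), ncol(X)))
  bad <- which(is.na(num) | !(num %in% c(0, 1, missing_codes)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unparseable or unknown cell value '%s' at row %d (person %s), column %d (%s)",
                 X[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 bad[1, 2], colnames(df)[-1][bad[1, 2]]))
  miss <- matrix(num %in% missing_codes, nrow(num))
  num[miss] <- NA
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (exclusion == "drop") {
    keep <- rowSums(miss) == 0L
    num <- num[keep, , drop = FALSE]
  }
  storage.mode(num) <- "integer"
  num
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_response_matrix()]: person ids in the first column,
#' item ids as the header.  `NA` cells are written as the first missing
#' code.  Round trips are lossless for 0/1/missing matrices.
#'
#' @param x response matrix (0/1/NA or raw codes).
#' @param path output file.
#' @param missing_code code used to serialize `NA` cells.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(x, path, missing_code = 9) {
  x <- as.matrix(x)
  ids <- rownames(x) %||% paste0("P", seq_len(nrow(x)))
  out <- as.data.frame(x)
  out[] <- lapply(out, function(col) {
    col[is.na(col)] <- missing_code
    # write integers without decimal points
    ifelse(col == as.integer(col), format(as.integer(col)), format(col))
  })
  df <- cbind(data.frame(person = ids), out)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export item characteristic curves as a long table
#'
#' Evaluates [icc()] for each item on an ability grid and returns a
#' long-format data frame (item, theta, p) ready for any plotting front
#' end.
#'
#' @param family model family.
#' @param items data frame of item parameters, one row per item (columns
#'   as in [item_params()]; missing columns take their defaults).
#' @param theta_grid finite ability grid.
#' @return data.frame with columns `item`, `theta`, `p`.
#' @export
export_icc_curves <- function(family, items,
                              theta_grid = seq(-4, 4, length.out = 81)) {
  stopifnot(all(is.finite(theta_grid)))
  items <- as.data.frame(items)
  ids <- rownames(items)
  if (is.null(ids) || identical(ids, as.character(seq_len(nrow(items)))))
    ids <- paste0("I", seq_len(nrow(items)))
  out <- lapply(seq_len(nrow(items)), function(j)
    data.frame(item = ids[j], theta = theta_grid,
               p = icc(family, theta_grid, as.list(items[j, ]))))
  do.call(rbind, out)
}
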