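#' Write a bin-count matrix as TSV
#'
#' Tab-separated with a header row: `site_id`, `bin_index` (0-based), then
#' one column per experiment labelled by its experiment label.
#'
#' @param M A `BinCountMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(M, path) {
  stopifnot(inherits(M, "BinCountMatrix"))
  df <- data.frame(site_id = rep(M$site_ids, each = M$n_bins),
                   bin_index = M$bin_index,
                   stringsAsFactors = FALSE)
  m <- M$counts
  colnames(m) <- M$experiments$label
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE,
                                digits = 15) else col
  }), sep = "\t"))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a bin-count matrix from TSV
#'
#' Inverse of [write_count_matrix()]. Optional `experiments` metadata (a
#' data.frame with `label` and typically `factor`, `context`) is matched
#' to the experiment columns by label.
#'
#' @param path Path to a matrix TSV.
#' @param experiments Optional experiment metadata data.frame.
#' @return A `BinCountMatrix`.
#' @export
read_count_matrix <- function(path, experiments = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("site_id", "bin_index") %in% colnames(df))) {
    stop("matrix TSV needs 'site_id' and 'bin_index' columns")
  }
  exp_cols <- setdiff(colnames(df), c("site_id", "bin_index"))
  if (length(exp_cols) == 0L) stop("no experiment columns in ", path)
  site_ids <- unique(df$site_id)
  n_bins <- length(unique(df$bin_index))
  o <- order(match(df$site_id, site_ids), df$bin_index)
  df <- df[o, , drop = FALSE]
  if (nrow(df) != length(site_ids) * n_bins) {
    stop("matrix is ragged: rows != n_sites * n_bins")
  }
  m <- as.matrix(df[, exp_cols, drop = FALSE])
  if (!is.null(experiments)) {
    if (!("label" %in% colnames(experiments)) ||
        !all(exp_cols %in% experiments$label)) {
      stop("experiments metadata must cover every matrix column by label")
    }
    experiments <- experiments[match(exp_cols, experiments$label), ,
                               drop = FALSE]
    rownames(experiments) <- NULL
  }
  new_bin_count_matrix(m, site_ids, n_bins, experiments = experiments)
}

# Deterministic TSV writer for data.frames (LF, no quotes, header row).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE,
                                  digits = 15)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
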