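#' Read a BED file of genomic intervals
#'
#' Parses BED3+ (tab-separated) into a `GRanges`. BED coordinates are
#' 0-based half-open; the returned `GRanges` follows the usual Bioconductor
#' 1-based closed convention, so `start(gr) == bed_start + 1` and
#' `end(gr) == bed_end`. Name (column 4) and score (column 5) are retained
#' as metadata columns when present; strand is ignored throughout the
#' package (binding-site logic is strandless). `track`, `browser` and `#`
#' comment lines are tolerated and skipped.
#'
#' @param path Path to a BED file.
#' @param layout Optional `Seqinfo` genome layout (see [genome_layout()]).
#'   When supplied, records are validated against it.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive
#'   (as in many publication supplementary tables) and are converted to the
#'   internal convention on read.
#' @param on_missing_chrom What to do with records on chromosomes absent
#'   from `layout`: `"error"` (default) or `"drop"`.
#' @param clip Truncate intervals exceeding chromosome bounds instead of
#'   erroring.
#' @param drop_chroms Character vector of chromosome names to filter out
#'   (e.g. `"chrY"`).
#' @param label Label for the set; defaults to the file name stem.
#' @return A `GRanges`, sorted as in the file, with `metadata(gr)$label`
#'   set. An empty file yields an empty `GRanges` with a warning.
#' @export
read_bed <- function(path, layout = NULL, one_based = FALSE,
                     on_missing_chrom = c("error", "drop"), clip = FALSE,
                     drop_chroms = NULL, label = NULL) {
  on_missing_chrom <- match.arg(on_missing_chrom)
  if (is.null(label)) {
    label <- sub("\\.(bed|txt|tsv)$", "", basename(path), ignore.case = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no intervals in ", path)
    gr <- GenomicRanges::GRanges()
    if (!is.null(layout)) gr <- set_layout(gr, layout)
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", lineno[which(nf < 3L)[1L]], " of ", path,
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0)
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1L]], " of ", path,
         ": non-integer coordinates")
  }
  if (one_based) s0 <- s0 - 1
  bad <- s0 < 0 | s0 >= e0
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1L]], " of ", path,
         ": invalid interval (start >= end or start < 0)")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
  if (any(nf >= 4L)) {
    nm <- rep(NA_character_, length(gr))
    nm[nf >= 4L] <- vapply(fields[nf >= 4L], `[[`, character(1), 4L)
    S4Vectors::mcols(gr)$name <- nm
  }
  if (any(nf >= 5L)) {
    sc <- rep(NA_real_, length(gr))
    sc[nf >= 5L] <- suppressWarnings(
      as.numeric(vapply(fields[nf >= 5L], `[[`, character(1), 5L)))
    S4Vectors::mcols(gr)$score <- sc
  }
  if (!is.null(drop_chroms)) {
    gr <- gr[!(as.character(GenomicRanges::seqnames(gr)) %in% drop_chroms)]
    GenomeInfoDb::seqlevels(gr) <- setdiff(GenomeInfoDb::seqlevels(gr),
                                           drop_chroms)
  }
  if (!is.null(layout)) {
    gr <- check_layout(gr, layout, on_missing = on_missing_chrom,
                       clip = clip, what = "BED record")
  }
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write intervals as BED
#'
#' Writes 0-based half-open BED with LF line endings. A plain `GRanges`
#' writes BED3, or BED5 when `name`/`score` metadata columns are present
#' (missing names become `"."`, missing scores `0`). A [refgen()] result
#' writes its per-interval vote support into the score column with
#' `consensus_<i>` names.
#'
#' @param x A `GRanges`, or a `ConsensusResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "ConsensusResult")) {
    gr <- x$intervals
    nm <- paste0("consensus_", seq_along(gr))
    sc <- S4Vectors::mcols(gr)$support
    x <- gr
    S4Vectors::mcols(x)$name <- nm
    S4Vectors::mcols(x)$score <- sc
  }
  stopifnot(methods::is(x, "GRanges"))
  chrom <- as.character(GenomicRanges::seqnames(x))
  s0 <- format_coord(GenomicRanges::start(x) - 1)
  e0 <- format_coord(GenomicRanges::end(x))
  mc <- S4Vectors::mcols(x)
  if ("name" %in% colnames(mc) || "score" %in% colnames(mc)) {
    nm <- if ("name" %in% colnames(mc)) mc$name else NA_character_
    sc <- if ("score" %in% colnames(mc)) mc$score else NA_real_
    nm <- ifelse(is.na(nm), ".", nm)
    sc <- ifelse(is.na(sc), "0", format(sc, trim = TRUE, scientific = FALSE))
    out <- paste(chrom, s0, e0, nm, sc, sep = "\t")
  } else {
    out <- paste(chrom, s0, e0, sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

format_coord <- function(x) {
  format(x, trim = TRUE, scientific = FALSE)
}
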