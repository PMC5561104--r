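#' Construct a genome layout
#'
#' A genome layout is the coordinate authority for all interval operations:
#' an ordered set of chromosome names with their lengths in bp (the usual
#' UCSC `chrom.sizes` content). Internally it is a
#' [GenomeInfoDb::Seqinfo-class] object, so it can be attached to any
#' `GRanges` produced by this package. Input order is preserved.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a two-column data.frame
#'   (name, length).
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(ncol(lengths) >= 2)
    nm <- as.character(lengths[[1]])
    ln <- as.numeric(lengths[[2]])
  } else {
    nm <- names(lengths)
    ln <- as.numeric(lengths)
  }
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("chromosome names are required")
  }
  if (anyDuplicated(nm)) {
    stop("duplicated chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(is.na(ln)) || any(ln <= 0) || any(ln != floor(ln))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = ln)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Path to a two-column tab-separated file: chromosome name and
#'   length in bp. No header.
#' @return A `Seqinfo` genome layout (input order preserved).
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\t| +")
  nm <- vapply(parts, `[[`, character(1), 1L)
  ln <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (any(is.na(ln))) {
    stop("non-numeric length in chrom.sizes at line ",
         which(is.na(ln))[1L])
  }
  genome_layout(stats::setNames(ln, nm))
}

#' Write a genome layout as chrom.sizes
#'
#' @param layout A `Seqinfo` layout.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(GenomeInfoDb::seqnames(layout),
                   GenomeInfoDb::seqlengths(layout), sep = "\t"),
             path)
  invisible(path)
}

# Validate intervals against a layout: unknown chromosomes and out-of-bound
# coordinates. `on_missing` handles chromosomes absent from the layout;
# `clip` truncates out-of-bound intervals instead of erroring.
check_layout <- function(gr, layout, on_missing = c("error", "drop"),
                         clip = FALSE, what = "interval") {
  on_missing <- match.arg(on_missing)
  known <- GenomeInfoDb::seqnames(layout)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- !(chrom %in% known)
  if (any(bad)) {
    if (on_missing == "error") {
      stop(sum(bad), " ", what, "(s) on chromosome(s) absent from layout: ",
           paste(unique(chrom[bad]), collapse = ", "))
    }
    gr <- gr[!bad]
    chrom <- chrom[!bad]
  }
  lens <- GenomeInfoDb::seqlengths(layout)[chrom]
  over <- GenomicRanges::end(gr) > lens | GenomicRanges::start(gr) < 1L
  if (any(over)) {
    if (!clip) {
      i <- which(over)[1L]
      stop(what, " exceeds chromosome bounds: ", chrom[i], ":",
           GenomicRanges::start(gr)[i] - 1L, "-", GenomicRanges::end(gr)[i],
           " (length ", lens[i], "); use clip to truncate")
    }
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), lens)
    GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
  }
  gr <- set_layout(gr, layout)
  gr
}

# Attach a layout's Seqinfo to a GRanges, keeping the layout's level order.
set_layout <- function(gr, layout) {
  GenomeInfoDb::seqlevels(gr) <-
    union(GenomeInfoDb::seqnames(layout), GenomeInfoDb::seqlevels(gr))
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- merge(
    GenomeInfoDb::seqinfo(gr), layout))
  gr
}
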