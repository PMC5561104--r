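#' Read a chromatin-state segmentation (BED4)
#'
#' Consumes a dense segmentation in the style ChromHMM/Spectacle emit:
#' BED4 with the state label in the name field. Segment intervals must be
#' non-overlapping; the state catalog, per-state genomic bp and per-state
#' fraction of the segmented genome are derived. State learning itself is
#' outside this package; labels pass through verbatim.
#'
#' @param path Path to a BED4 file.
#' @param layout Optional `Seqinfo` layout.
#' @return A `Segmentation`: list with `states` (`GRanges` with `state`
#'   column), `catalog` (sorted state labels), `state_bp` (named),
#'   `total_bp` (segmented bp), `fractions` (state_bp / total_bp).
#' @export
read_segmentation <- function(path, layout = NULL) {
  gr <- read_bed(path, layout = layout)
  as_segmentation(gr)
}

#' Build a Segmentation from labeled intervals
#'
#' @param gr `GRanges` with a `state` or `name` metadata column holding the
#'   state label of each interval.
#' @return A `Segmentation` (see [read_segmentation()]).
#' @export
as_segmentation <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  mc <- S4Vectors::mcols(gr)
  state <- if ("state" %in% colnames(mc)) mc$state else mc$name
  if (is.null(state) || anyNA(state)) {
    stop("every segmentation interval needs a state label (BED name field)")
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  state <- if ("state" %in% colnames(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$state
  } else {
    S4Vectors::mcols(gr)$name
  }
  self <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE)
  if (length(self) > 0L) {
    i <- S4Vectors::queryHits(self)[1L]
    j <- S4Vectors::subjectHits(self)[1L]
    stop("overlapping segmentation intervals, e.g. ",
         as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L, "-", GenomicRanges::end(gr)[i],
         " and ", as.character(GenomicRanges::seqnames(gr))[j], ":",
         GenomicRanges::start(gr)[j] - 1L, "-", GenomicRanges::end(gr)[j])
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(state = as.character(state))
  bp <- tapply(GenomicRanges::width(gr), S4Vectors::mcols(gr)$state, sum)
  bp <- stats::setNames(as.numeric(bp), names(bp))
  bp <- bp[sort(names(bp))]
  total <- sum(bp)
  structure(list(states = gr, catalog = names(bp), state_bp = bp,
                 total_bp = total, fractions = bp / total),
            class = "Segmentation")
}

#' @export
print.Segmentation <- function(x, ...) {
  cat("Segmentation:", length(x$states), "interval(s),",
      length(x$catalog), "state(s),", format_coord(x$total_bp),
      "bp segmented\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Write a segmentation as BED4
#'
#' @param seg A `Segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  gr <- seg$states
  out <- paste(as.character(GenomicRanges::seqnames(gr)),
               format_coord(GenomicRanges::start(gr) - 1),
               format_coord(GenomicRanges::end(gr)),
               S4Vectors::mcols(gr)$state, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Majority chromatin-state assignment per site
#'
#' Labels each site with the chromatin state covering the largest share of
#' its bases. Ties are broken deterministically by the lexicographically
#' smallest state label; sites with no base inside the segmentation are
#' labeled `"unsegmented"`.
#'
#' @param sites `GRanges` (or `ConsensusResult`).
#' @param seg A `Segmentation`.
#' @return Character vector of state labels, one per site.
#' @export
assign_majority_state <- function(sites, seg) {
  if (inherits(sites, "ConsensusResult")) sites <- sites$intervals
  stopifnot(methods::is(sites, "GRanges"), inherits(seg, "Segmentation"))
  lab <- rep("unsegmented", length(sites))
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(sites, seg$states, ignore.strand = TRUE))
  if (length(hit) == 0L) return(lab)
  si <- S4Vectors::queryHits(hit)
  st <- S4Vectors::mcols(seg$states)$state[S4Vectors::subjectHits(hit)]
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(sites)[si],
    GenomicRanges::ranges(seg$states)[S4Vectors::subjectHits(hit)]))
  bp <- rowsum(ov, paste(si, st, sep = "\r"))
  key <- rownames(bp)
  site_k <- as.integer(sub("\r.*$", "", key))
  state_k <- sub("^.*\r", "", key)
  # per site: max bp, ties to lexicographically smallest label
  o <- order(site_k, -bp[, 1L], state_k, method = "radix")
  first <- !duplicated(site_k[o])
  lab[site_k[o][first]] <- state_k[o][first]
  lab
}

#' Per-site state fractions by group
#'
#' Convenience summary: majority state per site, tabulated as fractions
#' within user-supplied site groups (e.g. co-occurrence classes).
#'
#' @param sites `GRanges` of sites.
#' @param seg A `Segmentation`.
#' @param groups Character vector, one group per site (default one group).
#' @return data.frame: `group`, `state`, `n`, `fraction` (within group).
#' @export
state_fractions <- function(sites, seg, groups = NULL) {
  lab <- assign_majority_state(sites, seg)
  if (is.null(groups)) groups <- rep("all", length(lab))
  stopifnot(length(groups) == length(lab))
  tab <- as.data.frame(table(group = groups, state = lab),
                       stringsAsFactors = FALSE)
  colnames(tab)[3L] <- "n"
  tot <- stats::ave(tab$n, tab$group, FUN = sum)
  tab$fraction <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab[tab$n > 0 | TRUE, , drop = FALSE]
}

#' Chromatin-state overlap enrichment of feature sets
#'
#' For each feature set, measures the fraction of its bases falling into
#' each chromatin state, compares it to the state's share of the segmented
#' genome, and converts the observed/expected ratios to Z-scores across
#' states (sample SD within the feature row), highlighting the states a
#' feature is enriched or depleted in. bp-weighted; for site-count
#' fractions use [state_fractions()].
#'
#' @param seg A `Segmentation`.
#' @param features Named list of `GRanges` feature sets (collapsed
#'   internally).
#' @return An `EnrichmentMatrix`: list of matrices (features x states)
#'   `observed`, `expected` (one row repeated), `ratio`, `z`, plus
#'   `flagged` (features with zero bp inside the segmentation, whose rows
#'   are `NA`).
#' @export
state_enrichment <- function(seg, features) {
  stopifnot(inherits(seg, "Segmentation"))
  if (length(features) == 0L || is.null(names(features))) {
    stop("features must be a non-empty named list")
  }
  states <- seg$catalog
  expected <- seg$fractions[states]
  obs <- t(vapply(features, function(f) {
    f <- collapse_intervals(f)
    total <- sum(GenomicRanges::width(f))
    if (total == 0) return(stats::setNames(rep(NA_real_, length(states)),
                                           states))
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(f, seg$states, ignore.strand = TRUE))
    v <- stats::setNames(numeric(length(states)), states)
    if (length(hit) > 0L) {
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(f)[S4Vectors::queryHits(hit)],
        GenomicRanges::ranges(seg$states)[S4Vectors::subjectHits(hit)]))
      st <- S4Vectors::mcols(seg$states)$state[S4Vectors::subjectHits(hit)]
      agg <- rowsum(ov, st)
      v[rownames(agg)] <- agg[, 1L]
    }
    inside <- sum(v)
    if (inside == 0) return(stats::setNames(rep(NA_real_, length(states)),
                                            states))
    v / total
  }, numeric(length(states))))
  ratio <- sweep(obs, 2L, expected, `/`)
  z <- t(apply(ratio, 1L, function(row) {
    if (anyNA(row)) return(rep(NA_real_, length(row)))
    sdr <- stats::sd(row)
    if (!is.finite(sdr) || sdr == 0) return(rep(NA_real_, length(row)))
    (row - mean(row)) / sdr
  }))
  colnames(z) <- states
  flagged <- names(features)[apply(obs, 1L, anyNA)]
  structure(list(observed = obs,
                 expected = matrix(expected, nrow(obs), length(states),
                                   byrow = TRUE,
                                   dimnames = dimnames(obs)),
                 ratio = ratio, z = z, flagged = flagged),
            class = "EnrichmentMatrix")
}

#' @export
print.EnrichmentMatrix <- function(x, ...) {
  cat("EnrichmentMatrix:", nrow(x$ratio), "feature(s) x",
      ncol(x$ratio), "state(s)\n")
  cat("enrichment ratios (observed/expected):\n")
  print(round(x$ratio, 3))
  if (length(x$flagged)) {
    cat("flagged (no bp inside segmentation):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
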