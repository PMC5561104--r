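#' Collapse an interval set to its minimal non-overlapping form
#'
#' Merges overlapping and book-ended intervals (half-open convention:
#' `[10,20)` and `[20,30)` merge to `[10,30)`) so that the set covers the
#' same bases with the minimal number of sorted, pairwise non-overlapping
#' intervals. Idempotent. Every input peak set is collapsed before voting
#' so one dataset cannot contribute two votes at a position.
#'
#' @param gr A `GRanges`.
#' @return A sorted, collapsed `GRanges` (metadata columns dropped; the set
#'   label is preserved).
#' @export
collapse_intervals <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  lab <- S4Vectors::metadata(gr)$label
  out <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- lab
  out
}

# Depth step-function over a pool of intervals, as a breakpoint sweep.
# This is the coverage step at the heart of the majority vote: every
# interval opens (+1) at its 0-based start and closes (-1) at its end;
# scanning breakpoints in order yields maximal constant-depth segments.
# Input: data.frame(chrom, s0, e0). Output: data.frame(chrom, s0, e0, depth)
# with depth >= 1 segments only, sorted by (chrom, s0), segments within a
# chromosome non-overlapping.
depth_segments <- function(chrom, s0, e0) {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), s0 = numeric(), e0 = numeric(),
                      depth = integer()))
  }
  n <- length(s0)
  pos <- c(s0, e0)
  delta <- c(rep(1L, n), rep(-1L, n))
  ch <- c(chrom, chrom)
  o <- order(ch, pos, method = "radix")
  pos <- pos[o]; delta <- delta[o]; ch <- ch[o]
  # cumulative depth restarts at each chromosome
  cum <- stats::ave(delta, ch, FUN = cumsum)
  # at duplicated (chrom,pos) keep the last cumulative value
  last <- !duplicated(cbind(ch, pos), fromLast = TRUE)
  pos <- pos[last]; cum <- cum[last]; ch <- ch[last]
  k <- length(pos)
  same <- ch[-k] == ch[-1L]
  seg <- data.frame(chrom = ch[-k][same], s0 = pos[-k][same],
                    e0 = pos[-1L][same], depth = cum[-k][same],
                    stringsAsFactors = FALSE)
  seg[seg$depth >= 1L & seg$e0 > seg$s0, , drop = FALSE]
}

# GRanges -> the 0-based triple used by the sweep
gr_bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             s0 = GenomicRanges::start(gr) - 1,
             e0 = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

seg_to_granges <- function(seg, layout = NULL) {
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$s0 + 1, seg$e0))
  if (!is.null(layout)) gr <- set_layout(gr, layout)
  gr
}

#' Multi-set genomic coverage
#'
#' Computes the vote depth track over a list of interval sets: the depth at
#' a position is the number of input sets covering it. Each set is
#' collapsed first, so a set contributes at most one unit of depth per
#' position. The track is returned as maximal constant-depth segments
#' (depth >= 1 only), the step function the majority vote thresholds.
#'
#' @param sets A list of `GRanges` (or a single `GRanges`).
#' @param layout Optional `Seqinfo` layout; when given, defines the
#'   chromosome universe and intervals are validated against it.
#' @param permissive Allow input sets to live on differing chromosome
#'   universes. Defaults to `TRUE` when a layout is supplied (the layout is
#'   then the universe), `FALSE` otherwise.
#' @return A `GRanges` with an integer `depth` metadata column; segments
#'   are sorted and non-overlapping within chromosomes.
#' @export
coverage_track <- function(sets, layout = NULL,
                           permissive = !is.null(layout)) {
  if (methods::is(sets, "GRanges")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  sets <- lapply(sets, function(g) {
    if (!is.null(layout)) g <- check_layout(g, layout)
    collapse_intervals(g)
  })
  if (!permissive) {
    unis <- lapply(sets, function(g)
      sort(unique(as.character(GenomicRanges::seqnames(g)))))
    if (length(unique(unis)) > 1L) {
      stop("input sets use different chromosome universes; ",
           "supply a layout or set permissive = TRUE")
    }
  }
  bed <- do.call(rbind, lapply(sets, gr_bed0))
  seg <- depth_segments(bed$chrom, bed$s0, bed$e0)
  gr <- seg_to_granges(seg, layout)
  S4Vectors::mcols(gr)$depth <- as.integer(seg$depth)
  gr
}

# Merge adjacent qualifying segments (depth >= tau) into maximal runs and
# report the max depth within each run. seg must be sorted (chrom, s0).
runs_at_tau <- function(seg, tau) {
  q <- seg[seg$depth >= tau, , drop = FALSE]
  if (nrow(q) == 0L) {
    return(data.frame(chrom = character(), s0 = numeric(), e0 = numeric(),
                      support = integer()))
  }
  new_run <- c(TRUE, !(q$chrom[-1L] == q$chrom[-nrow(q)] &
                         q$s0[-1L] == q$e0[-nrow(q)]))
  id <- cumsum(new_run)
  data.frame(
    chrom = q$chrom[new_run],
    s0 = q$s0[new_run],
    e0 = stats::ave(q$e0, id, FUN = max)[new_run],
    support = as.integer(stats::ave(q$depth, id, FUN = max)[new_run]),
    stringsAsFactors = FALSE)
}
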