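#' Binning scheme around site centers
#'
#' Defines how signal is extracted around binding sites: a window of
#' `half_window` bp on each side of the site center, fractioned into
#' consecutive non-overlapping bins of `bin_size` bp. The defaults
#' (+/- 5 kbp, 50-bp bins) give 200 bins per site. `bin_size` must divide
#' the window exactly.
#'
#' @param half_window Half window width in bp (default 5000).
#' @param bin_size Bin width in bp (default 50).
#' @return A `BinScheme` list with `half_window`, `bin_size`, `n_bins`.
#' @export
bin_scheme <- function(half_window = 5000L, bin_size = 50L) {
  half_window <- as.integer(half_window)
  bin_size <- as.integer(bin_size)
  stopifnot(half_window > 0L, bin_size > 0L)
  if ((2L * half_window) %% bin_size != 0L) {
    stop("bin_size must divide 2 * half_window exactly")
  }
  structure(list(half_window = half_window, bin_size = bin_size,
                 n_bins = (2L * half_window) %/% bin_size),
            class = "BinScheme")
}

# 0-based center and half-open window of each site
site_windows0 <- function(sites, half_window) {
  s0 <- GenomicRanges::start(sites) - 1
  e0 <- as.numeric(GenomicRanges::end(sites))
  c0 <- floor((s0 + e0) / 2)
  list(center = c0, win_start = c0 - half_window, win_end = c0 + half_window)
}

# Drop sites whose window exceeds chromosome bounds (right bound enforced
# only when chromosome lengths are known). Returns kept index.
keep_in_bounds <- function(sites, win, layout = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(sites))
  lens <- if (!is.null(layout)) GenomeInfoDb::seqlengths(layout) else
    GenomeInfoDb::seqlengths(sites)
  keep <- win$win_start >= 0
  known <- chrom %in% names(lens)[!is.na(lens)]
  keep[known] <- keep[known] &
    win$win_end[known] <= lens[chrom[known]]
  if (any(!keep)) {
    message(sum(!keep), " site(s) dropped: window exceeds chromosome bounds")
  }
  which(keep)
}

# Anchor 0-based position(s) of read placements
read_anchor0 <- function(reads, anchor) {
  s0 <- GenomicRanges::start(reads) - 1
  e0 <- as.numeric(GenomicRanges::end(reads))
  switch(anchor,
         midpoint = floor((s0 + e0) / 2),
         fiveprime = s0,
         stop("unknown read anchor: ", anchor))
}

#' Count read placements in bins around binding sites
#'
#' Builds the bin-count matrix that the normalization operates on: rows are
#' (site, bin) pairs in site-major order, columns are experiments, and each
#' cell counts the read placements of one experiment assigned to one bin.
#' Site center is `floor((start + end) / 2)` in 0-based coordinates; the
#' window is `[center - half_window, center + half_window)` with half-open
#' bins. Reads are assigned by their placement midpoint (default), 5' end,
#' or to every bin they overlap.
#'
#' @param reads A named list of `GRanges` (one per experiment) or a single
#'   `GRanges` read placements.
#' @param sites `GRanges` of binding sites (or a `ConsensusResult`).
#' @param scheme A [bin_scheme()].
#' @param read_anchor `"midpoint"`, `"fiveprime"`, or `"overlap"`.
#' @param layout Optional layout to bound-check windows; sites with
#'   out-of-bounds windows are dropped with a message so the row universe
#'   stays identical across experiments.
#' @param experiments Optional data.frame of column metadata with at least
#'   a `label` column (and typically `factor`, `context`).
#' @return A `BinCountMatrix`: list with `counts` (matrix), `site_ids`,
#'   `bin_index` (0-based, recycled per site), `sites` (kept `GRanges`),
#'   `scheme`, `experiments` (data.frame), `normalized` flag and
#'   `size_factors`.
#' @export
count_in_bins <- function(reads, sites, scheme = bin_scheme(),
                          read_anchor = c("midpoint", "fiveprime", "overlap"),
                          layout = NULL, experiments = NULL) {
  read_anchor <- match.arg(read_anchor)
  if (inherits(sites, "ConsensusResult")) sites <- sites$intervals
  stopifnot(methods::is(sites, "GRanges"))
  if (length(sites) == 0L) stop("empty site list")
  if (methods::is(reads, "GRanges")) reads <- list(exp1 = reads)
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    names(reads) <- paste0("exp", seq_along(reads))
  }
  win <- site_windows0(sites, scheme$half_window)
  keep <- keep_in_bounds(sites, win, layout)
  sites <- sites[keep]
  if (length(sites) == 0L) stop("no site window fits the genome")
  win <- lapply(win, `[`, keep)
  n_sites <- length(sites)
  nb <- scheme$n_bins
  site_chrom <- as.character(GenomicRanges::seqnames(sites))
  wgr <- GenomicRanges::GRanges(site_chrom,
                                IRanges::IRanges(win$win_start + 1,
                                                 win$win_end))
  counts <- vapply(reads, function(rd) {
    v <- numeric(n_sites * nb)
    if (length(rd) == 0L) return(v)
    if (read_anchor == "overlap") {
      hit <- GenomicRanges::findOverlaps(rd, wgr, ignore.strand = TRUE)
      if (length(hit) == 0L) return(v)
      ri <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
      rs0 <- GenomicRanges::start(rd)[ri] - 1
      re0 <- as.numeric(GenomicRanges::end(rd))[ri]
      b1 <- pmax(0, floor((rs0 - win$win_start[si]) / scheme$bin_size))
      b2 <- pmin(nb - 1, floor((re0 - 1 - win$win_start[si]) / scheme$bin_size))
      idx <- unlist(lapply(seq_along(ri), function(k) {
        (si[k] - 1) * nb + seq(b1[k], b2[k]) + 1
      }))
    } else {
      a0 <- read_anchor0(rd, read_anchor)
      pt <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(rd)),
        IRanges::IRanges(a0 + 1, width = 1L))
      hit <- GenomicRanges::findOverlaps(pt, wgr, ignore.strand = TRUE)
      if (length(hit) == 0L) return(v)
      ri <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
      b <- floor((a0[ri] - win$win_start[si]) / scheme$bin_size)
      idx <- (si - 1) * nb + b + 1
    }
    tab <- tabulate(idx, nbins = n_sites * nb)
    as.numeric(tab)
  }, numeric(n_sites * nb))
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = length(reads))
  colnames(counts) <- names(reads)
  if (is.null(experiments)) {
    experiments <- data.frame(label = names(reads),
                              stringsAsFactors = FALSE)
  }
  site_ids <- if (!is.null(S4Vectors::mcols(sites)$name) &&
                  !anyDuplicated(S4Vectors::mcols(sites)$name) &&
                  !anyNA(S4Vectors::mcols(sites)$name)) {
    S4Vectors::mcols(sites)$name
  } else {
    paste0("site_", seq_len(n_sites))
  }
  new_bin_count_matrix(counts, site_ids, nb, sites = sites, scheme = scheme,
                       experiments = experiments)
}

#' Construct a bin-count matrix from a plain matrix
#'
#' For users supplying precomputed counts: rows must be (site, bin) pairs
#' in site-major order, columns experiments. `site_ids` defaults to
#' `site_<i>` for `nrow / n_bins` sites.
#'
#' @param counts Numeric matrix of non-negative counts.
#' @param n_bins Bins per site; must divide `nrow(counts)`.
#' @param site_ids Optional site identifiers.
#' @param experiments Optional data.frame of column metadata (needs a
#'   `label` column; `factor` and `context` enable [two_step_normalize()]).
#' @return A `BinCountMatrix`.
#' @export
bin_count_matrix <- function(counts, n_bins = nrow(counts),
                             site_ids = NULL, experiments = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) %% n_bins != 0L) {
    stop("n_bins must divide the row count")
  }
  if (is.null(site_ids)) {
    site_ids <- paste0("site_", seq_len(nrow(counts) %/% n_bins))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("exp", seq_len(ncol(counts)))
  }
  new_bin_count_matrix(counts, site_ids, n_bins, experiments = experiments)
}

new_bin_count_matrix <- function(counts, site_ids, n_bins, sites = NULL,
                                 scheme = NULL, experiments = NULL,
                                 normalized = FALSE, size_factors = NULL) {
  stopifnot(nrow(counts) == length(site_ids) * n_bins)
  if (is.null(experiments)) {
    experiments <- data.frame(label = colnames(counts),
                              stringsAsFactors = FALSE)
  }
  stopifnot(nrow(experiments) == ncol(counts))
  if (any(counts < 0)) stop("bin counts must be non-negative")
  structure(list(counts = counts, site_ids = site_ids, n_bins = n_bins,
                 bin_index = rep(seq_len(n_bins) - 1L, times = length(site_ids)),
                 sites = sites, scheme = scheme, experiments = experiments,
                 normalized = normalized, size_factors = size_factors),
            class = "BinCountMatrix")
}

#' @export
print.BinCountMatrix <- function(x, ...) {
  cat("BinCountMatrix: ", length(x$site_ids), " site(s) x ", x$n_bins,
      " bin(s) x ", ncol(x$counts), " experiment(s)",
      if (x$normalized) " [normalized]", "\n", sep = "")
  invisible(x)
}

#' Count reads in a single window around each site center
#'
#' Single-bin variant of [count_in_bins()]: counts read placements in
#' `[center - half_width, center + half_width)` per site (half-open right
#' edge) and reports the per-site vector and its mean, the summary used to
#' follow binding intensity across conditions.
#'
#' @inheritParams count_in_bins
#' @param half_width Half width of the window in bp (default 200).
#' @return List with `counts` (matrix sites x experiments, or a vector for
#'   a single `GRanges` input) and `mean` (per-experiment mean count).
#' @export
count_in_window <- function(reads, sites, half_width = 200L,
                            read_anchor = c("midpoint", "fiveprime"),
                            layout = NULL) {
  read_anchor <- match.arg(read_anchor)
  single <- methods::is(reads, "GRanges")
  m <- count_in_bins(reads, sites,
                     scheme = bin_scheme(half_width, 2L * half_width),
                     read_anchor = read_anchor, layout = layout)
  counts <- m$counts
  rownames(counts) <- m$site_ids
  if (single) {
    v <- stats::setNames(counts[, 1L], m$site_ids)
    list(counts = v, mean = mean(v))
  } else {
    list(counts = counts, mean = colMeans(counts))
  }
}

as_count_matrix <- function(M) {
  if (inherits(M, "BinCountMatrix")) M$counts else as.matrix(M)
}

#' Median-of-ratios size factors for binned ChIP signal
#'
#' Estimates one scaling constant per experiment from a bin-count matrix,
#' extending the DESeq median-of-ratios method to binned signal profiles.
#' For each bin row `j` present in all experiments with a positive count,
#' the geometric mean `G_j = (prod_i M[j,i])^(1/N)` is computed; each row
#' is divided by its `G_j`; and the size factor of experiment `i` is the
#' median over rows of these ratios. Rows containing any zero are excluded
#' (their count is reported), unless a pseudocount is added first. The
#' geometric mean is computed in log space; for even row counts the median
#' is the mean of the two central order statistics.
#'
#' @param M A `BinCountMatrix` or a numeric matrix (rows = bins, columns =
#'   experiments, >= 2 columns).
#' @param pseudocount Constant added to every cell before the computation
#'   (default 0, i.e. zero rows are excluded instead).
#' @return Named numeric vector of size factors (one per column), with
#'   attribute `n_rows_used`.
#' @examples
#' M <- matrix(c(2, 4, 6, 8, 16, 24), ncol = 2)
#' normchip_size_factors(M)   # 0.5, 2.0
#' @export
normchip_size_factors <- function(M, pseudocount = 0) {
  m <- as_count_matrix(M)
  if (ncol(m) < 2L) {
    stop("size-factor estimation needs at least 2 experiments")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  m <- m + pseudocount
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    stop("no bin row is positive in all experiments; ",
         "consider pseudocount > 0")
  }
  n_excl <- sum(!ok)
  if (n_excl > 0L) {
    message(n_excl, " row(s) with zero counts excluded from ",
            "size-factor estimation")
  }
  mm <- m[ok, , drop = FALSE]
  logG <- rowMeans(log(mm))
  ratios <- exp(log(mm) - logG)   # M'[j,i] = M[j,i] / G_j
  s <- apply(ratios, 2L, stats::median)
  names(s) <- colnames(m)
  if (any(s <= 0)) stop("non-positive size factor estimated")
  attr(s, "n_rows_used") <- sum(ok)
  s
}

#' Apply size factors to a bin-count matrix
#'
#' Divides each experiment column by its size factor, putting all profiles
#' on a common scale. Size factors of the normalized matrix are all equal
#' (each equal to the geometric mean of the original factors).
#'
#' @param M A `BinCountMatrix` or numeric matrix.
#' @param s Strictly positive size factors, one per column (from
#'   [normchip_size_factors()]).
#' @return Same type as `M`, normalized; a `BinCountMatrix` records `s` and
#'   sets its `normalized` flag.
#' @export
normchip_apply <- function(M, s) {
  m <- as_count_matrix(M)
  s <- as.numeric(s)
  if (length(s) != ncol(m)) stop("length(s) must equal the column count")
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be finite and > 0")
  }
  out <- sweep(m, 2L, s, `/`)
  if (inherits(M, "BinCountMatrix")) {
    M$counts <- out
    M$normalized <- TRUE
    M$size_factors <- s
    M
  } else {
    out
  }
}

#' Normalize a bin-count matrix in one call
#'
#' Convenience wrapper: [normchip_size_factors()] then [normchip_apply()].
#'
#' @inheritParams normchip_size_factors
#' @return Normalized matrix of the same type as `M`.
#' @export
normchip <- function(M, pseudocount = 0) {
  normchip_apply(M, normchip_size_factors(M, pseudocount = pseudocount))
}

#' Average profiles column-wise by group
#'
#' Arithmetic mean of the (normalized) profile columns within each group,
#' e.g. averaging an experiment's replicates, or a factor's datasets within
#' an experimental context, into one reference profile.
#'
#' @param M A `BinCountMatrix` or numeric matrix.
#' @param groups Character/factor vector, one group key per column.
#' @return Same type as `M`, one column per group (group order = first
#'   appearance).
#' @export
average_profiles <- function(M, groups) {
  m <- as_count_matrix(M)
  if (length(groups) != ncol(m)) {
    stop("groups must have one entry per column")
  }
  groups <- as.character(groups)
  keys <- unique(groups)
  out <- vapply(keys, function(k) {
    rowMeans(m[, groups == k, drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(out)) out <- matrix(out, ncol = length(keys))
  colnames(out) <- keys
  if (inherits(M, "BinCountMatrix")) {
    new_bin_count_matrix(out, M$site_ids, M$n_bins, sites = M$sites,
                         scheme = M$scheme,
                         experiments = data.frame(label = keys,
                                                  stringsAsFactors = FALSE),
                         normalized = M$normalized)
  } else {
    out
  }
}

#' Two-step normalization across factors and contexts
#'
#' Produces one reference profile per (factor, experimental context):
#' step 1 normalizes each factor's datasets together across all contexts
#' (size factors within the factor) and averages the normalized profiles
#' within each context; step 2 normalizes, within each context, the
#' per-factor averaged profiles against each other. The result supports
#' both inter-context comparisons for one factor and intra-context
#' comparisons between factors. A factor with a single dataset skips the
#' step-1 scaling (identity) with a warning; a context with a single
#' factor skips step 2 likewise.
#'
#' @param M A `BinCountMatrix` whose `experiments` data.frame has `label`,
#'   `factor` and `context` columns.
#' @param pseudocount Passed to the size-factor estimation.
#' @return A `BinCountMatrix` with one column per (factor, context) pair
#'   present in the input, labelled `"<factor>|<context>"`; its
#'   `experiments` data.frame carries `factor` and `context`. Output is
#'   invariant to the input column order.
#' @export
two_step_normalize <- function(M, pseudocount = 0) {
  stopifnot(inherits(M, "BinCountMatrix"))
  ex <- M$experiments
  if (!all(c("factor", "context") %in% colnames(ex))) {
    stop("experiments metadata must have 'factor' and 'context' columns")
  }
  facs <- sort(unique(as.character(ex$factor)))
  # step 1: per factor across contexts, then average within context
  per_fc <- list()
  for (f in facs) {
    cols <- which(ex$factor == f)
    sub <- M$counts[, cols, drop = FALSE]
    if (length(cols) >= 2L) {
      sub <- normchip_apply(sub, normchip_size_factors(sub, pseudocount))
    } else {
      warning("factor '", f, "' has a single dataset; step-1 scaling ",
              "skipped (identity)")
    }
    ctx <- as.character(ex$context)[cols]
    for (cx in sort(unique(ctx))) {
      per_fc[[paste0(f, "|", cx)]] <-
        rowMeans(sub[, ctx == cx, drop = FALSE])
    }
  }
  keys <- sort(names(per_fc))
  avg <- do.call(cbind, per_fc[keys])
  meta <- data.frame(
    label = keys,
    factor = sub("\\|.*$", "", keys),
    context = sub("^.*\\|", "", keys),
    stringsAsFactors = FALSE)
  # step 2: per context across factors
  out <- avg
  for (cx in unique(meta$context)) {
    cols <- which(meta$context == cx)
    if (length(cols) >= 2L) {
      s <- normchip_size_factors(out[, cols, drop = FALSE], pseudocount)
      out[, cols] <- normchip_apply(out[, cols, drop = FALSE], s)
    } else {
      warning("context '", cx, "' has a single factor; step-2 scaling ",
              "skipped (identity)")
    }
  }
  new_bin_count_matrix(out, M$site_ids, M$n_bins, sites = M$sites,
                       scheme = M$scheme, experiments = meta,
                       normalized = TRUE)
}
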