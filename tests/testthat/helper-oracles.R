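suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# GRanges from 0-based half-open coordinates (the BED convention used in
# expected values throughout the tests).
gr0 <- function(chrom, s0, e0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0), ...)
}

# 0-based half-open data.frame view of a GRanges
bed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             s0 = as.numeric(start(gr) - 1), e0 = as.numeric(end(gr)),
             stringsAsFactors = FALSE)
}

# Per-base bitmap vote oracle: depth vector per chromosome. Position p
# (0-based) lives at index p + 1. Each set is deduplicated per base by
# construction of the bitmap (logical OR), independent of the package's
# collapse step.
bitmap_vote <- function(sets, chrom_lens) {
  out <- lapply(chrom_lens, function(L) integer(L))
  for (s in sets) {
    hit <- lapply(chrom_lens, function(L) logical(L))
    b <- bed0(s)
    for (k in seq_len(nrow(b))) {
      ch <- b$chrom[k]
      if (!ch %in% names(hit)) next
      idx <- seq(b$s0[k] + 1, min(b$e0[k], chrom_lens[[ch]]))
      hit[[ch]][idx] <- TRUE
    }
    for (ch in names(out)) out[[ch]] <- out[[ch]] + hit[[ch]]
  }
  out
}

# Maximal runs of depth >= tau from a bitmap, as 0-based intervals with
# max-depth support.
bitmap_consensus <- function(depth_by_chrom, tau) {
  rows <- lapply(names(depth_by_chrom), function(ch) {
    d <- depth_by_chrom[[ch]]
    r <- rle(d >= tau)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) == 0L) return(NULL)
    data.frame(chrom = ch, s0 = as.numeric(starts[keep] - 1),
               e0 = as.numeric(ends[keep]),
               support = vapply(keep, function(k)
                 max(d[starts[k]:ends[k]]), integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), s0 = numeric(), e0 = numeric(),
                      support = integer())
  }
  out[order(out$chrom, out$s0), , drop = FALSE]
}

# Random peak-set instance on small toy chromosomes
random_instance <- function(n_sets, chrom_lens, n_per_set = 15,
                            max_len = 800) {
  lapply(seq_len(n_sets), function(i) {
    ch <- sample(names(chrom_lens), n_per_set, replace = TRUE)
    L <- chrom_lens[ch]
    w <- sample(seq_len(max_len), n_per_set, replace = TRUE)
    s0 <- floor(runif(n_per_set) * (L - w))
    gr0(ch, s0, s0 + w)
  })
}

# Independent naive median-of-ratios oracle (explicit loops; no shared
# code with the package implementation).
naive_size_factors <- function(M) {
  keep <- apply(M, 1, function(r) all(r > 0))
  Mk <- M[keep, , drop = FALSE]
  G <- numeric(nrow(Mk))
  for (j in seq_len(nrow(Mk))) {
    p <- 1
    for (i in seq_len(ncol(Mk))) p <- p * Mk[j, i]
    G[j] <- p^(1 / ncol(Mk))
  }
  s <- numeric(ncol(Mk))
  for (i in seq_len(ncol(Mk))) {
    ratios <- Mk[, i] / G
    s[i] <- median(ratios)
  }
  s
}

toy_lens <- function(n = 3, L = 50000) {
  setNames(rep(L, n), paste0("chr", seq_len(n)))
}

expect_same_intervals <- function(gr, expected_df) {
  got <- bed0(gr)
  rownames(got) <- NULL
  rownames(expected_df) <- NULL
  expect_equal(got[order(got$chrom, got$s0), c("chrom", "s0", "e0")],
               expected_df[order(expected_df$chrom, expected_df$s0),
                           c("chrom", "s0", "e0")],
               ignore_attr = TRUE)
}
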