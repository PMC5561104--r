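# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derived per-replicate seed: documented counter scheme so any replicate is
# independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(counter)) %%
               2147483647)
}

#' Shuffle intervals to random genomic positions
#'
#' Produces one random interval per input interval with identical length,
#' placed uniformly at random on its own chromosome (the behaviour of
#' `bedtools shuffle -chrom`), or anywhere on the genome when
#' `same_chrom = FALSE` (chromosome chosen with probability proportional to
#' the number of valid start positions). Shuffled intervals may overlap
#' each other, as with the reference tool; they are collapsed before any
#' vote, like real inputs.
#'
#' @param gr A `GRanges` to shuffle.
#' @param layout `Seqinfo` layout giving chromosome lengths.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   placement exactly. The caller's RNG state is untouched.
#' @param same_chrom Keep each interval on its original chromosome
#'   (default `TRUE`).
#' @param exclude Optional `GRanges`; placements overlapping it are
#'   rejected and resampled, up to `max_attempts` per interval, then error.
#' @param max_attempts Rejection-sampling cap (default 1000).
#' @return A `GRanges` of shuffled intervals (no metadata columns).
#' @export
shuffle_intervals <- function(gr, layout, seed = NULL, same_chrom = TRUE,
                              exclude = NULL, max_attempts = 1000L) {
  stopifnot(methods::is(gr, "GRanges"))
  lens <- GenomeInfoDb::seqlengths(layout)
  w <- GenomicRanges::width(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (any(!(chrom %in% names(lens)))) {
    stop("interval chromosome(s) absent from layout: ",
         paste(setdiff(chrom, names(lens)), collapse = ", "))
  }
  if (same_chrom && any(w > lens[chrom])) {
    stop("interval longer than its chromosome")
  }
  if (!same_chrom && any(w > max(lens))) {
    stop("interval longer than every chromosome")
  }
  doit <- function() {
    n <- length(gr)
    if (n == 0L) return(GenomicRanges::GRanges(seqinfo = layout))
    place <- function(idx) {
      if (same_chrom) {
        ch <- chrom[idx]
      } else {
        ch <- vapply(idx, function(i) {
          ok <- names(lens)[lens >= w[i]]
          p <- lens[ok] - w[i] + 1
          sample(ok, 1L, prob = p)
        }, character(1))
      }
      nstart <- lens[ch] - w[idx] + 1  # valid 0-based starts: [0, len - w]
      s0 <- floor(stats::runif(length(idx)) * nstart)
      s0 <- pmin(s0, nstart - 1)
      GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, width = w[idx]))
    }
    out <- place(seq_len(n))
    if (!is.null(exclude) && length(exclude) > 0L) {
      for (att in seq_len(max_attempts)) {
        bad <- which(GenomicRanges::countOverlaps(
          out, exclude, ignore.strand = TRUE) > 0L)
        if (length(bad) == 0L) break
        out[bad] <- place(bad)
      }
      if (any(GenomicRanges::countOverlaps(out, exclude,
                                           ignore.strand = TRUE) > 0L)) {
        stop("could not place interval(s) outside the exclude set within ",
             max_attempts, " attempts")
      }
    }
    set_layout(out, layout)
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

#' Calibrate the consensus threshold against a random background
#'
#' For each threshold tau, compares the number of consensus regions
#' obtained from the real peak sets to the distribution obtained when every
#' input set is replaced by a same-chromosome shuffle preserving interval
#' counts and lengths. A tau where the observed count far exceeds the
#' random counts separates reproducible binding from coincidental overlap;
#' the full table is returned so the user chooses the threshold balancing
#' false positives and negatives.
#'
#' @param sets List of `GRanges` peak sets.
#' @param layout `Seqinfo` layout.
#' @param n_reps Number of random replicates (default 1000).
#' @param seed Master seed; replicate `r` uses the derived seed
#'   `(seed + 1000003 * r) mod (2^31 - 1)`.
#' @param tau_grid Integer vector of thresholds (default `1:n_sets`).
#' @return A `CalibrationTable`: data.frame with columns `tau`,
#'   `observed_n`, `observed_bp`, `rand_mean_n`, `rand_sd_n`, `rand_q05`,
#'   `rand_q95`; attributes `replicates` (matrix n_reps x n_tau of random
#'   counts), `replicates_bp`, `seed`, `n_reps`.
#' @export
calibrate_tau <- function(sets, layout, n_reps = 1000L, seed = 1L,
                          tau_grid = NULL) {
  if (methods::is(sets, "GRanges")) sets <- list(sets)
  n <- length(sets)
  stopifnot(n >= 1L, n_reps >= 1L)
  if (is.null(tau_grid)) tau_grid <- seq_len(n)
  tau_grid <- sort(unique(as.integer(tau_grid)))
  if (any(tau_grid < 1L | tau_grid > n)) {
    stop("tau_grid values must lie in [1, ", n, "]")
  }
  sets <- lapply(sets, function(g) check_layout(g, layout))
  count_runs <- function(inputs) {
    inputs <- lapply(inputs, collapse_intervals)
    bed <- do.call(rbind, lapply(inputs, gr_bed0))
    seg <- depth_segments(bed$chrom, bed$s0, bed$e0)
    t(vapply(tau_grid, function(tt) {
      r <- runs_at_tau(seg, tt)
      c(n = nrow(r), bp = sum(r$e0 - r$s0))
    }, c(n = 0, bp = 0)))
  }
  obs <- count_runs(sets)
  rand_n <- matrix(NA_real_, n_reps, length(tau_grid))
  rand_bp <- matrix(NA_real_, n_reps, length(tau_grid))
  for (r in seq_len(n_reps)) {
    sh <- lapply(seq_along(sets), function(i) {
      shuffle_intervals(sets[[i]], layout,
                        seed = derive_seed(seed, (r - 1L) * length(sets) + i))
    })
    cr <- count_runs(sh)
    rand_n[r, ] <- cr[, "n"]
    rand_bp[r, ] <- cr[, "bp"]
  }
  tab <- data.frame(
    tau = tau_grid,
    observed_n = obs[, "n"],
    observed_bp = obs[, "bp"],
    rand_mean_n = colMeans(rand_n),
    rand_sd_n = apply(rand_n, 2L, stats::sd),
    rand_q05 = apply(rand_n, 2L, stats::quantile, probs = 0.05),
    rand_q95 = apply(rand_n, 2L, stats::quantile, probs = 0.95),
    row.names = NULL)
  tab$enrichment <- ifelse(tab$rand_mean_n > 0,
                           tab$observed_n / tab$rand_mean_n, Inf)
  attr(tab, "replicates") <- rand_n
  attr(tab, "replicates_bp") <- rand_bp
  attr(tab, "seed") <- seed
  attr(tab, "n_reps") <- n_reps
  class(tab) <- c("CalibrationTable", "data.frame")
  tab
}
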