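#' Default toy genome layout for simulations
#'
#' Three chromosomes of 1 Mb: large enough that random triple collisions
#' of sparse peak sets are essentially absent, small enough for per-base
#' oracle checks.
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_len Length of each chromosome in bp (default 1e6).
#' @return A `Seqinfo` layout.
#' @export
toy_genome <- function(n_chroms = 3L, chrom_len = 1e6) {
  genome_layout(stats::setNames(rep(chrom_len, n_chroms),
                                paste0("chr", seq_len(n_chroms))))
}

#' Simulate a ground-truth cistrome
#'
#' Places non-overlapping "true" binding sites uniformly on the genome by
#' rejection sampling, with lengths drawn uniformly from
#' `[len_min, len_max]`. Deterministic for a given seed.
#'
#' @param layout `Seqinfo` genome layout.
#' @param n_sites Number of sites.
#' @param len_min,len_max Site length bounds in bp (defaults 150 and 400,
#'   typical ChIP-seq peak widths).
#' @param seed Integer seed.
#' @param max_rounds Cap on rejection-sampling rounds before erroring with
#'   a suggestion to enlarge the genome.
#' @return `GRanges` of non-overlapping sites, sorted, named
#'   `site_<i>`, with the layout attached.
#' @export
simulate_truth <- function(layout, n_sites, len_min = 150L, len_max = 400L,
                           seed = 1L, max_rounds = 200L) {
  stopifnot(n_sites >= 0L, len_min >= 1L, len_max >= len_min)
  if (n_sites == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = layout)
    S4Vectors::mcols(gr)$name <- character(0)
    return(gr)
  }
  lens <- GenomeInfoDb::seqlengths(layout)
  with_seed(seed, {
    accepted <- GenomicRanges::GRanges()
    rounds <- 0L
    while (length(accepted) < n_sites) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("could not place ", n_sites, " non-overlapping sites; ",
             "use a larger genome or fewer/shorter sites")
      }
      m <- 2L * (n_sites - length(accepted))
      w <- floor(stats::runif(m, len_min, len_max + 1))
      ch <- sample(names(lens), m, replace = TRUE,
                   prob = lens / sum(lens))
      s0 <- floor(stats::runif(m) * (lens[ch] - w + 1))
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, width = w))
      ok <- GenomicRanges::countOverlaps(cand, cand,
                                         ignore.strand = TRUE) == 1L
      if (length(accepted) > 0L) {
        ok <- ok & GenomicRanges::countOverlaps(cand, accepted,
                                                ignore.strand = TRUE) == 0L
      }
      accepted <- c(accepted, cand[ok])
      if (length(accepted) > n_sites) {
        accepted <- accepted[seq_len(n_sites)]
      }
    }
    accepted <- GenomicRanges::sort(set_layout(accepted, layout),
                                    ignore.strand = TRUE)
    S4Vectors::mcols(accepted)$name <-
      sprintf("site_%04d", seq_along(accepted))
    accepted
  })
}

#' Simulate multi-study peak sets around a truth cistrome
#'
#' Emulates the statistical structure that majority-vote integration
#' assumes: every study detects each true site independently with
#' probability `sensitivity` (peak boundaries jittered by Gaussian noise),
#' and additionally reports `noise_per_study` spurious peaks placed
#' uniformly. Peak provenance is recorded in the name field
#' (`true_<site>` / `noise_<k>`) so recovery can be scored unambiguously.
#'
#' @param truth `GRanges` from [simulate_truth()].
#' @param layout `Seqinfo` layout.
#' @param n_studies Number of studies (default 8).
#' @param sensitivity Per-site detection probability (default 0.9).
#' @param noise_per_study Spurious peaks per study (default 50).
#' @param jitter_sd SD in bp of the Gaussian boundary jitter (default 10).
#' @param seed Integer seed; study `i` uses a derived seed.
#' @return Named list of `GRanges` (`study_1`, ...), each with a `name`
#'   provenance column.
#' @export
simulate_studies <- function(truth, layout, n_studies = 8L,
                             sensitivity = 0.9, noise_per_study = 50L,
                             jitter_sd = 10, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, n_studies >= 1L)
  lens <- GenomeInfoDb::seqlengths(layout)
  truth_w <- GenomicRanges::width(truth)
  out <- lapply(seq_len(n_studies), function(i) {
    with_seed(derive_seed(seed, i), {
      take <- stats::runif(length(truth)) < sensitivity
      det <- truth[take]
      if (length(det) > 0L) {
        s0 <- GenomicRanges::start(det) - 1 +
          round(stats::rnorm(length(det), 0, jitter_sd))
        e0 <- as.numeric(GenomicRanges::end(det)) +
          round(stats::rnorm(length(det), 0, jitter_sd))
        ch <- as.character(GenomicRanges::seqnames(det))
        s0 <- pmax(0, pmin(s0, lens[ch] - 1))
        e0 <- pmax(s0 + 1, pmin(e0, lens[ch]))
        det <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, e0))
        S4Vectors::mcols(det)$name <-
          paste0("true_", S4Vectors::mcols(truth)$name[take])
      }
      if (noise_per_study > 0L) {
        w <- if (length(truth_w) > 0L) {
          sample(truth_w, noise_per_study, replace = TRUE)
        } else {
          rep(200L, noise_per_study)
        }
        ch <- sample(names(lens), noise_per_study, replace = TRUE,
                     prob = lens / sum(lens))
        s0 <- floor(stats::runif(noise_per_study) * (lens[ch] - w + 1))
        noise <- GenomicRanges::GRanges(ch,
                                        IRanges::IRanges(s0 + 1, width = w))
        S4Vectors::mcols(noise)$name <-
          paste0("noise_", seq_len(noise_per_study))
        det <- c(det, noise)
      }
      det <- GenomicRanges::sort(set_layout(det, layout),
                                 ignore.strand = TRUE)
      S4Vectors::metadata(det)$label <- paste0("study_", i)
      det
    })
  })
  names(out) <- paste0("study_", seq_len(n_studies))
  out
}

#' Simulate binned ChIP signal with planted structure
#'
#' Generates a bin-count matrix whose columns emulate ChIP experiments
#' differing by a planted per-experiment scale factor: each site has a
#' shared unimodal (Gaussian-bump) mean profile over the bins, with a
#' per-site amplitude drawn once and shared by all bump-class experiments
#' (emulating cofactor co-binding at the same sites); flat-class
#' experiments see only the baseline. Counts are Poisson with mean
#' `profile * size_factor`.
#'
#' @param n_sites Number of sites (default 50).
#' @param scheme A [bin_scheme()] (defaults give 200 bins).
#' @param experiments data.frame with columns `label`, `size_factor`
#'   (strictly positive), and `profile` (`"bump"` or `"flat"`).
#' @param baseline Baseline Poisson mean per bin before scaling
#'   (default 15, so all scaled means stay comfortably positive).
#' @param amplitude Peak height of the bump above baseline (default 60).
#' @param bump_sd_bins SD of the Gaussian bump in bins (default 8).
#' @param seed Integer seed.
#' @return A `BinCountMatrix` with the given experiment metadata and the
#'   planted size factors stored in `experiments$size_factor`.
#' @export
simulate_signal <- function(n_sites = 50L, scheme = bin_scheme(),
                            experiments = data.frame(
                              label = c("tri", "cofactor", "null"),
                              size_factor = c(1, 2.5, 0.4),
                              profile = c("bump", "bump", "flat")),
                            baseline = 15, amplitude = 60,
                            bump_sd_bins = 8, seed = 1L) {
  stopifnot(all(c("label", "size_factor", "profile") %in%
                  colnames(experiments)))
  s_star <- as.numeric(experiments$size_factor)
  if (any(s_star <= 0)) stop("planted size factors must be > 0")
  nb <- scheme$n_bins
  with_seed(seed, {
    center <- (nb - 1) / 2
    shape <- exp(-((seq_len(nb) - 1 - center)^2) / (2 * bump_sd_bins^2))
    amp <- stats::runif(n_sites, 0.5, 1.5) * amplitude
    mean_bump <- baseline + outer(shape, amp)  # nb x n_sites
    mu_bump <- as.vector(mean_bump)            # column-major = site-major
    mu_flat <- rep(baseline, n_sites * nb)
    counts <- vapply(seq_len(nrow(experiments)), function(i) {
      mu <- if (experiments$profile[i] == "bump") mu_bump else mu_flat
      stats::rpois(n_sites * nb, mu * s_star[i])
    }, numeric(n_sites * nb))
    if (!is.matrix(counts)) counts <- matrix(counts, ncol = nrow(experiments))
    colnames(counts) <- experiments$label
    new_bin_count_matrix(counts, sprintf("site_%04d", seq_len(n_sites)),
                         nb, scheme = scheme, experiments = experiments)
  })
}

#' Simulate a chromatin-state segmentation with planted feature association
#'
#' Tiles the genome with fixed-size blocks cycling through the state
#' catalog, then draws feature intervals that fall inside the planted
#' state with probability `planted_prob` and uniformly on the genome
#' otherwise, giving a recoverable feature-state enrichment.
#'
#' @param layout `Seqinfo` layout.
#' @param states Character state catalog (default `S1`..`S5`).
#' @param block_size Block size in bp (default 2000).
#' @param planted_state State to associate features with (default first).
#' @param planted_prob Probability a feature is drawn inside the planted
#'   state (default 0.8).
#' @param n_features Number of feature intervals (default 200).
#' @param feature_len Feature length in bp (default 300; must fit in a
#'   block).
#' @param seed Integer seed.
#' @return List with `segmentation` (a `Segmentation`) and `features`
#'   (`GRanges`).
#' @export
simulate_segmentation <- function(layout, states = paste0("S", 1:5),
                                  block_size = 2000L,
                                  planted_state = states[1L],
                                  planted_prob = 0.8, n_features = 200L,
                                  feature_len = 300L, seed = 1L) {
  stopifnot(length(states) >= 1L, planted_state %in% states,
            planted_prob >= 0, planted_prob <= 1,
            feature_len <= block_size)
  lens <- GenomeInfoDb::seqlengths(layout)
  segs <- do.call(rbind, lapply(names(lens), function(ch) {
    s0 <- seq(0, lens[[ch]] - 1, by = block_size)
    e0 <- pmin(s0 + block_size, lens[[ch]])
    data.frame(chrom = ch, s0 = s0, e0 = e0,
               state = rep_len(states, length(s0)),
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(segs$chrom,
                               IRanges::IRanges(segs$s0 + 1, segs$e0))
  S4Vectors::mcols(gr)$state <- segs$state
  gr <- set_layout(gr, layout)
  seg <- as_segmentation(gr)
  planted_blocks <- which(segs$state == planted_state &
                            segs$e0 - segs$s0 >= feature_len)
  features <- with_seed(seed, {
    inside <- stats::runif(n_features) < planted_prob
    ch <- character(n_features); s0 <- numeric(n_features)
    n_in <- sum(inside)
    if (n_in > 0L) {
      b <- sample(planted_blocks, n_in, replace = TRUE)
      off <- floor(stats::runif(n_in) *
                     (segs$e0[b] - segs$s0[b] - feature_len + 1))
      ch[inside] <- segs$chrom[b]
      s0[inside] <- segs$s0[b] + off
    }
    n_out <- n_features - n_in
    if (n_out > 0L) {
      cho <- sample(names(lens), n_out, replace = TRUE,
                    prob = lens / sum(lens))
      ch[!inside] <- cho
      s0[!inside] <- floor(stats::runif(n_out) * (lens[cho] - feature_len + 1))
    }
    f <- GenomicRanges::GRanges(ch,
                                IRanges::IRanges(s0 + 1,
                                                 width = feature_len))
    GenomicRanges::sort(set_layout(f, layout), ignore.strand = TRUE)
  })
  list(segmentation = seg, features = features)
}
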