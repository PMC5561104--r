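#' Majority-vote consensus of peak sets
#'
#' Builds a consensus cistrome from a list of peak sets: positions covered
#' by at least `tau` of the input sets (each collapsed to one vote per
#' position) are selected, and maximal runs of qualifying positions are
#' emitted as consensus intervals. `tau` is the "severity" of the vote:
#' `tau = 1` gives the collapsed union, `tau = n` the per-base
#' intersection. Each interval carries the maximum vote depth observed
#' within it as its `support`.
#'
#' @param sets A list of `GRanges` peak sets (>= 1).
#' @param tau Threshold. In `"count"` mode an integer in `[1, n]`; in
#'   `"fraction"` mode a value in `(0, 1]` and the effective threshold is
#'   `ceiling(tau * n)` (so 75 percent of 6 sets is 5).
#' @param tau_mode `"count"` or `"fraction"`.
#' @param min_len Drop consensus intervals shorter than this many bp
#'   (default 1, i.e. no filter).
#' @param layout Optional `Seqinfo` layout for validation.
#' @param permissive Passed to [coverage_track()]; defaults to `TRUE`
#'   because real peak sets rarely mention every chromosome.
#' @return A `ConsensusResult`: list with `intervals` (`GRanges` with
#'   integer `support` column), `tau` (effective integer threshold),
#'   `n_inputs`, and `input_labels`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 51), c(30, 60)))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(21, 40))
#' cc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(26, 56), c(35, 58)))
#' refgen(list(a, b, cc), tau = 2)
#' @export
refgen <- function(sets, tau, tau_mode = c("count", "fraction"),
                   min_len = 1L, layout = NULL, permissive = TRUE) {
  tau_mode <- match.arg(tau_mode)
  if (methods::is(sets, "GRanges")) sets <- list(sets)
  n <- length(sets)
  if (n < 1L) stop("refgen needs at least one input set")
  tau_eff <- effective_tau(tau, n, tau_mode)
  labels <- vapply(seq_along(sets), function(i) {
    lab <- S4Vectors::metadata(sets[[i]])$label
    if (is.null(lab)) paste0("set", i) else lab
  }, character(1))
  cov <- coverage_track(sets, layout = layout, permissive = permissive)
  seg <- data.frame(chrom = as.character(GenomicRanges::seqnames(cov)),
                    s0 = GenomicRanges::start(cov) - 1,
                    e0 = as.numeric(GenomicRanges::end(cov)),
                    depth = S4Vectors::mcols(cov)$depth,
                    stringsAsFactors = FALSE)
  runs <- runs_at_tau(seg, tau_eff)
  runs <- runs[runs$e0 - runs$s0 >= min_len, , drop = FALSE]
  gr <- seg_to_granges(runs, layout)
  S4Vectors::mcols(gr)$support <- runs$support
  structure(list(intervals = gr, tau = tau_eff, n_inputs = n,
                 input_labels = labels),
            class = "ConsensusResult")
}

effective_tau <- function(tau, n, tau_mode) {
  if (tau_mode == "fraction") {
    if (tau <= 0 || tau > 1) stop("fractional tau must be in (0, 1]")
    tau <- ceiling(tau * n)
  }
  if (tau != floor(tau) || tau < 1 || tau > n) {
    stop("tau must be an integer in [1, ", n, "], got ", tau)
  }
  as.integer(tau)
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult: ", length(x$intervals), " interval(s), tau = ",
      x$tau, " of ", x$n_inputs, " input set(s)\n", sep = "")
  cat("inputs:", paste(x$input_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical reference-cistrome construction
#'
#' Chains three majority votes to go from replicate-level peak sets to a
#' reference cistrome, mirroring how multi-study ChIP compendia are
#' integrated: (1) within each study, sites present in *all* biological
#' replicates are kept (`tau = n_replicates`); (2) within each experimental
#' context, sites present in at least a fraction (default 75 percent, rounded up)
#' of that context's study cistromes are kept; (3) the reference is the
#' union of the context cistromes (`tau = 1`).
#'
#' @param plan Nested named list: `context -> study -> list of GRanges`
#'   replicate peak sets (a single `GRanges` is accepted in place of a
#'   one-replicate list).
#' @param context_tau Threshold for the context-level vote (default 0.75).
#' @param context_tau_mode `"fraction"` (default) or `"count"`.
#' @param study_tau_mode Study-level rule: `"all"` (default; all replicates)
#'   or a numeric fraction in `(0,1]`.
#' @param layout Optional `Seqinfo` layout.
#' @return A list of class `ReferenceBuild` with `study_cistromes`
#'   (context -> study -> `GRanges`), `context_cistromes` (named list of
#'   `GRanges`), and `reference` (a `ConsensusResult` over contexts).
#' @export
build_reference <- function(plan, context_tau = 0.75,
                            context_tau_mode = c("fraction", "count"),
                            study_tau_mode = "all", layout = NULL) {
  context_tau_mode <- match.arg(context_tau_mode)
  if (length(plan) == 0L || is.null(names(plan)) || any(!nzchar(names(plan))))
    stop("plan must be a non-empty named list of contexts")
  study_cistromes <- lapply(names(plan), function(ctx) {
    studies <- plan[[ctx]]
    if (length(studies) == 0L) stop("context '", ctx, "' has no studies")
    out <- lapply(names(studies), function(st) {
      reps <- studies[[st]]
      if (methods::is(reps, "GRanges")) reps <- list(reps)
      if (length(reps) == 0L) {
        stop("study '", st, "' in context '", ctx, "' has no replicates")
      }
      if (identical(study_tau_mode, "all")) {
        res <- refgen(reps, tau = length(reps), layout = layout)
      } else {
        res <- refgen(reps, tau = study_tau_mode, tau_mode = "fraction",
                      layout = layout)
      }
      g <- res$intervals
      S4Vectors::mcols(g) <- NULL
      S4Vectors::metadata(g)$label <- st
      g
    })
    names(out) <- names(studies)
    out
  })
  names(study_cistromes) <- names(plan)
  context_cistromes <- lapply(names(plan), function(ctx) {
    res <- refgen(study_cistromes[[ctx]], tau = context_tau,
                  tau_mode = context_tau_mode, layout = layout)
    g <- res$intervals
    S4Vectors::mcols(g) <- NULL
    S4Vectors::metadata(g)$label <- ctx
    g
  })
  names(context_cistromes) <- names(plan)
  reference <- refgen(context_cistromes, tau = 1L, layout = layout)
  structure(list(study_cistromes = study_cistromes,
                 context_cistromes = context_cistromes,
                 reference = reference),
            class = "ReferenceBuild")
}

#' @export
print.ReferenceBuild <- function(x, ...) {
  cat("ReferenceBuild:", length(x$context_cistromes), "context(s);",
      length(x$reference$intervals), "reference interval(s)\n")
  for (ctx in names(x$context_cistromes)) {
    cat("  ", ctx, ": ", length(x$context_cistromes[[ctx]]),
        " site(s) from ", length(x$study_cistromes[[ctx]]),
        " study cistrome(s)\n", sep = "")
  }
  invisible(x)
}

#' Class reference sites by experimental-context co-occurrence
#'
#' Each reference binding site is labeled `Ck` where `k` is the number of
#' experimental contexts whose cistrome overlaps it (by at least
#' `min_overlap_bp`). The classes partition the reference cistrome: with
#' four contexts, `C1` sites are context-private, `C4` sites are bound in
#' every context.
#'
#' @param reference A `ConsensusResult` (from [build_reference()]'s
#'   `reference`) or a plain `GRanges` of reference sites.
#' @param context_cistromes Named list of `GRanges`, one per context.
#' @param min_overlap_bp Minimum overlap in bp to count a context
#'   (default 1).
#' @return A `CooccurrenceClassing`: list with `table` (data.frame:
#'   `site_id`, coordinates, `contexts` comma-joined, `k`, `class`) and
#'   `counts` (named integer vector per class), plus `sites` (`GRanges`).
#' @export
classify_cooccurrence <- function(reference, context_cistromes,
                                  min_overlap_bp = 1L) {
  user_supplied <- !inherits(reference, "ConsensusResult")
  sites <- if (user_supplied) reference else reference$intervals
  stopifnot(methods::is(sites, "GRanges"))
  if (length(context_cistromes) == 0L || is.null(names(context_cistromes)))
    stop("context_cistromes must be a non-empty named list")
  hits <- vapply(context_cistromes, function(ctx) {
    suppressWarnings(
      GenomicRanges::countOverlaps(sites, ctx, minoverlap = min_overlap_bp,
                                   ignore.strand = TRUE)) > 0L
  }, logical(length(sites)))
  if (length(sites) == 1L) hits <- matrix(hits, nrow = 1L,
                                          dimnames = list(NULL, names(context_cistromes)))
  k <- as.integer(rowSums(hits))
  if (any(k == 0L)) {
    if (!user_supplied) {
      stop(sum(k == 0L), " reference interval(s) overlap no context ",
           "cistrome; the reference does not derive from these contexts")
    }
    warning(sum(k == 0L), " site(s) overlap no context cistrome; ",
            "classed C0")
  }
  cls <- paste0("C", k)
  ctxs <- apply(hits, 1L, function(h)
    paste(names(context_cistromes)[h], collapse = ","))
  tab <- data.frame(
    site_id = paste0("site_", seq_along(sites)),
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1,
    end = as.numeric(GenomicRanges::end(sites)),
    contexts = ctxs, k = k, class = cls,
    stringsAsFactors = FALSE)
  lv <- paste0("C", seq(0L, length(context_cistromes)))
  counts <- table(factor(cls, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  counts <- counts[counts > 0L | names(counts) != "C0"]
  structure(list(table = tab, counts = counts, sites = sites,
                 n_contexts = length(context_cistromes)),
            class = "CooccurrenceClassing")
}

#' @export
print.CooccurrenceClassing <- function(x, ...) {
  cat("CooccurrenceClassing:", nrow(x$table), "site(s) over",
      x$n_contexts, "context(s)\n")
  print(x$counts)
  invisible(x)
}

#' Annotate reference sites with independent feature overlaps
#'
#' For each feature group (a set of replicate interval sets, e.g. three
#' ChIA-PET anchor replicates), a reference site is a hit iff it overlaps
#' at least `min_support` of the group's replicates by >= 1 bp. This
#' implements replicate-support rules such as "2 of 3 replicates" for
#' interaction anchors or "all replicates" for copy-number regions.
#'
#' @param reference `GRanges` of reference sites (or a `ConsensusResult`).
#' @param feature_groups Named list; each element a list of `GRanges`
#'   replicates (a bare `GRanges` counts as one replicate).
#' @param min_support Named integer vector (per group); groups not named
#'   default to 1. Must not exceed the group's replicate count.
#' @return An `OverlapAnnotation`: list with `hits` (logical matrix sites x
#'   groups), `fractions` (named numeric, fraction of reference sites hit),
#'   and `min_support` used.
#' @export
annotate_overlap <- function(reference, feature_groups,
                             min_support = integer()) {
  if (inherits(reference, "ConsensusResult")) reference <- reference$intervals
  stopifnot(methods::is(reference, "GRanges"))
  if (length(feature_groups) == 0L || is.null(names(feature_groups)))
    stop("feature_groups must be a non-empty named list")
  unknown <- setdiff(names(min_support), names(feature_groups))
  if (length(unknown)) {
    stop("min_support names unknown group(s): ",
         paste(unknown, collapse = ", "))
  }
  groups <- lapply(feature_groups, function(g) {
    if (methods::is(g, "GRanges")) list(g) else g
  })
  ms <- vapply(names(groups), function(nm) {
    v <- if (nm %in% names(min_support)) as.integer(min_support[[nm]]) else 1L
    if (v < 1L || v > length(groups[[nm]])) {
      stop("min_support for '", nm, "' must be in [1, ",
           length(groups[[nm]]), "]")
    }
    v
  }, integer(1))
  hits <- vapply(names(groups), function(nm) {
    reps <- groups[[nm]]
    n_over <- Reduce(`+`, lapply(reps, function(r) {
      as.integer(suppressWarnings(
        GenomicRanges::countOverlaps(reference, r,
                                     ignore.strand = TRUE)) > 0L)
    }))
    n_over >= ms[[nm]]
  }, logical(length(reference)))
  if (length(reference) == 1L) {
    hits <- matrix(hits, nrow = 1L, dimnames = list(NULL, names(groups)))
  }
  fractions <- if (length(reference) == 0L) {
    stats::setNames(rep(NA_real_, length(groups)), names(groups))
  } else {
    colMeans(hits)
  }
  structure(list(hits = hits, fractions = fractions, min_support = ms,
                 n_sites = length(reference)),
            class = "OverlapAnnotation")
}

#' @export
print.OverlapAnnotation <- function(x, ...) {
  cat("OverlapAnnotation over", x$n_sites, "site(s)\n")
  print(round(x$fractions, 4))
  invisible(x)
}
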