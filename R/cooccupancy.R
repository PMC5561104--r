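#' Per-site Pearson correlation between two signal profiles
#'
#' Correlates, at each binding site, the bin vector of the regulator of
#' interest with the bin vector of a candidate cofactor (both typically
#' normalized, context-matched reference profiles sharing the bin scheme
#' and site universe). Sites where either vector has zero variance yield
#' an undefined correlation (`NA`), which is excluded from and counted in
#' downstream averages rather than imputed as zero.
#'
#' @param x,y Numeric vectors of length `n_sites * n_bins` in site-major
#'   order (or single columns extracted from a `BinCountMatrix`).
#' @param n_bins Number of bins per site.
#' @param site_ids Optional site identifiers (length `n_sites`).
#' @return Named numeric vector of per-site correlations (`NA` where
#'   undefined).
#' @export
pearson_per_site <- function(x, y, n_bins, site_ids = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) %% n_bins != 0L) {
    stop("profile length is not a multiple of n_bins; bin schemes differ")
  }
  n_sites <- length(x) %/% n_bins
  g <- rep(seq_len(n_sites), each = n_bins)
  sx <- rowsum(x, g); sy <- rowsum(y, g)
  sxx <- rowsum(x * x, g); syy <- rowsum(y * y, g)
  sxy <- rowsum(x * y, g)
  nb <- n_bins
  cov <- sxy - sx * sy / nb
  vx <- sxx - sx^2 / nb
  vy <- syy - sy^2 / nb
  r <- rep(NA_real_, n_sites)
  ok <- vx > 0 & vy > 0
  r[ok] <- cov[ok] / sqrt(vx[ok] * vy[ok])
  r <- pmin(1, pmax(-1, r))
  r[!ok] <- NA_real_
  if (!is.null(site_ids)) names(r) <- site_ids
  r
}

#' Correlate a regulator's profile with candidate cofactor profiles
#'
#' Computes per-site Pearson correlations between one reference column of
#' a profile matrix (the regulator of interest) and every other selected
#' column (candidate cofactors), within a shared site universe and bin
#' scheme. Comparisons should be context-matched: pass the per-context
#' columns of a [two_step_normalize()] result.
#'
#' @param M A `BinCountMatrix` of (normalized) profiles.
#' @param tri_col Column name or index of the regulator-of-interest
#'   profile.
#' @param factor_cols Columns to correlate against (default: all others).
#' @param concatenated If `TRUE`, additionally compute one global r per
#'   factor over all bins concatenated.
#' @return A `CorrelationTable`: list with `r` (matrix sites x factors),
#'   `site_ids`, `n_undefined` per factor, and optionally `global_r`.
#' @export
correlate_profiles <- function(M, tri_col, factor_cols = NULL,
                               concatenated = FALSE) {
  stopifnot(inherits(M, "BinCountMatrix"))
  cn <- colnames(M$counts)
  if (is.character(tri_col)) tri_col <- match(tri_col, cn)
  if (is.na(tri_col) || tri_col < 1L || tri_col > ncol(M$counts)) {
    stop("unknown reference column")
  }
  if (is.null(factor_cols)) factor_cols <- setdiff(seq_along(cn), tri_col)
  if (is.character(factor_cols)) factor_cols <- match(factor_cols, cn)
  if (anyNA(factor_cols)) stop("unknown factor column(s)")
  x <- M$counts[, tri_col]
  r <- vapply(factor_cols, function(j) {
    pearson_per_site(x, M$counts[, j], M$n_bins)
  }, numeric(length(M$site_ids)))
  if (!is.matrix(r)) r <- matrix(r, ncol = length(factor_cols))
  colnames(r) <- cn[factor_cols]
  rownames(r) <- M$site_ids
  out <- list(r = r, site_ids = M$site_ids,
              tri = cn[tri_col],
              n_undefined = colSums(is.na(r)))
  if (concatenated) {
    out$global_r <- vapply(factor_cols, function(j) {
      stats::cor(x, M$counts[, j])
    }, numeric(1))
    names(out$global_r) <- cn[factor_cols]
  }
  structure(out, class = "CorrelationTable")
}

#' @export
print.CorrelationTable <- function(x, ...) {
  cat("CorrelationTable:", nrow(x$r), "site(s) x", ncol(x$r),
      "factor(s); reference =", x$tri, "\n")
  print(round(colMeans(x$r, na.rm = TRUE), 4))
  invisible(x)
}

#' Average per-site correlations within co-occurrence classes
#'
#' Arithmetic mean of the defined (non-`NA`) per-site correlations for each
#' (factor, class) cell, with the number of contributing sites. A class
#' with zero valid sites yields `NA` and is flagged by `n_valid = 0`.
#'
#' @param corr A `CorrelationTable` (or a numeric matrix sites x factors).
#' @param classing A `CooccurrenceClassing` covering the same site
#'   universe, or a character vector of class labels per site.
#' @return data.frame with columns `factor`, `class`, `mean_r`, `n_valid`.
#' @export
subset_mean <- function(corr, classing) {
  r <- if (inherits(corr, "CorrelationTable")) corr$r else as.matrix(corr)
  cls <- if (inherits(classing, "CooccurrenceClassing")) {
    classing$table$class
  } else {
    as.character(classing)
  }
  if (length(cls) != nrow(r)) {
    stop("classing does not cover the site universe (",
         length(cls), " classes vs ", nrow(r), " sites)")
  }
  levels <- sort(unique(cls))
  out <- do.call(rbind, lapply(colnames(r), function(f) {
    do.call(rbind, lapply(levels, function(cl) {
      v <- r[cls == cl, f]
      v <- v[!is.na(v)]
      data.frame(factor = f, class = cl,
                 mean_r = if (length(v)) mean(v) else NA_real_,
                 n_valid = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Rank sites by average cofactor correlation
#'
#' Averages each site's correlation over a chosen set of cofactors, ranks
#' sites by decreasing mean correlation (ties broken by stable site
#' order), and assigns quartile labels Q1 (top) to Q4. Sites undefined for
#' every selected factor are left unranked.
#'
#' @param corr A `CorrelationTable` or numeric matrix sites x factors.
#' @param factors Factor (column) names to average over (default: all).
#' @return data.frame with `site_id`, `mean_r`, `rank` (`NA` if
#'   unranked), `quartile` (`"Q1"`..`"Q4"` or `NA`).
#' @export
rank_sites_by_cofactor_support <- function(corr, factors = NULL) {
  r <- if (inherits(corr, "CorrelationTable")) corr$r else as.matrix(corr)
  ids <- rownames(r)
  if (is.null(ids)) ids <- paste0("site_", seq_len(nrow(r)))
  if (is.null(factors)) factors <- colnames(r)
  miss <- setdiff(factors, colnames(r))
  if (length(miss)) stop("unknown factor(s): ", paste(miss, collapse = ", "))
  if (length(factors) < 1L) stop("select at least one factor")
  sub <- r[, factors, drop = FALSE]
  mean_r <- rowMeans(sub, na.rm = TRUE)
  mean_r[rowSums(!is.na(sub)) == 0L] <- NA_real_
  ranked <- which(!is.na(mean_r))
  ord <- ranked[order(-mean_r[ranked], ranked, method = "radix")]
  rk <- rep(NA_integer_, length(mean_r))
  rk[ord] <- seq_along(ord)
  n <- length(ord)
  q <- rep(NA_character_, length(mean_r))
  if (n > 0L) q[!is.na(rk)] <- paste0("Q", ceiling(4 * rk[!is.na(rk)] / n))
  data.frame(site_id = ids, mean_r = mean_r, rank = rk, quartile = q,
             stringsAsFactors = FALSE, row.names = NULL)
}
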