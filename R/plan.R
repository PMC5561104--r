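#' Read an analysis plan from YAML
#'
#' @param path Path to a YAML plan file (see [run_plan()] for the schema).
#' @return The plan as a nested list, with `base_dir` set to the plan
#'   file's directory so relative paths resolve against it.
#' @export
read_plan <- function(path) {
  plan <- yaml::read_yaml(path)
  plan$base_dir <- dirname(normalizePath(path))
  plan
}

plan_path <- function(plan, p) {
  if (is.null(plan$base_dir) || grepl("^/", p)) p
  else file.path(plan$base_dir, p)
}

# Enumerate all validation problems before any computation.
validate_plan <- function(plan) {
  problems <- character()
  need <- function(cond, msg) {
    if (!cond) problems <<- c(problems, msg)
  }
  need(!is.null(plan$genome), "plan: 'genome' (chrom.sizes path) is required")
  if (!is.null(plan$genome)) {
    need(file.exists(plan_path(plan, plan$genome)),
         paste0("plan: genome file not found: ", plan$genome))
  }
  need(!is.null(plan$cistrome$contexts) &&
         length(plan$cistrome$contexts) > 0,
       "plan: 'cistrome: contexts' is required")
  for (ctx in names(plan$cistrome$contexts)) {
    studies <- plan$cistrome$contexts[[ctx]]
    need(length(studies) > 0, paste0("plan: context '", ctx, "' is empty"))
    for (st in names(studies)) {
      for (p in unlist(studies[[st]])) {
        need(file.exists(plan_path(plan, p)),
             paste0("plan: replicate file not found: ", p))
      }
    }
  }
  for (e in plan$signal$experiments) {
    need(!is.null(e$label) && !is.null(e$reads),
         "plan: each signal experiment needs 'label' and 'reads'")
    if (!is.null(e$reads)) {
      need(file.exists(plan_path(plan, e$reads)),
           paste0("plan: reads file not found: ", e$reads))
    }
  }
  for (g in names(plan$features$groups)) {
    for (p in unlist(plan$features$groups[[g]])) {
      need(file.exists(plan_path(plan, p)),
           paste0("plan: feature file not found: ", p))
    }
  }
  if (!is.null(plan$segmentation)) {
    need(file.exists(plan_path(plan, plan$segmentation)),
         paste0("plan: segmentation file not found: ", plan$segmentation))
  }
  problems
}

#' Run a full integrative analysis from a plan
#'
#' Orchestrates the three analysis arms from one declarative plan:
#' (1) hierarchical reference-cistrome construction and co-occurrence
#' classing (always run), with optional random-background threshold
#' calibration; (2) optional signal extraction, two-step normalization and
#' cofactor correlation; (3) optional feature-overlap annotation and
#' chromatin-state assignment/enrichment. All outputs are plain TSV/BED
#' plus a JSON manifest recording package version, seed and parameters;
#' re-running the same plan yields byte-identical outputs.
#'
#' Plan schema (YAML or nested list):
#' \preformatted{
#' genome: chrom.sizes            # required
#' seed: 17
#' drop_chroms: [chrY]            # optional input filter
#' cistrome:
#'   context_tau: 0.75            # fraction (default) or integer count
#'   context_tau_mode: fraction
#'   contexts:
#'     ContextA: {study1: [r1.bed, r2.bed], study2: [r3.bed]}
#' calibrate: {n_reps: 100}       # optional, per context
#' signal:                        # optional
#'   half_window: 5000
#'   bin_size: 50
#'   experiments:
#'     - {label: tri_1, factor: TRI, context: ContextA, reads: tri1.bed}
#'   tri_factor: TRI              # enables correlation stage
#' features:                      # optional
#'   groups: {chiapet: [a.bed, b.bed, c.bed]}
#'   min_support: {chiapet: 2}
#' segmentation: states.bed       # optional
#' }
#'
#' @param plan A plan list (e.g. from [read_plan()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_plan <- function(plan, outdir) {
  problems <- validate_plan(plan)
  if (length(problems) > 0L) {
    stop("plan validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(plan$seed)) 1L else as.integer(plan$seed)
  layout <- read_chrom_sizes(plan_path(plan, plan$genome))
  drop_chroms <- unlist(plan$drop_chroms)
  read_peaks <- function(p, label = NULL) {
    read_bed(plan_path(plan, p), layout = layout,
             drop_chroms = drop_chroms, label = label)
  }
  outputs <- character()
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(outdir, name)
  }

  ## -- cistrome arm ---------------------------------------------------
  ctx_tau <- plan$cistrome$context_tau
  if (is.null(ctx_tau)) ctx_tau <- 0.75
  ctx_mode <- plan$cistrome$context_tau_mode
  if (is.null(ctx_mode)) ctx_mode <- "fraction"
  tree <- lapply(plan$cistrome$contexts, function(studies) {
    lapply(studies, function(reps) lapply(unlist(reps), read_peaks))
  })
  build <- build_reference(tree, context_tau = ctx_tau,
                           context_tau_mode = ctx_mode, layout = layout)
  write_bed(build$reference, emit("reference.bed"))
  for (ctx in names(build$context_cistromes)) {
    write_bed(build$context_cistromes[[ctx]],
              emit(paste0("context_", ctx, ".bed")))
  }
  classing <- classify_cooccurrence(build$reference,
                                    build$context_cistromes)
  write_tsv(classing$table, emit("classes.tsv"))
  result <- list(build = build, classing = classing)

  ## -- optional tau calibration per context ---------------------------
  if (!is.null(plan$calibrate)) {
    n_reps <- plan$calibrate$n_reps
    if (is.null(n_reps)) n_reps <- 1000L
    for (ctx in names(build$study_cistromes)) {
      calib <- calibrate_tau(build$study_cistromes[[ctx]], layout,
                             n_reps = n_reps, seed = seed)
      write_tsv(as.data.frame(calib), emit(paste0("calibration_", ctx,
                                                  ".tsv")))
    }
  }

  ## -- signal arm ------------------------------------------------------
  if (!is.null(plan$signal)) {
    hw <- plan$signal$half_window
    if (is.null(hw)) hw <- 5000L
    bs <- plan$signal$bin_size
    if (is.null(bs)) bs <- 50L
    scheme <- bin_scheme(hw, bs)
    exps <- plan$signal$experiments
    meta <- data.frame(
      label = vapply(exps, `[[`, character(1), "label"),
      factor = vapply(exps, function(e)
        if (is.null(e$factor)) e$label else e$factor, character(1)),
      context = vapply(exps, function(e)
        if (is.null(e$context)) "all" else e$context, character(1)),
      stringsAsFactors = FALSE)
    reads <- lapply(exps, function(e) read_peaks(e$reads, label = e$label))
    names(reads) <- meta$label
    ref_sites <- build$reference$intervals
    S4Vectors::mcols(ref_sites)$name <- classing$table$site_id
    counts <- count_in_bins(reads, ref_sites,
                            scheme = scheme, layout = layout,
                            experiments = meta)
    write_count_matrix(counts, emit("counts.tsv"))
    profiles <- two_step_normalize(counts)
    write_count_matrix(profiles, emit("profiles.tsv"))
    result$counts <- counts
    result$profiles <- profiles
    tri <- plan$signal$tri_factor
    if (!is.null(tri)) {
      pm <- profiles$experiments
      corr_all <- list()
      for (cx in unique(pm$context)) {
        tri_col <- which(pm$factor == tri & pm$context == cx)
        others <- which(pm$factor != tri & pm$context == cx)
        if (length(tri_col) != 1L || length(others) == 0L) next
        ct <- correlate_profiles(profiles, tri_col, others)
        long <- data.frame(
          site_id = rep(rownames(ct$r), ncol(ct$r)),
          factor = rep(pm$factor[others], each = nrow(ct$r)),
          context = cx,
          r = as.vector(ct$r),
          stringsAsFactors = FALSE)
        corr_all[[cx]] <- long
      }
      if (length(corr_all) > 0L) {
        corr_df <- do.call(rbind, corr_all)
        rownames(corr_df) <- NULL
        write_tsv(corr_df, emit("correlations.tsv"))
        # subset means per context x factor x class
        site_cls <- classing$table$class[
          match(corr_df$site_id, classing$table$site_id)]
        agg <- stats::aggregate(
          r ~ context + factor + class,
          data = cbind(corr_df, class = site_cls),
          FUN = function(v) mean(v, na.rm = TRUE), na.action = stats::na.pass)
        nvalid <- stats::aggregate(
          r ~ context + factor + class,
          data = cbind(corr_df, class = site_cls),
          FUN = function(v) sum(!is.na(v)), na.action = stats::na.pass)
        agg$n_valid <- nvalid$r
        colnames(agg)[colnames(agg) == "r"] <- "mean_r"
        agg <- agg[order(agg$context, agg$factor, agg$class), ]
        write_tsv(agg, emit("correlation_summary.tsv"))
        result$correlations <- corr_df
      }
    }
  }

  ## -- feature-overlap arm --------------------------------------------
  if (!is.null(plan$features)) {
    groups <- lapply(plan$features$groups, function(ps)
      lapply(unlist(ps), read_peaks))
    ms <- unlist(plan$features$min_support)
    if (is.null(ms)) ms <- integer()
    ann <- annotate_overlap(build$reference$intervals, groups,
                            min_support = ms)
    df <- data.frame(site_id = paste0("site_",
                                      seq_len(nrow(ann$hits))),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(ann$hits))
    write_tsv(df, emit("feature_overlap.tsv"))
    write_tsv(data.frame(group = names(ann$fractions),
                         fraction = as.numeric(ann$fractions),
                         min_support = as.integer(ann$min_support),
                         stringsAsFactors = FALSE),
              emit("feature_fractions.tsv"))
    result$overlap <- ann
  }

  ## -- chromatin-state arm --------------------------------------------
  if (!is.null(plan$segmentation)) {
    seg <- read_segmentation(plan_path(plan, plan$segmentation),
                             layout = layout)
    states <- assign_majority_state(build$reference$intervals, seg)
    write_tsv(cbind(classing$table[, c("site_id", "chrom", "start", "end",
                                       "class")],
                    data.frame(state = states, stringsAsFactors = FALSE)),
              emit("site_states.tsv"))
    fr <- state_fractions(build$reference$intervals, seg,
                          groups = classing$table$class)
    write_tsv(fr, emit("class_state_fractions.tsv"))
    feats <- c(
      list(reference = build$reference$intervals),
      stats::setNames(
        lapply(names(build$context_cistromes),
               function(cx) build$context_cistromes[[cx]]),
        names(build$context_cistromes)))
    enr <- state_enrichment(seg, feats)
    enr_df <- data.frame(feature = rownames(enr$ratio),
                         stringsAsFactors = FALSE)
    for (st in colnames(enr$ratio)) {
      enr_df[[paste0("ratio_", st)]] <- enr$ratio[, st]
      enr_df[[paste0("z_", st)]] <- enr$z[, st]
    }
    write_tsv(enr_df, emit("state_enrichment.tsv"))
    result$segmentation <- seg
    result$enrichment <- enr
  }

  ## -- manifest --------------------------------------------------------
  manifest <- list(
    schema_version = "1.0",
    package = "cistromekit",
    package_version = as.character(utils::packageVersion("cistromekit")),
    seed = seed,
    parameters = list(
      context_tau = ctx_tau, context_tau_mode = ctx_mode,
      drop_chroms = if (is.null(drop_chroms)) list() else drop_chroms),
    contexts = names(plan$cistrome$contexts),
    n_reference_sites = length(build$reference$intervals),
    outputs = sort(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
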