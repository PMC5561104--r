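# Build a small self-contained fixture directory with simulated inputs and
# a full plan, returning the plan path.
make_fixture_dir <- function(dir, seed = 5) {
  lay <- toy_genome(2, 3e5)
  write_chrom_sizes(lay, file.path(dir, "genome.chrom.sizes"))
  truth <- simulate_truth(lay, 60, seed = seed)
  studies <- simulate_studies(truth, lay, n_studies = 4, sensitivity = 0.9,
                              noise_per_study = 10, jitter_sd = 5,
                              seed = seed)
  for (nm in names(studies)) {
    write_bed(studies[[nm]], file.path(dir, paste0(nm, ".bed")))
  }
  # reads: place one synthetic read at each truth-site center per "factor"
  centers <- floor((start(truth) - 1 + end(truth)) / 2)
  reads <- gr0(as.character(seqnames(truth)), centers, centers + 1)
  write_bed(reads, file.path(dir, "reads_tri.bed"))
  write_bed(reads, file.path(dir, "reads_cof.bed"))
  sim_seg <- simulate_segmentation(lay, block_size = 1000, seed = seed)
  write_segmentation(sim_seg$segmentation, file.path(dir, "seg.bed"))
  write_bed(sim_seg$features, file.path(dir, "features.bed"))
  plan <- list(
    genome = "genome.chrom.sizes",
    seed = 11,
    cistrome = list(
      context_tau = 0.75,
      contexts = list(
        ctxA = list(s1 = list("study_1.bed"), s2 = list("study_2.bed")),
        ctxB = list(s3 = list("study_3.bed"), s4 = list("study_4.bed")))),
    calibrate = list(n_reps = 5),
    signal = list(
      half_window = 500, bin_size = 50,
      experiments = list(
        list(label = "tri_a", factor = "TRI", context = "ctxA",
             reads = "reads_tri.bed"),
        list(label = "cof_a", factor = "COF", context = "ctxA",
             reads = "reads_cof.bed")),
      tri_factor = "TRI"),
    features = list(groups = list(feat = list("features.bed"))),
    segmentation = "seg.bed")
  yaml::write_yaml(plan, file.path(dir, "plan.yaml"))
  file.path(dir, "plan.yaml")
}

test_that("a minimal cistrome-only plan produces reference, classes, manifest", {
  d <- withr::local_tempdir()
  plan_path <- make_fixture_dir(d)
  plan <- read_plan(plan_path)
  plan$signal <- NULL; plan$features <- NULL
  plan$segmentation <- NULL; plan$calibrate <- NULL
  out <- file.path(d, "out_min")
  res <- run_plan(plan, out)
  expect_true(file.exists(file.path(out, "reference.bed")))
  expect_true(file.exists(file.path(out, "classes.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$n_reference_sites,
               length(res$build$reference$intervals))
  cls <- read.delim(file.path(out, "classes.tsv"))
  expect_equal(nrow(cls), man$n_reference_sites)
})

test_that("plan validation enumerates all problems before computing", {
  plan <- list(genome = "missing.sizes",
               cistrome = list(contexts = list(
                 c1 = list(s1 = list("absent.bed")))))
  err <- tryCatch(run_plan(plan, withr::local_tempdir()),
                  error = conditionMessage)
  expect_match(err, "validation failed")
  expect_match(err, "missing.sizes")
  expect_match(err, "absent.bed")
})

test_that("a full plan on simulated fixtures yields schema-valid outputs, byte-identical on rerun", {
  d <- withr::local_tempdir()
  plan_path <- make_fixture_dir(d)
  plan <- read_plan(plan_path)
  out1 <- file.path(d, "out1"); out2 <- file.path(d, "out2")
  suppressWarnings(suppressMessages(run_plan(plan, out1)))
  expected <- c("reference.bed", "context_ctxA.bed", "context_ctxB.bed",
                "classes.tsv", "calibration_ctxA.tsv",
                "calibration_ctxB.tsv", "counts.tsv", "profiles.tsv",
                "correlations.tsv", "correlation_summary.tsv",
                "feature_overlap.tsv", "feature_fractions.tsv",
                "site_states.tsv", "class_state_fractions.tsv",
                "state_enrichment.tsv", "manifest.json")
  for (f in expected) expect_true(file.exists(file.path(out1, f)),
                                  label = paste("exists:", f))
  # schema spot checks
  cls <- read.delim(file.path(out1, "classes.tsv"))
  expect_true(all(c("site_id", "chrom", "start", "end", "class") %in%
                    colnames(cls)))
  corr <- read.delim(file.path(out1, "correlations.tsv"))
  expect_true(all(c("site_id", "factor", "context", "r") %in%
                    colnames(corr)))
  calib <- read.delim(file.path(out1, "calibration_ctxA.tsv"))
  expect_true(all(c("tau", "observed_n", "rand_mean_n") %in%
                    colnames(calib)))
  # rerun: byte-identical outputs
  suppressWarnings(suppressMessages(run_plan(plan, out2)))
  for (f in expected) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = paste("identical:", f))
  }
})

test_that("CLI subcommands wrap the package functions end to end", {
  d <- withr::local_tempdir()
  lay <- toy_genome(1, 1e5)
  write_chrom_sizes(lay, file.path(d, "g.sizes"))
  a <- gr0("chr1", c(10, 500), c(200, 700))
  b <- gr0("chr1", 100, 600)
  write_bed(a, file.path(d, "a.bed"))
  write_bed(b, file.path(d, "b.bed"))
  out <- file.path(d, "ref.bed")
  status <- suppressMessages(cli_main(c(
    "refgen", "--inputs", file.path(d, "a.bed"),
    "--inputs", file.path(d, "b.bed"),
    "--tau", "2", "--genome", file.path(d, "g.sizes"), "--out", out)))
  expect_equal(status, 0L)
  got <- read_bed(out)
  expect_equal(bed0(got)[, c("s0", "e0")],
               data.frame(s0 = c(100, 500), e0 = c(200, 600)))

  # classify via CLI
  cls_out <- file.path(d, "classes.tsv")
  status <- suppressMessages(cli_main(c(
    "classify", "--reference", out,
    "--context", paste0("A=", file.path(d, "a.bed")),
    "--context", paste0("B=", file.path(d, "b.bed")),
    "--out", cls_out)))
  expect_equal(status, 0L)
  expect_equal(read.delim(cls_out)$class, c("C2", "C2"))

  # simulate fixture writer
  fix <- file.path(d, "fix")
  status <- suppressMessages(cli_main(c(
    "simulate", "--outdir", fix, "--seed", "3", "--n-sites", "30",
    "--n-studies", "3")))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(fix, "truth.bed")))
  expect_true(file.exists(file.path(fix, "manifest.json")))

  # usage / bad input paths return status 2
  expect_equal(suppressMessages(cli_main(character())), 2L)
  expect_equal(suppressMessages(cli_main(c("nope"))), 2L)
  expect_equal(suppressMessages(cli_main(c("refgen", "--tau", "1"))), 2L)
})

test_that("the installed CLI script is present and executable metadata intact", {
  script <- system.file("cli", "refchip", package = "cistromekit")
  expect_true(nzchar(script))
  first <- readLines(script, n = 1)
  expect_match(first, "Rscript")
})
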